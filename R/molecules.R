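#' Construct a heavy-atom molecule graph
#'
#' Molecules are represented as connected, element-labeled graphs over
#' heavy atoms (H suppressed), with bond orders retained for pi-electron
#' counting. Self-bonds and disconnected graphs are rejected.
#'
#' @param atoms Named character vector of element symbols; names are atom
#'   labels (e.g. PDB-style `CA`, `CB`).
#' @param bonds List of `c(label_a, label_b, order)` triples (order 1-3).
#' @param name Molecule name.
#' @param ref Reference (database accession) number, if any.
#' @return Object of class `molecule_graph` with fields `el` (elements),
#'   `adj` (logical adjacency), `ord` (integer bond orders), `n`,
#'   `labels`, `name`, `ref`.
#' @export
#' @examples
#' eth <- molecule_graph(c(C1 = "C", C2 = "C"), list(c("C1", "C2", 1)))
#' eth$n  # 2
molecule_graph <- function(atoms, bonds, name = "", ref = NA) {
  n <- length(atoms)
  if (!n) stop("molecule must contain at least one atom")
  labels <- names(atoms)
  if (is.null(labels) || anyDuplicated(labels)) {
    stop("atoms must be uniquely named")
  }
  ord <- matrix(0L, n, n, dimnames = list(labels, labels))
  for (b in bonds) {
    if (b[1] == b[2]) stop("self-bond on atom ", b[1])
    o <- as.integer(b[3])
    ord[b[1], b[2]] <- o
    ord[b[2], b[1]] <- o
  }
  adj <- ord > 0L
  if (n > 1) {
    # connectivity check by BFS from atom 1
    seen <- logical(n); seen[1] <- TRUE; q <- 1L
    while (length(q)) {
      v <- q[1]; q <- q[-1]
      nb <- which(adj[v, ] & !seen)
      seen[nb] <- TRUE; q <- c(q, nb)
    }
    if (!all(seen)) stop("molecule graph is disconnected")
  }
  structure(list(el = unname(atoms), adj = adj, ord = ord, n = n,
                 labels = labels, name = name, ref = ref),
            class = "molecule_graph")
}

#' @export
print.molecule_graph <- function(x, ...) {
  cat("Molecule", if (nzchar(x$name)) paste0("'", x$name, "'") else "",
      ": ", x$n, " heavy atoms (",
      paste(names(table(x$el)), table(x$el), sep = ":", collapse = " "),
      "), ", sum(x$adj) / 2, " bonds\n", sep = "")
  invisible(x)
}

# backbone shared by all encoded amino acids (neutral form):
# N-CA, CA-C, C=O, C-OXT(H), CA-CB
aa_backbone <- function(side_atoms, side_bonds) {
  atoms <- c(N = "N", CA = "C", C = "C", O = "O", OXT = "O", CB = "C",
             side_atoms)
  bonds <- c(list(c("N", "CA", 1), c("CA", "C", 1), c("C", "O", 2),
                  c("C", "OXT", 1), c("CA", "CB", 1)), side_bonds)
  list(atoms = atoms, bonds = bonds)
}

# Kekule connection tables of the eight panel amino acids (heavy atoms,
# neutral forms, PDB atom naming). Aromatic rings use alternating single/
# double bonds; per-atom pi-electron counts are independent of the Kekule
# choice for these molecules.
aa_structure_tables <- function() {
  list(
    M = aa_backbone(c(CG = "C", SD = "S", CE = "C"),
      list(c("CB", "CG", 1), c("CG", "SD", 1), c("SD", "CE", 1))),
    L = aa_backbone(c(CG = "C", CD1 = "C", CD2 = "C"),
      list(c("CB", "CG", 1), c("CG", "CD1", 1), c("CG", "CD2", 1))),
    I = aa_backbone(c(CG1 = "C", CG2 = "C", CD1 = "C"),
      list(c("CB", "CG1", 1), c("CB", "CG2", 1), c("CG1", "CD1", 1))),
    H = aa_backbone(c(CG = "C", ND1 = "N", CD2 = "C", CE1 = "C",
                      NE2 = "N"),
      list(c("CB", "CG", 1), c("CG", "CD2", 2), c("CG", "ND1", 1),
           c("ND1", "CE1", 1), c("CE1", "NE2", 2), c("NE2", "CD2", 1))),
    K = aa_backbone(c(CG = "C", CD = "C", CE = "C", NZ = "N"),
      list(c("CB", "CG", 1), c("CG", "CD", 1), c("CD", "CE", 1),
           c("CE", "NZ", 1))),
    R = aa_backbone(c(CG = "C", CD = "C", NE = "N", CZ = "C", NH1 = "N",
                      NH2 = "N"),
      list(c("CB", "CG", 1), c("CG", "CD", 1), c("CD", "NE", 1),
           c("NE", "CZ", 1), c("CZ", "NH1", 2), c("CZ", "NH2", 1))),
    F = aa_backbone(c(CG = "C", CD1 = "C", CD2 = "C", CE1 = "C",
                      CE2 = "C", CZ = "C"),
      list(c("CB", "CG", 1), c("CG", "CD1", 2), c("CD1", "CE1", 1),
           c("CE1", "CZ", 2), c("CZ", "CE2", 1), c("CE2", "CD2", 2),
           c("CD2", "CG", 1))),
    W = aa_backbone(c(CG = "C", CD1 = "C", NE1 = "N", CD2 = "C",
                      CE2 = "C", CE3 = "C", CZ3 = "C", CH2 = "C",
                      CZ2 = "C"),
      list(c("CB", "CG", 1), c("CG", "CD1", 2), c("CD1", "NE1", 1),
           c("NE1", "CE2", 1), c("CE2", "CD2", 1), c("CD2", "CG", 1),
           c("CD2", "CE3", 2), c("CE3", "CZ3", 1), c("CZ3", "CH2", 2),
           c("CH2", "CZ2", 1), c("CZ2", "CE2", 2)))
  )
}

# Reference numbers as printed in the source material. Note: 6106 is
# L-leucine and 6306 is L-isoleucine in the reference database, i.e. the
# printed list assigns I and L the transposed accessions; see aa_molecules().
AA_PRINTED_REFS <- c(M = 6137, L = 6306, I = 6106, H = 6274, K = 5962,
                     R = 6322, F = 6140, W = 6305)
AA_NAMES <- c(M = "L-methionine", L = "L-leucine", I = "L-isoleucine",
              H = "L-histidine", K = "L-lysine", R = "L-arginine",
              F = "L-phenylalanine", W = "L-tryptophan")

#' The amino-acid stimulus panel as molecule graphs
#'
#' Returns the eight panel amino acids as heavy-atom [molecule_graph()]s
#' (neutral forms, in-package connection tables).
#'
#' The reference-number list accompanying the similarity analysis assigns
#' accession 6306 to "L" and 6106 to "I", which is transposed relative to
#' the standard database (6306 is L-isoleucine, 6106 is L-leucine). With
#' `assignment = "identity"` (default) each code carries the structure of
#' the amino acid it names; with `assignment = "as_printed"` the codes L
#' and I carry the structures their printed accession numbers actually
#' resolve to (i.e. swapped), reproducing the similarity scores computed
#' from that list. See [ap_reference_report()].
#'
#' @param assignment `"identity"` or `"as_printed"`.
#' @return Named list of 8 `molecule_graph`s in panel order.
#' @export
#' @examples
#' vapply(aa_molecules(), `[[`, 0L, "n")  # heavy-atom counts
aa_molecules <- function(assignment = c("identity", "as_printed")) {
  assignment <- match.arg(assignment)
  tabs <- aa_structure_tables()
  if (assignment == "as_printed") {
    tabs[c("L", "I")] <- tabs[c("I", "L")]
  }
  out <- lapply(GLOMAP_PANEL, function(code) {
    molecule_graph(tabs[[code]]$atoms, tabs[[code]]$bonds,
                   name = AA_NAMES[[code]], ref = AA_PRINTED_REFS[[code]])
  })
  names(out) <- GLOMAP_PANEL
  out
}

#' Convert an SDF/MOL record to a molecule graph
#'
#' Accepts a `ChemmineR::SDF` object (read with `ChemmineR::read.SDFset`
#' or built from SMILES via `ChemmineR::smiles2sdf`); hydrogens are
#' dropped.
#'
#' @param sdf A `ChemmineR` SDF object.
#' @param name Molecule name.
#' @return A [molecule_graph()].
#' @export
as_molecule_graph <- function(sdf, name = "") {
  if (!requireNamespace("ChemmineR", quietly = TRUE)) {
    stop("reading SDF/MOL input requires the ChemmineR package")
  }
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  el <- sub("_.*$", "", rownames(ab))
  heavy <- which(el != "H")
  atoms <- setNames(el[heavy], paste0(el[heavy], seq_along(heavy)))
  remap <- match(seq_along(el), heavy)
  bonds <- list()
  for (i in seq_len(nrow(bb))) {
    a <- remap[bb[i, 1]]; b <- remap[bb[i, 2]]
    if (is.na(a) || is.na(b)) next
    bonds[[length(bonds) + 1L]] <- c(names(atoms)[a], names(atoms)[b],
                                     bb[i, 3])
  }
  molecule_graph(atoms, bonds, name = name)
}
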