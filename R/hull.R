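#' Volume of the 3D convex hull of a point set
#'
#' Exact convex-hull volume by supporting-plane enumeration: every triple
#' of points whose plane has all remaining points on one side contributes
#' a hull facet; coplanar facet points are merged into one face polygon
#' (ordered with the planar convex hull), and the volume is assembled as
#' the sum of tetrahedra from an interior point to the triangulated faces.
#' Intended for the small point sets of dendritic tuft clusters, where the
#' cubic enumeration is exact and fast.
#'
#' Degenerate inputs (fewer than 4 points, or all points coplanar or
#' collinear) have zero volume and are flagged rather than treated as
#' errors.
#'
#' @param points n x 3 coordinate matrix.
#' @return List with `volume` (um^3) and `degenerate` (logical).
#' @export
#' @examples
#' cube <- as.matrix(expand.grid(0:1, 0:1, 0:1))
#' convex_hull_volume(cube)$volume  # 1
convex_hull_volume <- function(points) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < 4) return(list(volume = 0, degenerate = TRUE))
  scale <- max(1, max(abs(points)))
  tol <- 1e-9 * scale

  ctr <- colMeans(points)
  p <- sweep(points, 2, ctr)

  seen_planes <- character(0)
  volume <- 0
  degenerate <- TRUE
  for (tri in utils::combn(n, 3, simplify = FALSE)) {
    a <- p[tri[1], ]; b <- p[tri[2], ]; cc <- p[tri[3], ]
    nrm <- c((b[2] - a[2]) * (cc[3] - a[3]) - (b[3] - a[3]) * (cc[2] - a[2]),
             (b[3] - a[3]) * (cc[1] - a[1]) - (b[1] - a[1]) * (cc[3] - a[3]),
             (b[1] - a[1]) * (cc[2] - a[2]) - (b[2] - a[2]) * (cc[1] - a[1]))
    nn <- sqrt(sum(nrm^2))
    if (nn < tol^2) next  # collinear triple
    nrm <- nrm / nn
    s <- as.numeric(p %*% nrm) - sum(nrm * a)
    if (all(abs(s) <= tol)) next  # the whole set is coplanar
    if (all(s <= tol)) {
      face_normal <- nrm
    } else if (all(s >= -tol)) {
      face_normal <- -nrm
      s <- -s
    } else next
    degenerate <- FALSE
    # canonical plane key so each facet plane is integrated once
    off <- sum(face_normal * a)
    key <- paste(signif(c(face_normal, off), 9), collapse = ",")
    if (key %in% seen_planes) next
    seen_planes <- c(seen_planes, key)

    on_plane <- which(abs(s) <= tol)
    # order the face polygon in its own plane
    e1 <- b - a; e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(face_normal[2] * e1[3] - face_normal[3] * e1[2],
            face_normal[3] * e1[1] - face_normal[1] * e1[3],
            face_normal[1] * e1[2] - face_normal[2] * e1[1])
    uv <- cbind(p[on_plane, , drop = FALSE] %*% e1,
                p[on_plane, , drop = FALSE] %*% e2)
    h <- chull(uv)
    poly <- on_plane[h]
    # fan triangulation; the interior point (origin) closes each tetra
    for (k in 2:(length(poly) - 1)) {
      v1 <- p[poly[1], ]; v2 <- p[poly[k], ]; v3 <- p[poly[k + 1], ]
      volume <- volume + abs(
        v1[1] * (v2[2] * v3[3] - v2[3] * v3[2]) -
        v1[2] * (v2[1] * v3[3] - v2[3] * v3[1]) +
        v1[3] * (v2[1] * v3[2] - v2[2] * v3[1])) / 6
    }
  }
  if (degenerate) return(list(volume = 0, degenerate = TRUE))
  list(volume = as.numeric(volume), degenerate = FALSE)
}
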