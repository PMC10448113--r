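#' Statistical test result container
#'
#' Light wrapper shared by the testing helpers: test name, statistic,
#' p-value, group sizes and (for post-hoc tables) the adjustment method.
#'
#' @param test Test name.
#' @param statistic Test statistic.
#' @param p Raw or adjusted p-value in `[0, 1]`.
#' @param n Group sizes.
#' @param adjust Adjustment method, if any.
#' @param extra Named list of extra fields merged into the result.
#' @return Object of class `glomap_test`.
#' @keywords internal
glomap_test <- function(test, statistic, p, n, adjust = "none",
                        extra = list()) {
  stopifnot(p >= 0, p <= 1)
  structure(c(list(test = test, statistic = unname(statistic),
                   p = unname(p), n = n, adjust = adjust), extra),
            class = "glomap_test")
}

#' @export
print.glomap_test <- function(x, ...) {
  cat(x$test, ": statistic = ", signif(x$statistic, 4),
      ", p = ", signif(x$p, 4), " ", significance_marker(x$p),
      " (n = ", paste(x$n, collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Significance markers
#'
#' Figure-convention markers: `***` for p <= 0.001, `*` for p <= 0.05,
#' `ns` otherwise.
#'
#' @param p p-value(s).
#' @return Character vector.
#' @export
significance_marker <- function(p) {
  ifelse(p <= 0.001, "***", ifelse(p <= 0.05, "*", "ns"))
}

#' Shapiro-Wilk normality test
#'
#' @param x Numeric sample (n >= 3).
#' @return A `glomap_test`.
#' @export
normality <- function(x) {
  if (length(x) < 3) stop("normality test needs at least 3 observations")
  sw <- shapiro.test(x)
  glomap_test("Shapiro-Wilk", sw$statistic, sw$p.value, length(x))
}

#' Kruskal-Wallis omnibus test
#'
#' Two-sided comparison between more than two groups.
#'
#' @param groups List of >= 2 numeric vectors.
#' @return A `glomap_test`.
#' @export
omnibus_kw <- function(groups) {
  if (length(groups) < 2) stop("Kruskal-Wallis needs at least 2 groups")
  kw <- kruskal.test(groups)
  glomap_test("Kruskal-Wallis", kw$statistic, kw$p.value,
              vapply(groups, length, 0L))
}

#' Dunn post-hoc tests with Bonferroni correction
#'
#' All pairwise comparisons following a Kruskal-Wallis test: z statistics
#' on the mean ranks of the pooled sample with tie correction, two-sided
#' normal p-values, Bonferroni-adjusted over the k(k-1)/2 comparisons
#' (`p_adj = min(1, p * m)`, monotone in the raw p).
#'
#' @param groups Named list of >= 2 numeric vectors.
#' @return data.frame: group_a, group_b, z, p, p_adj, marker.
#' @export
posthoc_dunn <- function(groups) {
  k <- length(groups)
  if (k < 2) stop("post-hoc comparisons need at least 2 groups")
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_len(k))
  x <- unlist(groups, use.names = FALSE)
  g <- rep(names(groups), vapply(groups, length, 0L))
  N <- length(x)
  rk <- rank(x)
  mean_rank <- tapply(rk, g, mean)[names(groups)]
  n <- vapply(groups, length, 0L)
  ties <- table(rk)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  m <- k * (k - 1) / 2
  rows <- lapply(utils::combn(k, 2, simplify = FALSE), function(ij) {
    i <- ij[1]; j <- ij[2]
    se <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / n[i] + 1 / n[j]))
    z <- (mean_rank[i] - mean_rank[j]) / se
    p <- 2 * pnorm(-abs(z))
    data.frame(group_a = names(groups)[i], group_b = names(groups)[j],
               z = unname(z), p = unname(p),
               p_adj = min(1, unname(p) * m))
  })
  out <- do.call(rbind, rows)
  out$marker <- significance_marker(out$p_adj)
  attr(out, "adjust") <- "bonferroni"
  out
}

#' Mann-Whitney U test between two groups
#'
#' Exact distribution for small groups (both n <= 8 and no ties), normal
#' approximation with tie and continuity correction otherwise.
#'
#' @param a,b Numeric samples (non-empty).
#' @return A `glomap_test`.
#' @export
two_group <- function(a, b) {
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  exact <- max(length(a), length(b)) <= 8 &&
    !anyDuplicated(c(a, b))
  wt <- suppressWarnings(wilcox.test(a, b, exact = exact))
  glomap_test("Mann-Whitney U", wt$statistic, wt$p.value,
              c(length(a), length(b)))
}

#' OLS slope test
#'
#' Ordinary least squares of y on x with the two-sided t test of
#' H0: slope = 0.
#'
#' @param x Predictor (must not be constant).
#' @param y Response.
#' @return A `glomap_test` with extra fields `slope`, `intercept`,
#'   `r_squared`.
#' @export
#' @examples
#' ols_slope_test(1:10, 2 * (1:10))$slope  # 2
ols_slope_test <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(x) < 3) stop("need at least 3 points")
  if (sd(x) == 0) stop("constant predictor: slope test undefined")
  fit <- lm(y ~ x)
  # summary.lm warns on zero-residual fits; that case is handled below
  sm <- suppressWarnings(summary(fit))
  co <- sm$coefficients
  # an exact linear relation has zero residual variance; the slope is then
  # significant at any level
  if (!is.finite(co["x", "Pr(>|t|)"])) {
    co["x", "Pr(>|t|)"] <- 0
    co["x", "t value"] <- sign(co["x", "Estimate"]) * Inf
  }
  glomap_test("OLS slope (t)", co["x", "t value"], co["x", "Pr(>|t|)"],
              length(x),
              extra = list(slope = co["x", "Estimate"],
                           intercept = co["(Intercept)", "Estimate"],
                           r_squared = sm$r.squared))
}
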