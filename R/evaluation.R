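#' Distance from a point to a sampled path
#'
#' Minimum Euclidean distance from `x` to the path's sampled points.
#' Paths are densely sampled (step ~0.1 mm), so the sampling error is at
#' most half a step and no segment interpolation is performed.
#'
#' @param x world-mm point.
#' @param c a [centerline] or point matrix.
#' @return Distance in mm.
#' @export
point_to_path <- function(x, c) {
  pts <- if (inherits(c, "centerline")) c$points else as.matrix(c)
  sqrt(min(colSums((t(pts) - as.numeric(x))^2)))
}

#' Hausdorff distance between two sampled curves
#'
#' Symmetric bidirectional max-min distance over the sampled points:
#' \deqn{H(C_A, C_B) = \max\{\max_{x \in C_A} D(x, C_B),
#'   \max_{y \in C_B} D(y, C_A)\}.}
#'
#' @param cA,cB [centerline]s or point matrices.
#' @return Distance in mm.
#' @export
hausdorff <- function(cA, cB) {
  a <- if (inherits(cA, "centerline")) cA$points else as.matrix(cA)
  b <- if (inherits(cB, "centerline")) cB$points else as.matrix(cB)
  max(directed_hausdorff(a, b), directed_hausdorff(b, a))
}

directed_hausdorff <- function(a, b) {
  # max over rows of a of min distance to rows of b; per-coordinate
  # differences (no sum-of-squares expansion, so identical points give
  # exactly zero), blocked to bound memory on long curves
  n <- nrow(a)
  block <- 1024L
  worst <- 0
  for (s in seq(1L, n, by = block)) {
    e <- min(s + block - 1L, n)
    ab <- a[s:e, , drop = FALSE]
    d2 <- outer(ab[, 1], b[, 1], "-")^2 +
      outer(ab[, 2], b[, 2], "-")^2 +
      outer(ab[, 3], b[, 3], "-")^2
    worst <- max(worst, sqrt(max(apply(d2, 1, min))))
  }
  worst
}

#' Centerline artery distance between automatic and manual centerlines
#'
#' Per-branch Hausdorff distance between the automatic and the manual
#' centerline, summarized by their maximum (the centerline artery
#' distance, CAD). A detection is flagged as failed when the CAD
#' strictly exceeds `threshold` (default 3.5 mm, about the mean carotid
#' artery radius, so a failed centerline is likely outside the vessel).
#'
#' @param auto_ica,auto_eca automatic branch [centerline]s.
#' @param manual_ica,manual_eca manual branch [centerline]s (resampled
#'   at the extraction step size; see [resample_path()]).
#' @param threshold failure threshold, mm.
#' @return An object of class `evaluation_report`: list with `H_ica`,
#'   `H_eca`, `CAD`, `failed`, `threshold`.
#' @export
cad <- function(auto_ica, auto_eca, manual_ica, manual_eca,
                threshold = 3.5) {
  h_i <- hausdorff(auto_ica, manual_ica)
  h_e <- hausdorff(auto_eca, manual_eca)
  v <- max(h_i, h_e)
  structure(list(H_ica = h_i, H_eca = h_e, CAD = v,
                 failed = v > threshold, threshold = threshold),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("H(ICA) = %.3f mm, H(ECA) = %.3f mm, CAD = %.3f mm [%s]\n",
              x$H_ica, x$H_eca, x$CAD,
              if (x$failed) "FAILED" else "ok"))
  invisible(x)
}

#' Leave-one-out selection of the smoothing constant
#'
#' For each held-out case, the smoothing value is chosen on the
#' remaining cases as the one with the fewest failures (CAD above
#' `threshold`); ties are broken by the lowest mean CAD, then by the
#' smallest smoothing value.
#'
#' @param cad_table numeric matrix of CAD values, cases in rows,
#'   smoothing values in columns; must be complete (no `NA`).
#' @param grid the smoothing values corresponding to the columns.
#' @param threshold failure threshold, mm.
#' @return Numeric vector: the selected smoothing value per case.
#' @export
select_omega_loo <- function(cad_table, grid = 0:10, threshold = 3.5) {
  cad_table <- as.matrix(cad_table)
  if (any(!is.finite(cad_table))) stop("'cad_table' must be complete")
  if (ncol(cad_table) != length(grid))
    stop("'grid' length must match the number of columns")
  n <- nrow(cad_table)
  if (n < 2L) stop("need at least two cases for leave-one-out")
  vapply(seq_len(n), function(i) {
    train <- cad_table[-i, , drop = FALSE]
    fails <- colSums(train > threshold)
    means <- colMeans(train)
    best <- order(fails, means, grid)[1L]
    grid[best]
  }, numeric(1))
}

#' Exact McNemar test on paired failure counts
#'
#' Two-sided exact binomial test on the discordant pairs: `b` cases
#' where only the first method failed and `c` where only the second
#' did. Under the null the discordant failures split Binomial(b + c,
#' 1/2); the p-value is twice the smaller tail, capped at 1. With no
#' discordant pairs the methods are indistinguishable and p = 1.
#'
#' @param b,c non-negative discordant counts.
#' @return The exact two-sided p-value.
#' @examples
#' mcnemar_exact(0, 5)  # 2 * 0.5^5 = 0.0625
#' @export
mcnemar_exact <- function(b, c) {
  if (b < 0 || c < 0 || b != round(b) || c != round(c))
    stop("'b' and 'c' must be non-negative integers")
  n <- b + c
  if (n == 0) return(1)
  min(1, 2 * stats::pbinom(min(b, c), n, 0.5))
}
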