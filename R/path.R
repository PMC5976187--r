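#' Centerline paths
#'
#' A `centerline` is an ordered polyline of world-mm points with a nominal
#' arc spacing `step` (the backtracking step size, mm). Consecutive points
#' are never further apart than `2 * step`.
#'
#' @param points n x 3 numeric matrix of world-mm points, n >= 2.
#' @param step nominal arc spacing in mm (> 0).
#' @return An object of class `centerline`.
#' @export
centerline <- function(points, step = 0.1) {
  points <- as.matrix(points)
  if (!is.numeric(points) || ncol(points) != 3L || nrow(points) < 2L)
    stop("'points' must be a numeric n x 3 matrix with n >= 2")
  if (!all(is.finite(points))) stop("'points' must be finite")
  step <- as.numeric(step)
  if (length(step) != 1L || !is.finite(step) || step <= 0)
    stop("'step' must be a single positive number")
  dimnames(points) <- NULL
  structure(list(points = points, step = step), class = "centerline")
}

#' @export
print.centerline <- function(x, ...) {
  cat(sprintf("<centerline> %d points, step %g mm, length %.2f mm\n",
              nrow(x$points), x$step, path_length(x)))
  invisible(x)
}

#' Arc length of a path
#'
#' Sum of Euclidean distances between consecutive points, in mm.
#'
#' @param p a [centerline] or an n x 3 point matrix.
#' @return Total length in mm.
#' @examples
#' path_length(centerline(rbind(c(0, 0, 0), c(3, 4, 0))))  # 5
#' @export
path_length <- function(p) {
  pts <- if (inherits(p, "centerline")) p$points else as.matrix(p)
  sum(seg_lengths(pts))
}

seg_lengths <- function(pts) {
  n <- nrow(pts)
  if (n < 2L) return(numeric(0))
  d <- pts[-1L, , drop = FALSE] - pts[-n, , drop = FALSE]
  sqrt(rowSums(d * d))
}

# cumulative arc position of each point, starting at 0
arc_positions <- function(pts) c(0, cumsum(seg_lengths(pts)))

#' Resample a point sequence at uniform arc spacing
#'
#' Fits a natural cubic spline through the input points, parameterized by
#' chord length, and returns points at (approximately) uniform arc spacing
#' `step`. Endpoints are preserved exactly. This is the resampling applied
#' to manually annotated centerlines before evaluation, and to any sparse
#' polyline before distance computations.
#'
#' @param points n x 3 matrix of world-mm points (n >= 2, not all equal).
#' @param step target arc spacing in mm.
#' @return A [centerline] with `step = step`.
#' @export
resample_path <- function(points, step = 0.1) {
  points <- as.matrix(points)
  if (nrow(points) < 2L) stop("need at least 2 points to resample")
  if (step <= 0) stop("'step' must be positive")
  # drop consecutive duplicates (zero chords break the parameterization)
  keep <- c(TRUE, seg_lengths(points) > 1e-12)
  points <- points[keep, , drop = FALSE]
  if (nrow(points) < 2L) stop("input points are all coincident")
  t_in <- arc_positions(points)
  # dense evaluation of the spline, then arc-length reparameterization
  n_dense <- max(200L, as.integer(ceiling(t_in[length(t_in)] / (step / 5))))
  t_dense <- seq(0, t_in[length(t_in)], length.out = n_dense)
  dense <- vapply(1:3, function(j) {
    if (nrow(points) == 2L)
      # spline through 2 points is the straight segment
      points[1L, j] + (points[2L, j] - points[1L, j]) *
        t_dense / t_in[2L]
    else
      stats::spline(t_in, points[, j], xout = t_dense,
                    method = "natural")$y
  }, numeric(n_dense))
  s_dense <- arc_positions(dense)
  total <- s_dense[n_dense]
  n_out <- max(2L, as.integer(round(total / step)) + 1L)
  s_out <- seq(0, total, length.out = n_out)
  out <- vapply(1:3, function(j)
    stats::approx(s_dense, dense[, j], xout = s_out, ties = "ordered")$y,
    numeric(n_out))
  out[1L, ] <- points[1L, ]
  out[n_out, ] <- points[nrow(points), ]
  centerline(out, step = step)
}

# point on a polyline at a given arc position (linear interpolation)
point_at_arc <- function(pts, s) {
  pos <- arc_positions(pts)
  total <- pos[length(pos)]
  s <- min(max(s, 0), total)
  i <- findInterval(s, pos, rightmost.closed = TRUE)
  i <- min(max(i, 1L), nrow(pts) - 1L)
  seg <- pos[i + 1L] - pos[i]
  w <- if (seg > 0) (s - pos[i]) / seg else 0
  pts[i, ] * (1 - w) + pts[i + 1L, ] * w
}

#' Read and write centerline files
#'
#' Centerlines are stored as JSON objects with a `points` field (list of
#' `[x, y, z]` mm coordinates) and a `step` field (arc spacing, mm).
#'
#' @param p a [centerline] to write.
#' @param path file path.
#' @return `read_path()` returns a [centerline]; `write_path()` returns
#'   `path` invisibly.
#' @export
write_path <- function(p, path) {
  stopifnot(inherits(p, "centerline"))
  jsonlite::write_json(
    list(points = unname(split(p$points, row(p$points))), step = p$step),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_path
#' @export
read_path <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$points) || is.null(obj$step))
    stop("centerline file must have 'points' and 'step' fields: ", path)
  pts <- obj$points
  if (is.list(pts)) pts <- do.call(rbind, pts)
  centerline(pts, step = obj$step)
}

#' Seed point sets for the carotid bifurcation
#'
#' Holds the three required seed points (common, internal, external
#' carotid) plus the optional annotated bifurcation gap point and its
#' derived shifted/estimated variants, all in world mm.
#'
#' @param CCA,ICA,ECA length-3 world-mm points (required, pairwise
#'   distinct).
#' @param BIF optional annotated bifurcation gap point.
#' @param BIF_s optional shifted bifurcation point (see
#'   [shift_bifurcation()]).
#' @param BIF_e optional estimated centerline-bifurcation point (see
#'   [estimate_bifurcation()]).
#' @return An object of class `seed_set`.
#' @export
seed_set <- function(CCA, ICA, ECA, BIF = NULL, BIF_s = NULL, BIF_e = NULL) {
  chk <- function(x, nm) {
    if (is.null(x)) return(NULL)
    x <- as.numeric(x)
    if (length(x) != 3L || any(!is.finite(x)))
      stop("seed '", nm, "' must be a finite length-3 point")
    x
  }
  s <- list(CCA = chk(CCA, "CCA"), ICA = chk(ICA, "ICA"),
            ECA = chk(ECA, "ECA"), BIF = chk(BIF, "BIF"),
            BIF_s = chk(BIF_s, "BIF_s"), BIF_e = chk(BIF_e, "BIF_e"))
  if (is.null(s$CCA) || is.null(s$ICA) || is.null(s$ECA))
    stop("seeds CCA, ICA and ECA are required")
  pts <- rbind(s$CCA, s$ICA, s$ECA)
  if (any(stats::dist(pts) < 1e-9))
    stop("seeds CCA, ICA, ECA must be pairwise distinct")
  structure(s, class = "seed_set")
}

#' @export
print.seed_set <- function(x, ...) {
  for (nm in names(x)) if (!is.null(x[[nm]]))
    cat(sprintf("  %-5s (%.2f, %.2f, %.2f) mm\n", nm,
                x[[nm]][1], x[[nm]][2], x[[nm]][3]))
  invisible(x)
}

#' Read and write seed files
#'
#' Seed files are JSON objects with keys `CCA`, `ICA`, `ECA` and optional
#' `BIF`, each a 3-element array of world-mm coordinates.
#'
#' @param path file path.
#' @param seeds a [seed_set] to write.
#' @return `read_seeds()` returns a [seed_set]; `write_seeds()` returns
#'   `path` invisibly.
#' @export
read_seeds <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (k in c("CCA", "ICA", "ECA"))
    if (is.null(obj[[k]])) stop("seeds file missing required key '", k,
                                "': ", path)
  seed_set(CCA = obj$CCA, ICA = obj$ICA, ECA = obj$ECA, BIF = obj$BIF)
}

#' @rdname read_seeds
#' @export
write_seeds <- function(seeds, path) {
  stopifnot(inherits(seeds, "seed_set"))
  obj <- Filter(Negate(is.null),
                list(CCA = seeds$CCA, ICA = seeds$ICA, ECA = seeds$ECA,
                     BIF = seeds$BIF))
  jsonlite::write_json(obj, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}
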