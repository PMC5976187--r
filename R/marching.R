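#' Single-voxel upwind Eikonal update
#'
#' Returns the smallest value `U` satisfying the first-order upwind
#' quadratic discretization of the Eikonal equation at one voxel,
#' \deqn{\sum_i \left(\frac{\max\{U - a_i, 0\}}{h_i}\right)^2 = c^2,}
#' where \eqn{a_i} is the smaller of the two neighbor values along axis
#' `i` (may be `Inf` if neither neighbor has a value) and \eqn{h_i} the
#' voxel spacing. Axes whose neighbor value exceeds the candidate
#' solution are excluded (upwind condition), implemented by sorting the
#' finite \eqn{a_i} and solving over the largest admissible prefix.
#'
#' Exported both as the building block of the fast-marching solver and
#' so that iterative (Gauss-Seidel) solutions of the same discretization
#' can be constructed independently.
#'
#' @param neighbors 3 x 2 matrix (or length-6 vector, axis-major) of
#'   neighbor `U` values per axis; use `Inf` for missing neighbors. At
#'   least one value must be finite.
#' @param cost local cost \eqn{c > 0}.
#' @param spacing voxel spacing per axis, mm.
#' @return The updated `U` value (finite).
#' @examples
#' local_update(cbind(c(0, 0, Inf), c(Inf, Inf, Inf)), 1, c(1, 1, 1))
#' # = 1/sqrt(2)
#' @export
local_update <- function(neighbors, cost, spacing = c(1, 1, 1)) {
  nb <- matrix(as.numeric(neighbors), nrow = 3L)
  if (ncol(nb) != 2L) stop("'neighbors' must be a 3 x 2 matrix")
  .fm_local_update(nb[, 1L], nb[, 2L], as.numeric(cost),
                   as.numeric(spacing))
}

#' Solve the Eikonal equation by fast marching
#'
#' Propagates a front from the source point over the cost volume
#' `p_tilde` using the classic three-set (ALIVE / TRIAL / FAR) fast
#' marching scheme with a 6-connected neighborhood, the anisotropic
#' upwind update of [local_update()], and a min-heap on trial values
#' (lazy re-insertion; heap ties broken by insertion order, on which the
#' result does not depend). Propagation stops as soon as every stop
#' point's voxel is frozen, or when the whole grid is frozen if no stop
#' points are given.
#'
#' The first-order upwind scheme carries a large discretization error
#' near a point source (the front is strongly curved there), which then
#' propagates outward along diagonal directions. The solver therefore
#' initializes all voxels within `init_radius` of the source with the
#' straight-line trapezoid integral of the cost as Dirichlet data
#' (`init_radius = 0` disables this and reduces to the plain scheme).
#' The default, five times the smallest voxel size, assumes the cost is
#' locally smooth on that scale — true at seed points placed inside the
#' vessel lumen.
#'
#' @param p_tilde a [vol3d] of strictly positive costs.
#' @param p0 source point, world mm.
#' @param stop_points optional list (or n x 3 matrix) of world-mm points
#'   at which propagation may stop early.
#' @param init_radius radius (mm) of the exact-initialization ball
#'   around the source.
#' @return An object of class `action_map`: list with `U` (a [vol3d];
#'   `Inf` outside the frozen set), `alive` (logical array), `source`
#'   (world-mm point), and `reached` (logical per stop point; `FALSE`
#'   entries indicate exhaustion before reaching that point).
#' @export
solve_action_map <- function(p_tilde, p0, stop_points = NULL,
                             init_radius = 5 * min(p_tilde$spacing)) {
  stopifnot(inherits(p_tilde, "vol3d"))
  if (min(p_tilde$data) <= 0) stop("cost must be strictly positive")
  d <- dim(p_tilde$data)
  src <- as.integer(round(world_to_voxel(p_tilde, p0)))
  if (!in_bounds(p_tilde, src)) stop("source point outside the volume")
  stops <- integer(0)
  n_stops <- 0L
  if (!is.null(stop_points)) {
    if (!is.matrix(stop_points))
      stop_points <- do.call(rbind, lapply(stop_points, as.numeric))
    sv <- round(world_to_voxel(p_tilde, stop_points))
    for (i in seq_len(nrow(sv)))
      if (!in_bounds(p_tilde, sv[i, ]))
        stop("stop point outside the volume")
    stops <- as.integer(t(sv))
    n_stops <- nrow(sv)
  }
  res <- .fm_solve(as.numeric(p_tilde$data), as.integer(d),
                   as.numeric(p_tilde$spacing), src, stops, n_stops,
                   as.numeric(init_radius))
  if (n_stops > 0L && !all(res$reached))
    warning("front exhausted before reaching all stop points")
  structure(list(U = vol3d(array(res$U, dim = d), p_tilde$spacing,
                           p_tilde$origin, check = FALSE),
                 alive = array(res$alive, dim = d),
                 source = as.numeric(p0),
                 reached = res$reached),
            class = "action_map")
}

#' @export
print.action_map <- function(x, ...) {
  cat(sprintf("<action_map> %d / %d voxels frozen, source (%.2f, %.2f, %.2f)\n",
              sum(x$alive), length(x$alive),
              x$source[1], x$source[2], x$source[3]))
  invisible(x)
}

#' Normalized gradient of an action map
#'
#' Finite-difference gradient of `U` scaled by voxel spacing: central
#' differences where both axis neighbors are frozen, one-sided where
#' only one is. The field is normalized to unit length and set exactly
#' to zero at non-frozen voxels and at the source voxel, so regions the
#' front never reached cannot influence backtracking.
#'
#' @param a an `action_map` from [solve_action_map()].
#' @return A list of three [vol3d]-shaped arrays (`gx`, `gy`, `gz`)
#'   plus the grid metadata, class `grad_field`.
#' @export
normalized_gradient <- function(a) {
  stopifnot(inherits(a, "action_map"))
  U <- a$U$data
  alive <- a$alive
  d <- dim(U)
  sp <- a$U$spacing
  g <- vector("list", 3L)
  for (ax in 1:3) {
    up <- shift_axis(U, ax, +1L)
    dn <- shift_axis(U, ax, -1L)
    up_ok <- shift_axis_logical(alive, ax, +1L)
    dn_ok <- shift_axis_logical(alive, ax, -1L)
    h <- sp[ax]
    gc <- array(0, dim = d)
    both <- up_ok & dn_ok
    gc[both] <- (up[both] - dn[both]) / (2 * h)
    onlyu <- up_ok & !dn_ok
    gc[onlyu] <- (up[onlyu] - U[onlyu]) / h
    onlyd <- dn_ok & !up_ok
    gc[onlyd] <- (U[onlyd] - dn[onlyd]) / h
    gc[!alive] <- 0
    g[[ax]] <- gc
  }
  norm <- sqrt(g[[1]]^2 + g[[2]]^2 + g[[3]]^2)
  nz <- norm > 0
  for (ax in 1:3) g[[ax]][nz] <- g[[ax]][nz] / norm[nz]
  src <- as.integer(round(world_to_voxel(a$U, a$source))) + 1L
  for (ax in 1:3) g[[ax]][src[1], src[2], src[3]] <- 0
  structure(list(gx = g[[1]], gy = g[[2]], gz = g[[3]],
                 spacing = sp, origin = a$U$origin),
            class = "grad_field")
}

# shift an array by one voxel along an axis, replicating the border
shift_axis <- function(a, axis, by) {
  d <- dim(a)
  idx <- pmin(pmax(seq_len(d[axis]) + by, 1L), d[axis])
  switch(axis, a[idx, , , drop = FALSE], a[, idx, , drop = FALSE],
         a[, , idx, drop = FALSE])
}

# as shift_axis but border voxels report FALSE (no neighbor there)
shift_axis_logical <- function(a, axis, by) {
  out <- shift_axis(a, axis, by)
  d <- dim(a)
  edge <- if (by > 0) d[axis] else 1L
  switch(axis,
         out[edge, , ] <- FALSE,
         out[, edge, ] <- FALSE,
         out[, , edge] <- FALSE)
  out
}

# trilinear interpolation of the gradient field at a continuous 0-based
# voxel coordinate; returns the (renormalized) descent direction
interp_gradient <- function(gf, idx) {
  d <- dim(gf$gx)
  idx <- pmin(pmax(idx, 0), d - 1)
  f <- pmax(pmin(floor(idx), d - 2), 0)
  w <- pmin(pmax(idx - f, 0), 1)
  out <- numeric(3)
  comp <- list(gf$gx, gf$gy, gf$gz)
  wx <- c(1 - w[1], w[1]); wy <- c(1 - w[2], w[2]); wz <- c(1 - w[3], w[3])
  for (c3 in 1:3) {
    arr <- comp[[c3]]
    acc <- 0
    for (a in 0:1) for (b in 0:1) for (cc in 0:1) {
      i <- min(f[1] + a + 1L, d[1]); j <- min(f[2] + b + 1L, d[2])
      k <- min(f[3] + cc + 1L, d[3])
      acc <- acc + wx[a + 1] * wy[b + 1] * wz[cc + 1] * arr[i, j, k]
    }
    out[c3] <- acc
  }
  out
}

#' Backtrack a minimum-cost path through an action map
#'
#' Integrates \eqn{\partial C/\partial s = -\nabla U_N} from the end
#' point down to the source with fourth-order Runge-Kutta at step
#' `delta` (mm), interpolating the normalized gradient field
#' trilinearly. Integration stops when the current point is within
#' `max(delta, min(spacing))` of the source, after which the source
#' point is appended; the returned path runs source to end point.
#'
#' @param a an `action_map`.
#' @param p1 end point, world mm; its voxel must be frozen.
#' @param delta integration step, mm.
#' @param max_steps safety cap on RK4 iterations; by default 10 x grid
#'   diameter / `delta`.
#' @return A [centerline] ordered from the source to `p1`.
#' @export
backtrack <- function(a, p1, delta = 0.1, max_steps = NULL) {
  stopifnot(inherits(a, "action_map"))
  if (delta <= 0) stop("'delta' must be positive")
  v <- a$U
  idx1 <- round(world_to_voxel(v, p1))
  if (!in_bounds(v, idx1) || !a$alive[idx1[1] + 1, idx1[2] + 1, idx1[3] + 1])
    stop("end point voxel is not frozen in the action map")
  gf <- normalized_gradient(a)
  p0 <- a$source
  diam <- sqrt(sum(((dim(v$data) - 1) * v$spacing)^2))
  if (is.null(max_steps)) max_steps <- ceiling(10 * diam / delta)
  stop_r <- max(delta, min(v$spacing))

  unit <- function(x) {
    n <- sqrt(sum(x * x))
    if (n > 1e-12) x / n else x
  }
  d <- dim(v$data)
  # greedy fallback where interpolated unit vectors cancel (saddles at
  # blocked-region boundaries): head for the lowest-U voxel center in
  # the 3x3x3 neighborhood
  greedy_dir <- function(pt) {
    ctr <- round(world_to_voxel(v, pt))
    best <- NULL; bestU <- Inf
    for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
      ix <- ctr + c(di, dj, dk)
      if (any(ix < 0) || any(ix > d - 1)) next
      u <- v$data[ix[1] + 1, ix[2] + 1, ix[3] + 1]
      if (u < bestU) { bestU <- u; best <- ix }
    }
    if (is.null(best)) return(c(0, 0, 0))
    unit(voxel_to_world(v, best) - pt)
  }
  vel <- function(pt) {
    g <- interp_gradient(gf, world_to_voxel(v, pt))
    if (sqrt(sum(g * g)) < 1e-3) greedy_dir(pt) else -unit(g)
  }
  pts <- matrix(NA_real_, nrow = max_steps + 2L, ncol = 3L)
  pts[1L, ] <- as.numeric(p1)
  cur <- as.numeric(p1)
  n_pts <- 1L
  done <- FALSE
  for (it in seq_len(max_steps)) {
    if (sqrt(sum((cur - p0)^2)) <= stop_r) { done <- TRUE; break }
    k1 <- vel(cur)
    k2 <- vel(cur + delta / 2 * k1)
    k3 <- vel(cur + delta / 2 * k2)
    k4 <- vel(cur + delta * k3)
    step <- delta / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (sqrt(sum(step * step)) < 1e-9 * delta)
      stop("backtracking stalled in a zero-gradient region")
    cur <- cur + step
    n_pts <- n_pts + 1L
    pts[n_pts, ] <- cur
  }
  if (!done && sqrt(sum((cur - p0)^2)) > stop_r)
    stop("backtracking did not reach the source within the step limit")
  n_pts <- n_pts + 1L
  pts[n_pts, ] <- p0
  centerline(pts[n_pts:1L, , drop = FALSE], step = delta)
}

#' Minimum-cost path between two points (anisotropic fast marching)
#'
#' Convenience composition: solves the action map from `p0` with `p1`
#' as stop point, then backtracks. The action map is returned alongside
#' the path so callers can compute average path costs without re-solving.
#'
#' @param p_tilde a [vol3d] of strictly positive costs.
#' @param p0,p1 distinct world-mm points inside the grid.
#' @param delta backtracking step, mm.
#' @return A list with `path` (a [centerline] from `p0` to `p1`) and
#'   `action` (the `action_map`).
#' @export
afm <- function(p_tilde, p0, p1, delta = 0.1) {
  p0 <- as.numeric(p0); p1 <- as.numeric(p1)
  if (sqrt(sum((p0 - p1)^2)) < 1e-9)
    stop("'p0' and 'p1' must be distinct points")
  a <- solve_action_map(p_tilde, p0, stop_points = rbind(p1))
  list(path = backtrack(a, p1, delta = delta), action = a)
}
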