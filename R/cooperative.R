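#' Average cost of a path under an action map
#'
#' The total accumulated cost of a minimum-cost path is the action-map
#' value at its end point; dividing by the path length gives a cost per
#' mm that is comparable across paths of different lengths.
#'
#' @param a an `action_map` whose source is the path start.
#' @param path a [centerline]; its end-point voxel must be frozen in
#'   `a`.
#' @return Average cost (per mm).
#' @export
average_path_cost <- function(a, path) {
  stopifnot(inherits(a, "action_map"), inherits(path, "centerline"))
  endp <- path$points[nrow(path$points), ]
  idx <- round(world_to_voxel(a$U, endp))
  if (!in_bounds(a$U, idx) ||
      !a$alive[idx[1] + 1, idx[2] + 1, idx[3] + 1])
    stop("path end point is not frozen in the action map")
  a$U$data[idx[1] + 1, idx[2] + 1, idx[3] + 1] / path_length(path)
}

#' Order two candidate paths by average cost
#'
#' The "best" path — the one assumed to be correctly placed and used as
#' the anchor of the cooperative correction — is the one with the lower
#' average cost. Ties go to `pathA`.
#'
#' @param pathA,pathB [centerline]s sharing the same start (the action
#'   map's source).
#' @param a the `action_map` both were backtracked from.
#' @return List with `best`, `neighbor` (the two paths), `best_is_A`
#'   (logical) and `avg_costs` (named numeric).
#' @export
select_best <- function(pathA, pathB, a) {
  ca <- average_path_cost(a, pathA)
  cb <- average_path_cost(a, pathB)
  best_is_A <- ca <= cb
  list(best = if (best_is_A) pathA else pathB,
       neighbor = if (best_is_A) pathB else pathA,
       best_is_A = best_is_A,
       avg_costs = c(A = ca, B = cb))
}

#' Index at which a constraint region starts along a path
#'
#' The constraint is anchored at the path point closest to a reference
#' point (the annotated bifurcation); earlier path points are left
#' unconstrained so the shared trunk remains traversable.
#'
#' @param path a [centerline].
#' @param x_ref reference point, world mm.
#' @return Integer index into the path's points (earliest on ties).
#' @export
constraint_start <- function(path, x_ref) {
  stopifnot(inherits(path, "centerline"))
  d2 <- colSums((t(path$points) - as.numeric(x_ref))^2)
  which.min(d2)
}

#' Build a constraint region around a path segment
#'
#' Marks every voxel whose center lies within `rho` mm (world distance,
#' so spherical in physical space and ellipsoidal in voxel units) of any
#' path point at or beyond `start_index`, then clears voxels within
#' `rho` of any `exclude` point so that shared targets and seeds remain
#' reachable.
#'
#' @param path a [centerline].
#' @param start_index first constrained path point (1-based);
#'   `nrow(points) + 1` yields an empty region.
#' @param rho dilation radius, mm.
#' @param grid a [vol3d] defining the voxel lattice.
#' @param exclude optional list/matrix of world-mm points to carve out.
#' @return An object of class `constraint_region`: list with `mask`
#'   (logical array on `grid`), `rho`, `start_index`, `start_point`.
#' @export
build_constraint <- function(path, start_index, rho, grid, exclude = NULL) {
  stopifnot(inherits(path, "centerline"), inherits(grid, "vol3d"))
  if (rho <= 0) stop("'rho' must be positive")
  n <- nrow(path$points)
  if (start_index < 1 || start_index > n + 1)
    stop("'start_index' out of range")
  mask <- array(FALSE, dim = dim(grid$data))
  if (start_index <= n) {
    seg <- path$points[start_index:n, , drop = FALSE]
    mask <- mark_balls(mask, grid, seg, rho, TRUE)
  }
  if (!is.null(exclude)) {
    if (!is.matrix(exclude))
      exclude <- do.call(rbind, lapply(exclude, as.numeric))
    mask <- mark_balls(mask, grid, exclude, rho, FALSE)
  }
  structure(list(mask = mask, rho = rho, start_index = start_index,
                 start_point = if (start_index <= n)
                   path$points[start_index, ] else NULL),
            class = "constraint_region")
}

# set (or clear) mask voxels within rho mm of any of the given points
mark_balls <- function(mask, grid, pts, rho, value) {
  d <- dim(mask)
  sp <- grid$spacing
  org <- grid$origin
  rv <- rho / sp
  for (q in seq_len(nrow(pts))) {
    p <- pts[q, ]
    idx <- (p - org) / sp
    lo <- pmax(floor(idx - rv), 0)
    hi <- pmin(ceiling(idx + rv), d - 1)
    if (any(lo > hi)) next
    ii <- lo[1]:hi[1]; jj <- lo[2]:hi[2]; kk <- lo[3]:hi[3]
    dx2 <- (ii * sp[1] + org[1] - p[1])^2
    dy2 <- (jj * sp[2] + org[2] - p[2])^2
    dz2 <- (kk * sp[3] + org[3] - p[3])^2
    inside <- outer(outer(dx2, dy2, "+"), dz2, "+") <= rho^2
    if (any(inside))
      mask[ii + 1L, jj + 1L, kk + 1L][inside] <- value
  }
  mask
}

#' Apply a constraint region to a cost volume
#'
#' Masked voxels get the blocking cost `K` exactly; all other voxels are
#' returned bit-identical to the input.
#'
#' @param p_tilde a [vol3d] cost volume.
#' @param kappa a `constraint_region` on the same grid.
#' @param K blocking cost; defaults to `1e3 *` the maximum finite cost,
#'   large enough to dominate any detour yet finite so the front can
#'   still cross the region if no alternative exists at all.
#' @return A [vol3d] with the masked voxels set to `K`.
#' @export
apply_constraint <- function(p_tilde, kappa, K = NULL) {
  stopifnot(inherits(p_tilde, "vol3d"), inherits(kappa, "constraint_region"))
  if (!identical(dim(p_tilde$data), dim(kappa$mask)))
    stop("constraint mask and cost volume are on different grids")
  if (is.null(K)) K <- 1e3 * max(p_tilde$data)
  out <- p_tilde$data
  out[kappa$mask] <- K
  vol3d(out, p_tilde$spacing, p_tilde$origin, check = FALSE)
}

# does a path violate the separation guarantee of a constraint region?
# The blocking cost acts on voxel centers: the unblocked voxel-center
# chain can run up to half a voxel diagonal inside the nominal
# rho-tube, and the smooth backtracked curve can deviate another half
# diagonal from that chain, so a legitimate path may come as close as
# rho minus one voxel diagonal to the constrained segment; anything
# deeper means the front crossed blocked voxels (no unblocked route
# existed). Points within rho of an exclusion point are exempt (the
# region was carved out there).
path_violates_constraint <- function(path, seg_points, rho, grid,
                                     exclude = NULL) {
  slack <- sqrt(sum(grid$spacing^2))
  lim <- rho - slack
  if (lim <= 0 || nrow(seg_points) == 0L) return(FALSE)
  for (i in seq_len(nrow(path$points))) {
    p <- path$points[i, ]
    if (!is.null(exclude) &&
        min(sqrt(rowSums(sweep(exclude, 2, p)^2))) <= rho) next
    if (point_to_path(p, seg_points) < lim) return(TRUE)
  }
  FALSE
}

#' Cooperative extraction of two branch paths
#'
#' Extracts the two paths `A -> B` and `A -> C` so that they do not
#' collapse onto one branch beyond the bifurcation. The procedure is a
#' single correction pass: (1) both paths are extracted independently
#' on `p_tilde`; (2) the one with the lower average cost is the best
#' path, assumed well placed; (3) a constraint region of radius `rho`
#' is dilated around the best path from its point closest to `x_ref`
#' onward (the other path's end point is carved out so it stays
#' reachable) and the neighbor path is re-extracted on the blocked
#' cost; (4) a second constraint region around the corrected neighbor
#' then re-extracts the best path. The two corrected paths are
#' guaranteed at least `rho` apart beyond the constraint starts (up to
#' voxelization of the region).
#'
#' @param p_tilde a [vol3d] cost volume.
#' @param A shared start point (common trunk seed), world mm.
#' @param B,C branch end points, world mm.
#' @param x_ref reference point anchoring the constraint start
#'   (annotated bifurcation gap point).
#' @param rho constraint radius, mm.
#' @param K blocking cost (`NULL` for the default of
#'   [apply_constraint()]).
#' @param delta backtracking step, mm.
#' @return List with `path_B`, `path_C` (corrected [centerline]s in
#'   argument order), and `diagnostics` (average costs, which input was
#'   best, constraint start points, and whether either corrected path
#'   crosses a constraint region).
#' @export
cooperative_pair <- function(p_tilde, A, B, C, x_ref, rho = 1.75, K = NULL,
                             delta = 0.1) {
  A <- as.numeric(A); B <- as.numeric(B); C <- as.numeric(C)
  am <- solve_action_map(p_tilde, A, stop_points = rbind(B, C))
  path_AB <- backtrack(am, B, delta = delta)
  path_AC <- backtrack(am, C, delta = delta)
  sel <- select_best(path_AB, path_AC, am)
  end_best <- sel$best$points[nrow(sel$best$points), ]
  end_nb <- sel$neighbor$points[nrow(sel$neighbor$points), ]

  k1_start <- constraint_start(sel$best, x_ref)
  kappa1 <- build_constraint(sel$best, k1_start, rho, p_tilde,
                             exclude = rbind(end_nb))
  p_N <- apply_constraint(p_tilde, kappa1, K)
  nb_corr <- afm(p_N, A, end_nb, delta = delta)$path
  seg1 <- sel$best$points[k1_start:nrow(sel$best$points), , drop = FALSE]
  nb_viol <- path_violates_constraint(nb_corr, seg1, rho, p_tilde,
                                      exclude = rbind(end_nb))
  if (nb_viol)
    warning("corrected neighbor path crosses the constraint region; ",
            "no unblocked route to its end point exists")

  k2_start <- constraint_start(nb_corr, x_ref)
  kappa2 <- build_constraint(nb_corr, k2_start, rho, p_tilde,
                             exclude = rbind(end_best))
  p_B2 <- apply_constraint(p_tilde, kappa2, K)
  best_corr <- afm(p_B2, A, end_best, delta = delta)$path
  seg2 <- nb_corr$points[k2_start:nrow(nb_corr$points), , drop = FALSE]
  best_viol <- path_violates_constraint(best_corr, seg2, rho, p_tilde,
                                        exclude = rbind(end_best))
  if (best_viol)
    warning("corrected best path crosses the constraint region")

  out_B <- if (sel$best_is_A) best_corr else nb_corr
  out_C <- if (sel$best_is_A) nb_corr else best_corr
  list(path_B = out_B, path_C = out_C,
       diagnostics = list(
         avg_costs = sel$avg_costs,
         best = if (sel$best_is_A) "B" else "C",
         kappa1_start = kappa1$start_point,
         kappa2_start = kappa2$start_point,
         neighbor_in_kappa = nb_viol,
         best_in_kappa = best_viol))
}

#' Shift the annotated bifurcation point along the trunk path
#'
#' The annotated bifurcation point sits in the gap between the two
#' branch lumens, outside the vessel; to be usable as a seed it is moved
#' a distance `t` back along the minimum-cost path from the trunk seed
#' to the annotation, placing it inside the lumen near the centerline
#' bifurcation.
#'
#' @param p_tilde a [vol3d] cost volume.
#' @param x_C trunk (common carotid) seed, world mm.
#' @param x_BIF annotated bifurcation gap point, world mm.
#' @param t shift distance in mm (must be smaller than the trunk-path
#'   length); 5.1 mm is the population-calibrated default.
#' @param delta backtracking step, mm.
#' @return The shifted point (length-3, world mm).
#' @export
shift_bifurcation <- function(p_tilde, x_C, x_BIF, t = 5.1, delta = 0.1) {
  if (t < 0) stop("'t' must be non-negative")
  path <- afm(p_tilde, x_C, x_BIF, delta = delta)$path
  total <- path_length(path)
  if (t >= total)
    stop("shift distance t (", t, " mm) is not smaller than the ",
         "trunk-path length (", round(total, 2), " mm)")
  point_at_arc(path$points, total - t)
}

#' Estimate the centerline bifurcation point from two branch paths
#'
#' Walks each path from its distal (branch) end toward the shared trunk
#' and finds the first point whose distance to the other path drops
#' below `tol`; the estimated bifurcation is the mean of the two points
#' found. Serves as a reference for where the two centerlines merge.
#'
#' @param c_ica,c_eca [centerline]s ordered trunk to branch end.
#' @param tol distance threshold, mm.
#' @return The estimated bifurcation point (length-3, world mm).
#' @export
estimate_bifurcation <- function(c_ica, c_eca, tol = 1.0) {
  stopifnot(inherits(c_ica, "centerline"), inherits(c_eca, "centerline"))
  found <- function(pa, pb) {
    for (i in rev(seq_len(nrow(pa)))) {
      if (point_to_path(pa[i, ], pb) < tol) return(pa[i, ])
    }
    NULL
  }
  a <- found(c_ica$points, c_eca)
  b <- found(c_eca$points, c_ica)
  if (is.null(a) || is.null(b))
    stop("paths never come within ", tol, " mm of each other")
  (a + b) / 2
}
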