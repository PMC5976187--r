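#' Cost-image parameters
#'
#' Tunables of the cost image \eqn{p(x) = 1 / (\epsilon + m(x)^\alpha
#' s(x)^\beta)}, where `m` is the multi-scale medialness response and `s`
#' the lumen intensity similarity, plus the smoothing constant
#' \eqn{\omega} added to `p` to penalize path length.
#'
#' @param alpha,beta non-negative exponents weighting medialness and
#'   similarity; equal by default so the two terms contribute equally.
#' @param epsilon small positive constant preventing singularities where
#'   both responses vanish; bounds the cost by `1/epsilon`.
#' @param scales medialness radii in mm, covering the expected vessel
#'   radii.
#' @param roi_radius_cca,roi_radius_branch radii (mm) of the spherical
#'   seed ROIs used to estimate the lumen intensity distribution: 3.5 mm
#'   at the common carotid seed, 2.5 mm at the branch seeds.
#' @param omega smoothing constant added to `p`; larger values penalize
#'   longer (hence more curved) paths.
#' @return An object of class `cost_params`.
#' @export
cost_params <- function(alpha = 1, beta = 1, epsilon = 1e-6,
                        scales = c(2, 2.5, 3, 3.5),
                        roi_radius_cca = 3.5, roi_radius_branch = 2.5,
                        omega = 0) {
  if (alpha < 0 || beta < 0) stop("'alpha' and 'beta' must be >= 0")
  if (epsilon <= 0) stop("'epsilon' must be positive")
  scales <- as.numeric(scales)
  if (length(scales) == 0L || any(scales <= 0))
    stop("'scales' must be a non-empty vector of positive radii")
  if (roi_radius_cca <= 0 || roi_radius_branch <= 0)
    stop("ROI radii must be positive")
  if (omega < 0) stop("'omega' must be >= 0")
  structure(list(alpha = alpha, beta = beta, epsilon = epsilon,
                 scales = scales, roi_radius_cca = roi_radius_cca,
                 roi_radius_branch = roi_radius_branch, omega = omega),
            class = "cost_params")
}

# sample a volume's data at a constant fractional in-plane voxel offset
# (dx, dy voxel units), bilinear, replicating the boundary
shift_inplane <- function(data, dx, dy) {
  fx <- floor(dx); fy <- floor(dy)
  wx <- dx - fx;   wy <- dy - fy
  sh <- function(a, sx, sy) {
    d <- dim(a)
    ix <- pmin(pmax(seq_len(d[1]) + sx, 1L), d[1])
    iy <- pmin(pmax(seq_len(d[2]) + sy, 1L), d[2])
    a[ix, iy, , drop = FALSE]
  }
  (1 - wx) * (1 - wy) * sh(data, fx, fy) +
    wx * (1 - wy) * sh(data, fx + 1L, fy) +
    (1 - wx) * wy * sh(data, fx, fy + 1L) +
    wx * wy * sh(data, fx + 1L, fy + 1L)
}

#' Multi-scale circular medialness filter
#'
#' For every voxel, casts `n_rays` equally spaced rays in the axial (x-y)
#' plane and measures the inward radial intensity gradient at distance
#' `r` along each ray (central difference over half the in-plane voxel
#' size), clipping negative ray responses at zero. Opposite rays are
#' combined by their minimum before averaging: a medial point of a
#' circular cross-section sees boundary evidence on *both* sides of
#' every diameter, whereas a point outside (or on) the boundary fires
#' only on rays pointing back at the vessel, so the pairwise minimum
#' suppresses the off-center halo that a plain ray mean produces. The
#' per-voxel output is the maximum over `scales`, normalized by the
#' global maximum so the response lies in [0, 1] and peaks at the
#' centers of bright, roughly circular cross-sections. Carotid arteries
#' run approximately axially in neck MRI, which is why an in-plane
#' response suffices.
#'
#' @param v a [vol3d] image.
#' @param scales radii in mm at which to probe; should cover the
#'   expected vessel radii.
#' @param n_rays number of rays per voxel (even).
#' @return A [vol3d] of medialness values in [0, 1] (identically 0 for a
#'   constant image).
#' @export
medialness <- function(v, scales = c(2, 2.5, 3, 3.5), n_rays = 16L) {
  stopifnot(inherits(v, "vol3d"))
  scales <- as.numeric(scales)
  if (length(scales) == 0L || any(scales <= 0))
    stop("'scales' must be positive radii")
  n_rays <- as.integer(n_rays)
  if (n_rays < 4L || n_rays %% 2L != 0L)
    stop("'n_rays' must be an even number >= 4")
  sp <- v$spacing
  h <- min(sp[1:2]) / 2                # central-difference half-step, mm
  n_half <- n_rays %/% 2L
  best <- NULL
  ray_response <- function(a, r) {
    ux <- cos(a); uy <- sin(a)
    inner <- shift_inplane(v$data, (r - h) * ux / sp[1],
                           (r - h) * uy / sp[2])
    outer <- shift_inplane(v$data, (r + h) * ux / sp[1],
                           (r + h) * uy / sp[2])
    g <- (inner - outer) / (2 * h)     # inward gradient, >0 at bright rim
    g[g < 0] <- 0
    g
  }
  for (r in scales) {
    acc <- NULL
    for (k in seq_len(n_half)) {
      a <- (k - 1) * 2 * pi / n_rays
      g <- pmin(ray_response(a, r), ray_response(a + pi, r))
      acc <- if (is.null(acc)) g else acc + g
    }
    acc <- acc / n_half
    best <- if (is.null(best)) acc else pmax(best, acc)
  }
  mx <- max(best)
  if (mx > 0) best <- best / mx
  vol3d(best, spacing = sp, origin = v$origin, check = FALSE)
}

#' Lumen intensity similarity
#'
#' Estimates the lumen intensity distribution from the union of spherical
#' ROIs around the seed points (radius `roi_radius_cca` at the common
#' carotid seed, `roi_radius_branch` at the branch seeds) and maps each
#' voxel's intensity through a Gaussian membership:
#' \eqn{s(x) = \exp(-(I(x) - \mu)^2 / (2\sigma^2))} with \eqn{\mu, \sigma}
#' the ROI mean and standard deviation. If the ROI is perfectly uniform
#' (\eqn{\sigma = 0}), `s` is 1 exactly where the intensity equals
#' \eqn{\mu} and 0 elsewhere.
#'
#' @param v a [vol3d] image.
#' @param seeds a [seed_set]; all three required seeds must lie inside
#'   the volume. ROI spheres are clipped at the volume boundary.
#' @param params a [cost_params] (only the ROI radii are used).
#' @return A [vol3d] of similarities in [0, 1].
#' @export
lumen_similarity <- function(v, seeds, params = cost_params()) {
  stopifnot(inherits(v, "vol3d"), inherits(seeds, "seed_set"))
  rois <- list(list(p = seeds$CCA, r = params$roi_radius_cca),
               list(p = seeds$ICA, r = params$roi_radius_branch),
               list(p = seeds$ECA, r = params$roi_radius_branch))
  sel <- rep(FALSE, length(v$data))
  d <- dim(v$data)
  for (roi in rois) {
    idx <- world_to_voxel(v, roi$p)
    if (!in_bounds(v, idx))
      stop("seed point lies outside the volume")
    rv <- roi$r / v$spacing            # radius in voxel units per axis
    lo <- pmax(floor(idx - rv), 0)
    hi <- pmin(ceiling(idx + rv), d - 1)
    ii <- lo[1]:hi[1]; jj <- lo[2]:hi[2]; kk <- lo[3]:hi[3]
    # world distances within the candidate box
    dx2 <- ((ii * v$spacing[1] + v$origin[1]) - roi$p[1])^2
    dy2 <- ((jj * v$spacing[2] + v$origin[2]) - roi$p[2])^2
    dz2 <- ((kk * v$spacing[3] + v$origin[3]) - roi$p[3])^2
    inside <- outer(outer(dx2, dy2, "+"), dz2, "+") <= roi$r^2
    lin <- as.vector(outer(outer(ii + 1L, (jj) * d[1], "+"),
                           (kk) * d[1] * d[2], "+"))
    sel[lin[as.vector(inside)]] <- TRUE
  }
  vals <- v$data[sel]
  if (length(vals) == 0L) stop("seed ROIs contain no voxels")
  mu <- mean(vals)
  sig <- stats::sd(vals)
  if (!is.finite(sig) || sig == 0) {
    s <- array(as.numeric(v$data == mu), dim = d)
  } else {
    s <- exp(-(v$data - mu)^2 / (2 * sig^2))
  }
  vol3d(s, spacing = v$spacing, origin = v$origin, check = FALSE)
}

#' Combine medialness and similarity into the cost image
#'
#' \eqn{p(x) = 1 / (\epsilon + m(x)^\alpha s(x)^\beta)}: low wherever both
#' the medialness and the lumen similarity are high (i.e. at vessel
#' centers), bounded above by \eqn{1/\epsilon}.
#'
#' @param m,s [vol3d] volumes on the same grid with values in [0, 1].
#' @param params a [cost_params].
#' @return A [vol3d] cost volume with values in \eqn{(0, 1/\epsilon]}.
#' @export
combine_cost <- function(m, s, params = cost_params()) {
  stopifnot(inherits(m, "vol3d"), inherits(s, "vol3d"))
  if (!identical(dim(m$data), dim(s$data)) ||
      max(abs(m$spacing - s$spacing)) > 1e-9 ||
      max(abs(m$origin - s$origin)) > 1e-9)
    stop("'m' and 's' must live on the same grid")
  p <- 1 / (params$epsilon + m$data^params$alpha * s$data^params$beta)
  vol3d(p, spacing = m$spacing, origin = m$origin, check = FALSE)
}

#' Build the (multispectral) cost image
#'
#' Computes medialness and lumen similarity for each input sequence,
#' takes the voxelwise maximum of each term across sequences, combines
#' them via [combine_cost()], and adds the smoothing constant
#' \eqn{\omega}. With a single input volume this reduces to the
#' single-sequence cost.
#'
#' @param volumes a list of [vol3d] volumes on one common grid
#'   (co-registered sequences), or a single [vol3d].
#' @param seeds a [seed_set].
#' @param params a [cost_params].
#' @return An object of class `cost_image`: list with `p` (the raw cost
#'   [vol3d]), `p_tilde` (`p + omega`), `m`, `s` (the combined term
#'   volumes) and `params`.
#' @export
multispectral_cost <- function(volumes, seeds, params = cost_params()) {
  if (inherits(volumes, "vol3d")) volumes <- list(volumes)
  if (length(volumes) == 0L) stop("need at least one input volume")
  ref <- volumes[[1L]]
  m_max <- NULL; s_max <- NULL
  for (v in volumes) {
    stopifnot(inherits(v, "vol3d"))
    if (!identical(dim(v$data), dim(ref$data)))
      stop("all input volumes must share one grid")
    m_i <- medialness(v, params$scales)$data
    s_i <- lumen_similarity(v, seeds, params)$data
    m_max <- if (is.null(m_max)) m_i else pmax(m_max, m_i)
    s_max <- if (is.null(s_max)) s_i else pmax(s_max, s_i)
  }
  m <- vol3d(m_max, ref$spacing, ref$origin, check = FALSE)
  s <- vol3d(s_max, ref$spacing, ref$origin, check = FALSE)
  p <- combine_cost(m, s, params)
  p_tilde <- vol3d(p$data + params$omega, ref$spacing, ref$origin,
                   check = FALSE)
  structure(list(p = p, p_tilde = p_tilde, m = m, s = s, params = params),
            class = "cost_image")
}

#' @export
print.cost_image <- function(x, ...) {
  cat("<cost_image>\n  p: "); print(x$p)
  cat(sprintf("  omega = %g, alpha = %g, beta = %g, epsilon = %g\n",
              x$params$omega, x$params$alpha, x$params$beta,
              x$params$epsilon))
  invisible(x)
}

#' Crop a cost image to the seed bounding box
#'
#' Restricts the grid to the axis-aligned bounding box of the seed
#' voxels, padded by `pad_xy` voxels in-plane and `pad_z` voxels axially
#' and clipped at the volume boundary. The origin is updated so world
#' coordinates are preserved; extraction results on the cropped grid are
#' directly comparable with the full grid.
#'
#' @param c a `cost_image` (from [multispectral_cost()]).
#' @param seeds a [seed_set] (all present points are included in the
#'   box).
#' @param pad_xy,pad_z padding in voxels.
#' @return A `cost_image` on the restricted grid.
#' @export
crop_roi <- function(c, seeds, pad_xy = 20L, pad_z = 3L) {
  stopifnot(inherits(c, "cost_image"), inherits(seeds, "seed_set"))
  v <- c$p
  d <- dim(v$data)
  pts <- do.call(rbind, Filter(Negate(is.null),
                               list(seeds$CCA, seeds$ICA, seeds$ECA,
                                    seeds$BIF, seeds$BIF_s)))
  idx <- round(world_to_voxel(v, pts))
  lo <- pmax(apply(idx, 2, min) - c(pad_xy, pad_xy, pad_z), 0)
  hi <- pmin(apply(idx, 2, max) + c(pad_xy, pad_xy, pad_z), d - 1)
  sub <- function(vol) {
    vol3d(vol$data[(lo[1]:hi[1]) + 1L, (lo[2]:hi[2]) + 1L,
                   (lo[3]:hi[3]) + 1L, drop = FALSE],
          spacing = vol$spacing,
          origin = vol$origin + lo * vol$spacing, check = FALSE)
  }
  structure(list(p = sub(c$p), p_tilde = sub(c$p_tilde), m = sub(c$m),
                 s = sub(c$s), params = c$params),
            class = "cost_image")
}
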