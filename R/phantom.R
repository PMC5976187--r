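#' Specification of a synthetic bifurcating-vessel phantom
#'
#' Describes a Y-shaped tube emulating the carotid bifurcation: a common
#' trunk running axially that splits into two branches, rendered into two
#' co-registered pseudo-sequences with bright lumen on a darker background
#' plus additive Gaussian noise. Each branch leaves the trunk axis along a
#' circular arc (tangent-continuous with the trunk) and then runs straight
#' at half the branch angle from the axial direction, so the geometry is
#' fully analytic and the first slice where the two lumens are disjoint is
#' well defined.
#'
#' @param volume_shape voxel counts per axis.
#' @param spacing voxel size in mm; the default is anisotropic with a
#'   coarser axial (z) direction, as in black-blood carotid MRI.
#' @param trunk_radius common-trunk lumen radius, mm.
#' @param branch_radii lumen radii of the two branches, mm.
#' @param bifurcation_z world-mm height at which the branch axes leave the
#'   trunk axis.
#' @param branch_angle angle between the two branches, degrees (each
#'   branch runs at half this angle from the axial direction).
#' @param arc_radius radius of the circular arc joining trunk and straight
#'   branch segments, mm.
#' @param lumen_intensity,background_intensity image intensities
#'   (arbitrary units).
#' @param branch_contrast multipliers in (0, 1] applied to the lumen
#'   intensity of each branch; lowering one below 1 renders that branch
#'   fainter than the other.
#' @param noise_sd standard deviation of the additive Gaussian noise.
#' @param rng_seed integer seed; phantoms are bit-reproducible given the
#'   same spec.
#' @return An object of class `phantom_spec`.
#' @seealso [make_phantom()], [faint_branch_preset()]
#' @export
phantom_spec <- function(volume_shape = c(64, 64, 44),
                         spacing = c(0.5, 0.5, 0.9),
                         trunk_radius = 3.5,
                         branch_radii = c(2.5, 2.5),
                         bifurcation_z = 16,
                         branch_angle = 40,
                         arc_radius = 10,
                         lumen_intensity = 100,
                         background_intensity = 20,
                         branch_contrast = c(1, 1),
                         noise_sd = 4,
                         rng_seed = 77L) {
  spec <- list(volume_shape = as.integer(volume_shape),
               spacing = as.numeric(spacing),
               trunk_radius = trunk_radius,
               branch_radii = as.numeric(branch_radii),
               bifurcation_z = bifurcation_z,
               branch_angle = branch_angle,
               arc_radius = arc_radius,
               lumen_intensity = lumen_intensity,
               background_intensity = background_intensity,
               branch_contrast = as.numeric(branch_contrast),
               noise_sd = noise_sd,
               rng_seed = as.integer(rng_seed))
  if (any(spec$volume_shape < 8L)) stop("volume too small")
  if (any(spec$spacing <= 0)) stop("spacing must be positive")
  if (spec$trunk_radius <= 0 || any(spec$branch_radii <= 0))
    stop("radii must be positive")
  if (spec$branch_angle <= 10 || spec$branch_angle >= 120)
    stop("branch_angle must lie in (10, 120) degrees")
  if (any(spec$branch_contrast <= 0) || any(spec$branch_contrast > 1))
    stop("branch_contrast components must lie in (0, 1]")
  if (spec$noise_sd < 0) stop("noise_sd must be non-negative")
  structure(spec, class = "phantom_spec")
}

#' Faint-branch phantom preset
#'
#' A fixed phantom configuration in which one branch is rendered at a
#' quarter of the other branch's lumen contrast over a noisy
#' background. With independently extracted minimum-cost paths, the
#' path to the faint branch's seed climbs the bright branch and only
#' jumps across near its end — the classic collapse failure that
#' cooperative extraction is designed to repair.
#'
#' The preset differs from the generator defaults in three fixed
#' choices: `branch_contrast = c(1, 0.23)` (the faint lumen barely
#' clears the noise floor, so the independent paths prefer the bright
#' corridor, yet enough signal remains for the constrained re-extraction
#' to recover the branch); `branch_radii = c(1.75, 1.75)` (branch lumen
#' diameter equal to the 3.5 mm constraint-region diameter, matching the
#' design premise that the constraint covers the neighbor artery's
#' lumen); and `branch_angle = 30` with `noise_sd = 6`.
#'
#' @return A fixed [phantom_spec]; two calls return identical specs.
#' @export
faint_branch_preset <- function() {
  phantom_spec(branch_radii = c(1.75, 1.75),
               branch_contrast = c(1, 0.23),
               branch_angle = 30,
               noise_sd = 6)
}

# analytic branch axis: arc then straight line, in the x-z plane through
# the trunk axis. side is +1 or -1; returns function(s1) -> point matrix
# where s1 is arc length beyond the bifurcation.
branch_axis_point <- function(spec, side, s1) {
  cx <- (spec$volume_shape[1] - 1) * spec$spacing[1] / 2
  cy <- (spec$volume_shape[2] - 1) * spec$spacing[2] / 2
  theta <- spec$branch_angle / 2 * pi / 180
  R <- spec$arc_radius
  arc_len <- R * theta
  s1 <- pmax(s1, 0)
  on_arc <- s1 <= arc_len
  phi <- pmin(s1 / R, theta)
  x <- cx + side * R * (1 - cos(phi))
  z <- spec$bifurcation_z + R * sin(phi)
  extra <- pmax(s1 - arc_len, 0)
  x <- x + side * sin(theta) * extra
  z <- z + cos(theta) * extra
  cbind(x, rep(cy, length(s1)), z)
}

# total arc length of a branch axis from bifurcation to a given z
branch_arc_for_z <- function(spec, z) {
  theta <- spec$branch_angle / 2 * pi / 180
  R <- spec$arc_radius
  dz <- z - spec$bifurcation_z
  z_arc <- R * sin(theta)
  ifelse(dz <= 0, 0,
         ifelse(dz <= z_arc, R * asin(pmin(dz / R, 1)),
                R * theta + (dz - z_arc) / cos(theta)))
}

#' Generate a synthetic bifurcating-vessel phantom
#'
#' Renders the tube described by a [phantom_spec] into two pseudo-sequence
#' volumes (identical geometry, independent noise draws) and returns the
#' analytic ground truth: both branch centerlines (sharing the trunk
#' prefix), and a [seed_set] whose `BIF` point follows the annotation
#' rule used for carotid MRI — the midpoint of the gap between the two
#' branch lumens at the first axial slice (starting from the trunk) where
#' the two cross-sections are disjoint.
#'
#' Voxels within a tube radius of a centerline get that tube's lumen
#' intensity (scaled by the branch's contrast), with a linear one-voxel
#' edge ramp to the background; overlapping tubes combine by maximum.
#'
#' @param spec a [phantom_spec].
#' @return A list with elements `seq1`, `seq2` ([vol3d] volumes), and
#'   `truth` — a list with `centerline_ICA`, `centerline_ECA`
#'   ([centerline]s from the CCA seed to each branch end), `seeds`
#'   ([seed_set] with `BIF` set), and `spec`.
#' @examples
#' ph <- make_phantom(phantom_spec(volume_shape = c(32, 32, 24),
#'                                 bifurcation_z = 8, noise_sd = 0))
#' ph$seq1
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  sh <- spec$volume_shape
  sp <- spec$spacing
  extent <- (sh - 1) * sp
  cx <- extent[1] / 2
  cy <- extent[2] / 2
  z_top <- extent[3]
  if (spec$bifurcation_z <= 5 || spec$bifurcation_z >= z_top - 5)
    stop("bifurcation_z must lie well inside the volume")

  step <- 0.1
  z_seed_lo <- 4                      # CCA seed height (ROI sphere fits)
  z_seed_hi <- z_top - 3              # branch seed height
  s_end <- branch_arc_for_z(spec, z_seed_hi)

  # truth centerlines: straight trunk from z_seed_lo to bifurcation, then
  # the analytic branch axis, sampled at the nominal step
  trunk_z <- seq(z_seed_lo, spec$bifurcation_z, by = step)
  trunk <- cbind(cx, cy, trunk_z)
  s1 <- seq(step, s_end, by = step)
  if (s1[length(s1)] < s_end) s1 <- c(s1, s_end)
  mk_branch <- function(side)
    centerline(rbind(trunk, branch_axis_point(spec, side, s1)), step = step)
  cl_ica <- mk_branch(+1)
  cl_eca <- mk_branch(-1)

  end_ica <- cl_ica$points[nrow(cl_ica$points), ]
  end_eca <- cl_eca$points[nrow(cl_eca$points), ]
  r_max <- max(spec$trunk_radius, spec$branch_radii)
  for (p in list(end_ica, end_eca))
    if (p[1] < r_max || p[1] > extent[1] - r_max ||
        p[2] < r_max || p[2] > extent[2] - r_max)
      stop("branch tube leaves the volume; enlarge volume_shape or ",
           "reduce branch_angle")

  # bifurcation gap point: first slice where the two lumen disks are
  # disjoint, midpoint between the two branch axes there
  z_slices <- seq(0, z_top, by = sp[3])
  gap_z <- NA_real_
  for (z in z_slices[z_slices > spec$bifurcation_z]) {
    s_here <- branch_arc_for_z(spec, z)
    a1 <- branch_axis_point(spec, +1, s_here)
    a2 <- branch_axis_point(spec, -1, s_here)
    sep <- abs(a1[1] - a2[1])
    if (sep > sum(spec$branch_radii)) { gap_z <- z; break }
  }
  if (is.na(gap_z)) stop("branches never separate inside the volume")
  x_bif <- c(cx, cy, gap_z)

  seeds <- seed_set(CCA = c(cx, cy, z_seed_lo), ICA = end_ica,
                    ECA = end_eca, BIF = x_bif)

  # render: per-slice distance from the in-plane grid to each tube axis
  render <- tube_render(spec, cl_ica, cl_eca)

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$rng_seed)
  noise <- function() if (spec$noise_sd > 0)
    array(stats::rnorm(prod(sh), 0, spec$noise_sd), dim = sh)
  else array(0, dim = sh)
  seq1 <- vol3d(render + noise(), spacing = sp, check = FALSE)
  seq2 <- vol3d(render + noise(), spacing = sp, check = FALSE)

  list(seq1 = seq1, seq2 = seq2,
       truth = list(centerline_ICA = cl_ica, centerline_ECA = cl_eca,
                    seeds = seeds, spec = spec))
}

# noiseless tube image: intensity profile per tube with 1-voxel edge ramp,
# combined across tubes by maximum
tube_render <- function(spec, cl_ica, cl_eca) {
  sh <- spec$volume_shape
  sp <- spec$spacing
  edge <- min(sp[1:2]) / 2             # in-plane edge ramp width, mm
  bg <- spec$background_intensity
  img <- array(bg, dim = sh)
  xs <- (seq_len(sh[1]) - 1) * sp[1]
  ys <- (seq_len(sh[2]) - 1) * sp[2]
  gx <- matrix(xs, sh[1], sh[2])
  gy <- matrix(ys, sh[1], sh[2], byrow = TRUE)

  tubes <- list(
    list(cl = cl_ica, radius = spec$branch_radii[1],
         amp = spec$lumen_intensity * spec$branch_contrast[1]),
    list(cl = cl_eca, radius = spec$branch_radii[2],
         amp = spec$lumen_intensity * spec$branch_contrast[2]))

  for (k in seq_len(sh[3])) {
    z <- (k - 1) * sp[3]
    slice <- img[, , k]
    for (tb in tubes) {
      pts <- tb$cl$points
      # tube radius: trunk radius below the bifurcation
      near <- abs(pts[, 3] - z) <= 2 * sp[3]
      if (!any(near)) next
      pn <- pts[near, , drop = FALSE]
      # thin the axis samples: 0.25 mm is enough against a >= 2 mm radius
      thin <- seq(1L, nrow(pn), by = max(1L, as.integer(0.25 / tb$cl$step)))
      pn <- pn[thin, , drop = FALSE]
      rad <- ifelse(pn[, 3] <= spec$bifurcation_z + 1e-9,
                    spec$trunk_radius, tb$radius)
      margin <- NULL                   # signed distance to tube surface
      for (i in seq_len(nrow(pn))) {
        d2 <- (gx - pn[i, 1])^2 + (gy - pn[i, 2])^2 + (z - pn[i, 3])^2
        m <- sqrt(d2) - rad[i]
        margin <- if (is.null(margin)) m else pmin(margin, m)
      }
      w <- pmin(pmax(1 - margin / edge, 0), 1)  # 1 inside, ramp to 0
      val <- bg + (tb$amp - bg) * w
      slice <- pmax(slice, val)
    }
    img[, , k] <- slice
  }
  img
}
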