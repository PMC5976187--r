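# Shared fixtures, computed once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_env))
    assign(name, expr, envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# small noise-free phantom for fast geometric checks
small_clean_phantom <- function() {
  fixture("small_clean", make_phantom(
    phantom_spec(volume_shape = c(48, 48, 32), bifurcation_z = 10,
                 noise_sd = 0)))
}

# full-size clean phantom pipeline (two sequences, noise on)
clean_pipeline <- function() {
  fixture("clean_pipe", {
    ph <- make_phantom(phantom_spec())
    ci <- crop_roi(multispectral_cost(list(ph$seq1, ph$seq2),
                                      ph$truth$seeds,
                                      cost_params(omega = 2)),
                   ph$truth$seeds)
    list(ph = ph, ci = ci,
         truth_ica = resample_path(ph$truth$centerline_ICA$points, 0.1),
         truth_eca = resample_path(ph$truth$centerline_ECA$points, 0.1))
  })
}

# faint-branch preset pipeline plus all four method fits
faint_pipeline <- function() {
  fixture("faint_pipe", {
    ph <- make_phantom(faint_branch_preset())
    scales <- sort(unique(c(ph$truth$spec$branch_radii, 2.5,
                            ph$truth$spec$trunk_radius)))
    ci <- crop_roi(multispectral_cost(list(ph$seq1, ph$seq2),
                                      ph$truth$seeds,
                                      cost_params(omega = 2,
                                                  scales = scales)),
                   ph$truth$seeds)
    fits <- lapply(c(SCIE = "SCIE", SCBIE = "SCBIE", CCIE = "CCIE",
                     CCBIE = "CCBIE"),
                   function(m) run_method(ci, ph$truth$seeds, method = m))
    list(ph = ph, ci = ci, fits = fits,
         truth_ica = resample_path(ph$truth$centerline_ICA$points, 0.1),
         truth_eca = resample_path(ph$truth$centerline_ECA$points, 0.1))
  })
}

# mean over the points of path A beyond height z of their distance to
# path B: ~0 when the two paths coincide there
mean_dist_beyond <- function(pa, pb, z) {
  sel <- pa$points[, 3] > z
  mean(vapply(which(sel),
              function(i) point_to_path(pa$points[i, ], pb), numeric(1)))
}

min_dist_beyond <- function(pa, pb, z) {
  sa <- pa$points[pa$points[, 3] > z, , drop = FALSE]
  sb <- pb$points[pb$points[, 3] > z, , drop = FALSE]
  min(vapply(seq_len(nrow(sa)),
             function(i) point_to_path(sa[i, ], sb), numeric(1)))
}

# random positive cost volume for solver tests
random_cost <- function(dims, spacing, seed, lo = 0.2, hi = 3) {
  withr::with_seed(seed, {
    vol3d(array(stats::runif(prod(dims), lo, hi), dim = dims),
          spacing = spacing)
  })
}

# Independent iterative oracle: fast-sweeping (Gauss-Seidel) solution of
# the upwind discretization, sharing the solver's Dirichlet boundary
# data (source voxel plus exact-initialization ball). Sweeps in the 8
# axis orderings until the fixed point is reached.
gauss_seidel_oracle <- function(p_tilde, p0, init_radius, tol = 1e-13,
                                max_sweeps = 500) {
  d <- dim(p_tilde$data)
  sp <- p_tilde$spacing
  U <- array(Inf, dim = d)
  src <- as.integer(round(world_to_voxel(p_tilde, p0)))
  fixed <- array(FALSE, dim = d)
  U[src[1] + 1, src[2] + 1, src[3] + 1] <- 0
  fixed[src[1] + 1, src[2] + 1, src[3] + 1] <- TRUE
  c0 <- p_tilde$data[src[1] + 1, src[2] + 1, src[3] + 1]
  if (init_radius > 0) {
    for (i in seq_len(d[1])) for (j in seq_len(d[2]))
      for (k in seq_len(d[3])) {
        dv <- (c(i, j, k) - 1 - src) * sp
        dist <- sqrt(sum(dv^2))
        if (dist > 0 && dist <= init_radius) {
          U[i, j, k] <- dist * (c0 + p_tilde$data[i, j, k]) / 2
          fixed[i, j, k] <- TRUE
        }
      }
  }
  orders <- expand.grid(x = c(1, -1), y = c(1, -1), z = c(1, -1))
  for (sweep in seq_len(max_sweeps)) {
    delta <- 0
    o <- orders[(sweep - 1) %% 8 + 1, ]
    is <- if (o$x > 0) seq_len(d[1]) else rev(seq_len(d[1]))
    js <- if (o$y > 0) seq_len(d[2]) else rev(seq_len(d[2]))
    ks <- if (o$z > 0) seq_len(d[3]) else rev(seq_len(d[3]))
    for (k in ks) for (j in js) for (i in is) {
      if (fixed[i, j, k]) next
      nb <- matrix(Inf, 3, 2)
      if (i > 1) nb[1, 1] <- U[i - 1, j, k]
      if (i < d[1]) nb[1, 2] <- U[i + 1, j, k]
      if (j > 1) nb[2, 1] <- U[i, j - 1, k]
      if (j < d[2]) nb[2, 2] <- U[i, j + 1, k]
      if (k > 1) nb[3, 1] <- U[i, j, k - 1]
      if (k < d[3]) nb[3, 2] <- U[i, j, k + 1]
      if (all(!is.finite(nb))) next
      cand <- local_update(nb, p_tilde$data[i, j, k], sp)
      if (cand < U[i, j, k]) {
        delta <- max(delta, if (is.finite(U[i, j, k]))
          U[i, j, k] - cand else Inf)
        U[i, j, k] <- cand
      }
    }
    if (sweep > 8 && delta < tol) break
  }
  U
}

# trilinear interpolation of a (possibly Inf-padded) array at a
# continuous 0-based voxel coordinate; NA where a corner is not finite
interp_finite <- function(U, vox) {
  f <- pmax(pmin(floor(vox), dim(U) - 2), 0)
  w <- vox - f
  acc <- 0
  for (a in 0:1) for (b in 0:1) for (cc in 0:1) {
    u <- U[f[1] + a + 1, f[2] + b + 1, f[3] + cc + 1]
    if (!is.finite(u)) return(NA_real_)
    acc <- acc + u * abs(1 - a - w[1]) * abs(1 - b - w[2]) *
      abs(1 - cc - w[3])
  }
  acc
}
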