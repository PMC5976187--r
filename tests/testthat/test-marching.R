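test_that("local_update solves the upwind quadratic", {
  expect_equal(local_update(cbind(c(0, Inf, Inf), Inf), 1, c(1, 1, 1)), 1)
  expect_equal(local_update(cbind(c(0, 0, Inf), Inf), 1, c(1, 1, 1)),
               1 / sqrt(2))
  expect_equal(local_update(cbind(c(0, Inf, 0), Inf), 1, c(0.5, 1, 0.9)),
               1 / sqrt(1 / 0.25 + 1 / 0.81))
  # upwind prefix rule: the large neighbor is excluded
  expect_equal(local_update(cbind(c(0, 10, Inf), Inf), 1, c(1, 1, 1)), 1)
  # min of the two per-axis neighbors is used
  expect_equal(local_update(cbind(c(5, Inf, Inf), c(0, Inf, Inf)), 2,
                            c(1, 1, 1)), 2)
  expect_error(local_update(matrix(Inf, 3, 2), 1, c(1, 1, 1)), "finite")
  expect_error(local_update(cbind(c(0, Inf, Inf), Inf), 0, c(1, 1, 1)),
               "positive")
})

test_that("uniform-cost chains give exact linear action maps", {
  for (cost in c(1, 2.5)) {
    v <- vol3d(array(cost, c(1, 1, 30)), spacing = c(1, 1, 0.9))
    am <- solve_action_map(v, c(0, 0, 0))
    expect_lt(max(abs(am$U$data[1, 1, ] - cost * 0.9 * (0:29))), 1e-12)
  }
})

test_that("action map tracks Euclidean distance on a uniform grid", {
  v <- vol3d(array(1, c(41, 41, 41)), spacing = c(1, 1, 1))
  am <- solve_action_map(v, c(20, 20, 20))
  idx <- as.matrix(expand.grid(0:40, 0:40, 0:40))
  eu <- sqrt(rowSums(sweep(idx, 2, c(20, 20, 20))^2))
  rel <- abs(as.vector(am$U$data) - eu) / pmax(eu, 1e-12)
  expect_lte(max(rel[eu >= 5]), 0.10)
})

test_that("fast marching matches the Gauss-Seidel fixed point", {
  # independent iterative oracle on small random-cost grids
  withr::with_seed(100, {
    cases <- lapply(1:5, function(i)
      list(dims = sample(7:13, 3, replace = TRUE),
           spacing = stats::runif(3, 0.4, 1.2),
           seed = sample.int(1e6, 1)))
  })
  for (cs in cases) {
    v <- random_cost(cs$dims, cs$spacing, cs$seed)
    p0 <- voxel_to_world(v, floor(cs$dims / 2))
    ir <- 2 * min(v$spacing)
    am <- solve_action_map(v, p0, init_radius = ir)
    oracle <- gauss_seidel_oracle(v, p0, init_radius = ir)
    expect_lt(max(abs(am$U$data - oracle)), 1e-9)
  }
})

test_that("action maps are deterministic and anisotropy-consistent", {
  v <- random_cost(c(12, 12, 12), c(0.5, 0.5, 0.9), 42)
  a1 <- solve_action_map(v, c(2, 2, 2))
  a2 <- solve_action_map(v, c(2, 2, 2))
  expect_identical(a1$U$data, a2$U$data)
  # z-constant cost: doubling h_z while halving the voxel count leaves
  # U on shared physical points unchanged within discretization error
  slice <- random_cost(c(16, 16, 1), c(0.5, 0.5, 1), 7)$data[, , 1]
  fine <- vol3d(array(rep(slice, 16), c(16, 16, 16)),
                spacing = c(0.5, 0.5, 0.5))
  coarse <- vol3d(array(rep(slice, 8), c(16, 16, 8)),
                  spacing = c(0.5, 0.5, 1))
  af <- solve_action_map(fine, c(3, 3, 3))
  ac <- solve_action_map(coarse, c(3, 3, 3))
  shared_f <- af$U$data[, , seq(1, 16, by = 2)]
  rel <- abs(shared_f - ac$U$data) / pmax(ac$U$data, 1e-9)
  expect_lt(stats::quantile(rel, 0.95), 0.05)
})

test_that("adding a constant to a uniform cost rescales U exactly", {
  base <- 0.8; omega <- 10
  v1 <- vol3d(array(base, c(9, 9, 9)), spacing = c(0.7, 0.7, 1))
  v2 <- vol3d(array(base + omega, c(9, 9, 9)), spacing = c(0.7, 0.7, 1))
  u1 <- solve_action_map(v1, c(0, 0, 0))$U$data
  u2 <- solve_action_map(v2, c(0, 0, 0))$U$data
  expect_lt(max(abs(u2 - u1 * (base + omega) / base) /
                  pmax(u2, 1e-12)), 1e-9)
})

test_that("normalized gradient is unit length, zero off the front", {
  v <- vol3d(array(1, c(1, 1, 15)), spacing = c(1, 1, 1))
  am <- solve_action_map(v, c(0, 0, 0))
  g <- normalized_gradient(am)
  # monotone ramp: gradient points away from the source
  expect_true(all(g$gz[1, 1, 2:15] == 1))
  expect_equal(g$gz[1, 1, 1], 0)       # source voxel
  # partial front: non-alive voxels are exactly zero
  ph <- small_clean_phantom()
  ci <- multispectral_cost(list(ph$seq1), ph$truth$seeds,
                           cost_params(scales = c(2.5, 3.5)))
  am2 <- solve_action_map(ci$p_tilde, ph$truth$seeds$CCA,
                          stop_points = rbind(ph$truth$seeds$ICA))
  expect_true(any(!am2$alive))
  g2 <- normalized_gradient(am2)
  norms <- sqrt(g2$gx^2 + g2$gy^2 + g2$gz^2)
  expect_true(all(norms[!am2$alive] == 0))
  nz <- norms > 0
  expect_lt(max(abs(norms[nz] - 1)), 1e-9)
})

test_that("backtracking recovers the straight uniform-cost geodesic", {
  v <- vol3d(array(1, c(41, 21, 21)), spacing = c(0.5, 0.5, 0.5))
  r <- afm(v, c(0, 5, 5), c(10, 5, 5), delta = 0.1)
  pts <- r$path$points
  expect_equal(pts[1, ], c(0, 5, 5))
  expect_equal(pts[nrow(pts), ], c(10, 5, 5))
  perp <- sqrt((pts[, 2] - 5)^2 + (pts[, 3] - 5)^2)
  expect_lte(max(perp), 0.5)
  expect_gte(path_length(r$path), 10)
  # U interpolated along the path is non-increasing end -> source
  interp_u <- function(U, vox) {
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
  uvals <- apply(pts, 1, function(p)
    interp_u(r$action$U$data, world_to_voxel(v, p)))
  uvals <- uvals[!is.na(uvals)]
  expect_true(all(diff(rev(uvals)) <= 1e-6))
  expect_error(afm(v, c(0, 5, 5), c(0, 5, 5)), "distinct")
})

test_that("geodesics are symmetric under endpoint exchange", {
  v <- random_cost(c(20, 20, 14), c(0.6, 0.6, 0.9), 17, lo = 0.5, hi = 2)
  A <- c(1, 1, 1); B <- c(10, 10, 10)
  pab <- afm(v, A, B, delta = 0.1)$path
  pba <- afm(v, B, A, delta = 0.1)$path
  diag_vox <- sqrt(sum(v$spacing^2))
  expect_lte(hausdorff(pab, pba), diag_vox)
})

test_that("smoothing shortens phantom paths", {
  cp <- clean_pipeline()
  seeds <- cp$ph$truth$seeds
  ci0 <- crop_roi(multispectral_cost(list(cp$ph$seq1, cp$ph$seq2), seeds,
                                     cost_params(omega = 0)), seeds)
  p0 <- afm(ci0$p_tilde, seeds$CCA, seeds$ICA)$path
  ci10 <- crop_roi(multispectral_cost(list(cp$ph$seq1, cp$ph$seq2), seeds,
                                      cost_params(omega = 10)), seeds)
  p10 <- afm(ci10$p_tilde, seeds$CCA, seeds$ICA)$path
  expect_lte(path_length(p10), path_length(p0))
})

test_that("phantom centerline from fast marching stays inside the vessel", {
  cp <- clean_pipeline()
  fitpath <- afm(cp$ci$p_tilde, cp$ph$truth$seeds$CCA,
                 cp$ph$truth$seeds$ICA)$path
  devs <- vapply(seq_len(nrow(fitpath$points)), function(i)
    point_to_path(fitpath$points[i, ], cp$truth_ica), numeric(1))
  expect_lt(max(devs), 3.5)
})
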