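test_that("average path cost divides terminal action by length", {
  v <- vol3d(array(2, c(31, 5, 5)), spacing = c(0.5, 0.5, 0.5))
  r <- afm(v, c(0, 1, 1), c(14, 1, 1), delta = 0.1)
  # uniform cost: average cost approximates the cost itself
  expect_equal(average_path_cost(r$action, r$path), 2, tolerance = 0.02)
  # plug-in check: U(end) / length
  u_end <- r$action$U$data[rbind(round(world_to_voxel(v, c(14, 1, 1))) + 1)]
  expect_equal(average_path_cost(r$action, r$path),
               u_end / path_length(r$path))
  expect_error(
    average_path_cost(solve_action_map(v, c(0, 1, 1),
                                       stop_points = rbind(c(3, 1, 1))),
                      r$path),
    "not frozen")
})

test_that("select_best prefers the cheaper corridor and breaks ties to A", {
  # two corridors of different cost: along y = 0.5 the cost is 0.4,
  # elsewhere 2. The path to B runs inside the cheap corridor; the
  # path to C must traverse the expensive region.
  dat <- array(2, c(31, 11, 3))
  dat[, 1:2, ] <- 0.4
  v <- vol3d(dat, spacing = c(0.5, 0.5, 0.5))
  A <- c(0, 0.5, 0.5); B <- c(14, 0.5, 0.5); C <- c(14, 4.5, 0.5)
  am <- solve_action_map(v, A, stop_points = rbind(B, C))
  pb <- backtrack(am, B); pc <- backtrack(am, C)
  sel <- select_best(pb, pc, am)
  expect_true(sel$best_is_A)
  expect_lt(sel$avg_costs["A"], sel$avg_costs["B"])
  # argument order does not change which path wins
  sel_swapped <- select_best(pc, pb, am)
  expect_false(sel_swapped$best_is_A)
  expect_equal(sel_swapped$best$points, sel$best$points)
  # exact tie goes to the first argument
  sel_tie <- select_best(pc, pc, am)
  expect_true(sel_tie$best_is_A)
})

test_that("constraint_start finds the nearest path point", {
  pts <- cbind(seq(0, 10, by = 0.1), 0, 0)
  p <- centerline(pts, step = 0.1)
  expect_equal(constraint_start(p, pts[37, ]), 37)
  expect_equal(constraint_start(p, c(5.04, 1, 0)), 51)
  # brute force agreement on random references
  withr::with_seed(21, {
    for (i in 1:10) {
      x <- stats::runif(3, -2, 12)
      brute <- which.min(colSums((t(pts) - x)^2))
      expect_equal(constraint_start(p, x), brute)
    }
  })
  # equidistant references resolve to the earliest index
  ptie <- centerline(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)), 1)
  expect_equal(constraint_start(ptie, c(0.5, 3, 0)), 1)
})

test_that("build_constraint dilates the constrained segment only", {
  g <- vol3d(array(1, c(14, 12, 9)), spacing = c(0.5, 0.6, 0.9))
  pts <- cbind(seq(0.5, 5, length.out = 12),
               seq(0.5, 4, length.out = 12),
               seq(0.5, 6, length.out = 12))
  p <- centerline(pts, step = 0.5)
  # empty segment -> empty mask
  expect_equal(sum(build_constraint(p, 13, 1.5, g)$mask), 0)
  # brute-force oracle over voxels x constrained points
  rho <- 1.3; start <- 6
  kap <- build_constraint(p, start, rho, g)
  d <- dim(g$data)
  brute <- array(FALSE, d)
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    w <- (c(i, j, k) - 1) * g$spacing
    dmin <- min(sqrt(colSums((t(pts[start:12, , drop = FALSE]) - w)^2)))
    brute[i, j, k] <- dmin <= rho
  }
  expect_identical(kap$mask, brute)
  # threshold behavior around one constrained point
  single <- centerline(rbind(c(3, 3, 3), c(3, 3, 3.1)), 0.1)
  kap1 <- build_constraint(single, 1, 1.75, g)
  near <- round(world_to_voxel(g, c(3 + 1.0, 3, 3))) + 1
  far <- round(world_to_voxel(g, c(3 + 2.5, 3, 3))) + 1
  expect_true(kap1$mask[near[1], near[2], near[3]])
  expect_false(kap1$mask[far[1], far[2], far[3]])
  # exclusion carves a ball out of the mask
  kap2 <- build_constraint(p, start, rho, g, exclude = rbind(pts[12, ]))
  expect_lt(sum(kap2$mask), sum(kap$mask))
  excl_vox <- which(kap$mask & !kap2$mask, arr.ind = TRUE)
  dists <- sqrt(colSums((t(sweep(excl_vox, 2, 1) %*% diag(g$spacing)) -
                           pts[12, ])^2))
  expect_true(all(dists <= rho + 1e-9))
})

test_that("apply_constraint realizes the blocking cost exactly", {
  withr::with_seed(31, {
    v <- vol3d(array(stats::runif(14 * 12 * 9, 0.5, 2), c(14, 12, 9)),
               spacing = c(0.5, 0.6, 0.9))
  })
  p <- centerline(cbind(seq(1, 5, length.out = 8), 2, 3), 0.5)
  kap <- build_constraint(p, 3, 1.2, v)
  out <- apply_constraint(v, kap, K = 123.5)
  expect_true(all(out$data[kap$mask] == 123.5))
  expect_identical(out$data[!kap$mask], v$data[!kap$mask])
  # empty region: output identical to input
  kap0 <- build_constraint(p, 9, 1.2, v)
  expect_identical(apply_constraint(v, kap0, K = 9)$data, v$data)
  vbad <- vol3d(array(1, c(5, 5, 5)))
  expect_error(apply_constraint(vbad, kap, 1), "grids")
})

test_that("cooperative correction is inactive on well-separated branches", {
  cp <- clean_pipeline()
  seeds <- cp$ph$truth$seeds
  fit_s <- run_method(cp$ci, seeds, method = "SCIE")
  fit_c <- run_method(cp$ci, seeds, method = "CCIE")
  diag_vox <- sqrt(sum(cp$ci$p$spacing^2))
  expect_lte(hausdorff(fit_s$centerline_ICA, fit_c$centerline_ICA),
             diag_vox)
  expect_lte(hausdorff(fit_s$centerline_ECA, fit_c$centerline_ECA),
             diag_vox)
})

test_that("cooperative correction repairs the faint-branch collapse", {
  fp <- faint_pipeline()
  gap_z <- fp$ph$truth$seeds$BIF[3]
  scie <- fp$fits$SCIE
  # the two independent centerlines coincide beyond the bifurcation
  expect_lt(mean_dist_beyond(scie$centerline_ICA, scie$centerline_ECA,
                             gap_z), 1)
  for (m in c("CCIE", "CCBIE")) {
    fit <- fp$fits[[m]]
    r <- cad(fit$centerline_ICA, fit$centerline_ECA,
             fp$truth_ica, fp$truth_eca)
    expect_lt(r$H_ica, 3.5)
    expect_lt(r$H_eca, 3.5)
    # corrected paths keep the full constraint distance beyond the
    # kappa starts
    ks <- max(fit$diagnostics$kappa1_start[3],
              fit$diagnostics$kappa2_start[3])
    expect_gte(min_dist_beyond(fit$centerline_ICA, fit$centerline_ECA,
                               ks), 1.75)
    expect_false(fit$diagnostics$neighbor_in_kappa)
    expect_false(fit$diagnostics$best_in_kappa)
  }
})

test_that("shift_bifurcation walks back along the trunk path", {
  v <- vol3d(array(1, c(46, 9, 9)), spacing = c(0.5, 0.5, 0.5))
  A <- c(0, 2, 2); B <- c(20, 2, 2)
  # straight 20 mm path: t = 5.1 lands at arc position 14.9
  s <- shift_bifurcation(v, A, B, t = 5.1, delta = 0.1)
  expect_equal(s, c(14.9, 2, 2), tolerance = 0.1)
  s0 <- shift_bifurcation(v, A, B, t = 0)
  expect_equal(s0, B, tolerance = 1e-9)
  expect_error(shift_bifurcation(v, A, B, t = 25), "not smaller")
  # on the phantom the shifted point sits inside the vessel, near one
  # of the truth centerlines (the gap point itself lies outside both)
  cp <- clean_pipeline()
  seeds <- cp$ph$truth$seeds
  bs <- shift_bifurcation(cp$ci$p_tilde, seeds$CCA, seeds$BIF, t = 5.1)
  d_vessel <- min(point_to_path(bs, cp$truth_ica),
                  point_to_path(bs, cp$truth_eca))
  expect_lt(d_vessel, max(cp$ph$truth$spec$branch_radii))
  d_gap <- min(point_to_path(seeds$BIF, cp$truth_ica),
               point_to_path(seeds$BIF, cp$truth_eca))
  expect_lt(d_vessel, d_gap)
})

test_that("estimate_bifurcation finds where branch paths merge", {
  p <- centerline(cbind(seq(0, 10, by = 0.1), 0, 0), 0.1)
  expect_equal(estimate_bifurcation(p, p), c(10, 0, 0))
  # two straight lines converging at the origin, half-angle 20 deg
  th <- 20 * pi / 180
  s <- seq(0, 15, by = 0.1)
  la <- centerline(cbind(s * sin(th), 0, s * cos(th)), 0.1)
  lb <- centerline(cbind(-s * sin(th), 0, s * cos(th)), 0.1)
  est <- estimate_bifurcation(la, lb, tol = 1)
  # analytic: distance between lines is below 1 mm where the
  # perpendicular distance from one line's point to the other < 1
  d_pt <- vapply(seq_len(nrow(la$points)), function(i)
    point_to_path(la$points[i, ], lb), numeric(1))
  first <- max(which(d_pt < 1))
  analytic <- (la$points[first, ] + lb$points[first, ]) / 2
  expect_lt(sqrt(sum((est - analytic)^2)), 0.2)
  far_a <- centerline(cbind(s, 0, 0), 0.1)
  far_b <- centerline(cbind(s, 8, 0), 0.1)
  expect_error(estimate_bifurcation(far_a, far_b, tol = 1), "never")
})

test_that("all methods hit their seed endpoints on the clean phantom", {
  cp <- clean_pipeline()
  seeds <- cp$ph$truth$seeds
  for (m in c("SCIE", "SCBIE", "CCIE", "CCBIE")) {
    fit <- run_method(cp$ci, seeds, method = m)
    for (br in c("ICA", "ECA")) {
      pts <- fit[[paste0("centerline_", br)]]$points
      expect_lt(sqrt(sum((pts[1, ] - seeds$CCA)^2)), 0.1)
      expect_lt(sqrt(sum((pts[nrow(pts), ] - seeds[[br]])^2)), 0.1)
    }
    r <- cad(fit$centerline_ICA, fit$centerline_ECA,
             cp$truth_ica, cp$truth_eca)
    expect_false(r$failed)
    if (m %in% c("SCBIE", "CCBIE")) {
      # the shifted bifurcation seed is an exact path point
      bs <- fit$diagnostics$BIF_s
      di <- min(sqrt(colSums((t(fit$centerline_ICA$points) - bs)^2)))
      de <- min(sqrt(colSums((t(fit$centerline_ECA$points) - bs)^2)))
      expect_lt(max(di, de), 1e-9)
    }
  }
  seeds_nobif <- seed_set(CCA = seeds$CCA, ICA = seeds$ICA,
                          ECA = seeds$ECA)
  expect_error(run_method(cp$ci, seeds_nobif, method = "CCBIE"),
               "requires")
  expect_error(run_method(cp$ci, seeds_nobif, method = "CCIE"),
               "requires")
})

test_that("method results are deterministic", {
  fp <- faint_pipeline()
  again <- run_method(fp$ci, fp$ph$truth$seeds, method = "CCIE")
  expect_identical(again$centerline_ICA$points,
                   fp$fits$CCIE$centerline_ICA$points)
  expect_identical(again$centerline_ECA$points,
                   fp$fits$CCIE$centerline_ECA$points)
})
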