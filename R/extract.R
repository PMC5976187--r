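#' Extract carotid bifurcation centerlines
#'
#' Runs one of the four extraction variants on a cost image and a seed
#' set, returning both branch centerlines (common carotid seed to the
#' internal / external branch seed):
#'
#' * `SCIE` — two **S**eparated independent paths, **C**ommon to
#'   **I**nternal and **E**xternal.
#' * `SCBIE` — separated paths routed through the shifted
#'   **B**ifurcation seed: one path common-to-bifurcation, then two
#'   independent paths bifurcation-to-branch; each centerline is the
#'   concatenation.
#' * `CCIE` — **C**ooperative extraction of the two branch paths (see
#'   [cooperative_pair()]), with the annotated bifurcation point
#'   anchoring the constraint region.
#' * `CCBIE` — cooperative extraction from the shifted bifurcation
#'   seed, concatenated with the common-to-bifurcation path.
#'
#' `SCBIE` and `CCBIE` require the annotated bifurcation point
#' (`seeds$BIF`); it is shifted `shift_t` mm back along the
#' trunk-to-bifurcation path to sit inside the lumen (see
#' [shift_bifurcation()]). `CCIE` requires `seeds$BIF` as the
#' constraint-region anchor.
#'
#' @param cost a `cost_image` from [multispectral_cost()] (optionally
#'   cropped with [crop_roi()]), or a plain [vol3d] cost volume.
#' @param seeds a [seed_set].
#' @param method one of `"SCIE"`, `"SCBIE"`, `"CCIE"`, `"CCBIE"`.
#' @param rho cooperative constraint radius, mm.
#' @param K blocking cost (`NULL` for the default; see
#'   [apply_constraint()]).
#' @param delta backtracking step, mm.
#' @param shift_t bifurcation shift distance, mm.
#' @return An object of class `carotid_centerlines`: list with
#'   `centerline_ICA`, `centerline_ECA` ([centerline]s), `method`,
#'   `seeds`, and `diagnostics`.
#' @examples
#' \donttest{
#' ph <- make_phantom(phantom_spec(noise_sd = 0))
#' ci <- multispectral_cost(list(ph$seq1), ph$truth$seeds)
#' fit <- run_method(ci, ph$truth$seeds, method = "SCIE")
#' fit
#' }
#' @export
run_method <- function(cost, seeds, method = c("SCIE", "SCBIE", "CCIE",
                                               "CCBIE"),
                       rho = 1.75, K = NULL, delta = 0.1, shift_t = 5.1) {
  method <- match.arg(method)
  stopifnot(inherits(seeds, "seed_set"))
  p_tilde <- if (inherits(cost, "cost_image")) cost$p_tilde
             else if (inherits(cost, "vol3d")) cost
             else stop("'cost' must be a cost_image or vol3d")
  x_C <- seeds$CCA; x_I <- seeds$ICA; x_E <- seeds$ECA
  diag_info <- list(method = method)

  needs_bif <- method %in% c("SCBIE", "CCIE", "CCBIE")
  if (needs_bif && is.null(seeds$BIF))
    stop("method ", method, " requires the annotated bifurcation seed ",
         "'BIF'")

  concat <- function(trunk, branch) {
    # join at the shared point without duplicating it
    centerline(rbind(trunk$points,
                     branch$points[-1L, , drop = FALSE]),
               step = delta)
  }

  if (method == "SCIE") {
    am <- solve_action_map(p_tilde, x_C, stop_points = rbind(x_I, x_E))
    cl_i <- backtrack(am, x_I, delta = delta)
    cl_e <- backtrack(am, x_E, delta = delta)
    diag_info$avg_costs <- c(ICA = average_path_cost(am, cl_i),
                             ECA = average_path_cost(am, cl_e))
  } else if (method == "SCBIE") {
    bif_s <- shift_bifurcation(p_tilde, x_C, seeds$BIF, t = shift_t,
                               delta = delta)
    trunk <- afm(p_tilde, x_C, bif_s, delta = delta)$path
    am <- solve_action_map(p_tilde, bif_s, stop_points = rbind(x_I, x_E))
    cl_i <- concat(trunk, backtrack(am, x_I, delta = delta))
    cl_e <- concat(trunk, backtrack(am, x_E, delta = delta))
    diag_info$BIF_s <- bif_s
  } else if (method == "CCIE") {
    cp <- cooperative_pair(p_tilde, x_C, x_I, x_E, x_ref = seeds$BIF,
                           rho = rho, K = K, delta = delta)
    cl_i <- cp$path_B
    cl_e <- cp$path_C
    diag_info <- c(diag_info, cp$diagnostics)
  } else {                             # CCBIE
    bif_s <- shift_bifurcation(p_tilde, x_C, seeds$BIF, t = shift_t,
                               delta = delta)
    trunk <- afm(p_tilde, x_C, bif_s, delta = delta)$path
    cp <- cooperative_pair(p_tilde, bif_s, x_I, x_E, x_ref = seeds$BIF,
                           rho = rho, K = K, delta = delta)
    cl_i <- concat(trunk, cp$path_B)
    cl_e <- concat(trunk, cp$path_C)
    diag_info$BIF_s <- bif_s
    diag_info <- c(diag_info, cp$diagnostics)
  }

  structure(list(centerline_ICA = cl_i, centerline_ECA = cl_e,
                 method = method, seeds = seeds,
                 diagnostics = diag_info),
            class = "carotid_centerlines")
}

#' One-call centerline extraction from images and seeds
#'
#' Builds the cost image from one or more co-registered volumes, crops
#' it to the seed bounding box, and runs the requested extraction
#' method. This is the main user-facing entry point; see [run_method()]
#' for the method variants.
#'
#' @param volumes a [vol3d] or list of co-registered [vol3d] volumes.
#' @param seeds a [seed_set].
#' @param method extraction variant (see [run_method()]).
#' @param params a [cost_params].
#' @param crop crop the cost image to the padded seed bounding box
#'   before solving (recommended; solves a much smaller grid).
#' @param ... further arguments passed to [run_method()] (`rho`, `K`,
#'   `delta`, `shift_t`).
#' @return A `carotid_centerlines` object (see [run_method()]), with
#'   the cost image attached as `$cost`.
#' @export
extract_centerlines <- function(volumes, seeds, method = "CCBIE",
                                params = cost_params(), crop = TRUE, ...) {
  ci <- multispectral_cost(volumes, seeds, params)
  if (crop) ci <- crop_roi(ci, seeds)
  fit <- run_method(ci, seeds, method = method, ...)
  fit$cost <- ci
  fit
}

#' @export
print.carotid_centerlines <- function(x, ...) {
  cat(sprintf("<carotid_centerlines> method %s\n", x$method))
  cat("  ICA: "); print(x$centerline_ICA)
  cat("  ECA: "); print(x$centerline_ECA)
  invisible(x)
}

#' @export
summary.carotid_centerlines <- function(object, ...) {
  cl <- list(ICA = object$centerline_ICA, ECA = object$centerline_ECA)
  cat(sprintf("Carotid centerline extraction (%s)\n", object$method))
  for (nm in names(cl)) {
    p <- cl[[nm]]
    cat(sprintf("  %s: %d points, length %.2f mm, start (%.1f, %.1f, %.1f), end (%.1f, %.1f, %.1f)\n",
                nm, nrow(p$points), path_length(p),
                p$points[1, 1], p$points[1, 2], p$points[1, 3],
                p$points[nrow(p$points), 1], p$points[nrow(p$points), 2],
                p$points[nrow(p$points), 3]))
  }
  if (!is.null(object$diagnostics$avg_costs)) {
    ac <- object$diagnostics$avg_costs
    cat(sprintf("  average path cost: %s\n",
                paste(sprintf("%s = %.3g", names(ac), ac),
                      collapse = ", ")))
  }
  invisible(object)
}

#' Plot extracted centerlines
#'
#' Simple projection plot of both centerlines (and the seeds) onto one
#' of the coordinate planes.
#'
#' @param x a `carotid_centerlines` object.
#' @param plane `"xz"` (default), `"xy"` or `"yz"`.
#' @param truth optional list with `centerline_ICA`, `centerline_ECA`
#'   to overlay as reference (dashed).
#' @param ... passed to [graphics::plot()].
#' @export
plot.carotid_centerlines <- function(x, plane = c("xz", "xy", "yz"),
                                     truth = NULL, ...) {
  plane <- match.arg(plane)
  ax <- switch(plane, xz = c(1, 3), xy = c(1, 2), yz = c(2, 3))
  lab <- strsplit(plane, "")[[1]]
  pi_ <- x$centerline_ICA$points[, ax]
  pe_ <- x$centerline_ECA$points[, ax]
  rng <- apply(rbind(pi_, pe_), 2, range)
  graphics::plot(NA, xlim = rng[, 1], ylim = rng[, 2],
                 xlab = paste0(lab[1], " (mm)"),
                 ylab = paste0(lab[2], " (mm)"),
                 main = paste("Centerlines,", x$method), asp = 1, ...)
  if (!is.null(truth)) {
    graphics::lines(truth$centerline_ICA$points[, ax], lty = 2,
                    col = "grey50")
    graphics::lines(truth$centerline_ECA$points[, ax], lty = 2,
                    col = "grey50")
  }
  graphics::lines(pi_, col = "firebrick", lwd = 2)
  graphics::lines(pe_, col = "royalblue", lwd = 2)
  for (nm in c("CCA", "ICA", "ECA", "BIF")) {
    p <- x$seeds[[nm]]
    if (!is.null(p)) graphics::points(p[ax[1]], p[ax[2]], pch = 4)
  }
  graphics::legend("topleft", legend = c("ICA", "ECA"),
                   col = c("firebrick", "royalblue"), lwd = 2, bty = "n")
  invisible(x)
}
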