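#' @title End-to-end phantom pipeline
#' @name pipeline_module
#' @description
#' Chains phantom generation, eigendecomposition, seeding, tracking,
#' whole-tract HA classification and regional quantification into one
#' reproducible call, mirroring the analysis applied to a mid-ventricular
#' lateral-wall ROI: a sector of the wall is seeded, tracts are capped by
#' the \eqn{\pi R} or ROI length policy, and the median-HA histogram
#' variance ratio, the three transmural HA curves, the TCI and the
#' zero-crossing depth are reported.
NULL

#' Sector ROI on a phantom wall
#'
#' Wall voxels with circumferential angle within `half_angle_deg` of the
#' +x direction and axial position within the central `axial_frac` of the
#' phantom height — a lateral-wall, mid-ventricular quantification region.
#'
#' @param ph a `phantom`.
#' @param half_angle_deg sector half-angle (degrees).
#' @param axial_frac fraction of the axial extent retained, centered.
#' @return Logical 3D array.
#' @export
phantom_roi <- function(ph, half_angle_deg = 25, axial_frac = 1 / 3) {
  mask <- ph$tensors$mask
  sp <- ph$tensors$spacing
  dims <- dim(mask)
  idx <- which(mask, arr.ind = TRUE)
  pts <- sweep(idx - 0.5, 2L, sp, `*`)
  ctr <- c(dims[1] * sp[1] / 2, dims[2] * sp[2] / 2)
  th <- atan2(pts[, 2] - ctr[2], pts[, 1] - ctr[1]) * 180 / pi
  zmid <- dims[3] * sp[3] / 2
  zin <- abs(pts[, 3] - zmid) <= ph$spec$height * axial_frac / 2
  roi <- array(FALSE, dims)
  roi[idx[abs(th) <= half_angle_deg & zin, , drop = FALSE]] <- TRUE
  roi
}

#' Run the full phantom quantification pipeline
#'
#' @param spec a [phantom_spec()] (e.g. from [phantom_preset()]).
#' @param params a [tracking_params()].
#' @param length_mode `"pi_r"`, `"roi_clip"` or `"unlimited"`.
#' @param roi_half_angle_deg,roi_axial_frac ROI sector geometry, see
#'   [phantom_roi()].
#' @param via_dwi if `TRUE`, the tensors are additionally pushed through
#'   the forward DWI simulation and re-fit by [fit_tensor()] before
#'   tracking (exercises the acquisition model); `dwi_noise_sd` is the
#'   signal noise SD used then.
#' @param dwi_noise_sd see `via_dwi`.
#' @return List with `phantom`, `roi`, `R` (effective radius, mm),
#'   `tracts`, `classification`, `curves`, `tci`, `histogram`,
#'   `zero_crossing`, and `metrics` (flat named list for serialization).
#' @export
run_phantom_pipeline <- function(spec,
                                 params = tracking_params(seed = spec$seed),
                                 length_mode = c("pi_r", "roi_clip",
                                                 "unlimited"),
                                 roi_half_angle_deg = 25,
                                 roi_axial_frac = 1 / 3,
                                 via_dwi = FALSE, dwi_noise_sd = 0) {
  length_mode <- match.arg(length_mode)
  ph <- generate_phantom(spec)
  tv <- ph$tensors
  if (via_dwi) {
    dwi <- simulate_dwi(ph, noise_sd = dwi_noise_sd, seed = spec$seed)
    tv <- fit_tensor(dwi, ph$tensors$mask)
  }
  ef <- eigendecompose(tv)
  sp <- tv$spacing
  R <- effective_radius(tv$mask, sp, ph$frame)
  roi <- phantom_roi(ph, roi_half_angle_deg, roi_axial_frac)
  seeds <- make_seeds(roi, sp, params)
  policy <- switch(length_mode,
                   pi_r = length_policy("pi_r", R = R),
                   roi_clip = length_policy("roi_clip", roi = roi),
                   unlimited = length_policy("unlimited"))
  tracts <- track(ef, seeds, params, policy)
  cls <- classify_tracts(tracts, ph$frame, params$min_points)
  curves <- transmural_curves(tracts, cls, roi, tv$mask, ph$frame, sp)
  tci_res <- tci(curves)
  hist_res <- ha_histogram(cls)
  zc <- zero_crossing(curves)
  metrics <- list(n_tracts = length(tracts$points),
                  effective_radius_mm = R,
                  tci = tci_res$tci,
                  tci_numerator = tci_res$numerator,
                  tci_denominator = tci_res$denominator,
                  variance_ratio = hist_res$variance_ratio,
                  zero_crossing = zc$depth,
                  length_mode = length_mode)
  list(phantom = ph, roi = roi, R = R, tracts = tracts,
       classification = cls, curves = curves, tci = tci_res,
       histogram = hist_res, zero_crossing = zc, metrics = metrics)
}
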