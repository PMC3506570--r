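#' @title Transmural HA curves, TCI, histograms and variance ratio
#' @name quantify_module
#' @description
#' Whole-tract HA statistics are reduced to regional summaries by a
#' two-step averaging: each classified tract deposits its (min, median,
#' max) HA into every ROI voxel its polyline traverses; per-voxel means
#' are then averaged along the base-apex direction (yielding a 2D
#' transmural x anterior-posterior map per statistic) and finally along
#' the anterior-posterior direction, producing three 1D transmural HA
#' curves. The tractographic coherence index (TCI) is the ratio of the
#' integrated squared median curve to the integrated squared deviations of
#' the min and max curves from the median.
NULL

# Core nested averaging: per-voxel values (already deposit-averaged) with
# (t, a, b) bin indices -> per-t curves. Step 1 averages over a within each
# (t, b) column; step 2 averages the columns over b.
nested_average <- function(values, t_bin, a_bin, b_bin) {
  key_tb <- interaction(t_bin, b_bin, drop = TRUE)
  col_mean <- tapply(values, key_tb, mean)           # average over base-apex
  tb <- do.call(rbind, strsplit(names(col_mean), "\\."))
  t_of_col <- as.integer(tb[, 1])
  out <- tapply(as.numeric(col_mean), t_of_col, mean) # average over ant-post
  list(t = as.integer(names(out)), value = as.numeric(out))
}

#' Build transmural HA curves from classified tracts
#'
#' Deposits each valid tract's whole-tract (min, median, max) HA into
#' every ROI voxel it traverses, then applies the two-step base-apex /
#' anterior-posterior averaging. Local ROI axes come from the frame at the
#' ROI centroid: transmural = radial, base-apex = longitudinal,
#' anterior-posterior = circumferential. Normalized transmural depth x is
#' assigned from each voxel's distance to the center line, scaled by the
#' wall limits of the myocardium mask within the ROI's axial band.
#'
#' @param tracts a `tract_set` from [track()].
#' @param classification matching [classify_tracts()] output.
#' @param roi logical 3D array: quantification region.
#' @param mask logical 3D myocardium mask (defines the wall limits).
#' @param frame a [cardiac_frame()].
#' @param spacing voxel size (mm).
#' @return A `transmural_curves` object: data.frame-like list with `x`
#'   (normalized depth), `ha_min`, `ha_med`, `ha_max`, `counts` (tract
#'   deposits per sample).
#' @export
transmural_curves <- function(tracts, classification, roi, mask, frame,
                              spacing) {
  spacing <- as.numeric(spacing)
  dims <- dim(roi)
  roi_lin <- which(roi)
  if (length(roi_lin) == 0L) stop("transmural_curves: empty ROI")
  st <- classification$stats
  valid <- which(st$valid)

  # --- deposition: tract stats into every traversed ROI voxel ---
  dep_vox <- integer(0); dep_tract <- integer(0)
  for (i in valid) {
    p <- tracts$points[[i]]
    v <- floor(sweep(p, 2L, spacing, `/`))
    keep <- v[, 1] >= 0 & v[, 2] >= 0 & v[, 3] >= 0 &
      v[, 1] < dims[1] & v[, 2] < dims[2] & v[, 3] < dims[3]
    if (!any(keep)) next
    lin <- unique(v[keep, 1] + dims[1] * (v[keep, 2] + dims[2] * v[keep, 3]) + 1)
    lin <- lin[roi[lin]]
    if (length(lin)) {
      dep_vox <- c(dep_vox, lin)
      dep_tract <- c(dep_tract, rep.int(i, length(lin)))
    }
  }
  if (!length(dep_vox)) stop("transmural_curves: no tract intersects the ROI")

  vox_f <- factor(dep_vox)
  per_vox <- data.frame(
    vox = as.integer(levels(vox_f)),
    n = as.integer(table(vox_f)),
    ha_min = as.numeric(tapply(st$ha_min[dep_tract], vox_f, mean)),
    ha_med = as.numeric(tapply(st$ha_med[dep_tract], vox_f, mean)),
    ha_max = as.numeric(tapply(st$ha_max[dep_tract], vox_f, mean)))

  # --- local ROI axes and bins ---
  arr <- arrayInd(per_vox$vox, dims)
  pts <- sweep(arr - 0.5, 2L, spacing, `*`)
  roi_arr <- arrayInd(roi_lin, dims)
  roi_pts <- sweep(roi_arr - 0.5, 2L, spacing, `*`)
  centroid <- colMeans(roi_pts)
  tri0 <- frame_at(frame, matrix(centroid, 1L))
  tri <- frame_at(frame, pts)

  # wall limits from mask voxels in the ROI's axial band
  mask_arr <- which(mask, arr.ind = TRUE)
  mask_pts <- sweep(mask_arr - 0.5, 2L, spacing, `*`)
  tri_m <- frame_at(frame, mask_pts)
  s_rng <- range(frame_at(frame, roi_pts)$s)
  in_band <- tri_m$s >= s_rng[1] - mean(spacing) &
             tri_m$s <= s_rng[2] + mean(spacing)
  r_wall <- tri_m$r[in_band]
  r_endo <- min(r_wall); r_epi <- max(r_wall)
  if (r_epi - r_endo <= 0) stop("transmural_curves: degenerate wall limits")

  h <- mean(spacing)
  x <- (tri$r - r_endo) / (r_epi - r_endo)
  n_t <- max(3L, as.integer(round((r_epi - r_endo) / h)) + 1L)
  t_bin <- pmin(n_t - 1L, pmax(0L, as.integer(floor(x * n_t)))) + 1L
  a_bin <- as.integer(floor((tri$s - s_rng[1]) / h)) + 1L
  # anterior-posterior: arc length of the angle about the centroid triad
  rho <- pts - matrix(centroid, nrow(pts), 3L, byrow = TRUE)
  th <- atan2(rho %*% t(tri0$c_hat), 1e-12 + rho %*% t(tri0$r_hat))
  b_bin <- as.integer(floor(as.numeric(th) * mean(tri$r) / h))
  b_bin <- b_bin - min(b_bin) + 1L

  res_min <- nested_average(per_vox$ha_min, t_bin, a_bin, b_bin)
  res_med <- nested_average(per_vox$ha_med, t_bin, a_bin, b_bin)
  res_max <- nested_average(per_vox$ha_max, t_bin, a_bin, b_bin)
  x_of_t <- tapply(x, t_bin, mean)
  counts <- tapply(per_vox$n, t_bin, sum)
  tt <- res_med$t
  ord <- order(x_of_t[as.character(tt)])
  structure(list(x = as.numeric(x_of_t[as.character(tt)])[ord],
                 ha_min = res_min$value[ord],
                 ha_med = res_med$value[ord],
                 ha_max = res_max$value[ord],
                 counts = as.integer(counts[as.character(tt)])[ord]),
            class = "transmural_curves")
}

#' Construct transmural curves directly
#'
#' Mainly for closed-form analyses and testing: wraps precomputed curves
#' in the `transmural_curves` container used by [tci()] and
#' [zero_crossing()].
#'
#' @param x normalized depth samples (strictly increasing, in `[0, 1]`).
#' @param ha_min,ha_med,ha_max HA curves (degrees).
#' @param counts tract deposits per sample.
#' @return A `transmural_curves` object.
#' @export
transmural_curves_from_values <- function(x, ha_min, ha_med, ha_max,
                                          counts = rep(1L, length(x))) {
  stopifnot(all(diff(x) > 0),
            length(ha_min) == length(x), length(ha_med) == length(x),
            length(ha_max) == length(x))
  structure(list(x = as.numeric(x), ha_min = as.numeric(ha_min),
                 ha_med = as.numeric(ha_med), ha_max = as.numeric(ha_max),
                 counts = as.integer(counts)),
            class = "transmural_curves")
}

#' @export
print.transmural_curves <- function(x, ...) {
  cat(sprintf("transmural_curves: %d depth samples, median HA %+.1f -> %+.1f deg\n",
              length(x$x), x$ha_med[1], x$ha_med[length(x$x)]))
  invisible(x)
}

#' @export
plot.transmural_curves <- function(x, ...) {
  rng <- range(c(x$ha_min, x$ha_med, x$ha_max), na.rm = TRUE)
  graphics::plot(x$x, x$ha_med, type = "l", lwd = 2, ylim = rng,
                 xlab = "transmural depth (endo → epi)",
                 ylab = "helix angle (deg)", ...)
  graphics::lines(x$x, x$ha_min, lty = 2)
  graphics::lines(x$x, x$ha_max, lty = 2)
  graphics::abline(h = 0, col = "gray")
  invisible(x)
}

#' Tractographic coherence index
#'
#' \deqn{TCI = \frac{\int_{endo}^{epi} HA_{med}(x)^2 dx}{
#'   \int (HA_{max}-HA_{med})^2 dx + \int (HA_{min}-HA_{med})^2 dx}}
#' Integrals use the trapezoidal rule over the valid samples on
#' normalized depth, so the index is a pure ratio. High values mean the
#' min/max classifications hug the median: coherent tracts. A vanishing
#' denominator with nonzero numerator returns `Inf` with a flag; 0/0 is an
#' error.
#'
#' @param curves a `transmural_curves` object.
#' @return A `tci_result`: list with `tci`, `numerator`, `denominator`,
#'   `n_samples`, `perfect` (logical flag for the +Inf sentinel).
#' @export
tci <- function(curves) {
  ok <- is.finite(curves$ha_min) & is.finite(curves$ha_med) &
        is.finite(curves$ha_max)
  if (sum(ok) < 3L) stop("tci: fewer than 3 valid transmural samples")
  x <- curves$x[ok]
  med <- curves$ha_med[ok]
  num <- trapz(x, med^2)
  den <- trapz(x, (curves$ha_max[ok] - med)^2) +
         trapz(x, (curves$ha_min[ok] - med)^2)
  if (den < 1e-12 && num < 1e-12)
    stop("tci: undefined (0/0) - all curves identically zero")
  perfect <- den < 1e-12 * num
  structure(list(tci = if (perfect) Inf else num / den,
                 numerator = num, denominator = den,
                 n_samples = sum(ok), perfect = perfect),
            class = "tci_result")
}

#' @export
print.tci_result <- function(x, ...) {
  cat(sprintf("TCI = %.3g (numerator %.4g, denominator %.4g, %d samples)%s\n",
              x$tci, x$numerator, x$denominator, x$n_samples,
              if (x$perfect) " [perfect coherence]" else ""))
  invisible(x)
}

#' Helix-angle histogram and variance ratio
#'
#' Histograms one whole-tract HA statistic over (-90, 90] and computes the
#' variance ratio: sample variance of the strictly negative values divided
#' by that of the strictly positive values (HA = 0 excluded from both).
#' The ratio is computed from the raw values, not the binned counts; near
#' 1 for a symmetric architecture, well below 1 after a rightward
#' (positive) HA shift.
#'
#' @param classification a [classify_tracts()] result, or a numeric vector
#'   of per-tract HA values.
#' @param statistic which whole-tract statistic to use
#'   (`"median"` default, `"min"`, `"max"`, `"mean"`).
#' @param bin_width histogram bin width (degrees).
#' @return An `ha_histogram`: list with `bin_edges`, `counts`,
#'   `statistic`, `variance_ratio` (`NA` with `ratio_defined = FALSE` when
#'   either side has fewer than 2 values), `n_negative`, `n_positive`.
#' @export
ha_histogram <- function(classification,
                         statistic = c("median", "min", "max", "mean"),
                         bin_width = 5) {
  statistic <- match.arg(statistic)
  vals <- if (is.numeric(classification)) classification else {
    col <- c(median = "ha_med", min = "ha_min", max = "ha_max",
             mean = "ha_mean")[statistic]
    classification$stats[[col]][classification$stats$valid]
  }
  vals <- vals[is.finite(vals)]
  edges <- seq(-90, 90, by = bin_width)
  if (edges[length(edges)] < 90) edges <- c(edges, 90)
  counts <- as.integer(table(cut(vals, edges, right = TRUE,
                                 include.lowest = TRUE)))
  neg <- vals[vals < 0]
  pos <- vals[vals > 0]
  defined <- length(neg) >= 2L && length(pos) >= 2L
  structure(list(bin_edges = edges, counts = counts, statistic = statistic,
                 variance_ratio = if (defined) stats::var(neg) / stats::var(pos)
                                  else NA_real_,
                 ratio_defined = defined,
                 n_negative = length(neg), n_positive = length(pos)),
            class = "ha_histogram")
}

#' @export
print.ha_histogram <- function(x, ...) {
  cat(sprintf("ha_histogram (%s HA): %d tracts (%d neg / %d pos), variance ratio %s\n",
              x$statistic, sum(x$counts), x$n_negative, x$n_positive,
              if (x$ratio_defined) sprintf("%.3f", x$variance_ratio)
              else "undefined"))
  invisible(x)
}

#' @export
plot.ha_histogram <- function(x, ...) {
  mids <- (utils::head(x$bin_edges, -1) + utils::tail(x$bin_edges, -1)) / 2
  graphics::barplot(x$counts, names.arg = round(mids), space = 0,
                    xlab = "helix angle (deg)", ylab = "tracts", ...)
  invisible(x)
}

#' Zero-crossing depth of the median HA curve
#'
#' Linear interpolation between the samples bracketing each sign change of
#' the median curve. A rightward (positive) HA shift displaces the
#' crossing toward the epicardium (depth > 0.5).
#'
#' @param curves a `transmural_curves` object.
#' @return List with `depth` (first crossing, `NA` if none), `all`
#'   (every crossing), `multiple` and `none_found` flags.
#' @export
zero_crossing <- function(curves) {
  ok <- is.finite(curves$ha_med)
  x <- curves$x[ok]; y <- curves$ha_med[ok]
  sgn <- sign(y)
  cross <- numeric(0)
  for (i in seq_len(length(y) - 1L)) {
    if (y[i] == 0) { cross <- c(cross, x[i]); next }
    if (sgn[i] * sgn[i + 1L] < 0) {
      cross <- c(cross, x[i] - y[i] * (x[i + 1L] - x[i]) / (y[i + 1L] - y[i]))
    }
  }
  if (length(y) && y[length(y)] == 0) cross <- c(cross, x[length(y)])
  cross <- unique(cross)
  list(depth = if (length(cross)) cross[1] else NA_real_,
       all = cross,
       multiple = length(cross) > 1L,
       none_found = length(cross) == 0L)
}
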