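#' @title LV coordinate frame and helix-angle classification
#' @name helix_angle_module
#' @description
#' The helix angle (HA) of a myofiber is its inclination out of the LV
#' short-axis plane, measured against the local circumferential direction.
#' A `cardiac_frame` maps any wall point to the orthonormal triad
#' (circumferential \eqn{\hat c}, longitudinal \eqn{\hat l}, radial
#' \eqn{\hat r}), with \eqn{\hat r} pointing outward and
#' \eqn{\hat c = \hat l \times \hat r}. Whole tracts are classified by the
#' minimum, maximum, median and mean HA along the tract in addition to the
#' discrete per-point values.
NULL

#' Construct a cardiac frame
#'
#' @param long_axis unit 3-vector, LV long axis (base to apex by package
#'   convention).
#' @param center_line matrix with columns `(s, cx, cy, cz)`: axial position
#'   `s` (mm, measured along `long_axis` from the origin) and the LV
#'   centroid at that position. A single row yields a straight axis.
#' @return A `cardiac_frame` object.
#' @export
cardiac_frame <- function(long_axis, center_line) {
  long_axis <- as.numeric(long_axis)
  long_axis <- long_axis / sqrt(sum(long_axis^2))
  center_line <- matrix(as.numeric(center_line), ncol = 4L)
  center_line <- center_line[order(center_line[, 1]), , drop = FALSE]
  structure(list(long_axis = long_axis, center_line = center_line),
            class = "cardiac_frame")
}

#' Fit the LV frame from a myocardium mask
#'
#' The long axis is taken from the principal-component analysis of the
#' masked voxel centers: the LV cross-section is approximately circularly
#' symmetric, so the long axis is the eigenvector whose eigenvalue is most
#' isolated from the other two (largest spread for an elongated ventricle,
#' smallest for a short thick annulus). The center line is the per-slice
#' centroid of the mask, slices taken perpendicular to the fitted axis at
#' one-voxel intervals.
#'
#' @param mask logical 3D array (nonzero = myocardium).
#' @param spacing voxel size per axis (mm).
#' @return A [cardiac_frame()].
#' @export
fit_lv_frame <- function(mask, spacing) {
  spacing <- as.numeric(spacing)
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("fit_lv_frame: empty mask")
  pts <- sweep(idx - 0.5, 2L, spacing, `*`)   # voxel centers, world mm
  com <- colMeans(pts)
  cv <- stats::cov(pts)
  e <- eigen(cv, symmetric = TRUE)
  if (e$values[3] < 1e-9 * e$values[1])
    stop("fit_lv_frame: degenerate mask (planar or linear)")
  # eigenvalue most isolated from the other two marks the symmetry axis
  axis <- if ((e$values[1] - e$values[2]) >= (e$values[2] - e$values[3]))
    e$vectors[, 1] else e$vectors[, 3]
  lead <- which(abs(axis) == max(abs(axis)))[1]
  if (axis[lead] < 0) axis <- -axis
  s <- as.numeric(pts %*% axis)
  h <- mean(spacing)
  bins <- floor((s - min(s)) / h)
  cl <- t(vapply(split(seq_along(s), bins), function(i) {
    c(mean(s[i]), colMeans(pts[i, , drop = FALSE]))
  }, numeric(4)))
  cardiac_frame(axis, cl)
}

#' Evaluate the local LV triad at points
#'
#' @param frame a [cardiac_frame()].
#' @param points n x 3 matrix of world coordinates (mm).
#' @return List of n x 3 matrices `c_hat`, `l_hat`, `r_hat` plus numeric
#'   `r` (distance from the center line, mm) and `s` (axial position, mm).
#'   Points on the center line yield `NA` rows.
#' @export
frame_at <- function(frame, points) {
  stopifnot(inherits(frame, "cardiac_frame"))
  points <- matrix(as.numeric(points), ncol = 3L)
  l <- frame$long_axis
  s <- as.numeric(points %*% l)
  cl <- frame$center_line
  if (nrow(cl) == 1L) {
    ctr <- matrix(cl[1, 2:4], nrow(points), 3L, byrow = TRUE)
  } else {
    ctr <- cbind(stats::approx(cl[, 1], cl[, 2], s, rule = 2)$y,
                 stats::approx(cl[, 1], cl[, 3], s, rule = 2)$y,
                 stats::approx(cl[, 1], cl[, 4], s, rule = 2)$y)
  }
  d <- points - ctr
  d <- d - outer(as.numeric(d %*% l), l)      # in-plane offset
  r <- row_norms(d)
  r_hat <- normalize_rows(d)
  l_hat <- matrix(l, nrow(points), 3L, byrow = TRUE)
  c_hat <- cross3(l_hat, r_hat)
  list(c_hat = c_hat, l_hat = l_hat, r_hat = r_hat, r = r, s = s)
}

#' Helix angle of fiber vectors
#'
#' Projects each fiber onto the local tangent plane spanned by the
#' circumferential and longitudinal directions and returns
#' \eqn{\mathrm{atan2}(f\cdot\hat l,\, f\cdot\hat c)} in degrees after
#' flipping the fiber so its circumferential component is non-negative
#' (fibers are axial: HA(f) = HA(-f)). Results lie in (-90, 90]. Fibers
#' parallel to the radial direction (in-plane norm < 1e-9) are undefined
#' and returned as `NA`.
#'
#' @param fibers n x 3 matrix of fiber vectors (need not be unit).
#' @param triad output of [frame_at()] at the same n points.
#' @return numeric vector of helix angles (degrees).
#' @export
helix_angle <- function(fibers, triad) {
  fibers <- matrix(as.numeric(fibers), ncol = 3L)
  hc <- rowSums(fibers * triad$c_hat)
  hl <- rowSums(fibers * triad$l_hat)
  inplane <- sqrt(hc^2 + hl^2)
  undef <- !is.finite(inplane) | inplane < 1e-9 * row_norms(fibers)
  flip <- !undef & hc < 0
  hc[flip] <- -hc[flip]
  hl[flip] <- -hl[flip]
  ha <- atan2(hl, hc) * 180 / pi * .ha_sign
  ha[!undef & ha <= -90] <- 90   # fold the open end of (-90, 90]
  ha[undef] <- NA_real_
  ha
}

#' Classify tracts by whole-tract helix-angle statistics
#'
#' Computes the discrete per-point HA along every streamline and reduces
#' each tract to its minimum, median, maximum and mean HA. The median of an
#' even count is the mean of the two central values. Vertices with
#' undefined HA (radial fibers) are excluded from the statistics and
#' counted; tracts whose defined vertices fall below `min_points`, or whose
#' discrete HA jumps by more than 90 degrees between consecutive vertices
#' (wrap-around suspicion), are flagged.
#'
#' @param tracts a `tract_set` from [track()] (or any list with a `points`
#'   field holding n x 3 matrices).
#' @param frame a [cardiac_frame()].
#' @param min_points minimum defined vertices for a valid classification.
#' @return A `tract_classification`: list with `stats` (data.frame
#'   `tract_id, n_points, n_undefined, ha_min, ha_med, ha_max, ha_mean,
#'   jump_flag, valid`) and `discrete` (list of per-point HA vectors).
#' @export
classify_tracts <- function(tracts, frame, min_points = 3L) {
  pts_list <- tracts$points
  n <- length(pts_list)
  npts <- vapply(pts_list, nrow, integer(1))
  all_pts <- do.call(rbind, pts_list)
  id <- rep.int(seq_len(n), npts)
  triad <- frame_at(frame, all_pts)
  # fiber direction at a vertex: mean of adjacent segment directions
  off <- c(0L, cumsum(npts))
  fib <- matrix(NA_real_, nrow(all_pts), 3L)
  for (i in seq_len(n)) {
    p <- pts_list[[i]]
    m <- nrow(p)
    rows <- (off[i] + 1L):(off[i] + m)
    if (m == 1L) next
    d <- diff(p)
    d <- normalize_rows(d)
    v <- rbind(d[1, , drop = FALSE],
               if (m > 2L) normalize_rows(d[-nrow(d), , drop = FALSE] +
                                          d[-1L, , drop = FALSE]),
               d[nrow(d), , drop = FALSE])
    fib[rows, ] <- v
  }
  ha <- helix_angle(fib, triad)
  discrete <- split(ha, factor(id, levels = seq_len(n)))
  stats_df <- do.call(rbind, lapply(seq_len(n), function(i) {
    h <- discrete[[i]]
    hv <- h[is.finite(h)]
    jump <- length(hv) > 1L && any(abs(diff(hv)) > 90)
    valid <- length(hv) >= min_points
    data.frame(tract_id = i,
               n_points = length(h),
               n_undefined = sum(!is.finite(h)),
               ha_min = if (valid) min(hv) else NA_real_,
               ha_med = if (valid) stats::median(hv) else NA_real_,
               ha_max = if (valid) max(hv) else NA_real_,
               ha_mean = if (valid) mean(hv) else NA_real_,
               jump_flag = jump,
               valid = valid)
  }))
  structure(list(stats = stats_df, discrete = discrete),
            class = "tract_classification")
}

#' @export
print.tract_classification <- function(x, ...) {
  cat(sprintf("tract_classification: %d tracts (%d valid), median HA range [%.1f, %.1f] deg\n",
              nrow(x$stats), sum(x$stats$valid),
              min(x$stats$ha_med, na.rm = TRUE),
              max(x$stats$ha_med, na.rm = TRUE)))
  invisible(x)
}
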