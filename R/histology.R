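#' @title Hessian ridge orientation analysis of histology sections
#' @name histology_module
#' @description
#' Recovers the mean fiber orientation of a 2D grayscale microscopy
#' section: the image is Gaussian-smoothed, the per-pixel Hessian
#' eigendecomposed, and ridge pixels (local extrema of the principal
#' intensity curvature along its own direction) extracted, thinned to
#' single-pixel width, chained into 8-connected segments and summarized by
#' a length-weighted circular mean on the half-circle (axial angles:
#' +90 and -90 degrees are the same orientation).
#'
#' Image convention: matrices are indexed `[row, col]`; angles are
#' measured against the horizontal axis, counterclockwise with y pointing
#' up (row index increasing downward), in (-90, 90].
NULL

# Separable Gaussian smoothing with replicate padding.
gaussian_smooth <- function(img, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  smooth_dim <- function(m, along_rows) {
    if (along_rows) m <- t(m)
    n <- ncol(m)
    pad <- cbind(m[, rep(1L, r), drop = FALSE], m,
                 m[, rep(n, r), drop = FALSE])
    out <- matrix(0, nrow(m), n)
    for (i in seq_along(k))
      out <- out + k[i] * pad[, i:(i + n - 1L), drop = FALSE]
    if (along_rows) t(out) else out
  }
  smooth_dim(smooth_dim(img, FALSE), TRUE)
}

# Shift a matrix by (dr, dc) with replicate padding.
shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- pmin(nr, pmax(1L, seq_len(nr) + dr))
  ci <- pmin(nc, pmax(1L, seq_len(nc) + dc))
  m[ri, ci, drop = FALSE]
}

# Zhang-Suen thinning of a logical matrix to single-pixel width.
thin_mask <- function(mask) {
  m <- mask * 1L
  repeat {
    changed <- FALSE
    for (pass in 1:2) {
      # 8-neighborhood in order P2..P9 (N, NE, E, SE, S, SW, W, NW), y up:
      # with matrix rows increasing downward, N = row - 1.
      p2 <- shift_mat(m, -1L, 0L); p3 <- shift_mat(m, -1L, 1L)
      p4 <- shift_mat(m, 0L, 1L);  p5 <- shift_mat(m, 1L, 1L)
      p6 <- shift_mat(m, 1L, 0L);  p7 <- shift_mat(m, 1L, -1L)
      p8 <- shift_mat(m, 0L, -1L); p9 <- shift_mat(m, -1L, -1L)
      B <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      A <- (p2 == 0 & p3 == 1) + (p3 == 0 & p4 == 1) + (p4 == 0 & p5 == 1) +
           (p5 == 0 & p6 == 1) + (p6 == 0 & p7 == 1) + (p7 == 0 & p8 == 1) +
           (p8 == 0 & p9 == 1) + (p9 == 0 & p2 == 1)
      if (pass == 1L) {
        cond <- p2 * p4 * p6 == 0 & p4 * p6 * p8 == 0
      } else {
        cond <- p2 * p4 * p8 == 0 & p2 * p6 * p8 == 0
      }
      del <- m == 1L & B >= 2 & B <= 6 & A == 1 & cond
      if (any(del)) {
        m[del] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m == 1L
}

# 8-connected component labels for a logical matrix (BFS).
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  idx <- which(mask)
  offs <- expand.grid(dr = -1:1, dc = -1:1)
  offs <- offs[!(offs$dr == 0 & offs$dc == 0), ]
  for (start in idx) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      v <- queue[length(queue)]
      queue <- queue[-length(queue)]
      r0 <- ((v - 1L) %% nr) + 1L
      c0 <- ((v - 1L) %/% nr) + 1L
      rr <- r0 + offs$dr
      cc <- c0 + offs$dc
      ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
      nb <- (cc[ok] - 1L) * nr + rr[ok]
      nb <- nb[mask[nb] & lab[nb] == 0L]
      if (length(nb)) {
        lab[nb] <- cur
        queue <- c(queue, nb)
      }
    }
  }
  lab
}

# Orientation (degrees in (-90, 90], y up) of a pixel chain via the
# principal axis of its coordinate covariance.
chain_angle <- function(rows, cols) {
  x <- cols
  y <- -rows                 # y up
  if (length(x) < 2L) return(NA_real_)
  cxx <- stats::var(x); cyy <- stats::var(y); cxy <- stats::cov(x, y)
  ang <- 0.5 * atan2(2 * cxy, cxx - cyy) * 180 / pi
  if (ang <= -90) ang <- ang + 180
  if (ang > 90) ang <- ang - 180
  ang
}

#' Extract ridge segments from a section image
#'
#' Ridge pixels are local extrema of the principal intensity curvature:
#' pixels where the magnitude of the dominant Hessian eigenvalue of the
#' Gaussian-smoothed image exceeds `curvature_threshold` and the intensity
#' is extremal along the principal-curvature direction (both bright
#' fibers and dark interstitial spaces are kept). The ridge mask is
#' thinned to single-pixel width and chained into 8-connected segments;
#' segments shorter than `min_segment_length` pixels are dropped.
#'
#' @param img numeric matrix of intensities.
#' @param scale_sigma Gaussian smoothing scale (pixels), >= 1.
#' @param curvature_threshold absolute principal-curvature cutoff; the
#'   default `NULL` uses half the standard deviation of the principal
#'   curvature over the image.
#' @param min_segment_length minimum chain length (pixels).
#' @return A `ridge_segments` object: data.frame `segments`
#'   (`segment_id, angle_deg, length_px`), list `pixels` of `(row, col)`
#'   matrices, logical `empty` flag, and the thinned `ridge_mask`.
#' @export
hessian_orientation <- function(img, scale_sigma = 2,
                                curvature_threshold = NULL,
                                min_segment_length = 10L) {
  stopifnot(is.matrix(img), scale_sigma >= 1)
  s <- gaussian_smooth(img, scale_sigma)
  # central-difference Hessian (x = col, y = -row)
  Ixx <- shift_mat(s, 0L, 1L) - 2 * s + shift_mat(s, 0L, -1L)
  Iyy <- shift_mat(s, 1L, 0L) - 2 * s + shift_mat(s, -1L, 0L)
  Ixy <- (shift_mat(s, -1L, 1L) + shift_mat(s, 1L, -1L) -
          shift_mat(s, -1L, -1L) - shift_mat(s, 1L, 1L)) / 4
  tr2 <- (Ixx + Iyy) / 2
  disc <- sqrt(((Ixx - Iyy) / 2)^2 + Ixy^2)
  k1 <- tr2 + disc
  k2 <- tr2 - disc
  kp <- ifelse(abs(k1) >= abs(k2), k1, k2)   # principal curvature
  if (is.null(curvature_threshold))
    curvature_threshold <- 0.5 * stats::sd(kp)
  # unit eigenvector of the principal curvature: (Ixy, kp - Ixx) in (x, y)
  vx <- Ixy
  vy <- kp - Ixx
  nrm <- sqrt(vx^2 + vy^2)
  deg <- nrm < 1e-12                          # isotropic: direction from axes
  vx[deg] <- as.numeric(abs(Ixx) >= abs(Iyy))[deg]
  vy[deg] <- as.numeric(abs(Ixx) < abs(Iyy))[deg]
  nrm[deg] <- 1
  vx <- vx / nrm; vy <- vy / nrm

  # extremal along the principal direction: compare with bilinear samples
  # one pixel away on either side (step in rows is -vy: y up).
  sample_off <- function(sx, sy) {
    rr <- matrix(rep(seq_len(nrow(s)), ncol(s)), nrow(s)) - sy
    cc <- matrix(rep(seq_len(ncol(s)), each = nrow(s)), nrow(s)) + sx
    r0 <- pmin(nrow(s) - 1L, pmax(1L, floor(rr))); fr <- rr - r0
    c0 <- pmin(ncol(s) - 1L, pmax(1L, floor(cc))); fc <- cc - c0
    i00 <- (c0 - 1L) * nrow(s) + r0
    s[i00] * (1 - fr) * (1 - fc) + s[i00 + 1L] * fr * (1 - fc) +
      s[i00 + nrow(s)] * (1 - fr) * fc + s[i00 + nrow(s) + 1L] * fr * fc
  }
  up <- sample_off(vx, vy)
  dn <- sample_off(-vx, -vy)
  ridge <- abs(kp) > curvature_threshold &
    ((kp < 0 & s >= up & s >= dn) |   # bright ridge: intensity maximum
     (kp > 0 & s <= up & s <= dn))    # dark ridge: intensity minimum
  # border pixels have unreliable derivatives
  ridge[c(1L, nrow(ridge)), ] <- FALSE
  ridge[, c(1L, ncol(ridge))] <- FALSE

  if (!any(ridge)) {
    return(structure(list(segments = data.frame(segment_id = integer(0),
                                                angle_deg = numeric(0),
                                                length_px = integer(0)),
                          pixels = list(), empty = TRUE,
                          ridge_mask = ridge),
                     class = "ridge_segments"))
  }
  thin <- thin_mask(ridge)
  lab <- label_components(thin)
  ids <- setdiff(unique(as.integer(lab)), 0L)
  segs <- list(); pix <- list(); k <- 0L
  for (id in ids) {
    w <- which(lab == id, arr.ind = TRUE)
    if (nrow(w) < min_segment_length) next
    k <- k + 1L
    segs[[k]] <- data.frame(segment_id = k,
                            angle_deg = chain_angle(w[, 1], w[, 2]),
                            length_px = nrow(w))
    pix[[k]] <- w
  }
  if (k == 0L) {
    return(structure(list(segments = data.frame(segment_id = integer(0),
                                                angle_deg = numeric(0),
                                                length_px = integer(0)),
                          pixels = list(), empty = TRUE, ridge_mask = thin),
                     class = "ridge_segments"))
  }
  structure(list(segments = do.call(rbind, segs), pixels = pix,
                 empty = FALSE, ridge_mask = thin),
            class = "ridge_segments")
}

#' @export
print.ridge_segments <- function(x, ...) {
  if (x$empty) {
    cat("ridge_segments: no ridges found\n")
  } else {
    cat(sprintf("ridge_segments: %d segments, total length %d px, mean angle %.1f deg\n",
                nrow(x$segments), sum(x$segments$length_px),
                section_mean_ha(x)))
  }
  invisible(x)
}

#' Mean helix angle of a section
#'
#' Length-weighted circular mean of the segment angles on the half-circle:
#' angles are doubled, averaged as unit vectors, halved and mapped back to
#' (-90, 90]. Axial statistics are required because fiber orientation has
#' no polarity (a +80 and a -80 degree segment average to +/-90, not 0).
#' The global MR sign convention ([ha_sign_convention()]) is applied.
#'
#' @param segs a `ridge_segments` object (or data.frame with `angle_deg`
#'   and `length_px`).
#' @param weighted length-weight the mean (default) or treat all segments
#'   equally.
#' @return Mean orientation in degrees, (-90, 90].
#' @export
section_mean_ha <- function(segs, weighted = TRUE) {
  df <- if (inherits(segs, "ridge_segments")) segs$segments else segs
  if (nrow(df) == 0L) stop("section_mean_ha: no segments")
  w <- if (weighted) df$length_px else rep(1, nrow(df))
  a2 <- df$angle_deg * 2 * pi / 180
  ang <- atan2(sum(w * sin(a2)), sum(w * cos(a2))) / 2 * 180 / pi
  if (ang <= -90) ang <- ang + 180
  .ha_sign * ang
}

#' Transmural HA profile from sectioned histology
#'
#' Runs the ridge analysis on each section and tabulates the per-level
#' mean HA, ordered from endocardium (level 1) to epicardium.
#'
#' @param sections named or unnamed list of image matrices.
#' @param levels integer transmural level per section (1 = endo); defaults
#'   to list order.
#' @param ... passed to [hessian_orientation()].
#' @return data.frame `(level, mean_ha_deg, n_segments, total_length_px)`;
#'   levels with no segments carry `NA`.
#' @export
transmural_profile <- function(sections, levels = seq_along(sections), ...) {
  stopifnot(length(sections) >= 2L, length(levels) == length(sections))
  rows <- lapply(seq_along(sections), function(i) {
    segs <- hessian_orientation(sections[[i]], ...)
    if (segs$empty) {
      data.frame(level = levels[i], mean_ha_deg = NA_real_,
                 n_segments = 0L, total_length_px = 0L)
    } else {
      data.frame(level = levels[i],
                 mean_ha_deg = section_mean_ha(segs),
                 n_segments = nrow(segs$segments),
                 total_length_px = sum(segs$segments$length_px))
    }
  })
  out <- do.call(rbind, rows)
  out[order(out$level), , drop = FALSE]
}
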