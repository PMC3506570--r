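test_that("fit_lv_frame recovers the cylinder axis, also after rotation", {
  mk_mask <- function(rot = diag(3)) {
    n <- 40; nz <- 40
    mask <- array(FALSE, c(n, n, nz))
    ctr <- c(n / 2, n / 2, nz / 2)
    idx <- which(array(TRUE, c(n, n, nz)), arr.ind = TRUE)
    p <- sweep(idx - 0.5, 2, ctr, `-`)
    q <- p %*% rot                       # coordinates in the cylinder frame
    r <- sqrt(q[, 1]^2 + q[, 2]^2)
    sel <- r >= 8 & r <= 12 & abs(q[, 3]) <= 14
    mask[idx[sel, , drop = FALSE]] <- TRUE
    mask
  }
  fr <- fit_lv_frame(mk_mask(), c(1, 1, 1))
  expect_gt(abs(sum(fr$long_axis * c(0, 0, 1))), cos(0.1 * pi / 180))

  th <- 30 * pi / 180
  rot <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)), 3)
  fr2 <- fit_lv_frame(mk_mask(rot), c(1, 1, 1))
  true_axis <- as.numeric(rot %*% c(0, 0, 1))
  expect_gt(abs(sum(fr2$long_axis * true_axis)), cos(1 * pi / 180))

  expect_error(fit_lv_frame(array(FALSE, c(4, 4, 4)), c(1, 1, 1)), "empty")
  planar <- array(FALSE, c(8, 8, 8)); planar[, , 4] <- TRUE
  planar[, , 4][c(1, 64)] <- TRUE
  expect_error(fit_lv_frame(planar, c(1, 1, 1)), "degenerate")
})

test_that("the frame triad is orthonormal, outward-radial, and fixed-handed", {
  frame <- cardiac_frame(c(0, 0, 1), matrix(c(0, 0, 0, 0), 1))
  tri <- frame_at(frame, rbind(c(5, 0, 2), c(0, 7, -1), c(-3, 3, 4)))
  for (i in 1:3) {
    M <- rbind(tri$c_hat[i, ], tri$l_hat[i, ], tri$r_hat[i, ])
    expect_equal(tcrossprod(M), diag(3), tolerance = 1e-9)
  }
  # point at (r, 0, z) with axis +z: r = +x, and c = l x r = +y
  expect_equal(tri$r_hat[1, ], c(1, 0, 0), tolerance = 1e-12)
  expect_equal(tri$c_hat[1, ], c(0, 1, 0), tolerance = 1e-12)
  expect_equal(tri$r[1], 5)
})

test_that("helix_angle follows its conventions and symmetry", {
  frame <- cardiac_frame(c(0, 0, 1), matrix(c(0, 0, 0, 0), 1))
  p <- matrix(c(5, 0, 0), 1)
  tri <- frame_at(frame, p[rep(1, 6), ])
  ch <- c(0, 1, 0); lh <- c(0, 0, 1); rh <- c(1, 0, 0)
  fib <- rbind(ch, lh, (ch + lh) / sqrt(2), (ch - lh) / sqrt(2), -ch, rh)
  ha <- helix_angle(fib, tri)
  expect_equal(ha[1:5], c(0, 90, 45, -45, 0), tolerance = 1e-9)
  expect_true(is.na(ha[6]))                  # radial fiber: undefined
  # antipodal: HA(f) == HA(-f) for random fibers
  set.seed(1)
  f <- matrix(stats::rnorm(60), ncol = 3)
  tri2 <- frame_at(frame, matrix(rep(c(5, 0, 0), 20), ncol = 3, byrow = TRUE))
  expect_equal(helix_angle(f, tri2), helix_angle(-f, tri2), tolerance = 1e-9)
  ha_all <- helix_angle(f, tri2)
  expect_true(all(ha_all > -90 & ha_all <= 90))
})

test_that("classify_tracts reduces discrete HA by the stated statistics", {
  # synthetic 'tract_set' with hand-made geometry: vertices along c with
  # controlled inclination produce exactly the intended HA sequence
  frame <- cardiac_frame(c(0, 0, 1), matrix(c(0, 0, 0, 0), 1))
  mk_tract <- function(ha_seq) {
    # walk in the tangent plane at radius 1000 (locally flat): each segment
    # direction = cos(ha) c + sin(ha) l with c ~ +y at (1000, 0, z)
    p <- c(1000, 0, 0)
    pts <- matrix(p, 1)
    for (a in ha_seq * pi / 180) {
      p <- p + 1e-3 * c(0, cos(a), sin(a))
      pts <- rbind(pts, p)
    }
    pts
  }
  # segment HAs [10, 20, 30] -> vertex HAs [10, 15, 25, 30]
  tr <- structure(list(points = list(mk_tract(c(10, 20, 30)),
                                     mk_tract(c(25, 25, 25, 25)),
                                     mk_tract(c(-60, -10, 20)))),
                  class = "tract_set")
  cls <- classify_tracts(tr, frame)
  st <- cls$stats
  expect_equal(st$ha_min[1], 10, tolerance = 1e-3)
  expect_equal(st$ha_max[1], 30, tolerance = 1e-3)
  expect_equal(st$ha_med[1], 20, tolerance = 1e-3)
  expect_equal(st$ha_mean[1], 20, tolerance = 1e-3)
  # constant tract: all four statistics equal
  expect_equal(unlist(st[2, c("ha_min", "ha_med", "ha_max", "ha_mean")]),
               rep(25, 4), tolerance = 1e-3, ignore_attr = TRUE)
  # segment HAs [-60, -10, 20] -> vertex HAs [-60, -35, 5, 20]:
  # even-count median = mean of the two central values
  d3 <- cls$discrete[[3]]
  expect_equal(length(d3), 4L)
  expect_equal(st$ha_med[3], mean(sort(d3)[2:3]))
  expect_equal(st$ha_med[3], -15, tolerance = 1e-3)
})

test_that("tract median HA tracks the generating profile depth by depth", {
  spec <- phantom_preset("normal-human", orientation_noise_sd = 0, seed = 1)
  ph <- generate_phantom(spec)
  ef <- eigendecompose(ph$tensors)
  sp <- ph$tensors$spacing
  roi <- phantom_roi(ph, 30, 0.5)
  seeds <- make_seeds(roi, sp)
  R <- effective_radius(ph$tensors$mask, sp, ph$frame)
  tr <- track(ef, seeds, tracking_params(), length_policy("pi_r", R = R))
  cls <- classify_tracts(tr, ph$frame)
  seed_pts <- t(vapply(tr$points, function(p) p[(nrow(p) + 1) %/% 2, ],
                       numeric(3)))
  r_seed <- frame_at(ph$frame, seed_pts)$r
  x <- (r_seed - spec$inner_radius) /
    (spec$outer_radius - spec$inner_radius)
  ok <- cls$stats$valid & x > 0.1 & x < 0.9
  pred <- spec$alpha_endo + x * (spec$alpha_epi - spec$alpha_endo)
  expect_lt(max(abs(cls$stats$ha_med[ok] - pred[ok])), 2)
  # sign audit: subendocardial positive, subepicardial negative
  expect_true(all(cls$stats$ha_med[cls$stats$valid & x < 0.35] > 0))
  expect_true(all(cls$stats$ha_med[cls$stats$valid & x > 0.65] < 0))
})

test_that("whole-tract statistics narrow the discrete HA range in a tapered wall", {
  spec <- small_phantom_spec(orientation_noise_sd = 0, taper = 0.5,
                             height = 24)
  ph <- generate_phantom(spec)
  ef <- eigendecompose(ph$tensors)
  sp <- ph$tensors$spacing
  roi <- phantom_roi(ph, 30, 0.25)
  R <- effective_radius(ph$tensors$mask, sp, ph$frame)
  tr <- track(ef, make_seeds(roi, sp), tracking_params(),
              length_policy("pi_r", R = R))
  cls <- classify_tracts(tr, ph$frame)
  disc_spread <- vapply(seq_along(cls$discrete), function(i) {
    h <- cls$discrete[[i]]; diff(range(h[is.finite(h)]))
  }, numeric(1))
  ok <- cls$stats$valid & vapply(cls$discrete,
                                 function(h) sum(is.finite(h)) > 20, TRUE)
  # per-tract discrete range exceeds the (zero) spread of its single median
  expect_gt(mean(disc_spread[ok]), 0)
  # and across tracts, the median-HA range is narrower than the discrete range
  disc_all <- range(unlist(cls$discrete[ok]), na.rm = TRUE)
  med_all <- range(cls$stats$ha_med[ok])
  expect_lt(diff(med_all), diff(disc_all))
})

test_that("radial-fiber vertices are excluded and all-undefined tracts invalidated", {
  frame <- cardiac_frame(c(0, 0, 1), matrix(c(0, 0, 0, 0), 1))
  # tract walking radially outward: every vertex has an undefined HA
  pts <- cbind(seq(5, 6, by = 0.1), 0, 0)
  tr <- structure(list(points = list(pts)), class = "tract_set")
  cls <- classify_tracts(tr, frame)
  expect_false(cls$stats$valid[1])
  expect_equal(cls$stats$n_undefined[1], nrow(pts))
})
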