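test_that("a uniform field yields straight, uniformly spaced polylines", {
  f <- uniform_field(20)
  seed <- matrix(c(10, 10.5, 10.5), 1)
  tr <- track(f, seed, tracking_params(step_fraction = 0.25),
              length_policy("unlimited"))
  p <- tr$points[[1]]
  expect_true(all(abs(p[, 2] - 10.5) < 1e-9))
  expect_true(all(abs(p[, 3] - 10.5) < 1e-9))
  spacing <- cardiotract:::row_norms(diff(p))
  expect_equal(spacing, rep(0.25, nrow(p) - 1), tolerance = 1e-6)
  expect_equal(as.character(tr$termination$fwd[1]), "mask_exit")
  expect_equal(as.character(tr$termination$bwd[1]), "mask_exit")
})

test_that("the tracker follows the analytic circular field with small radial drift", {
  cf <- circular_field(Rc = 30)
  seed <- matrix(c(cf$center[1] + cf$Rc, cf$center[2],
                   cf$nz * cf$spacing / 2), 1)
  # R/100 step; full revolution via the pi_r cap at 2 Rc
  tr <- track(cf$field, seed, tracking_params(step_fraction = cf$Rc / 100),
              length_policy("pi_r", R = 2 * cf$Rc))
  p <- tr$points[[1]]
  r <- sqrt((p[, 1] - cf$center[1])^2 + (p[, 2] - cf$center[2])^2)
  expect_gt(sum(cardiotract:::row_norms(diff(p))), 2 * pi * cf$Rc * 0.99)
  expect_lt(max(abs(r - cf$Rc)), 1e-3 * cf$Rc)
})

test_that("the reference RK4 integrator converges at fourth order on the circle", {
  Rc <- 30
  f <- function(p) c(-p[2], p[1], 0)
  endpoint_error <- function(h) {
    n <- round(2 * pi * Rc / h)
    pts <- rk4_streamline(f, c(Rc, 0, 0), h, n)
    s <- n * h
    truth <- c(Rc * cos(s / Rc), Rc * sin(s / Rc), 0)
    sqrt(sum((pts[n + 1, ] - truth)^2))
  }
  e1 <- endpoint_error(Rc / 40)
  e2 <- endpoint_error(Rc / 80)
  expect_lt(e1, 1e-3 * Rc)
  expect_gte(e1 / e2, 8)           # global O(h^4)
})

test_that("propagation-angle termination fires at a sharp planar interface", {
  n <- 24
  mk_interface <- function(deg) {
    e1 <- array(0, c(n, n, n, 3))
    e1[1:12, , , 1] <- 1                    # +x on the left half
    a <- deg * pi / 180
    e1[13:n, , , 1] <- cos(a)               # rotated beyond x = 12
    e1[13:n, , , 2] <- sin(a)
    list(e1 = e1, mask = array(TRUE, c(n, n, n)), spacing = c(1, 1, 1))
  }
  seeds <- cbind(6, seq(8.5, 15.5, by = 1), 12.5)
  # an 80-degree interface turns by more than 35 degrees within a single
  # half-voxel step despite trilinear smoothing: every branch stops at the
  # plane with reason 'angle'
  tr <- track(mk_interface(80), seeds,
              tracking_params(step_fraction = 0.5,
                              max_propagation_angle = 35),
              length_policy("unlimited"))
  expect_true(all(tr$termination$fwd == "angle"))
  ends <- vapply(tr$points, function(p) max(p[, 1]), numeric(1))
  expect_true(all(ends < 13.5))             # stopped at the interface
  # a 40-degree interface at quarter-voxel steps is smoothed below the
  # threshold by interpolation and traversed: the criterion is per step
  tr40 <- track(mk_interface(40), seeds,
                tracking_params(step_fraction = 0.25,
                                max_propagation_angle = 35),
                length_policy("unlimited"))
  expect_true(all(tr40$termination$fwd == "mask_exit"))
})

test_that("tract geometry is invariant under a global eigenvector sign flip", {
  cf <- circular_field(n = 40, Rc = 14, band = 6)
  seeds <- rbind(c(cf$center[1] + cf$Rc, cf$center[2], 4.5),
                 c(cf$center[1], cf$center[2] + cf$Rc, 4.5))
  tr1 <- track(cf$field, seeds, tracking_params(),
               length_policy("pi_r", R = cf$Rc))
  f2 <- cf$field
  f2$e1 <- -f2$e1
  tr2 <- track(f2, seeds, tracking_params(),
               length_policy("pi_r", R = cf$Rc))
  expect_equal(length(tr1$points), length(tr2$points))
  for (i in seq_along(tr1$points))
    expect_lt(max(abs(tr1$points[[i]] - tr2$points[[i]])), 1e-9)
})

test_that("length policies cap tract length and clip to the ROI", {
  ph <- generate_phantom(small_phantom_spec(orientation_noise_sd = 3,
                                            seed = 5))
  ef <- eigendecompose(ph$tensors)
  sp <- ph$tensors$spacing
  roi <- phantom_roi(ph, 30, 0.5)
  seeds <- make_seeds(roi, sp)
  R <- effective_radius(ph$tensors$mask, sp, ph$frame)
  trp <- track(ef, seeds, tracking_params(), length_policy("pi_r", R = R))
  lens <- tract_lengths(trp)
  expect_true(all(lens <= pi * R + trp$step + 1e-9))
  expect_gt(max(lens), pi * R - 2 * trp$step)   # caps actually bind

  trr <- track(ef, seeds, tracking_params(), length_policy("roi_clip",
                                                           roi = roi))
  dims <- dim(roi)
  for (p in trr$points) {
    v <- floor(sweep(p, 2, sp, `/`))
    lin <- v[, 1] + dims[1] * (v[, 2] + dims[2] * v[, 3]) + 1
    expect_true(all(roi[lin]))
  }
  # every branch carries a termination reason
  expect_false(any(is.na(trp$termination$fwd)))
  expect_false(any(is.na(trp$termination$bwd)))
})

test_that("make_seeds is deterministic, jitters within voxels, and rejects empty regions", {
  region <- array(FALSE, c(4, 4, 4))
  region[2:3, 2:3, 2] <- TRUE
  sp <- c(1, 2, 1)
  s1 <- make_seeds(region, sp, tracking_params(seeds_per_voxel = 1))
  expect_equal(nrow(s1), 4L)
  expect_equal(s1[1, ], c(1.5, 3, 1.5), ignore_attr = TRUE)  # voxel center

  s4a <- make_seeds(region, sp, tracking_params(seeds_per_voxel = 4, seed = 2))
  s4b <- make_seeds(region, sp, tracking_params(seeds_per_voxel = 4, seed = 2))
  s4c <- make_seeds(region, sp, tracking_params(seeds_per_voxel = 4, seed = 3))
  expect_identical(s4a, s4b)
  expect_false(identical(s4a, s4c))
  expect_equal(nrow(s4a), 16L)
  # jittered seeds stay inside their voxels
  vox <- floor(sweep(s4a, 2, sp, `/`))
  expect_true(all(region[vox + 1]))

  expect_error(make_seeds(array(FALSE, c(2, 2, 2)), c(1, 1, 1)), "empty")
})

test_that("seeds outside the mask are skipped and counted", {
  f <- uniform_field(10)
  f$mask[, , 1:2] <- FALSE
  seeds <- rbind(c(5, 5, 5), c(5, 5, 1))    # second seed in the masked-out slab
  tr <- track(f, seeds, tracking_params(), length_policy("unlimited"))
  expect_equal(length(tr$points), 1L)
  expect_equal(tr$n_skipped_seeds, 1L)
})

test_that("effective_radius matches the annulus geometry and scales homogeneously", {
  mk_annulus <- function(inner, outer, spacing) {
    n <- ceiling(2 * (outer + 2) / spacing)
    nz <- ceiling(12 / spacing)
    xs <- (seq_len(n) - 0.5) * spacing - n * spacing / 2
    r <- sqrt(outer(xs^2, xs^2, `+`))
    mask <- array(r >= inner & r <= outer, c(n, n, nz))
    mask
  }
  m <- mk_annulus(25, 35, 1)
  R <- effective_radius(m, c(1, 1, 1))
  expect_equal(R, 30, tolerance = 0.5 / 30)

  m2 <- mk_annulus(50, 70, 2)               # geometry x2, spacing x2
  R2 <- effective_radius(m2, c(2, 2, 2))
  expect_equal(R2 / R, 2, tolerance = 0.02)

  # single-slice mask: degenerate band falls back to the whole mask
  m1 <- m[, , 1, drop = FALSE]
  frame <- cardiac_frame(c(0, 0, 1),
                         matrix(c(0.5, dim(m)[1] / 2, dim(m)[2] / 2, 0.5), 1))
  R1 <- effective_radius(m1, c(1, 1, 1), frame)
  expect_equal(R1, 30, tolerance = 0.5 / 30)
})
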