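test_that("the nested two-step averaging equals hand-computed nested means", {
  # 2 x 2 x 2 cells (transmural x base-apex x ant-post), one value each
  t_bin <- c(1, 1, 1, 1, 2, 2, 2, 2)
  a_bin <- c(1, 2, 1, 2, 1, 2, 1, 2)
  b_bin <- c(1, 1, 2, 2, 1, 1, 2, 2)
  vals  <- c(10, 20, 30, 50, 0, 10, -10, 30)
  res <- cardiotract:::nested_average(vals, t_bin, a_bin, b_bin)
  # by hand: t=1: base-apex means (15, 40) -> 27.5; t=2: (5, 10) -> 7.5
  expect_equal(res$t, c(1L, 2L))
  expect_equal(res$value, c(27.5, 7.5))

  # unbalanced columns still average columns with equal weight
  res2 <- cardiotract:::nested_average(c(10, 20, 30, 40),
                                       t_bin = c(1, 1, 1, 1),
                                       a_bin = c(1, 2, 3, 1),
                                       b_bin = c(1, 1, 1, 2))
  expect_equal(res2$value, mean(c(mean(c(10, 20, 30)), 40)))
})

test_that("constant-HA tracts give constant curves through the full deposition path", {
  ph <- generate_phantom(small_phantom_spec(orientation_noise_sd = 0))
  ef <- eigendecompose(ph$tensors)
  sp <- ph$tensors$spacing
  roi <- phantom_roi(ph, 30, 0.5)
  tr <- track(ef, make_seeds(roi, sp), tracking_params(),
              length_policy("roi_clip", roi = roi))
  cls <- classify_tracts(tr, ph$frame)
  cls$stats$ha_min <- rep(17, nrow(cls$stats))
  cls$stats$ha_med <- rep(17, nrow(cls$stats))
  cls$stats$ha_max <- rep(17, nrow(cls$stats))
  cv <- transmural_curves(tr, cls, roi, ph$tensors$mask, ph$frame, sp)
  expect_equal(cv$ha_min, rep(17, length(cv$x)))
  expect_equal(cv$ha_med, rep(17, length(cv$x)))
  expect_equal(cv$ha_max, rep(17, length(cv$x)))
  expect_true(all(diff(cv$x) > 0))
})

test_that("phantom transmural curves track the generating profile and stay ordered", {
  spec <- phantom_preset("normal-human", orientation_noise_sd = 0, seed = 2)
  res <- run_phantom_pipeline(spec)
  cv <- res$curves
  interior <- cv$x > 0.1 & cv$x < 0.9
  pred <- spec$alpha_endo + cv$x * (spec$alpha_epi - spec$alpha_endo)
  expect_lt(max(abs(cv$ha_med[interior] - pred[interior])), 2)
  expect_true(all(cv$ha_min <= cv$ha_med + 1e-9))
  expect_true(all(cv$ha_med <= cv$ha_max + 1e-9))
})

test_that("tci matches the closed-form value on the linear curve family", {
  x <- seq(0, 1, length.out = 201)
  med <- 60 - 120 * x
  cv <- transmural_curves_from_values(x, med - 10, med, med + 10)
  res <- tci(cv)
  # exact integrals: 1200 / (100 + 100) = 6
  expect_equal(res$numerator, 1200, tolerance = 1e-3)
  expect_equal(res$denominator, 200, tolerance = 1e-6)
  expect_equal(res$tci, 6.0, tolerance = 1e-3)
})

test_that("tci handles sentinels, sign flips, and added spread monotonically", {
  x <- seq(0, 1, length.out = 101)
  med <- 60 - 120 * x
  # perfect coherence: min = med = max (nonzero) -> +Inf sentinel
  perfect <- transmural_curves_from_values(x, med, med, med)
  res <- tci(perfect)
  expect_true(res$perfect)
  expect_identical(res$tci, Inf)
  # all-zero curves: undefined 0/0
  zero <- transmural_curves_from_values(x, rep(0, 101), rep(0, 101),
                                        rep(0, 101))
  expect_error(tci(zero), "0/0")
  # global sign flip leaves TCI unchanged
  a <- tci(transmural_curves_from_values(x, med - 10, med, med + 10))
  b <- tci(transmural_curves_from_values(x, -med - 10, -med, -med + 10))
  expect_equal(a$tci, b$tci, tolerance = 1e-12)
  # widening the min/max spread strictly lowers TCI
  tcis <- vapply(c(5, 10, 20), function(d)
    tci(transmural_curves_from_values(x, med - d, med, med + d))$tci,
    numeric(1))
  expect_true(all(diff(tcis) < 0))
  expect_error(tci(transmural_curves_from_values(c(0, 1), c(0, 0), c(1, 1),
                                                 c(2, 2))),
               "fewer than 3")
})

test_that("variance ratio follows its closed-form examples and reciprocal symmetry", {
  expect_equal(ha_histogram(c(-40, -20, 20, 40))$variance_ratio, 1.0)
  expect_equal(ha_histogram(c(-10, -10, 30, 50))$variance_ratio, 0.0)
  h <- ha_histogram(c(-10, 30, 50))           # single negative value
  expect_false(h$ratio_defined)
  expect_true(is.na(h$variance_ratio))
  # h -> -h maps the ratio to its reciprocal; HA = 0 is excluded
  set.seed(3)
  v <- c(stats::rnorm(40, -25, 12), stats::rnorm(60, 30, 8), 0)
  r1 <- ha_histogram(v)$variance_ratio
  r2 <- ha_histogram(-v)$variance_ratio
  expect_equal(r1 * r2, 1, tolerance = 1e-12)
  # histogram covers (-90, 90] and counts every value
  h2 <- ha_histogram(v, bin_width = 5)
  expect_equal(range(h2$bin_edges), c(-90, 90))
  expect_equal(sum(h2$counts), length(v))
})

test_that("zero_crossing interpolates linearly and flags missing crossings", {
  x <- seq(0, 1, length.out = 25)
  cv <- transmural_curves_from_values(x, 60 - 120 * x - 5, 60 - 120 * x,
                                      60 - 120 * x + 5)
  zc <- zero_crossing(cv)
  expect_equal(zc$depth, 0.5, tolerance = 1e-9)
  expect_false(zc$multiple)
  pos <- transmural_curves_from_values(x, rep(5, 25), rep(10, 25),
                                       rep(20, 25))
  expect_true(zero_crossing(pos)$none_found)
})

test_that("remote-zone architecture shifts the quantitative signature as expected", {
  rn <- run_phantom_pipeline(phantom_preset("normal-human", seed = 1))
  rr <- run_phantom_pipeline(phantom_preset("remote-zone", seed = 1))
  expect_lt(rr$metrics$variance_ratio, rn$metrics$variance_ratio)
  expect_gt(rr$metrics$zero_crossing, 0.5)
  expect_gt(rr$metrics$zero_crossing, rn$metrics$zero_crossing)
  # coherence is preserved by the (coherent) remodeling
  expect_gte(rr$metrics$tci, 0.1)
  expect_lt(abs(log(rr$metrics$tci / rn$metrics$tci)), log(3))
})

test_that("ROI-limited tracts are more coherent than pi-R tracts on the same phantom", {
  p <- run_phantom_pipeline(phantom_preset("normal-sheep", seed = 2))
  r <- run_phantom_pipeline(phantom_preset("normal-sheep", seed = 2),
                            length_mode = "roi_clip")
  expect_gt(r$metrics$tci, p$metrics$tci)
})
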