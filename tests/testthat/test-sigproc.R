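test_that("TIFF stacks round-trip bit-identically with sidecar metadata", {
  gv <- generate_video(small_aggregate_scene(side = 32, noise_sd = 0.05),
                       std_wave(), basal_protocol(3))
  tf <- tempfile(fileext = ".tiff")
  write_stack(gv$stack, tf, sidecar = list(seed = gv$truth$seed))
  rd <- read_stack(tf, frame_rate_hz = 50, pixel_size_mm = 0.05)
  expect_identical(dim(rd$frames), dim(gv$stack$frames))
  expect_equal(rd$frames, gv$stack$frames)
  expect_true(file.exists(sub("\\.tiff$", ".json", tf)))
  js <- jsonlite::read_json(sub("\\.tiff$", ".json", tf))
  expect_equal(js$seed, gv$truth$seed)
  # duration is metadata passthrough
  expect_equal(dim(rd$frames)[3] / rd$frame_rate_hz, 3)
  unlink(c(tf, sub("\\.tiff$", ".json", tf)))
})

test_that("degenerate stacks are rejected", {
  expect_error(video_stack(array(1, c(8, 8, 1)), 50), "at least 2 frames")
  expect_error(video_stack(array(c(NA, 1), c(8, 8, 2)), 50), "finite")
})

test_that("mask recovers the aggregate footprint", {
  gv <- generate_video(small_aggregate_scene(noise_sd = 1 / 8, seed = 4),
                       std_wave(), basal_protocol(5))
  msk <- build_mask(gv$stack, intensity_quantile = 0.4)
  truth <- gv$truth$footprint
  jaccard <- sum(msk$mask & truth) / sum(msk$mask | truth)
  expect_gte(jaccard, 0.95)
})

test_that("uniform stack with quantile 0 keeps every pixel", {
  fr <- array(100, c(8, 8, 120))
  fr[, , seq(1, 120, by = 10)] <- 150       # some temporal structure
  st <- video_stack(fr, 50)
  msk <- build_mask(st, intensity_quantile = 0, snr_floor = 0)
  expect_true(all(msk$mask))
})

test_that("pure-noise stacks yield an empty-mask error", {
  set.seed(7)
  fr <- array(100 + rnorm(8 * 8 * 150), c(8, 8, 150))
  st <- video_stack(fr, 50)
  expect_error(build_mask(st, snr_floor = 5), "lower")
})

test_that("raising the SNR floor never adds pixels", {
  gv <- generate_video(small_aggregate_scene(noise_sd = 0.3, seed = 8,
                                             side = 32),
                       std_wave(), basal_protocol(5))
  m1 <- build_mask(gv$stack, snr_floor = 1)$mask
  m2 <- build_mask(gv$stack, snr_floor = 3)$mask
  expect_true(all(m1[m2]))                  # m2 subset of m1
  expect_lte(sum(m2), sum(m1))
})

test_that("polarity auto-flip leaves CaTD unchanged for down-pointing twins", {
  wv <- std_wave()
  pr <- basal_protocol(6)
  up <- generate_video(small_aggregate_scene(seed = 5, side = 32), wv, pr)
  dn <- generate_video(scene_config("aggregate", 32, 32, frame_rate_hz = 50,
                                    polarity = "down", seed = 5), wv, pr)
  tr_up <- condition_trace(roi_trace(up$stack, up$truth$footprint), 50)
  tr_dn <- condition_trace(roi_trace(dn$stack, dn$truth$footprint), 50)
  expect_false(tr_up$flipped)
  expect_true(tr_dn$flipped)
  expect_gt(skewness_of(tr_dn$dff), 0)      # transients point upward now
  c_up <- mean(detect_beats(tr_up)$catd50_ms, na.rm = TRUE)
  c_dn <- mean(detect_beats(tr_dn)$catd50_ms, na.rm = TRUE)
  expect_equal(c_up, c_dn, tolerance = 0.01)
})

test_that("photobleaching is removed by the sliding-percentile baseline", {
  sc <- scene_config("aggregate", 32, 32, frame_rate_hz = 50,
                     bleach_tau_s = 30, seed = 6)
  gv <- generate_video(sc, std_wave(), basal_protocol(10))
  tr <- condition_trace(roi_trace(gv$stack, gv$truth$footprint), 50)
  # residual baseline drift of the conditioned trace, relative to amplitude,
  # over the interior (the first/last baseline windows are half-open and
  # carry a known edge bias)
  base <- calmapr:::rolling_percentile_cols(matrix(tr$dff, ncol = 1), 150, 0.1)
  n <- length(base)
  amp <- diff(range(tr$dff))
  expect_lt(diff(range(base[75:(n - 75)])), 0.01 * amp)
})

test_that("conditioning is idempotent and preserves peak positions", {
  y <- kernel_trace(std_wave(), fps = 50, duration = 8)
  t1 <- condition_trace(y, 50)
  t2 <- condition_trace(t1$dff, 50)
  expect_lt(max(abs(t2$dff - t1$dff)), 0.1 * max(t1$dff))
  # zero-phase: the ground-truth peak index moves < 1 frame (window holds
  # exactly one beat)
  p_raw <- which.max(y[10:60])
  p_cond <- which.max(t1$dff[10:60])
  expect_lte(abs(p_cond - p_raw), 1)
})

test_that("already-conditioned flat-positive traces pass through", {
  y <- rep(5, 200)
  y[seq(20, 200, by = 50)] <- 6             # sparse small peaks
  tr <- condition_trace(y, 50)
  expect_true(all(is.finite(tr$dff)))
  expect_equal(stats::median(tr$dff), 0, tolerance = 1e-6)
})

test_that("spatial binning averages blocks and scales the pixel size", {
  gv <- generate_video(small_aggregate_scene(side = 32), std_wave(),
                       basal_protocol(3))
  b <- bin_stack(gv$stack, 2)
  expect_equal(dim(b$frames)[1:2], c(16, 16))
  expect_equal(b$pixel_size_mm, 2 * gv$stack$pixel_size_mm)
  expect_equal(b$frames[1, 1, 1],
               mean(gv$stack$frames[1:2, 1:2, 1]))
})

test_that("perfusion CSV round-trips", {
  ps <- simulate_perfusion(-2, 1e6, 0.1, 0.5, 20, 18, 0:6)
  tf <- tempfile(fileext = ".csv")
  write_perfusion_csv(ps, tf)
  rd <- read_perfusion_csv(tf, cin_mM = 20, dilution_per_day = 0.5)
  expect_equal(rd$conc_mM, ps$conc_mM)
  expect_equal(rd$cells_per_ml, ps$cells_per_ml)
  unlink(tf)
})
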