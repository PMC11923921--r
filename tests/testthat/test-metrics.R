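test_that("noise-free transient trains are detected beat for beat", {
  y <- kernel_trace(std_wave(), fps = 100, duration = 4,
                    activations = c(1, 2, 3))
  tr <- condition_trace(y, 100)
  b <- detect_beats(tr)
  expect_equal(nrow(b), 3)
  expect_equal(diff(b$activation_time_s), c(1, 1), tolerance = 1e-3)
})

test_that("flat traces yield zero beats, not an error", {
  tr <- condition_trace(rep(3, 300), 50)
  expect_equal(nrow(detect_beats(tr)), 0)
})

test_that("beats at SNR 8 are counted exactly in at least 95% of seeds", {
  hits <- vapply(1:100, function(s) {
    y <- kernel_trace(std_wave(tau = 0.25), fps = 50, duration = 10,
                      noise_sd = 1 / 8, seed = s)
    nrow(detect_beats(condition_trace(y, 50)))
  }, 0L)
  expect_gte(mean(hits == 10), 0.95)
})

test_that("CaTD of an instantaneous-rise exponential matches tau log laws", {
  # CaTD50 = tau ln 2 = 138.6 ms; CaTD70 = tau ln(10/3) = 240.8 ms,
  # measured within half a frame at 200 fps
  fs <- 200
  wv <- waveform_params(1e-4, 0.2, rise_shape = "instant",
                        refractory_period_s = 0.5,
                        amplitude = 1, diastolic_level = 1)
  # stimuli aligned to frame midpoints: the sub-frame position of a 1-frame
  # jump is otherwise unidentifiable
  y <- kernel_trace(wv, fps = fs, duration = 6,
                    activations = seq(0.5, 5, by = 1.5) + 0.5 / fs)
  tr <- condition_trace(y, fs, smooth_frames = 1)
  b <- detect_beats(tr)
  half_frame <- 1000 / fs / 2
  expect_lt(abs(mean(b$catd50_ms, na.rm = TRUE) - 138.6), half_frame)
  expect_lt(abs(mean(b$catd70_ms, na.rm = TRUE) - 240.8), half_frame)
  expect_lt(abs(mean(b$catd90_ms, na.rm = TRUE) - 460.5), half_frame)
})

test_that("CaTD90 is flagged undefined when pacing outruns recovery", {
  # tau = 0.5 s: 90% recovery takes 1.15 s but beats arrive every 0.8 s
  wv <- std_wave(tau = 0.5, refractory = 0.3)
  y <- kernel_trace(wv, fps = 100, duration = 8,
                    activations = seq(0.5, 7.5, by = 0.8))
  b <- detect_beats(condition_trace(y, 100))
  expect_gt(nrow(b), 5)
  expect_true(all(is.na(b$catd90_ms[-nrow(b)])))
  expect_true(any(!is.na(b$catd50_ms)))
})

test_that("CaTD is monotone in p wherever defined", {
  for (s in 1:5) {
    y <- kernel_trace(std_wave(tau = 0.2 + 0.1 * s), fps = 50, duration = 10,
                      noise_sd = 1 / 10, seed = s)
    b <- detect_beats(condition_trace(y, 50))
    cat_mat <- as.matrix(b[, c("catd20_ms", "catd50_ms",
                               "catd70_ms", "catd90_ms")])
    for (i in seq_len(nrow(cat_mat))) {
      v <- cat_mat[i, !is.na(cat_mat[i, ])]
      if (length(v) > 1) expect_true(all(diff(v) > 0))
    }
  }
})

test_that("upstroke durations follow the generator's closed form", {
  # smoothstep rise with analytic 10-90% time, within one frame at 100 fps
  fs <- 100
  y <- kernel_trace(std_wave(upstroke = 0.08), fps = fs, duration = 6,
                    activations = seq(0.5, 5.5, by = 1))
  b <- detect_beats(condition_trace(y, fs))
  expect_lt(abs(mean(b$upstroke_s, na.rm = TRUE) - 0.08), 1 / fs)
  # 1-frame instantaneous rise is bounded by the frame period
  wv <- waveform_params(1e-4, 0.3, rise_shape = "instant",
                        refractory_period_s = 0.5)
  y2 <- kernel_trace(wv, fps = 50, duration = 6,
                     activations = seq(0.5, 5.5, by = 1))
  b2 <- detect_beats(condition_trace(y2, 50, smooth_frames = 1))
  expect_lte(mean(b2$upstroke_s, na.rm = TRUE), 1 / 50 + 1e-9)
})

test_that("IBI statistics use activation times and population SD", {
  b <- data.frame(activation_time_s = c(1, 2, 3),
                  peak_time_s = c(1.1, 2.1, 3.1))
  r <- ibi_series(b)
  expect_equal(r$mean_s, 1)
  expect_equal(r$sd_s, 0)
  b2 <- data.frame(activation_time_s = cumsum(c(1, 0.8, 1.2, 0.8, 1.2)),
                   peak_time_s = NA)
  r2 <- ibi_series(b2)
  expect_equal(r2$mean_s, 1)
  expect_equal(r2$sd_s, 0.2)
  expect_true(is.na(ibi_series(b[1, ])$mean_s))
})

test_that("dominant frequency resolves a pure sinusoid and a beat train", {
  fs <- 50
  tt <- seq(0, 10 - 1 / fs, by = 1 / fs)
  expect_equal(dominant_frequency(sin(2 * pi * tt), frame_rate_hz = fs),
               1, tolerance = 0.011)
  y <- kernel_trace(std_wave(tau = 0.2), fps = fs, duration = 10,
                    activations = seq(0.3, 9.7, by = 1 / 1.5),
                    noise_sd = 1 / 8, seed = 2)
  expect_equal(dominant_frequency(condition_trace(y, fs)), 1.5,
               tolerance = 0.05)
  expect_error(dominant_frequency(sin(2 * pi * tt[1:100]),
                                  frame_rate_hz = fs), "too short")
})

test_that("DF is invariant to amplitude scaling and polarity inversion", {
  y <- kernel_trace(std_wave(), fps = 50, duration = 10, noise_sd = 0.05,
                    seed = 3)
  f1 <- dominant_frequency(condition_trace(y, 50))
  f2 <- dominant_frequency(condition_trace(7 * y, 50))
  f3 <- dominant_frequency(condition_trace(2 * mean(y) - y, 50))  # inverted
  expect_equal(f1, f2)
  expect_equal(f1, f3)
})

test_that("mean IBI and DF are reciprocal on periodic input", {
  for (freq in c(0.8, 1.25, 2)) {
    y <- kernel_trace(std_wave(tau = 0.15), fps = 50, duration = 10,
                      activations = seq(0.2, 9.8, by = 1 / freq))
    tr <- condition_trace(y, 50)
    b <- detect_beats(tr)
    prod <- ibi_series(b)$mean_s * dominant_frequency(tr)
    expect_gte(prod, 0.98)
    expect_lte(prod, 1.02)
  }
})

test_that("metric maps are homogeneous for synchronous aggregates", {
  gv <- generate_video(small_aggregate_scene(seed = 9, noise_sd = 0.05),
                       std_wave(), basal_protocol(8))
  mm <- metric_maps(gv$stack, bin_factor = 2)
  sm <- mm$summary
  df_row <- sm[sm$metric == "df_hz", ]
  expect_lt(df_row$sd, 0.02)                # below the frequency resolution
  expect_equal(df_row$mean, 1, tolerance = 0.03)
  expect_equal(mm$global_df_hz, 1, tolerance = 0.03)
  catd_row <- sm[sm$metric == "catd50_ms", ]
  expect_equal(catd_row$mean, gv$truth$catd_ms[["catd50"]], tolerance = 0.05)
  # masking contract: summaries only over valid pixels, counts reported
  expect_equal(df_row$n_defined + df_row$n_undefined, sum(mm$mask))
})

test_that("metric maps respect an externally supplied partial mask", {
  gv <- generate_video(small_aggregate_scene(seed = 10, side = 32),
                       std_wave(), basal_protocol(6))
  m <- gv$truth$footprint
  m[, 1:16] <- FALSE                        # mask out half the frame
  mm <- metric_maps(gv$stack, mask = m, bin_factor = 2)
  expect_true(all(is.na(mm$df_hz[, 1:8])))
  expect_equal(sum(mm$mask), sum(calmapr:::bin_mask(m, 2)))
})
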