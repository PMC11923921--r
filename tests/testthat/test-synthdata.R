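test_that("pacing faster than the refractory period drops stimuli", {
  # 3 Hz pacing against a 0.8 s refractory period: only every third stimulus
  # can capture, emulating an immature aggregate entering a refractory state
  wv <- std_wave(refractory = 0.8, tau = 0.15, upstroke = 0.05)
  pr <- pacing_protocol(0, 5, 3, "paced")
  gv <- generate_video(small_aggregate_scene(), wv, pr)
  seg <- gv$truth$segments
  expect_equal(seg$stimuli, 15)
  expect_lt(seg$capture_ratio, 1)
  expect_equal(seg$beats, 5)              # one capture per second
  expect_equal(seg$df_true_hz, 1)
})

test_that("short refractory period captures every stimulus at 3 Hz", {
  wv <- std_wave(refractory = 0.2, tau = 0.15, upstroke = 0.05)
  pr <- pacing_protocol(0, 5, 3, "paced")
  gv <- generate_video(small_aggregate_scene(), wv, pr)
  expect_equal(gv$truth$segments$capture_ratio, 1)
  expect_equal(gv$truth$segments$df_true_hz, 3)
})

test_that("monolayer activation delays follow distance over velocity", {
  # 20 mm/s and 0.05 mm pixels: 1 mm (20 px) apart = 50 ms delay
  sc <- scene_config("monolayer", 64, 64, frame_rate_hz = 100,
                     pixel_size_mm = 0.05, cv_mm_s = 20,
                     stim_origin_px = c(1, 1), seed = 1)
  gv <- generate_video(sc, std_wave(), basal_protocol(3))
  dmap <- gv$truth$delay_map_s
  expect_equal(dmap[1, 21] - dmap[1, 1], 0.050, tolerance = 1e-12)
  # per-pixel delay gradient equals exactly 1/CV (continuous-time truth)
  expect_equal(diff(dmap[1, ]), rep(0.05 / 20, 63), tolerance = 1e-12)
  expect_equal(gv$truth$cv_mm_s, 20)
})

test_that("regeneration with the same seed is bit-identical", {
  wv <- std_wave()
  pr <- basal_protocol(4)
  sc <- small_aggregate_scene(seed = 11, noise_sd = 0.1, side = 32)
  a <- generate_video(sc, wv, pr)
  b <- generate_video(sc, wv, pr)
  expect_identical(a$stack$frames, b$stack$frames)
  # and noise-free with bleach off is deterministic by construction
  scn <- small_aggregate_scene(seed = 12, noise_sd = 0, side = 32)
  expect_identical(generate_video(scn, wv, pr)$stack$frames,
                   generate_video(scn, wv, pr)$stack$frames)
})

test_that("polarity=down inverts transients around the resting level", {
  wv <- std_wave()
  pr <- basal_protocol(4)
  up <- generate_video(small_aggregate_scene(seed = 3, side = 32), wv, pr)
  dn <- generate_video(scene_config("aggregate", 32, 32, frame_rate_hz = 50,
                                    polarity = "down", seed = 3), wv, pr)
  px <- which(up$truth$footprint)[1]
  tu <- up$stack$frames[row(up$truth$footprint)[px],
                        col(up$truth$footprint)[px], ]
  td <- dn$stack$frames[row(dn$truth$footprint)[px],
                        col(dn$truth$footprint)[px], ]
  expect_gt(skewness_of(tu), 0)
  expect_lt(skewness_of(td), 0)
})

test_that("protocol longer than the video is a configuration error", {
  expect_error(generate_video(small_aggregate_scene(), std_wave(),
                              basal_protocol(10), duration_s = 5),
               "beyond the video duration")
})

test_that("ground-truth CaTD is monotone in p for generated videos", {
  for (tau in c(0.15, 0.3, 0.6)) {
    gv <- generate_video(small_aggregate_scene(side = 32),
                         std_wave(tau = tau), basal_protocol(3))
    expect_true(all(diff(gv$truth$catd_ms) > 0))
  }
})

test_that("perfusion simulator matches the batch and washout closed forms", {
  # constant-rate batch: linear decline at q X / 1e6 mM per day
  ps <- simulate_perfusion(q_true = -2, X0 = 1e6, mu = 0, D = 0, Cin = 0,
                           C0 = 20, t_grid = seq(0, 5, by = 0.5))
  expect_equal(ps$conc_mM, 20 - 2 * ps$t_day, tolerance = 1e-8)
  # washout: C = Cin + (C0 - Cin) exp(-D t), relative error < 1e-6
  ps2 <- simulate_perfusion(q_true = 0, X0 = 1e6, mu = 0, D = 0.7, Cin = 10,
                            C0 = 2, t_grid = seq(0, 6, by = 0.25))
  expect_equal(ps2$conc_mM, 10 + (2 - 10) * exp(-0.7 * ps2$t_day),
               tolerance = 1e-6)
})

test_that("adaptive integration agrees with a fixed-step RK4 oracle", {
  q <- -3; X0 <- 0.5e6; mu <- 0.2; D <- 0.5; Cin <- 20; C0 <- 18
  f <- function(t, C) q * X0 * exp(mu * t) * 1e-6 + D * (Cin - C)
  rk4 <- function(tgrid, h) {
    C <- C0; out <- C0
    for (k in seq_len(length(tgrid) - 1)) {
      t0 <- tgrid[k]; t1 <- tgrid[k + 1]
      tt <- t0
      while (tt < t1 - 1e-12) {
        hh <- min(h, t1 - tt)
        k1 <- f(tt, C); k2 <- f(tt + hh / 2, C + hh * k1 / 2)
        k3 <- f(tt + hh / 2, C + hh * k2 / 2); k4 <- f(tt + hh, C + hh * k3)
        C <- C + hh * (k1 + 2 * k2 + 2 * k3 + k4) / 6
        tt <- tt + hh
      }
      out <- c(out, C)
    }
    out
  }
  tg <- 0:8
  ps <- simulate_perfusion(q, X0, mu, D, Cin, C0, tg)
  oracle <- rk4(tg, h = 0.005)
  expect_lt(max(abs(ps$conc_mM - oracle) / abs(oracle)), 1e-3)
})

test_that("negative simulated concentrations abort with the failure time", {
  expect_error(simulate_perfusion(q_true = -50, X0 = 1e6, mu = 0, D = 0,
                                  Cin = 0, C0 = 5, t_grid = 0:5),
               "negative at t")
})

test_that("synthetic aggregate images carry exact Feret ground truth", {
  sh <- aggregate_shapes(kind = c("disc", "square", "ellipse"),
                         cx = c(60, 170, 300), cy = c(70, 70, 70),
                         size = c(80, 70, 90), size2 = c(NA, NA, 40))
  gi <- generate_aggregate_image(sh, 140, 360)
  expect_equal(gi$feret_true_px, c(80, 70 * sqrt(2), 90))
  expect_true(all(gi$image %in% c(0, 1)))
  # overlap warning
  sh2 <- aggregate_shapes(kind = c("disc", "disc"), cx = c(60, 100),
                          cy = c(60, 60), size = c(60, 60))
  expect_warning(generate_aggregate_image(sh2, 140, 200), "overlap")
})
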