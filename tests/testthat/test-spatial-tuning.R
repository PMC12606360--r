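test_that("periodogram: perfect periodicity, constancy, shift invariance", {
  # identical cycles: all variance explained (times off bin boundaries)
  one_cycle <- c(0.1023, 0.1217, 0.3041)
  spikes <- unlist(lapply(0:9, function(c) one_cycle + c * 0.5))
  per <- chi2_periodogram(spikes, 5, 2)
  expect_equal(per$pct_var, 100)
  expect_lt(per$p, 1e-10)
  # homogeneous Poisson spiking: little variance at the stimulus frequency
  set.seed(20)
  pois <- sort(runif(300, 0, 30))
  per0 <- chi2_periodogram(pois, 30, 2)
  expect_lt(per0$pct_var, 15)
  # empty train: 0/0 guarded to zero, non-significant
  perE <- chi2_periodogram(numeric(0), 10, 1)
  expect_identical(perE$pct_var, 0)
  expect_identical(perE$p, 1)
  expect_error(chi2_periodogram(pois, 1.2, 1), "fewer than 2")
  # %Var invariant to a whole-period shift of every spike
  set.seed(21)
  sp <- sort(runif(150, 0, 8))
  a <- chi2_periodogram(sp, 10, 2)$pct_var
  b <- chi2_periodogram(sp + 1, 10, 2)$pct_var   # shift by 2 periods
  expect_equal(a, b, tolerance = 1e-9)
})

test_that("direction/orientation indices follow the stated formulas exactly", {
  dirs <- seq(0, 315, by = 45)
  # D_pref 12, D_null 4 -> DSI 0.5, DS label
  amp <- c(12, 6, 5, 4, 4, 4, 5, 6)
  dt <- direction_tuning(amp, dirs)
  expect_equal(dt$dsi, 0.5)
  expect_identical(dt$label, "DS")
  expect_equal(dt$preferred_direction, 0)
  # flat tuning: zero indices
  dtf <- direction_tuning(rep(7, 8), dirs)
  expect_equal(dtf$dsi, 0)
  expect_equal(dtf$osi, 0)
  expect_identical(dtf$label, "untuned")
  # all-zero amplitudes: undefined indices
  dt0 <- direction_tuning(rep(0, 8), dirs)
  expect_true(is.na(dt0$dsi))
  # 1000 random amplitude sets equal a brute-force oracle exactly
  set.seed(22)
  for (i in 1:1000) {
    a <- round(runif(8, 0, 20), 3)
    if (all(a == 0)) next
    dt <- direction_tuning(a, dirs)
    ip <- which.max(a)
    dn <- a[(ip - 1 + 4) %% 8 + 1]
    expect_identical(dt$dsi, (a[ip] - dn) / (a[ip] + dn))
    pair <- (a[1:4] + a[5:8]) / 2
    io <- which.max(pair)
    on <- pair[(io - 1 + 2) %% 4 + 1]
    expect_identical(dt$osi, (pair[io] - on) / (pair[io] + on))
  }
})

test_that("tuning surface: argmax stimulus, cutoffs and interpolation", {
  set.seed(23)
  sess <- session_spec(grating_trials = 2, grating_cycles = 6)
  # responsive at exactly one stimulus
  spec1 <- cell_spec("V", baseline = 2, grating_amp = 40, dsi_target = 1,
                     pref_direction = 90)
  g <- hypovis:::sim_grating_rasters(spec1, sess)
  keep <- g$stimuli$sf_deg_per_cycle == 64 & g$stimuli$speed_deg_per_s == 30
  # silence all but one stimulus by replacing other rasters with near-empty
  rasters <- g$rasters
  hot <- which(keep & g$stimuli$direction_deg == 90)
  for (i in seq_along(rasters)) {
    if (i != hot) {
      rasters[[i]]$trials <- lapply(rasters[[i]]$trials, function(.) numeric(0))
    }
  }
  ts1 <- tuning_surface(rasters, g$stimuli)
  expect_equal(ts1$optimal$sf_deg_per_cycle, 64)
  expect_equal(ts1$optimal$speed_deg_per_s, 30)
  expect_equal(ts1$optimal$direction_deg, 90)
  expect_equal(ts1$temporal_cutoff, 30 / 64, tolerance = 1e-9)
  expect_equal(ts1$spatial_cutoff, 1 / 64, tolerance = 1e-9)
  # interpolated cutoff equals the hand-solved log2-linear crossing
  ts <- tuning_surface(g$rasters, g$stimuli)
  gr <- ts$grid[ts$grid$direction_deg == ts$optimal$direction_deg &
                  ts$grid$sf_deg_per_cycle == ts$optimal$sf_deg_per_cycle, ]
  agg <- tapply(gr$pct_var, gr$tf_hz, max)
  f <- as.numeric(names(agg)); v <- as.numeric(agg)
  o <- order(f); f <- f[o]; v <- v[o]
  half <- max(ts$grid$pct_var) / 2
  i <- max(which(v >= half))
  expected <- if (i == length(f) || v[i + 1] <= 0) f[i] else
    2^(log2(f[i]) + (half - v[i]) * (log2(f[i + 1]) - log2(f[i])) /
         (v[i + 1] - v[i]))
  expect_equal(ts$temporal_cutoff, expected, tolerance = 1e-9)
})

test_that("a generative low-pass cell yields a temporal cutoff near its corner", {
  set.seed(24)
  sess <- session_spec(grating_trials = 3, grating_cycles = 8)
  g0 <- hypovis:::sim_grating_rasters(cell_spec("IV", grating_amp = 25), sess)
  # impose first-order low-pass attenuation with a 2 Hz corner by thinning
  atten <- 1 / sqrt(1 + (g0$stimuli$speed_deg_per_s /
                           g0$stimuli$sf_deg_per_cycle / 2)^2)
  cuts <- replicate(5, {
    g <- hypovis:::sim_grating_rasters(cell_spec("IV", grating_amp = 25), sess)
    for (i in seq_along(g$rasters)) {
      g$rasters[[i]]$trials <- lapply(g$rasters[[i]]$trials, function(tr)
        tr[runif(length(tr)) < (0.3 + 0.7 * atten[i])])
    }
    tuning_surface(g$rasters, g$stimuli)$temporal_cutoff
  })
  expect_gt(median(cuts), 0.469)   # at least the lowest tested frequency
  expect_lt(median(cuts), 10)      # attenuated well below the highest (30 Hz)
})

test_that("motion selectivity: boundaries, luminance control and loom cells", {
  set.seed(25)
  sess <- session_spec(spot_trials = 20)
  # generative loom-selective cell: approach class, MSI near 1
  loom_cls <- replicate(10, {
    sp <- cell_spec("VI", loom_gain = 30)
    sim <- hypovis:::sim_spot_rasters(sp, sess)
    ms <- motion_selectivity(sim$rasters, sim$stimuli)
    c(ms$class, ms$msi)
  })
  expect_gte(mean(loom_cls[1, ] == "approach"), 0.95)
  expect_gt(mean(as.numeric(loom_cls[2, loom_cls[1, ] == "approach"])), 0.3)
  # index boundaries: control silent -> 1; equal responses -> 0
  expect_identical(msi_index(20, 0), 1)
  expect_identical(msi_index(7, 7), 0)
  expect_identical(msi_index(0, 12), -1)
  expect_true(is.na(msi_index(0, 0)))
  # generative luminance cell: responds to spots, classed luminance
  spL <- cell_spec("II", lum_gain = 30, lum_sign = 1)
  simL <- hypovis:::sim_spot_rasters(spL, sess)
  msL <- motion_selectivity(simL$rasters, simL$stimuli)
  expect_identical(msL$class, "luminance ON")
  expect_lt(abs(msL$msi), 0.5)
  # unresponsive cell: class none
  sp0 <- cell_spec("IV")
  sim0 <- hypovis:::sim_spot_rasters(sp0, sess)
  ms0 <- motion_selectivity(sim0$rasters, sim0$stimuli)
  expect_identical(ms0$class, "none")
  # missing control is rejected
  drop <- sim0$stimuli$kind != "lum_down"
  expect_error(motion_selectivity(sim0$rasters[drop],
                                  sim0$stimuli[drop, ]), "control")
})

test_that("receptive-field mapping recovers generative fields and polarity", {
  set.seed(26)
  sess <- session_spec(bar_positions = seq(-21, 21, by = 2))
  sp <- cell_spec("IV", rf_gain = 25, rf_centre = c(10, -5), rf_sigma = 3)
  b <- hypovis:::sim_bar_rasters(sp, sess)
  rf <- map_receptive_field(b$rasters, b$stimuli)
  expect_true(rf$detectable)
  expect_identical(rf$polarity, "ON")
  expect_lt(abs(rf$centre[["azimuth"]] - 10), 2)
  expect_lt(abs(rf$centre[["elevation"]] + 5), 2)
  expect_gt(rf$diameter, 5.5); expect_lt(rf$diameter, 8.7)
  # dark-bar-driven cell: OFF polarity
  spD <- cell_spec("IV", rf_gain = 25, rf_polarity = "dark")
  bD <- hypovis:::sim_bar_rasters(spD, sess)
  expect_identical(map_receptive_field(bD$rasters, bD$stimuli)$polarity,
                   "OFF")
  # position-independent response: no RF
  set.seed(261)
  spF <- cell_spec("I", baseline = 10)
  bF <- hypovis:::sim_bar_rasters(spF, sess)
  rfF <- map_receptive_field(bF$rasters, bF$stimuli)
  expect_false(rfF$detectable)
  expect_identical(rfF$polarity, "none")
  # non-contiguous grid rejected
  gap <- b$stimuli$position_deg != 1
  expect_error(map_receptive_field(b$rasters[gap], b$stimuli[gap, ]),
               "non-contiguous")
})

test_that("RF centre estimates shift with the simulated field (equivariance)", {
  set.seed(27)
  sess <- session_spec(bar_positions = seq(-21, 21, by = 2))
  centres <- vapply(c(-6, 0, 6), function(shift) {
    sp <- cell_spec("IV", rf_gain = 25, rf_centre = c(shift, shift),
                    rf_sigma = 3)
    b <- hypovis:::sim_bar_rasters(sp, sess)
    map_receptive_field(b$rasters, b$stimuli)$centre[["azimuth"]]
  }, 0)
  expect_equal(diff(centres), c(6, 6), tolerance = 1)
})

test_that("functional-group precedence follows the stated rules", {
  resp_sus <- list(responsive = TRUE, kind = "sustained")
  resp_tra <- list(responsive = TRUE, kind = "transient")
  resp_no <- list(responsive = FALSE, kind = "none")
  step_on <- list(on_peak = 30, off_peak = 5)
  grat_ds <- structure(list(responsive = TRUE, dsi = 0.5), class = "grating_tuning")
  grat_un <- structure(list(responsive = TRUE, dsi = 0.1), class = "grating_tuning")
  grat_no <- structure(list(responsive = FALSE, dsi = NA_real_),
                       class = "grating_tuning")
  mot_app <- structure(list(class = "approach"), class = "motion_selectivity")
  mot_no <- structure(list(class = "none"), class = "motion_selectivity")
  # DSI > 0.33 wins over motion selectivity (precedence V before VI)
  expect_identical(assign_functional_group(resp_sus, step_on, grat_ds,
                                           mot_app)$group, "V")
  # motion-selective, not direction tuned: VI even when full-field responsive
  expect_identical(assign_functional_group(resp_tra, step_on, grat_un,
                                           mot_app)$group, "VI")
  # sustained, untuned, not motion selective: I
  expect_identical(assign_functional_group(resp_sus, step_on, grat_un,
                                           mot_no)$group, "I")
  # transient ON vs OFF bias splits II/III
  expect_identical(assign_functional_group(resp_tra, step_on, grat_no,
                                           mot_no)$group, "II")
  expect_identical(assign_functional_group(resp_tra,
                                           list(on_peak = 5, off_peak = -30),
                                           grat_no, mot_no)$group, "III")
  # no full-field response but a mapped RF: IV
  rf_yes <- structure(list(detectable = TRUE), class = "rf_profile")
  expect_identical(assign_functional_group(resp_no, NULL, grat_no, mot_no,
                                           rf_yes)$group, "IV")
  expect_identical(assign_functional_group(resp_no, NULL, NULL, NULL,
                                           NULL)$group, "unresponsive")
  expect_error(assign_functional_group(list(responsive = FALSE,
                                            kind = "sustained")),
               "contradictory")
})
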