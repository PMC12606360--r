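test_that("responsiveness detects a generative rate step and not its absence", {
  set.seed(101)
  sp <- cell_spec("I", baseline = 5, step_sustained = 45)
  r <- hypovis:::sim_step_raster(sp, 20, 2)
  expect_true(test_light_responsive(r)$responsive)
  # identical spike trains pre and post (shifted copies): zero mean difference
  tr <- c(-0.2, -0.1, 0.05, 0.15)
  r2 <- event_raster(rep(list(tr), 10), 1, 2, 1)
  res <- test_light_responsive(r2, window = 0.25)
  expect_false(res$responsive)
  expect_equal(res$diff_on, 0)
  # zero variance in both windows flags a degenerate test
  r3 <- event_raster(rep(list(numeric(0)), 10), 1, 2, 1)
  res3 <- test_light_responsive(r3)
  expect_false(res3$responsive)
  expect_identical(res3$flag, "degenerate")
})

test_that("sustained vs transient classification recovers generative labels", {
  set.seed(102)
  sus <- vapply(1:20, function(i) {
    sp <- cell_spec("I", baseline = 5, step_sustained = 25)
    classify_sustained_transient(hypovis:::sim_step_raster(sp, 20, 2))$kind
  }, "")
  expect_gte(mean(sus == "sustained"), 0.95)
  tra <- vapply(1:20, function(i) {
    rate <- function(t) 5 + 45 * (t > 0 & t <= 0.2)
    r <- hypovis:::gen_raster(rate, 2, 2, 1, 20, 51)
    classify_sustained_transient(r)$kind
  }, "")
  expect_gte(mean(tra == "transient"), 0.9)
  # null case: last 500 ms identical to baseline by construction
  segs <- data.frame(from = c(-2, 0), to = c(0, 2), rate = c(10, 10))
  r <- deterministic_raster(segs, 2, 2, 1)
  expect_identical(classify_sustained_transient(r)$kind, "transient")
  expect_error(classify_sustained_transient(
    event_raster(list(0.1, 0.2), 2, 0.3, 1)), "shorter")
})

test_that("latency: step onset recovered, no-change undefined, step at zero fast", {
  set.seed(103)
  lats <- replicate(30, {
    r <- hypovis:::gen_raster(function(t) ifelse(t > 0.1, 80, 5), 2, 2, 0.5,
                              50, 81)
    response_latency(r)$latency
  })
  expect_true(median(lats) >= 0.095 && median(lats) <= 0.115)
  # homogeneous rate: no crossing
  r0 <- poisson_raster(10, 2, 2, 0.5, 20)
  expect_true(is.na(response_latency(r0)$latency) ||
                response_latency(r0)$latency > 0)
  lat0 <- median(replicate(10, {
    r <- hypovis:::gen_raster(function(t) ifelse(t > 0, 80, 5), 2, 2, 0.5,
                              50, 81)
    response_latency(r)$latency
  }))
  expect_lt(lat0, 0.01)
})

test_that("step measures match arithmetic and a direct binning oracle", {
  # deterministic profile: 5 baseline, 30 throughout the step
  segs <- data.frame(from = c(-2, 0, 2), to = c(0, 2, 3), rate = c(5, 30, 5))
  r <- deterministic_raster(segs, 2, 2, 1)
  m <- quantify_step_response(r)
  expect_equal(m$tonic, 25)
  # regular 30 Hz spiking alternates 1/2 spikes per 50 ms bin: peak 40 - 5
  expect_equal(m$on_peak, 35)
  # constant rate (20 Hz: exactly one spike per 50 ms bin): all measures 0
  rc <- deterministic_raster(data.frame(from = -2, to = 3, rate = 20),
                             2, 2, 1)
  mc <- quantify_step_response(rc)
  expect_equal(mc$on_peak, 0)
  expect_equal(mc$tonic, 0)
  # arbitrary simulated profile equals a direct 50 ms binning oracle
  set.seed(104)
  ra <- poisson_raster(23, 2, 2, 1, 12)
  ma <- quantify_step_response(ra)
  base <- mean(vapply(ra$trials, function(tr) sum(tr > -2 & tr <= 0), 0)) / 2
  bins <- seq(0, 1, by = 0.05)
  rates <- vapply(seq_len(20), function(i) {
    mean(vapply(ra$trials, function(tr)
      sum(tr > bins[i] & tr <= bins[i + 1]), 0)) / 0.05
  }, 0)
  ch <- rates - base
  expect_equal(ma$on_peak, ch[which.max(abs(ch))], tolerance = 1e-9)
  expect_equal(ma$baseline, base, tolerance = 1e-9)
})

test_that("window measures ignore spikes outside their windows", {
  segs <- data.frame(from = c(-2, 0), to = c(0, 2), rate = c(5, 30))
  r1 <- deterministic_raster(segs, 2, 2, 1)
  # add a burst strictly after the OFF search window
  r2 <- r1
  r2$trials <- lapply(r2$trials, function(tr) c(tr, seq(2.95, 2.99, 0.001)))
  m1 <- quantify_step_response(r1, off_search = 0.5)
  m2 <- quantify_step_response(r2, off_search = 0.5)
  expect_equal(m1$on_peak, m2$on_peak)
  expect_equal(m1$tonic, m2$tonic)
  expect_equal(m1$off_peak, m2$off_peak)
})

test_that("melanopsin-contrast windows separate a melanopsin-driven late response", {
  set.seed(105)
  sp <- cell_spec("I", baseline = 5, step_sustained = 10, mel_gain = 20)
  rh <- hypovis:::sim_step_raster(sp, 10, 10, mel = "high")
  rl <- hypovis:::sim_step_raster(sp, 10, 10, mel = "low")
  mc <- melanopsin_contrast(rh, rl)
  expect_gt(mc$summary[["late_diff"]], 0.2)
  expect_lt(abs(mc$summary[["early_diff"]]), 0.3)
  # identical rasters: exactly zero differences
  mc0 <- melanopsin_contrast(rh, rh)
  expect_equal(unname(mc0$summary), c(0, 0))
  # window means match a direct slicing oracle (unnormalised)
  mcu <- melanopsin_contrast(rh, rl, normalise = FALSE)
  base <- mean(vapply(rh$trials, function(tr) sum(tr > -2 & tr <= 0), 0)) / 2
  late <- mean(vapply(rh$trials, function(tr) sum(tr > 5 & tr <= 10), 0)) / 5
  got <- mean(mcu$table$value[mcu$table$stimulus == "mel_high" &
                                mcu$table$window == "late"])
  expect_equal(got, late - base, tolerance = 1e-9)
  r_short <- hypovis:::sim_step_raster(sp, 10, 2)
  expect_error(melanopsin_contrast(rh, r_short), "differ")
})

test_that("cone classification: signs, preference formula and opponency", {
  # deterministic rasters: k spikes per increment half-cycle (alternating
  # +/- 1 across cycles so the paired test has nonzero variance but an exact
  # mean), k_dec per decrement half-cycle
  mk <- function(k_inc, k_dec, cycles = 10) {
    tr <- unlist(lapply(seq_len(cycles) - 1, function(c) {
      ki <- k_inc + if (k_inc > 1) c(1, -1)[c %% 2 + 1] else 0
      kd <- k_dec + if (k_dec > 1) c(-1, 1)[c %% 2 + 1] else 0
      c(if (ki > 0) seq(0.1, 1.9, length.out = ki) + c * 4,
        if (kd > 0) seq(2.1, 3.9, length.out = kd) + c * 4)
    }))
    event_raster(list(sort(tr), sort(tr)), 0, cycles * 4, 0.01)
  }
  # r_L = +10, r_S = +10: ON with zero preference
  cc <- classify_cone_response(list(L_only = mk(25, 5), S_only = mk(25, 5)))
  expect_identical(cc$class, "ON")
  expect_equal(cc$preference, 0)
  # r_L = +10, r_S = -5: L-ON opponent, preference (10-5)/15
  ccL <- classify_cone_response(list(L_only = mk(25, 5), S_only = mk(5, 15)))
  expect_identical(ccL$class, "L-ON opponent")
  expect_equal(ccL$r_L, 10)
  expect_equal(ccL$r_S, -5)
  expect_equal(ccL$preference, 1 / 3, tolerance = 1e-12)
  # silence: no response
  cc0 <- classify_cone_response(list(L_only = mk(10, 10), S_only = mk(8, 8)))
  expect_identical(cc0$class, "no response")
})

test_that("simulated opponent cells respond more to chromatic than achromatic contrast", {
  set.seed(106)
  sp <- cell_spec("II", baseline = 10, cone_w_L = 0.45, cone_w_S = -0.35)
  cr <- hypovis:::sim_cone_rasters(sp, session_spec(cone_trials = 3,
                                                    cone_cycles = 5))
  cc <- classify_cone_response(cr)
  expect_identical(cc$class, "L-ON opponent")
  expect_gt(cc$amp_L_minus_S, cc$amp_L_plus_S)
})
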