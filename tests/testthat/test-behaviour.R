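test_that("shape model: rigid-only data, mode recovery and orthonormality", {
  set.seed(41)
  base <- toy_shape_model()
  K <- nrow(base$mean_pose)
  # frames that are rigid transforms of one shape: no deformation variance
  frames <- array(0, c(120, K, 3))
  for (t in 1:120) {
    frames[t, , ] <- base$mean_pose %*% hypovis:::yaw_matrix(runif(1, 0, 2 * pi)) +
      rep(runif(3, -50, 50), each = K)
  }
  m0 <- fit_shape_model(frames)
  expect_true(m0$degenerate)
  expect_length(m0$eigenposes, 0)
  # centred mean recovers the shape up to a rigid transform
  tr <- hypovis:::kabsch(m0$mean_pose, base$mean_pose)
  expect_lt(max(abs(m0$mean_pose %*% tr$R + rep(tr$T, each = K) -
                      base$mean_pose)), 1e-6)
  # frames from two known orthogonal modes: subspace recovered
  set.seed(42)
  bts <- cbind(rnorm(300, 0, 3), rnorm(300, 0, 1.5))
  fr2 <- array(0, c(300, K, 3))
  P <- vapply(base$eigenposes, as.vector, numeric(3 * K))
  for (t in 1:300) {
    S <- base$mean_pose + matrix(P %*% bts[t, ], nrow = K)
    fr2[t, , ] <- S %*% hypovis:::yaw_matrix(runif(1, 0, 2 * pi)) +
      rep(runif(3, -20, 20), each = K)
  }
  m2 <- fit_shape_model(fr2, n_eigenposes = 2, landmarks = base$landmarks)
  Q <- vapply(m2$eigenposes, as.vector, numeric(3 * K))
  # orthonormal under the flattened inner product
  expect_equal(t(Q) %*% Q, diag(2), tolerance = 1e-8)
  # principal angles between true and recovered subspaces < 1 degree
  sv <- svd(t(P) %*% Q)$d
  angles <- acos(pmin(1, sv)) * 180 / pi
  expect_lt(max(angles), 1)
})

test_that("pose decomposition: rigid case, round trip and self-consistency", {
  model <- toy_shape_model()
  K <- nrow(model$mean_pose)
  # pure rigid motion: b near zero, R and T recovered
  theta <- 0.7; Tv <- c(12, -3, 5)
  fr <- array(0, c(2, K, 3))
  fr[1, , ] <- model$mean_pose
  fr[2, , ] <- model$mean_pose %*% hypovis:::yaw_matrix(theta) +
    rep(Tv, each = K)
  dec <- decompose_pose(fr, model)
  expect_lt(max(abs(dec$b)), 1e-6)
  expect_equal(dec$R[[2]], hypovis:::yaw_matrix(theta), tolerance = 1e-6)
  expect_equal(dec$T[2, ], Tv, tolerance = 1e-6)
  expect_true(all(vapply(dec$R, function(R)
    abs(det(R) - 1) < 1e-8 && max(abs(crossprod(R) - diag(3))) < 1e-8, TRUE)))
  # known (b, R, T) round trip at 1e-6
  set.seed(43)
  sim <- simulate_pose_session(n_trials = 1, noise_sd = 0, seed = 43)
  dec2 <- decompose_pose(sim$seq$frames, model)
  expect_lt(max(dec2$rmse), 1e-6)
  expect_lt(max(abs(dec2$b - sim$b)), 1e-5)
  # reconstruction matches the input within the reported error
  rec <- reconstruct_pose(dec2, model)
  rmse_chk <- sqrt(apply((rec - sim$seq$frames)^2, 1, mean))
  expect_equal(rmse_chk, dec2$rmse, tolerance = 1e-9)
})

test_that("features: constant walk, closed-form rotation, static pose", {
  model <- toy_shape_model()
  K <- nrow(model$mean_pose)
  # straight-line walk at constant v, fixed posture
  v <- 3.2; Tn <- 30
  fr <- array(0, c(Tn, K, 3))
  for (t in seq_len(Tn)) {
    fr[t, , ] <- model$mean_pose + rep(c(v * t, 0, 0), each = K)
  }
  seqs <- landmark_sequence(fr, 15, model$landmarks)
  f <- extract_features(decompose_pose(fr, model), seqs, model)
  expect_equal(f$locomotion[-1], rep(v, Tn - 1), tolerance = 1e-6)
  expect_equal(f$rotation[-1], rep(0, Tn - 1), tolerance = 1e-6)
  expect_equal(f$d_rear, rep(0, Tn), tolerance = 1e-6)
  expect_true(all(f$freeze[-1] == 0))
  # in-place rotation by theta per frame: Frobenius distance closed form
  theta <- 0.31
  fr2 <- array(0, c(10, K, 3))
  for (t in 1:10) fr2[t, , ] <- model$mean_pose %*%
      hypovis:::yaw_matrix(theta * t)
  f2 <- extract_features(decompose_pose(fr2, model),
                         landmark_sequence(fr2, 15, model$landmarks), model)
  expect_equal(f2$rotation[-1], rep(2 * sqrt(2) * abs(sin(theta / 2)), 9),
               tolerance = 1e-9)
  # static pose: every motion feature zero, freeze on
  fr3 <- array(rep(model$mean_pose, each = 5), c(5, K, 3))
  fr3 <- aperm(array(model$mean_pose, c(K, 3, 5)), c(3, 1, 2))
  f3 <- extract_features(decompose_pose(fr3, model),
                         landmark_sequence(fr3, 15, model$landmarks), model)
  expect_true(all(abs(f3$locomotion) < 1e-9))
  expect_true(all(f3$freeze[-1] == 1))
})

test_that("features are invariant to a global rigid transform of the arena", {
  set.seed(44)
  model <- toy_shape_model()
  sim <- simulate_pose_session(n_trials = 1, noise_sd = 0, seed = 44)
  fr <- sim$seq$frames
  K <- dim(fr)[2]
  Rg <- hypovis:::yaw_matrix(1.1)
  fr2 <- fr
  for (t in seq_len(dim(fr)[1])) {
    fr2[t, , ] <- fr[t, , ] %*% Rg + rep(c(100, -40, 7), each = K)
  }
  f1 <- extract_features(decompose_pose(fr, model),
                         landmark_sequence(fr, 15, model$landmarks), model)
  f2 <- extract_features(decompose_pose(fr2, model),
                         landmark_sequence(fr2, 15, model$landmarks), model)
  for (col in c("elongation", "bend", "locomotion", "rotation", "freeze")) {
    expect_equal(f2[[col]], f1[[col]], tolerance = 1e-6)
  }
})

test_that("freeze binarisation applies the strict 2 mm rule", {
  K <- 4
  mk <- function(disps) {
    Tn <- length(disps) + 1
    fr <- array(0, c(Tn, K, 3))
    for (t in 2:Tn) fr[t, , 1] <- fr[t - 1, , 1] + disps[t - 1] / K
    fr
  }
  # summed displacement 1.5 mm -> freeze; exactly 2.0 mm -> no freeze
  bf <- binarize_freeze(mk(c(1.5, 2.0, 2.5)))
  expect_equal(bf$freeze, c(0L, 1L, 0L, 0L))
  expect_equal(bf$displacement[-1], c(1.5, 2.0, 2.5), tolerance = 1e-12)
  # vigorous synthetic walking never freezes outside injected freezes
  sim <- simulate_pose_session(n_trials = 1, seed = 45)
  fz <- binarize_freeze(sim$seq)$freeze
  onset <- round(sim$seq$stim_log$onset_s[sim$seq$stim_log$type == "loom"] * 15) + 1
  injected <- (onset + 2):(onset + 1 + round(0.6 * 15))
  expect_true(all(fz[setdiff(2:length(fz), injected)] == 0))
})

test_that("stimulus-response table: constants, steps and a slicing oracle", {
  fr <- 15
  Tn <- 20 * fr
  feats <- data.frame(locomotion = rep(1.5, Tn), rear = rep(8, Tn))
  stim <- data.frame(trial = 1:2, type = "flash", onset_s = c(5, 12))
  tab <- stimulus_response(feats, stim, frame_rate = fr)
  expect_true(all(tab$delta == 0))
  # a step of height h exactly at the window start
  h <- 2.5
  onset_f <- round(5 * fr) + 1
  feats2 <- feats
  feats2$locomotion[(onset_f + 2):Tn] <- 1.5 + h
  tab2 <- stimulus_response(feats2, stim[1, ], frame_rate = fr)
  expect_equal(tab2$delta[tab2$feature == "locomotion"], h)
  # arbitrary series: window means equal direct slicing
  set.seed(46)
  feats3 <- data.frame(x = rnorm(Tn))
  tab3 <- stimulus_response(feats3, stim[1, ], frame_rate = fr)
  r0 <- onset_f + 2; r1 <- r0 + fr - 1
  b0 <- onset_f - 2 * fr; b1 <- onset_f - 1
  expect_equal(tab3$response, mean(feats3$x[r0:r1]), tolerance = 1e-12)
  expect_equal(tab3$baseline, mean(feats3$x[b0:b1]), tolerance = 1e-12)
  expect_equal(tab3$delta, tab3$response - tab3$baseline, tolerance = 1e-15)
  # windows beyond the recording drop the trial with a warning
  expect_warning(
    tabw <- stimulus_response(feats3, data.frame(trial = 9, type = "flash",
                                                 onset_s = 19.9),
                              frame_rate = fr),
    "dropped")
  expect_null(tabw)
})

test_that("freeze events: counting, single-gap bridging, empty windows", {
  # 0,1,1,1,0,0: one event of 3 frames
  expect_equal(freeze_event_durations(c(0, 1, 1, 1, 0, 0), 1:6), 3 / 15)
  # isolated non-freeze frame does not terminate the event
  expect_equal(freeze_event_durations(c(1, 0, 1, 1, 0, 0), 1:6), 4 / 15)
  # freezing continuing past the window end is followed to termination
  expect_equal(freeze_event_durations(c(0, 1, 1, 1, 1, 1, 0, 0), 1:3), 5 / 15)
  expect_length(freeze_event_durations(rep(0, 10), 2:8), 0)
})

test_that("injected pose effects are recovered end to end", {
  set.seed(47)
  sim <- simulate_pose_session(n_trials = 4, noise_sd = 0.05, seed = 47)
  model <- toy_shape_model()
  dec <- decompose_pose(sim$seq$frames, model)
  feats <- extract_features(dec, sim$seq, model)
  tab <- stimulus_response(feats, sim$seq$stim_log)
  loc <- tab[tab$feature == "locomotion" & tab$type == "flash", ]
  expect_equal(mean(loc$delta), 4, tolerance = 0.15)
  # injected 0.6 s freeze recovered within one frame
  fz <- feats$freeze
  durs <- vapply(which(sim$seq$stim_log$type == "loom"), function(i) {
    onset <- round(sim$seq$stim_log$onset_s[i] * 15) + 1
    freeze_event_durations(fz, (onset + 2):(onset + 1 + 15))
  }, 0)
  expect_true(all(abs(durs - 0.6) <= 1 / 15 + 1e-9))
})
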