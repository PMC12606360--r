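# Synthetic pose sessions, two-channel volumes and retinal point patterns,
# all seed-deterministic with ground truth returned alongside.

#' A small mouse-like shape model for simulation
#'
#' Eight landmarks along the body axis (nose to tail base) with two
#' orthonormal deformation modes: axial elongation in the XZ plane and
#' lateral bend in the XY plane.
#'
#' @param scale body length scale, mm.
#' @return a `shape_model` usable with [decompose_pose()] and
#'   [simulate_pose_session()].
#' @export
toy_shape_model <- function(scale = 80) {
  lm <- c("nose", "head", "neck", "spine1", "spine2", "spine3", "hip",
          "tail_base")
  K <- length(lm)
  x <- seq(scale / 2, -scale / 2, length.out = K)
  mean_pose <- cbind(x = x, y = rep(0, K),
                     z = 18 - 14 * (seq_len(K) - 1) / (K - 1) +
                       c(0, 0, 4, 5, 5, 4, 2, 0))
  mean_pose <- sweep(mean_pose, 2, colMeans(mean_pose))
  elong <- matrix(0, K, 3)
  elong[, 1] <- x / sqrt(sum(x^2))            # stretch along the body axis
  elong[, 3] <- 0
  bend <- matrix(0, K, 3)
  bend[, 2] <- (x^2 - mean(x^2))
  bend[, 2] <- bend[, 2] / sqrt(sum(bend[, 2]^2))
  # sign convention: nose-tail distance grows with positive elongation
  if (sum((elong[K, ] - elong[1, ]) * (mean_pose[K, ] - mean_pose[1, ])) < 0) {
    elong <- -elong
  }
  structure(list(mean_pose = mean_pose,
                 eigenposes = list(elong, bend),
                 variance = c(4, 2),
                 elongation_mode = elong, bend_mode = bend,
                 landmarks = lm, degenerate = FALSE),
            class = "shape_model")
}

yaw_matrix <- function(theta) {
  c <- cos(theta); s <- sin(theta)
  matrix(c(c, s, 0, -s, c, 0, 0, 0, 1), 3, 3)
}

#' Simulate a behavioural session with stimulus-locked responses
#'
#' Generates a 15 Hz landmark trajectory from a shape model: smooth
#' random-walk locomotion and heading plus autoregressive shape
#' coefficients, with stimulus-locked injected changes — light flashes
#' increase locomotion, looming stimuli trigger freezing of a known
#' duration, sounds change body bend and rotation. Ground-truth injected
#' effects are returned per trial.
#'
#' @param model a `shape_model` (default [toy_shape_model()]).
#' @param n_trials trials per stimulus type.
#' @param effects list with `flash_locomotion` (mm/frame added),
#'   `loom_freeze_s` (s of immobility), `sound_bend` (a.u. added to the bend
#'   coefficient) and `sound_rotation` (rad/frame of extra yaw).
#' @param frame_rate Hz.
#' @param inter_trial s between stimulus onsets.
#' @param noise_sd landmark measurement noise, mm (applied outside injected
#'   freezes).
#' @param seed integer seed.
#' @return list with `seq` (a [landmark_sequence()] carrying the stimulus
#'   log), `truth` (per-trial injected effect sizes) and the generative
#'   `b`, `R`, `T` series.
#' @export
simulate_pose_session <- function(model = toy_shape_model(), n_trials = 5,
                                  effects = list(flash_locomotion = 4,
                                                 loom_freeze_s = 0.6,
                                                 sound_bend = 1.5,
                                                 sound_rotation = 0.1),
                                  frame_rate = 15, inter_trial = 10,
                                  noise_sd = 0.05, seed = 1) {
  stopifnot(n_trials >= 1)
  set.seed(seed)
  types <- rep(c("flash", "loom", "sound"), n_trials)
  onsets <- 5 + inter_trial * (seq_along(types) - 1)
  Tn <- as.integer((max(onsets) + inter_trial) * frame_rate)
  K <- nrow(model$mean_pose)
  nm <- length(model$eigenposes)
  # baseline kinematics: AR(1) speed and yaw rate, AR(1) shape coefficients
  speed <- stats::filter(stats::rnorm(Tn, 0, 0.2), 0.9, "recursive") + 1.5
  speed <- pmax(0.3, as.numeric(speed))
  yaw_rate <- as.numeric(stats::filter(stats::rnorm(Tn, 0, 0.02), 0.95,
                                       "recursive"))
  b <- vapply(seq_len(nm), function(i)
    as.numeric(stats::filter(stats::rnorm(Tn, 0, 0.1), 0.9, "recursive")),
    numeric(Tn))
  onset_frame <- round(onsets * frame_rate) + 1L
  resp_len <- round(1 * frame_rate)
  freeze_frames <- integer(0)
  for (i in seq_along(types)) {
    w <- (onset_frame[i] + 2L):(onset_frame[i] + 1L + resp_len)
    if (types[i] == "flash") {
      speed[w] <- speed[w] + effects$flash_locomotion
    } else if (types[i] == "loom") {
      nf <- round(effects$loom_freeze_s * frame_rate)
      fz <- (onset_frame[i] + 2L):(onset_frame[i] + 1L + nf)
      freeze_frames <- c(freeze_frames, fz)
    } else {
      bend_idx <- min(nm, 2L)
      b[w, bend_idx] <- b[w, bend_idx] + effects$sound_bend
      yaw_rate[w] <- yaw_rate[w] + effects$sound_rotation
    }
  }
  speed[freeze_frames] <- 0
  yaw_rate[freeze_frames] <- 0
  for (f in freeze_frames) if (f > 1) b[f, ] <- b[f - 1, ]
  theta <- cumsum(yaw_rate)
  pos <- cbind(cumsum(speed * cos(theta)), cumsum(speed * sin(theta)), 0)
  frames <- array(0, dim = c(Tn, K, 3))
  P <- vapply(model$eigenposes, as.vector, numeric(3 * K))
  for (t in seq_len(Tn)) {
    S <- model$mean_pose + matrix(P %*% b[t, ], nrow = K)
    frames[t, , ] <- S %*% yaw_matrix(theta[t]) + rep(pos[t, ], each = K)
  }
  if (noise_sd > 0) {
    noise <- array(stats::rnorm(length(frames), 0, noise_sd), dim(frames))
    noise[freeze_frames, , ] <- 0
    frames <- frames + noise
  }
  stim_log <- data.frame(trial = seq_along(types), type = types,
                         onset_s = onsets)
  truth <- data.frame(trial = seq_along(types), type = types,
                      flash_locomotion = ifelse(types == "flash",
                                                effects$flash_locomotion, 0),
                      loom_freeze_s = ifelse(types == "loom",
                                             effects$loom_freeze_s, 0),
                      sound_bend = ifelse(types == "sound",
                                          effects$sound_bend, 0))
  list(seq = landmark_sequence(frames, frame_rate, model$landmarks,
                               stim_log),
       truth = truth, b = b, theta = theta, pos = pos)
}

#' Simulate a two-channel puncta volume with controlled colocalization
#'
#' The label channel holds `n_puncta` bright voxels over dim background
#' noise; a fraction `coloc_fraction` of the marker puncta sit exactly on
#' label puncta and the rest (plus `marker_density` of all voxels) are
#' placed independently.
#'
#' @param dims voxel dimensions (x, y, z).
#' @param voxel_size um.
#' @param n_puncta label puncta count.
#' @param coloc_fraction fraction of label puncta that are marker-positive.
#' @param marker_density independent marker-positive voxel fraction.
#' @param seed integer seed.
#' @return list with `stack` (a [two_channel_stack()]) and `truth`.
#' @export
simulate_volume <- function(dims = c(70, 56, 8), voxel_size = c(5, 5, 5),
                            n_puncta = 2000, coloc_fraction = 0,
                            marker_density = 0.15, seed = 1) {
  stopifnot(coloc_fraction >= 0, coloc_fraction <= 1)
  set.seed(seed)
  nv <- prod(dims)
  if (n_puncta > nv / 4) {
    stop("n_puncta too large for the volume (must be <= ", floor(nv / 4), ")")
  }
  label <- array(stats::runif(nv, 0, 0.15), dims)
  lab_idx <- sample.int(nv, n_puncta)
  label[lab_idx] <- stats::runif(n_puncta, 0.8, 1)
  marker <- array(stats::runif(nv, 0, 0.15), dims)
  n_co <- round(coloc_fraction * n_puncta)
  if (n_co > 0) {
    marker[sample(lab_idx, n_co)] <- stats::runif(n_co, 0.8, 1)
  }
  n_bg <- round(marker_density * nv)
  if (n_bg > 0) {
    marker[sample.int(nv, n_bg)] <- stats::runif(n_bg, 0.8, 1)
  }
  list(stack = two_channel_stack(label, marker, voxel_size),
       truth = list(coloc_fraction = coloc_fraction,
                    marker_density = marker_density, n_puncta = n_puncta))
}

#' Simulate a retinal point pattern with quadrant density weights
#'
#' Labelled-cell coordinates drawn over an annulus around the optic disc,
#' with the angular density piecewise constant over the four anatomical
#' quadrants in proportion to `weights` (ordered as in
#' [quadrant_distribution()]: dorsonasal, ventronasal, ventrotemporal,
#' dorsotemporal, counter-clockwise from the dorsal axis).
#'
#' @param weights non-negative quadrant weights (sum > 0).
#' @param n_cells number of points.
#' @param disc_centre optic disc (x, y), mm.
#' @param retina_radius mm.
#' @param dorsal_angle deg.
#' @param seed integer seed.
#' @return list with `points` (n x 2 matrix, mm), `disc_centre`,
#'   `retina_area`, `dorsal_angle` and `truth` (the weights).
#' @export
simulate_retina <- function(weights = c(1, 1, 1, 1), n_cells = 200,
                            disc_centre = c(0, 0), retina_radius = 1.6,
                            dorsal_angle = 90, seed = 1) {
  stopifnot(length(weights) == 4, all(weights >= 0), sum(weights) > 0)
  set.seed(seed)
  quad <- sample.int(4, n_cells, replace = TRUE, prob = weights)
  ang <- (quad - 1) * 90 + stats::runif(n_cells, 0, 90)
  ang <- (ang + dorsal_angle) * pi / 180
  r <- retina_radius * sqrt(stats::runif(n_cells, 0.15^2, 1))
  pts <- cbind(x = disc_centre[1] + r * cos(ang),
               y = disc_centre[2] + r * sin(ang))
  list(points = pts, disc_centre = disc_centre,
       retina_area = pi * retina_radius^2, dorsal_angle = dorsal_angle,
       truth = list(weights = weights / sum(weights)))
}
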