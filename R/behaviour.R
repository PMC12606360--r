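# Behavioural feature extraction from 3D landmark trajectories, freeze
# logic, and stimulus-evoked response tables.

#' Landmark trajectory container
#'
#' @param frames T x K x 3 array of landmark coordinates, mm.
#' @param frame_rate Hz.
#' @param landmarks character vector of K landmark names; the rear feature
#'   needs `"neck"` and `"tail_base"`.
#' @param stim_log optional data.frame with `trial`, `type` (`"flash"`,
#'   `"loom"`, `"sound"`), `onset_s`.
#' @return object of class `landmark_sequence`.
#' @export
landmark_sequence <- function(frames, frame_rate = 15, landmarks = NULL,
                              stim_log = NULL) {
  stopifnot(length(dim(frames)) == 3, dim(frames)[3] == 3, frame_rate > 0,
            dim(frames)[2] >= 3)
  if (any(!is.finite(frames))) stop("missing landmark coordinates")
  if (!is.null(landmarks)) stopifnot(length(landmarks) == dim(frames)[2])
  structure(list(frames = frames, frame_rate = frame_rate,
                 landmarks = landmarks, stim_log = stim_log),
            class = "landmark_sequence")
}

#' Read landmark trajectories from a long CSV
#'
#' Long format: columns `frame`, `landmark`, `x_mm`, `y_mm`, `z_mm`. A
#' wide "tracking-software" dialect (columns `<landmark>_x`, `<landmark>_y`,
#' `<landmark>_z`) is also accepted.
#'
#' @param path CSV file.
#' @param frame_rate Hz.
#' @return a [landmark_sequence()].
#' @export
read_landmarks_csv <- function(path, frame_rate = 15) {
  d <- utils::read.csv(path)
  if (all(c("frame", "landmark", "x_mm", "y_mm", "z_mm") %in% names(d))) {
    lm <- sort(unique(d$landmark))
    fr <- sort(unique(d$frame))
    arr <- array(NA_real_, dim = c(length(fr), length(lm), 3))
    for (j in seq_along(lm)) {
      sub <- d[d$landmark == lm[j], ]
      sub <- sub[order(sub$frame), ]
      arr[, j, ] <- as.matrix(sub[, c("x_mm", "y_mm", "z_mm")])
    }
    return(landmark_sequence(arr, frame_rate, landmarks = lm))
  }
  xcols <- grep("_x$", names(d), value = TRUE)
  lm <- sub("_x$", "", xcols)
  arr <- array(NA_real_, dim = c(nrow(d), length(lm), 3))
  for (j in seq_along(lm)) {
    arr[, j, ] <- as.matrix(d[, paste0(lm[j], c("_x", "_y", "_z"))])
  }
  landmark_sequence(arr, frame_rate, landmarks = lm)
}

#' Binarise immobility into a freeze series
#'
#' Per frame, sums the Euclidean displacement of every landmark relative to
#' the previous frame; a summed displacement strictly below `threshold`
#' scores 1 (freeze), otherwise 0. Exactly `threshold` scores 0 (strict
#' inequality). The first frame has no predecessor and scores 0.
#'
#' @param seq_or_frames a [landmark_sequence()] or T x K x 3 array.
#' @param threshold mm.
#' @return list with `freeze` (integer 0/1 series) and `displacement` (mm,
#'   `Inf` at frame 1 by convention).
#' @export
binarize_freeze <- function(seq_or_frames, threshold = 2) {
  frames <- if (inherits(seq_or_frames, "landmark_sequence"))
    seq_or_frames$frames else seq_or_frames
  Tn <- dim(frames)[1]
  if (Tn < 2) stop("need at least 2 frames")
  d <- frames[-1, , , drop = FALSE] - frames[-Tn, , , drop = FALSE]
  disp <- c(Inf, rowSums(sqrt(apply(d^2, c(1, 2), sum))))
  list(freeze = as.integer(disp < threshold), displacement = disp)
}

#' Extract the nine behavioural features
#'
#' Per-frame series: `rear` (vertical distance neck to tail base, mm),
#' `elongation` and `bend` (projections of the rigid-aligned shape residual
#' onto the model's designated XZ- and XY-plane deformation modes, a.u.),
#' their first differences `d_rear`, `d_elongation`, `d_bend` (padded with 0
#' at frame 1), `locomotion` (XY displacement of the body position `T(t)`
#' per frame, mm/frame), `rotation` (Frobenius distance between consecutive
#' rotation matrices, 0 at frame 1) and the binary `freeze` series.
#'
#' @param decomp a [decompose_pose()] of `seq`'s frames.
#' @param seq a [landmark_sequence()].
#' @param model the [fit_shape_model()] used for `decomp`.
#' @param freeze_threshold mm, see [binarize_freeze()].
#' @return data.frame of T rows with the nine feature columns.
#' @export
extract_features <- function(decomp, seq, model, freeze_threshold = 2) {
  stopifnot(inherits(decomp, "pose_decomposition"),
            inherits(seq, "landmark_sequence"),
            inherits(model, "shape_model"))
  frames <- seq$frames
  Tn <- dim(frames)[1]; K <- dim(frames)[2]
  lm <- seq$landmarks %||% model$landmarks
  if (is.null(lm) || !all(c("neck", "tail_base") %in% lm)) {
    stop("landmark names with 'neck' and 'tail_base' are required")
  }
  rear <- frames[, match("neck", lm), 3] - frames[, match("tail_base", lm), 3]
  if (is.null(model$elongation_mode) || is.null(model$bend_mode)) {
    stop("model lacks designated plane deformation modes")
  }
  # shape residual in model space, per frame
  proj <- function(mode) {
    v <- as.vector(mode)
    v <- v / sqrt(sum(v^2))
    vapply(seq_len(Tn), function(t) {
      Xs <- (frames[t, , ] - rep(decomp$T[t, ], each = K)) %*%
        t(decomp$R[[t]])
      sum(as.vector(Xs - model$mean_pose) * v)
    }, 0)
  }
  elong <- proj(model$elongation_mode)
  bend <- proj(model$bend_mode)
  dT <- diff(decomp$T[, 1:2, drop = FALSE])
  locomotion <- c(0, sqrt(rowSums(dT^2)))
  rotation <- c(0, vapply(2:Tn, function(t)
    sqrt(sum((decomp$R[[t]] - decomp$R[[t - 1]])^2)), 0))
  d1 <- function(x) c(0, diff(x))
  data.frame(rear = rear, elongation = elong, bend = bend,
             d_rear = d1(rear), d_elongation = d1(elong), d_bend = d1(bend),
             locomotion = locomotion, rotation = rotation,
             freeze = binarize_freeze(frames, freeze_threshold)$freeze)
}

#' Stimulus-evoked change in each behavioural feature
#'
#' For every stimulus trial and feature: the mean over a response window
#' (default 1 s starting exactly 2 frames after stimulus onset), the mean
#' over the 2 s baseline immediately preceding the stimulus, their
#' difference, and the absolute (unsubtracted) response mean. Trials whose
#' windows fall outside the recording are dropped with a warning.
#'
#' @param features data.frame from [extract_features()].
#' @param stim_log data.frame with `trial`, `type`, `onset_s`.
#' @param frame_rate Hz.
#' @param response_window s.
#' @param onset_offset_frames frames between stimulus onset and the start of
#'   the response window.
#' @param baseline s.
#' @param first_k restrict to the first k trials of each stimulus type
#'   (`NULL` for all).
#' @return tidy data.frame: `trial`, `type`, `feature`, `baseline`,
#'   `response`, `delta`, `absolute`.
#' @export
stimulus_response <- function(features, stim_log, frame_rate = 15,
                              response_window = 1, onset_offset_frames = 2,
                              baseline = 2, first_k = NULL) {
  stopifnot(all(c("trial", "type", "onset_s") %in% names(stim_log)))
  if (!is.null(first_k)) {
    stim_log <- do.call(rbind, lapply(split(stim_log, stim_log$type),
                                      function(d) utils::head(
                                        d[order(d$onset_s), ], first_k)))
  }
  Tn <- nrow(features)
  out <- list()
  for (i in seq_len(nrow(stim_log))) {
    onset <- round(stim_log$onset_s[i] * frame_rate) + 1L
    r0 <- onset + onset_offset_frames
    r1 <- r0 + round(response_window * frame_rate) - 1L
    b0 <- onset - round(baseline * frame_rate)
    b1 <- onset - 1L
    if (b0 < 1 || r1 > Tn) {
      warning("trial ", stim_log$trial[i], " window outside recording; dropped")
      next
    }
    for (f in names(features)) {
      resp <- mean(features[[f]][r0:r1])
      base <- mean(features[[f]][b0:b1])
      out[[length(out) + 1L]] <- data.frame(
        trial = stim_log$trial[i], type = stim_log$type[i], feature = f,
        baseline = base, response = resp, delta = resp - base,
        absolute = resp)
    }
  }
  do.call(rbind, out)
}

#' Durations of stimulus-driven freeze events
#'
#' An event is initiated by the first freeze frame within the analysis
#' window and terminated by two consecutive non-freeze frames (the scan
#' continues past the window end if freezing is ongoing); a single
#' non-freeze frame does not terminate the event. Duration counts frames
#' from the event start to the last freeze frame before termination.
#'
#' @param freeze 0/1 series.
#' @param window integer indices of the analysis window within `freeze`.
#' @param frame_rate Hz.
#' @return numeric vector of event durations, s (length 0 when the window
#'   holds no freezing).
#' @export
freeze_event_durations <- function(freeze, window, frame_rate = 15) {
  stopifnot(all(freeze %in% c(0, 1)))
  w <- window[window >= 1 & window <= length(freeze)]
  start <- w[which(freeze[w] == 1)[1]]
  if (is.na(start)) return(numeric(0))
  i <- start
  last_one <- start
  while (i <= length(freeze)) {
    if (freeze[i] == 1) {
      last_one <- i
    } else if (i > start && i < length(freeze) && freeze[i + 1] == 0) {
      break
    } else if (i == length(freeze)) {
      break
    }
    i <- i + 1
  }
  (last_one - start + 1) / frame_rate
}
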