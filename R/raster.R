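# Trial-aligned spike rasters and peri-stimulus time histograms.

#' Trial-aligned spike raster for one unit under one stimulus condition
#'
#' Spike times are in seconds relative to stimulus onset; each trial spans
#' `[-pre_window, stim_duration + post_window]`.
#'
#' @param trials list of numeric spike-time vectors (one per trial). Times
#'   must be sorted and `>= -pre_window`.
#' @param pre_window recorded baseline before onset, s.
#' @param stim_duration stimulus duration, s.
#' @param post_window recorded time after stimulus offset, s.
#' @param unit_id,condition labels.
#' @return object of class `event_raster`.
#' @export
event_raster <- function(trials, pre_window, stim_duration, post_window = 1,
                         unit_id = NA_character_, condition = NA_character_) {
  stopifnot(is.list(trials), pre_window >= 0, stim_duration > 0,
            post_window >= 0)
  trials <- lapply(trials, as.numeric)
  for (tr in trials) {
    if (is.unsorted(tr)) stop("spike times must be sorted within each trial")
    if (length(tr) && min(tr) < -pre_window)
      stop("spike time earlier than -pre_window")
  }
  structure(list(unit_id = unit_id, condition = condition, trials = trials,
                 pre_window = pre_window, stim_duration = stim_duration,
                 post_window = post_window),
            class = "event_raster")
}

#' @export
print.event_raster <- function(x, ...) {
  cat("<event_raster>", x$unit_id, "|", x$condition, "|",
      length(x$trials), "trials,",
      sum(lengths(x$trials)), "spikes, stim", x$stim_duration, "s\n")
  invisible(x)
}

n_trials <- function(raster) length(raster$trials)

# Spike count per trial in the half-open window (from, to].
window_counts <- function(raster, from, to) {
  vapply(raster$trials, function(tr) sum(tr > from & tr <= to), 0L)
}

# Mean firing rate per trial in (from, to], spikes/s.
window_rates <- function(raster, from, to) {
  window_counts(raster, from, to) / (to - from)
}

baseline_rate <- function(raster) {
  mean(window_rates(raster, -raster$pre_window, 0))
}

#' Peri-stimulus time histogram
#'
#' Bins spikes across trials over the full recorded span and returns the
#' trial-averaged rate, optionally smoothed with a Gaussian kernel. The
#' unsmoothed counts conserve the total number of spikes falling inside the
#' binned span.
#'
#' @param raster an [event_raster()].
#' @param bin_width s, > 0.
#' @param kernel_sigma Gaussian smoothing sd in s, or `NULL` for none.
#' @return data.frame with `time` (bin centres, s), `count` (summed across
#'   trials) and `rate` (trial-mean spikes/s, smoothed if requested), plus
#'   attribute `counts_by_trial` (trials x bins matrix).
#' @export
build_psth <- function(raster, bin_width, kernel_sigma = NULL) {
  stopifnot(inherits(raster, "event_raster"), bin_width > 0)
  t0 <- -raster$pre_window
  t1 <- raster$stim_duration + raster$post_window
  n_bins <- max(1L, floor((t1 - t0) / bin_width + 1e-9))
  breaks <- t0 + bin_width * (0:n_bins)
  if (sum(lengths(raster$trials)) == 0L) {
    warning("empty raster: returning all-zero PSTH")
  }
  cbt <- t(vapply(raster$trials, function(tr) {
    tr <- tr[tr > breaks[1] & tr <= breaks[n_bins + 1]]
    tabulate(pmin(n_bins, ceiling((tr - t0) / bin_width)), nbins = n_bins)
  }, integer(n_bins)))
  count <- colSums(cbt)
  rate <- count / (n_trials(raster) * bin_width)
  if (!is.null(kernel_sigma) && kernel_sigma > 0) {
    rate <- gauss_smooth(rate, kernel_sigma / bin_width)
  }
  out <- data.frame(time = breaks[-1] - bin_width / 2, count = count,
                    rate = rate)
  attr(out, "counts_by_trial") <- cbt
  out
}

#' Read trial-aligned spike tables from CSV
#'
#' The spike CSV has columns `unit_id`, `trial`, `time_s` (stimulus-relative
#' seconds); the stimulus log has columns `trial`, `condition`, `duration_s`
#' (an `onset_s` column, if present, is ignored here because spike times are
#' already stimulus-relative). Trials are assigned to conditions through the
#' stimulus log; one [event_raster()] per unit x condition is returned.
#'
#' @param spikes_path,stim_path CSV files, or data.frames already read.
#' @param pre_window,post_window recording extents, s.
#' @return named list of rasters (`unit@condition`).
#' @export
read_spike_csv <- function(spikes_path, stim_path, pre_window = 2,
                           post_window = 1) {
  sp <- if (is.data.frame(spikes_path)) spikes_path else
    utils::read.csv(spikes_path)
  st <- if (is.data.frame(stim_path)) stim_path else
    utils::read.csv(stim_path)
  stopifnot(all(c("unit_id", "trial", "time_s") %in% names(sp)),
            all(c("trial", "condition", "duration_s") %in% names(st)))
  out <- list()
  for (u in unique(sp$unit_id)) {
    rows <- sp[sp$unit_id == u, ]
    for (cond in unique(st$condition)) {
      stc <- st[st$condition == cond, ]
      trs <- lapply(stc$trial, function(tr) sort(rows$time_s[rows$trial == tr]))
      out[[paste0(u, "@", cond)]] <- event_raster(
        trs, pre_window = pre_window, stim_duration = stc$duration_s[1],
        post_window = post_window, unit_id = as.character(u), condition = cond)
    }
  }
  out
}
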