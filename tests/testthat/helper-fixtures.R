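# Deterministic fixtures used across the suite.

# Perfectly regular spike train at `rate` spikes/s over (from, to].
regular_spikes <- function(rate, from, to) {
  if (rate <= 0) return(numeric(0))
  seq(from + 1 / (2 * rate), to, by = 1 / rate)
}

# Raster whose every trial is an identical deterministic rate profile:
# `segments` is a data.frame with from, to, rate.
deterministic_raster <- function(segments, pre, dur, post, n_trials = 10) {
  tr <- sort(unlist(Map(regular_spikes, segments$rate, segments$from,
                        segments$to)))
  event_raster(rep(list(tr), n_trials), pre_window = pre,
               stim_duration = dur, post_window = post)
}

# Homogeneous Poisson raster.
poisson_raster <- function(rate, pre, dur, post, n_trials) {
  total <- pre + dur + post
  trials <- lapply(seq_len(n_trials), function(i)
    sort(stats::runif(stats::rpois(1, rate * total), -pre, dur + post)))
  event_raster(trials, pre_window = pre, stim_duration = dur,
               post_window = post)
}
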