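# Classification of single-unit responses to full-field light stimuli.

#' Test whether a unit is light responsive
#'
#' A unit is light responsive when its firing rate in the first `window`
#' seconds after light ON or light OFF is significantly increased relative to
#' an equal-length baseline window immediately before onset (paired two-tailed
#' t-test across trials; an increase requires a positive mean difference in
#' addition to p < alpha).
#'
#' @param raster an [event_raster()] with at least 5 trials.
#' @param window test window length, s.
#' @param alpha significance level.
#' @return list with `responsive`, `p_on`, `p_off`, the mean rate differences
#'   `diff_on`/`diff_off` (spikes/s) and `flag` (`"degenerate"` when both
#'   windows have zero variance across trials).
#' @export
test_light_responsive <- function(raster, window = 0.25, alpha = 0.05) {
  stopifnot(inherits(raster, "event_raster"))
  if (n_trials(raster) < 5) stop("need at least 5 trials")
  if (raster$pre_window < window) stop("pre-stimulus window too short")
  base <- window_rates(raster, -window, 0)
  on <- window_rates(raster, 0, window)
  d_on <- on - base
  p_on <- safe_t_p(d_on)
  p_off <- NA_real_
  d_off <- rep(NA_real_, n_trials(raster))
  if (raster$post_window >= window) {
    off <- window_rates(raster, raster$stim_duration,
                        raster$stim_duration + window)
    d_off <- off - base
    p_off <- safe_t_p(d_off)
  }
  flag <- if (is.na(p_on) && is.na(p_off)) "degenerate" else NA_character_
  responsive <- isTRUE(!is.na(p_on) && p_on < alpha && mean(d_on) > 0) ||
    isTRUE(!is.na(p_off) && p_off < alpha && mean(d_off) > 0)
  list(responsive = responsive, p_on = p_on, p_off = p_off,
       diff_on = mean(d_on), diff_off = mean(d_off), flag = flag)
}

#' Classify a light-responsive unit as sustained or transient
#'
#' Sustained cells keep firing above baseline through the light step: the
#' trial-wise rate over the last 500 ms of light ON is compared against the
#' rate over the `baseline` seconds before onset by a paired two-tailed
#' t-test; the unit is sustained iff the test is significant with a positive
#' mean difference, otherwise transient.
#'
#' @param raster an [event_raster()]; `stim_duration` must be >= 0.5 s (and
#'   >= 1 s is assumed by the protocol).
#' @param alpha significance level.
#' @param baseline baseline length, s (default 2, truncated to the recorded
#'   `pre_window` with a warning).
#' @param tail length of the terminal ON window, s.
#' @return list with `kind` (`"sustained"`/`"transient"`), `p_tonic` and the
#'   mean rate difference `diff` (spikes/s).
#' @export
classify_sustained_transient <- function(raster, alpha = 0.05, baseline = 2,
                                         tail = 0.5) {
  stopifnot(inherits(raster, "event_raster"))
  if (raster$stim_duration < tail) {
    stop("stimulus shorter than the terminal analysis window")
  }
  if (raster$pre_window < baseline) {
    warning("recorded baseline shorter than requested; using ",
            raster$pre_window, " s")
    baseline <- raster$pre_window
  }
  pre <- window_rates(raster, -baseline, 0)
  late <- window_rates(raster, raster$stim_duration - tail,
                       raster$stim_duration)
  d <- late - pre
  p <- safe_t_p(d)
  kind <- if (!is.na(p) && p < alpha && mean(d) > 0) "sustained" else
    "transient"
  list(kind = kind, p_tonic = p, diff = mean(d))
}

#' Response latency from a kernel-smoothed rate
#'
#' The pooled spike train is binned at `step` resolution and smoothed with a
#' moving Gaussian kernel window (sd `kernel_sigma`); latency is the time of
#' the first post-onset sample exceeding the 95% confidence limits of the
#' pre-stimulus smoothed rate (upper limit for excitation, lower for
#' suppression), sustained for `min_run` consecutive samples. The kernel
#' window trails the evaluation time (causal half-Gaussian) so that
#' stimulus-driven spikes cannot pull the estimated onset earlier than the
#' first evoked spike; `kernel = "centered"` gives the symmetric variant.
#' Confidence limits are mean +/- 1.96 sd of the baseline samples by default;
#' `method = "percentile"` uses the 2.5/97.5 baseline percentiles instead.
#' With a silent baseline the limits are degenerate; the function then falls
#' back to requiring the smoothed rate to exceed half the contribution of a
#' single spike (flagged).
#'
#' @param raster an [event_raster()] with >= 1 s of recorded baseline.
#' @param kernel_sigma Gaussian kernel sd, s.
#' @param step evaluation step, s.
#' @param baseline length of baseline used for the limits, s.
#' @param method `"normal"` or `"percentile"`.
#' @param kernel `"causal"` (default) or `"centered"`.
#' @param min_run consecutive supra-threshold samples required (default 10
#'   samples = 10 ms, two kernel sds: a crossing must be sustained to count).
#' @return list with `latency` (s, or `NA` if no crossing before stimulus
#'   end), `direction` (`"increase"`/`"decrease"`), `limits` and `flag`.
#' @export
response_latency <- function(raster, kernel_sigma = 0.005, step = 0.001,
                             baseline = 1, method = c("normal", "percentile"),
                             kernel = c("causal", "centered"), min_run = 10) {
  stopifnot(inherits(raster, "event_raster"))
  method <- match.arg(method)
  kernel <- match.arg(kernel)
  if (raster$pre_window < baseline) {
    stop("need at least ", baseline, " s of pre-stimulus baseline")
  }
  if (kernel == "centered") {
    psth <- build_psth(raster, bin_width = step, kernel_sigma = kernel_sigma)
  } else {
    psth <- build_psth(raster, bin_width = step)
    psth$rate <- causal_smooth(psth$rate, kernel_sigma / step)
  }
  tt <- psth$time
  rate <- psth$rate
  base <- rate[tt < 0 & tt >= -baseline]
  flag <- NA_character_
  if (sum(base) == 0) {
    flag <- "silent_baseline"
    one_spike_peak <- stats::dnorm(0, sd = kernel_sigma) / n_trials(raster)
    lims <- c(lower = -Inf, upper = 0.5 * one_spike_peak)
  } else if (method == "normal") {
    lims <- c(lower = mean(base) - 1.96 * stats::sd(base),
              upper = mean(base) + 1.96 * stats::sd(base))
  } else {
    q <- stats::quantile(base, c(0.025, 0.975), names = FALSE)
    lims <- c(lower = q[1], upper = q[2])
  }
  post <- which(tt > 0 & tt <= raster$stim_duration)
  out <- rate[post] > lims["upper"] | rate[post] < lims["lower"]
  run <- 0L
  i <- NA_integer_
  for (j in seq_along(out)) {
    run <- if (out[j]) run + 1L else 0L
    if (run >= min_run) { i <- post[j - min_run + 1L]; break }
  }
  if (is.na(i)) {
    return(list(latency = NA_real_, direction = NA_character_,
                limits = lims, flag = flag))
  }
  list(latency = tt[i],
       direction = if (rate[i] > lims["upper"]) "increase" else "decrease",
       limits = lims, flag = flag)
}

#' Step-response measures: ON peak, tonic and OFF peak
#'
#' Peak change in firing in any 50 ms bin within a search window after light
#' ON (and after light OFF), plus the mean rate over the last 500 ms of light
#' ON, all baseline subtracted. Peaks are signed: the value with the largest
#' absolute deviation from baseline is returned, so suppressions appear as
#' negative peaks.
#'
#' @param raster an [event_raster()] with `stim_duration >= 1` s.
#' @param bin peak bin width, s.
#' @param on_search,off_search search window lengths after each transition, s.
#' @param tail terminal ON window for the tonic measure, s.
#' @return list with `on_peak`, `tonic`, `off_peak`, `baseline` (spikes/s) and
#'   `flag` (`"no_post_off"` when the recording ends at light OFF).
#' @export
quantify_step_response <- function(raster, bin = 0.05, on_search = 1,
                                   off_search = 1, tail = 0.5) {
  stopifnot(inherits(raster, "event_raster"))
  if (raster$stim_duration < 1) stop("stimulus step shorter than 1 s")
  base <- baseline_rate(raster)
  peak_in <- function(from, to) {
    nb <- max(1L, floor((to - from) / bin + 1e-9))
    rates <- vapply(seq_len(nb), function(i) {
      mean(window_rates(raster, from + (i - 1) * bin, from + i * bin))
    }, 0)
    ch <- rates - base
    ch[which.max(abs(ch))]
  }
  on_peak <- peak_in(0, min(on_search, raster$stim_duration))
  tonic <- mean(window_rates(raster, raster$stim_duration - tail,
                             raster$stim_duration)) - base
  flag <- NA_character_
  off_peak <- NA_real_
  if (raster$post_window >= bin) {
    off_peak <- peak_in(raster$stim_duration,
                        raster$stim_duration +
                          min(off_search, raster$post_window))
  } else {
    flag <- "no_post_off"
  }
  list(on_peak = on_peak, tonic = tonic, off_peak = off_peak,
       baseline = base, flag = flag)
}

#' Melanopsin-contrast window measures for long light steps
#'
#' For a pair of spectrally distinct but cone-matched long steps (high vs low
#' melanopsin excitation), computes baseline-subtracted mean rates over the
#' first 250 ms and the last 5 s of the step for every trial. A melanopsin
#' contribution appears as a high-vs-low difference in the late window with
#' little difference in the early (rod/cone dominated) window.
#'
#' @param raster_high,raster_low [event_raster()]s with identical
#'   `stim_duration` (default protocol: 10 s steps).
#' @param early early window length, s.
#' @param late late window length, s.
#' @param normalise divide by the largest absolute trial-mean early response
#'   across the two stimuli (when positive).
#' @return list with `table` (tidy data.frame: stimulus, window, trial,
#'   value) and `summary` (`early_diff`, `late_diff`: high minus low
#'   trial-mean responses).
#' @export
melanopsin_contrast <- function(raster_high, raster_low, early = 0.25,
                                late = 5, normalise = TRUE) {
  stopifnot(inherits(raster_high, "event_raster"),
            inherits(raster_low, "event_raster"))
  if (raster_high$stim_duration != raster_low$stim_duration) {
    stop("stimulus durations differ between the high and low rasters")
  }
  dur <- raster_high$stim_duration
  if (dur < late) stop("stimulus shorter than the late analysis window")
  one <- function(raster, label) {
    base <- window_rates(raster, -raster$pre_window, 0)
    rbind(
      data.frame(stimulus = label, window = "early",
                 trial = seq_len(n_trials(raster)),
                 value = window_rates(raster, 0, early) - base),
      data.frame(stimulus = label, window = "late",
                 trial = seq_len(n_trials(raster)),
                 value = window_rates(raster, dur - late, dur) - base))
  }
  tab <- rbind(one(raster_high, "mel_high"), one(raster_low, "mel_low"))
  if (normalise) {
    scale <- max(abs(tapply(tab$value[tab$window == "early"],
                            tab$stimulus[tab$window == "early"], mean)))
    if (scale > 0) tab$value <- tab$value / scale
  }
  m <- tapply(tab$value, list(tab$stimulus, tab$window), mean)
  list(table = tab,
       summary = c(early_diff = m["mel_high", "early"] - m["mel_low", "early"],
                   late_diff = m["mel_high", "late"] - m["mel_low", "late"]))
}

# Phase-resolved response amplitude to a square-wave stimulus: mean rate over
# increment half-cycles minus decrement half-cycles, per cycle (cycles pooled
# across trials), with a paired test across cycles.
square_wave_amplitude <- function(raster, freq = 0.25) {
  period <- 1 / freq
  half <- period / 2
  diffs <- unlist(lapply(raster$trials, function(tr) {
    tr <- tr[tr >= 0 & tr < raster$stim_duration]
    nc <- floor(raster$stim_duration / period)
    if (nc < 1) return(numeric(0))
    tr <- tr[tr < nc * period]
    cyc <- floor(tr / period)
    phase <- tr - cyc * period
    inc <- tabulate(cyc[phase < half] + 1L, nbins = nc)
    dec <- tabulate(cyc[phase >= half] + 1L, nbins = nc)
    (inc - dec) / half
  }))
  list(amplitude = mean(diffs), p = safe_t_p(diffs), n_cycles = length(diffs))
}

#' Cone opsin preference index
#'
#' `(|r_L| - |r_S|) / (|r_L| + |r_S|)`, in `[-1, 1]`, +1 for a purely
#' L-opsin-driven response and -1 for purely S-driven. `NA` when both
#' amplitudes are 0.
#'
#' @param r_L,r_S signed response amplitudes to the L- and S-opsin-isolating
#'   stimuli, spikes/s.
#' @return index in `[-1, 1]` or `NA`.
#' @export
cone_preference_index <- function(r_L, r_S) {
  s <- abs(r_L) + abs(r_S)
  ifelse(s == 0, NA_real_, (abs(r_L) - abs(r_S)) / s)
}

#' Classify cone-opsin response pattern and opponency
#'
#' Given square-wave (default 0.25 Hz) full-field rasters for S-opsin-only,
#' L-opsin-only, in-phase (L+S) and antiphase (L-S) cone-isolating stimuli,
#' computes signed response amplitudes to each opsin (rate on opsin-excitation
#' increments minus decrements, paired test across cycles), assigns the
#' response class from the sign pattern and reports a cone preference index
#' `(|r_L| - |r_S|)/(|r_L| + |r_S|)` in `[-1, 1]`, positive toward L.
#'
#' @param rasters named list with elements `S_only`, `L_only` and optionally
#'   `L_plus_S`, `L_minus_S` ([event_raster()]s, >= 10 cycles each).
#' @param freq square-wave frequency, Hz.
#' @param alpha per-opsin significance level.
#' @return list with `class` (one of `"ON"`, `"OFF"`, `"L-ON opponent"`,
#'   `"S-ON opponent"`, `"no response"`), `r_L`, `r_S`, `p_L`, `p_S`,
#'   `preference`, and amplitudes for the joint stimuli when supplied.
#' @export
classify_cone_response <- function(rasters, freq = 0.25, alpha = 0.05) {
  stopifnot(all(c("S_only", "L_only") %in% names(rasters)))
  for (nm in names(rasters)) {
    nc <- sum(vapply(rasters[[nm]]$trials, function(.) 1L, 1L)) *
      floor(rasters[[nm]]$stim_duration * freq)
    if (nc < 10) warning(nm, ": fewer than 10 stimulus cycles")
  }
  aL <- square_wave_amplitude(rasters$L_only, freq)
  aS <- square_wave_amplitude(rasters$S_only, freq)
  sig_L <- !is.na(aL$p) && aL$p < alpha
  sig_S <- !is.na(aS$p) && aS$p < alpha
  rL <- aL$amplitude; rS <- aS$amplitude
  cls <- if (!sig_L && !sig_S) {
    "no response"
  } else if (sig_L && sig_S && sign(rL) != sign(rS)) {
    if (rL > 0) "L-ON opponent" else "S-ON opponent"
  } else {
    r_dom <- if (sig_L && sig_S) {
      if (abs(rL) >= abs(rS)) rL else rS
    } else if (sig_L) rL else rS
    if (r_dom > 0) "ON" else "OFF"
  }
  pref <- cone_preference_index(rL, rS)
  out <- list(class = cls, r_L = rL, r_S = rS, p_L = aL$p, p_S = aS$p,
              preference = pref)
  for (nm in c("L_plus_S", "L_minus_S")) {
    if (nm %in% names(rasters)) {
      out[[paste0("amp_", nm)]] <-
        square_wave_amplitude(rasters[[nm]], freq)$amplitude
    }
  }
  out
}
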