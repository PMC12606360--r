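# Receptive-field mapping, periodogram tuning, direction/orientation and
# motion selectivity, and the Group I-VI functional taxonomy.

#' Map a receptive field from flashing-bar responses
#'
#' Each bar condition (position x axis x polarity) contributes a
#' baseline-subtracted response (mean rate in a 250 ms window after bar
#' onset, minus an equal-length pre-onset baseline, per trial). Positions are
#' tested for a significant response (paired t-test across trials) with
#' Benjamini-Hochberg control across all conditions; the RF is declared
#' undetectable if nothing survives. A 1-D Gaussian is fitted separately to
#' the azimuth profile (vertical bars) and the elevation profile (horizontal
#' bars) of the dominant polarity; the centre is the pair of fitted means and
#' the diameter the mean of the fitted full widths at half maximum.
#'
#' @param rasters list of [event_raster()]s, one per bar condition.
#' @param stimuli data.frame aligned with `rasters`: columns `position_deg`,
#'   `axis` (`"azimuth"` for vertical bars, `"elevation"` for horizontal) and
#'   `polarity` (`"light"`/`"dark"`).
#' @param window response window after bar onset, s.
#' @param alpha significance level (applied to BH-adjusted p-values).
#' @param bar_width bar width in degrees (used for surround detection within
#'   3 bar widths of the centre).
#' @return object of class `rf_profile`: list with `profiles` (tidy
#'   data.frame of responses and adjusted p per condition), `detectable`,
#'   `polarity` (`"ON"`/`"OFF"`/`"none"`), `centre` (azimuth, elevation, deg),
#'   `diameter` (deg), `fwhm` per axis and `surround` flag.
#' @export
map_receptive_field <- function(rasters, stimuli, window = 0.25, alpha = 0.05,
                                bar_width = 7) {
  stopifnot(length(rasters) == nrow(stimuli),
            all(c("position_deg", "axis", "polarity") %in% names(stimuli)))
  for (ax in unique(stimuli$axis)) {
    pos <- sort(unique(stimuli$position_deg[stimuli$axis == ax]))
    if (length(pos) > 2 && max(diff(pos)) > 1.5 * stats::median(diff(pos))) {
      stop("non-contiguous ", ax, " position grid")
    }
  }
  resp <- do.call(rbind, lapply(seq_along(rasters), function(i) {
    r <- rasters[[i]]
    d <- window_rates(r, 0, window) - window_rates(r, -window, 0)
    data.frame(position_deg = stimuli$position_deg[i], axis = stimuli$axis[i],
               polarity = stimuli$polarity[i], response = mean(d),
               p = safe_t_p(d))
  }))
  resp$p_adj <- stats::p.adjust(resp$p, method = "BH")
  detect <- !is.na(resp$p_adj) & resp$p_adj < alpha
  # an RF needs position structure: at least two conditions surviving BH
  if (sum(detect) < 2) {
    return(structure(list(profiles = resp, detectable = FALSE,
                          polarity = "none", centre = c(azimuth = NA_real_,
                                                        elevation = NA_real_),
                          diameter = NA_real_, fwhm = c(azimuth = NA_real_,
                                                        elevation = NA_real_),
                          surround = FALSE),
                     class = "rf_profile"))
  }
  peak_by_pol <- tapply(abs(resp$response[detect]), resp$polarity[detect], max)
  dom_pol <- names(peak_by_pol)[which.max(peak_by_pol)]
  dom <- resp[resp$polarity == dom_pol, ]
  fit_axis <- function(ax) {
    pr <- dom[dom$axis == ax, ]
    if (nrow(pr) < 4) return(c(mu = NA_real_, fwhm = NA_real_, amp = NA_real_))
    pk <- pr$position_deg[which.max(abs(pr$response))]
    amp0 <- pr$response[which.max(abs(pr$response))]
    fit <- tryCatch(minpack.lm::nlsLM(
      response ~ a * exp(-(position_deg - mu)^2 / (2 * s^2)) + c0,
      data = pr,
      start = list(a = amp0, mu = pk, s = bar_width / 2, c0 = 0),
      lower = c(-Inf, min(pr$position_deg), 0.1, -Inf),
      upper = c(Inf, max(pr$position_deg), diff(range(pr$position_deg)), Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) return(c(mu = pk, fwhm = NA_real_, amp = amp0))
    cf <- stats::coef(fit)
    c(mu = unname(cf["mu"]), fwhm = 2 * sqrt(2 * log(2)) * unname(cf["s"]),
      amp = unname(cf["a"]))
  }
  az <- fit_axis("azimuth")
  el <- fit_axis("elevation")
  # position-independent (flat) responses are not a spatial RF: the fitted
  # width must be narrower than the stimulated span on some axis
  spans <- tapply(dom$position_deg, dom$axis, function(p) diff(range(p)))
  flat <- TRUE
  for (ax in c("azimuth", "elevation")) {
    fw <- if (ax == "azimuth") az["fwhm"] else el["fwhm"]
    if (!is.na(fw) && fw < spans[[ax]]) flat <- FALSE
  }
  if (flat) {
    return(structure(list(profiles = resp, detectable = FALSE,
                          polarity = "none",
                          centre = c(azimuth = NA_real_,
                                     elevation = NA_real_),
                          diameter = NA_real_,
                          fwhm = c(azimuth = NA_real_,
                                   elevation = NA_real_),
                          surround = FALSE),
                     class = "rf_profile"))
  }
  peak_sign <- sign(dom$response[which.max(abs(dom$response))])
  polarity <- if ((dom_pol == "light") == (peak_sign > 0)) "ON" else "OFF"
  centre <- c(azimuth = unname(az["mu"]), elevation = unname(el["mu"]))
  fwhm <- c(azimuth = unname(az["fwhm"]), elevation = unname(el["fwhm"]))
  diameter <- mean(fwhm, na.rm = TRUE)
  near_centre <- !is.na(centre[match(dom$axis, names(centre))]) &
    abs(dom$position_deg - centre[match(dom$axis, names(centre))]) <=
      3 * bar_width
  dom_adj <- resp$p_adj[resp$polarity == dom_pol]
  surround <- any(near_centre & dom$response * peak_sign < 0 &
                    !is.na(dom_adj) & dom_adj < alpha)
  structure(list(profiles = resp, detectable = TRUE, polarity = polarity,
                 centre = centre, diameter = diameter, fwhm = fwhm,
                 surround = surround),
            class = "rf_profile")
}

#' Cycle-folded chi-square periodogram at the stimulus frequency
#'
#' Bins the firing of one or more sweeps at `n_bins_per_cycle` bins per
#' stimulus cycle, folds complete cycles into a cycles x bins matrix and
#' quantifies the percentage of rate variance explained by the cycle-mean
#' waveform: `%Var = 100 * Var(cycle-mean waveform) / Var(full series)`
#' (population variances). Significance uses the cycle-folded chi-square
#' statistic `Q = K * N * %Var/100` (K complete cycles, N bins per cycle)
#' against a chi-square distribution with `N - 1` degrees of freedom.
#'
#' @param spike_times numeric vector, or list of vectors (one per sweep),
#'   seconds from sweep start.
#' @param duration sweep duration, s.
#' @param stim_freq stimulus temporal frequency, Hz.
#' @param n_bins_per_cycle bins per cycle.
#' @return list with `pct_var`, `Q`, `df`, `p`, `n_cycles` and the cycle-mean
#'   `waveform` (spikes/s). Constant series are guarded to `%Var = 0`.
#' @export
chi2_periodogram <- function(spike_times, duration, stim_freq,
                             n_bins_per_cycle = 100) {
  if (!is.list(spike_times)) spike_times <- list(spike_times)
  period <- 1 / stim_freq
  cyc_per_sweep <- floor(duration / period + 1e-9)
  if (cyc_per_sweep < 2) stop("fewer than 2 complete stimulus cycles")
  if (cyc_per_sweep * length(spike_times) < 5) {
    warning("fewer than 5 complete stimulus cycles in total")
  }
  N <- n_bins_per_cycle
  K <- cyc_per_sweep * length(spike_times)
  dt <- period / N
  lin <- unlist(lapply(seq_along(spike_times), function(s) {
    tr <- spike_times[[s]]
    tr <- tr[tr >= 0 & tr < cyc_per_sweep * period]
    if (!length(tr)) return(integer(0))
    cyc <- floor(tr / period)
    bin <- pmin(N - 1L, floor((tr - cyc * period) / dt))
    ((s - 1L) * cyc_per_sweep + cyc) * N + bin + 1L
  }))
  counts <- matrix(tabulate(lin, nbins = K * N), nrow = K, ncol = N,
                   byrow = TRUE)
  waveform <- colMeans(counts)
  grand <- mean(counts)
  v_wave <- mean((waveform - grand)^2)
  v_all <- mean((counts - grand)^2)
  pct <- if (v_all == 0) 0 else 100 * v_wave / v_all
  Q <- K * N * pct / 100
  p <- if (v_all == 0) 1 else stats::pchisq(Q, df = N - 1, lower.tail = FALSE)
  list(pct_var = pct, Q = Q, df = N - 1, p = p, n_cycles = K,
       waveform = waveform / dt)
}

# Peak-trough amplitude of the cycle-averaged response waveform (rate), with
# circular 5-point boxcar smoothing as used for direction tuning.
cycle_amplitude <- function(spike_times, duration, stim_freq,
                            n_bins_per_cycle = 100, smooth_pts = 5) {
  w <- chi2_periodogram(spike_times, duration, stim_freq,
                        n_bins_per_cycle)$waveform
  if (smooth_pts > 1) {
    half <- (smooth_pts - 1) %/% 2
    idx <- outer(seq_along(w), -half:half, `+`)
    idx <- (idx - 1L) %% length(w) + 1L
    w <- rowMeans(matrix(w[idx], nrow = length(w)))
  }
  max(w) - min(w)
}

#' Direction and orientation selectivity from 8-direction amplitudes
#'
#' Given peak-trough response amplitudes at the optimal grating for 8 equally
#' spaced directions: the preferred direction is the amplitude argmax (ties
#' toward the smaller angle) and the null its opposite;
#' `DSI = (D_pref - D_null) / (D_pref + D_null)`. Orientations average each
#' opposing direction pair; the preferred orientation is the pair-mean argmax
#' and the null the orthogonal pair, with OSI defined analogously. Cells with
#' an index above `0.33` are labelled direction (or orientation) selective.
#'
#' @param amplitudes 8 non-negative peak-trough amplitudes, spikes/s.
#' @param directions corresponding direction angles, deg (default 0-315 in
#'   45 deg steps).
#' @param threshold DS/OS labelling threshold.
#' @return list with `dsi`, `osi`, `preferred_direction`,
#'   `preferred_orientation` (deg), `d_pref`, `d_null`, and `label`
#'   (`"DS"`, `"OS"`, or `"untuned"`; `DSI` takes precedence). All-zero
#'   amplitudes give `NA` indices and label `"untuned"`.
#' @export
direction_tuning <- function(amplitudes, directions = seq(0, 315, by = 45),
                             threshold = 0.33) {
  stopifnot(length(amplitudes) == 8, length(directions) == 8)
  o <- order(directions)
  directions <- directions[o]; amplitudes <- amplitudes[o]
  if (all(amplitudes == 0)) {
    return(list(dsi = NA_real_, osi = NA_real_,
                preferred_direction = NA_real_,
                preferred_orientation = NA_real_, d_pref = 0, d_null = 0,
                label = "untuned"))
  }
  ip <- which.max(amplitudes)               # first max: smaller angle wins
  inull <- (ip - 1 + 4) %% 8 + 1
  d_pref <- amplitudes[ip]; d_null <- amplitudes[inull]
  dsi <- (d_pref - d_null) / (d_pref + d_null)
  pair <- (amplitudes[1:4] + amplitudes[5:8]) / 2
  iop <- which.max(pair)
  ioo <- (iop - 1 + 2) %% 4 + 1
  osi <- (pair[iop] - pair[ioo]) / (pair[iop] + pair[ioo])
  label <- if (!is.na(dsi) && dsi > threshold) "DS" else
    if (!is.na(osi) && osi > threshold) "OS" else "untuned"
  list(dsi = dsi, osi = osi,
       preferred_direction = directions[ip],
       preferred_orientation = directions[iop] %% 180,
       d_pref = d_pref, d_null = d_null, label = label)
}

#' Spatiotemporal tuning surface from a drifting-grating battery
#'
#' Runs the chi-square periodogram on every grating stimulus (temporal
#' frequency = speed / spatial period), finds the optimal stimulus as the
#' `%Var` argmax (ties broken toward lower spatial frequency, then lower
#' speed, then smaller direction angle), derives DSI/OSI from the peak-trough
#' amplitudes across the 8 directions at the optimal spatial frequency and
#' speed, and estimates high-frequency cutoffs: the highest temporal
#' frequency (Hz) and highest spatial frequency (cycles/deg) at which `%Var`
#' is at least half its maximum, with linear interpolation in log2 frequency
#' between tested values (boundary values returned when there is no
#' crossing).
#'
#' @param rasters list of [event_raster()]s, one per grating stimulus.
#' @param stimuli aligned data.frame with columns `sf_deg_per_cycle`,
#'   `speed_deg_per_s`, `direction_deg`.
#' @param alpha periodogram significance level.
#' @param n_bins_per_cycle passed to [chi2_periodogram()].
#' @return object of class `grating_tuning`: list with `grid` (stimuli plus
#'   `pct_var`, `p`), `responsive`, `optimal`, `dsi`, `osi`,
#'   `preferred_direction`, `preferred_orientation`, `label`,
#'   `temporal_cutoff` (Hz) and `spatial_cutoff` (cycles/deg).
#' @export
tuning_surface <- function(rasters, stimuli, alpha = 0.05,
                           n_bins_per_cycle = 100) {
  stopifnot(length(rasters) == nrow(stimuli),
            all(c("sf_deg_per_cycle", "speed_deg_per_s", "direction_deg") %in%
                  names(stimuli)))
  grid <- stimuli
  grid$tf_hz <- grid$speed_deg_per_s / grid$sf_deg_per_cycle
  per <- lapply(seq_along(rasters), function(i) {
    r <- rasters[[i]]
    trs <- lapply(r$trials, function(tr) tr[tr >= 0 & tr <= r$stim_duration])
    chi2_periodogram(trs, r$stim_duration, grid$tf_hz[i], n_bins_per_cycle)
  })
  grid$pct_var <- vapply(per, `[[`, 0, "pct_var")
  grid$p <- vapply(per, `[[`, 0, "p")
  # multiplicity control across the battery: a cell is grating responsive
  # when any stimulus survives Benjamini-Hochberg at alpha
  grid$p_adj <- stats::p.adjust(grid$p, method = "BH")
  responsive <- any(grid$p_adj < alpha)
  ord <- order(-grid$pct_var, grid$sf_deg_per_cycle, grid$speed_deg_per_s,
               grid$direction_deg)
  opt <- grid[ord[1], ]
  if (!responsive) {
    return(structure(list(grid = grid, responsive = FALSE, optimal = opt,
                          dsi = NA_real_, osi = NA_real_,
                          preferred_direction = NA_real_,
                          preferred_orientation = NA_real_,
                          label = "unresponsive",
                          temporal_cutoff = NA_real_,
                          spatial_cutoff = NA_real_),
                     class = "grating_tuning"))
  }
  sel <- grid$sf_deg_per_cycle == opt$sf_deg_per_cycle &
    grid$speed_deg_per_s == opt$speed_deg_per_s
  dirs <- grid$direction_deg[sel]
  amps <- vapply(which(sel), function(i) {
    r <- rasters[[i]]
    trs <- lapply(r$trials, function(tr) tr[tr >= 0 & tr <= r$stim_duration])
    cycle_amplitude(trs, r$stim_duration, grid$tf_hz[i], n_bins_per_cycle)
  }, 0)
  dt <- direction_tuning(amps, dirs)
  half <- max(grid$pct_var) / 2
  cutoff <- function(freq, pv) {
    agg <- tapply(pv, freq, max)
    f <- as.numeric(names(agg)); v <- as.numeric(agg)
    o <- order(f); f <- f[o]; v <- v[o]
    above <- which(v >= half)
    if (!length(above)) return(f[1])
    i <- max(above)
    if (i == length(f)) return(f[i])          # no crossing: boundary value
    if (v[i + 1] <= 0) return(f[i])           # no response beyond: no crossing
    # log2-linear interpolation between the bracketing tested frequencies
    x1 <- log2(f[i]); x2 <- log2(f[i + 1])
    2^(x1 + (half - v[i]) * (x2 - x1) / (v[i + 1] - v[i]))
  }
  at_dir <- grid$direction_deg == opt$direction_deg
  tf_sel <- at_dir & grid$sf_deg_per_cycle == opt$sf_deg_per_cycle
  sf_sel <- at_dir & grid$speed_deg_per_s == opt$speed_deg_per_s
  structure(list(
    grid = grid, responsive = TRUE, optimal = opt,
    dsi = dt$dsi, osi = dt$osi,
    preferred_direction = dt$preferred_direction,
    preferred_orientation = dt$preferred_orientation,
    label = dt$label,
    temporal_cutoff = cutoff(grid$tf_hz[tf_sel], grid$pct_var[tf_sel]),
    spatial_cutoff = cutoff(1 / grid$sf_deg_per_cycle[sf_sel],
                            grid$pct_var[sf_sel])),
    class = "grating_tuning")
}

#' Motion selectivity index
#'
#' `(S_motion - S_control) / (S_motion + S_control)` with responses floored
#' at zero, so the index lies in `[-1, 1]` and equals 1 exactly when the
#' control response is 0 (and -1 when the motion response is 0). `NA` when
#' both are 0.
#'
#' @param s_motion,s_control response amplitudes, spikes/s.
#' @return index in `[-1, 1]` or `NA`.
#' @export
msi_index <- function(s_motion, s_control) {
  m <- pmax(0, s_motion); c0 <- pmax(0, s_control)
  ifelse(m + c0 == 0, NA_real_, (m - c0) / (m + c0))
}

# Matched luminance-control for each motion stimulus: an expanding light spot
# and a contracting dark spot brighten the display (control = luminance-up);
# the other two combinations darken it.
motion_control_kind <- function(kind, polarity) {
  up <- (kind == "expand" & polarity == "light") |
    (kind == "contract" & polarity == "dark")
  ifelse(kind %in% c("expand", "contract"),
         ifelse(up, "lum_up", "lum_down"), NA_character_)
}

#' Motion selectivity from looming/receding spot responses
#'
#' Per-stimulus response = the largest 50 ms-binned, baseline-subtracted
#' firing rate within 650 ms of stimulus delivery (baseline: 500 ms
#' pre-stimulus), averaged across trials. A cell is motion selective when its
#' overall best response is to an expanding or contracting spot and exceeds
#' the response to that spot's luminance-matched static control (unpaired
#' t-test across trials at `alpha_motion`). The motion selectivity index is
#' `MSI = (S_motion - S_control)/(S_motion + S_control)` for the best
#' stimulus pair (responses floored at 0 so MSI stays in `[-1, 1]` and equals
#' 1 only when the control response is 0).
#'
#' @param rasters list of [event_raster()]s, one per spot stimulus.
#' @param stimuli aligned data.frame with columns `kind` (`"expand"`,
#'   `"contract"`, `"lum_up"`, `"lum_down"`), `polarity` (`"light"`/`"dark"`)
#'   and `speed_s` (transition duration, s).
#' @param alpha_motion motion-vs-control significance level (0.0065: 0.05
#'   with a conservative multiplicity correction).
#' @param alpha_response significance level for any-response detection.
#' @param window,bin,baseline analysis windows, s.
#' @return object of class `motion_selectivity`: list with `table`
#'   (per-stimulus responses), `s_motion`, `s_control`, `msi`,
#'   `p_vs_control`, and `class` (one of `"approach"`, `"recede"`,
#'   `"approach+recede"`, `"luminance ON"`, `"luminance OFF"`, `"none"`).
#' @export
motion_selectivity <- function(rasters, stimuli, alpha_motion = 0.0065,
                               alpha_response = 0.05, window = 0.65,
                               bin = 0.05, baseline = 0.5) {
  stopifnot(length(rasters) == nrow(stimuli),
            all(c("kind", "polarity", "speed_s") %in% names(stimuli)))
  if (any(vapply(rasters, n_trials, 0L) < 20)) {
    warning("fewer than 20 repeats for some stimuli")
  }
  trial_peaks <- function(r, from, len) {
    base <- window_rates(r, -baseline, 0)
    nb <- floor(len / bin + 1e-9)
    vapply(seq_len(n_trials(r)), function(tr) {
      cts <- vapply(seq_len(nb), function(i)
        sum(r$trials[[tr]] > from + (i - 1) * bin &
              r$trials[[tr]] <= from + i * bin), 0L)
      max(cts / bin - base[tr])
    }, 0)
  }
  peaks <- lapply(rasters, trial_peaks, from = 0, len = window)
  # bias-matched null for response detection: the same peak statistic over an
  # equal-length pre-stimulus window, so a cell with no evoked response is not
  # called responsive merely because a maximum over bins exceeds the mean
  # baseline rate
  det_len <- min(window, baseline)
  det_peaks <- lapply(rasters, trial_peaks, from = 0, len = det_len)
  null_peaks <- lapply(rasters, trial_peaks, from = -det_len, len = det_len)
  tab <- stimuli
  tab$response <- vapply(peaks, mean, 0)
  tab$p_any <- vapply(seq_along(peaks), function(i) {
    d <- det_peaks[[i]] - null_peaks[[i]]
    p <- safe_t_p(d)
    if (!is.na(p) && mean(d) <= 0) p <- 1
    p
  }, 0)
  tab$control_kind <- motion_control_kind(tab$kind, tab$polarity)
  find_control <- function(i) {
    which(tab$kind == tab$control_kind[i] & tab$polarity == tab$polarity[i] &
            tab$speed_s == tab$speed_s[i])
  }
  is_motion <- tab$kind %in% c("expand", "contract")
  if (any(is_motion & vapply(seq_len(nrow(tab)), function(i)
    is_motion[i] && length(find_control(i)) == 0, TRUE))) {
    stop("missing luminance-matched control for a motion stimulus")
  }
  best <- which.max(tab$response)
  # best stimulus / counterpart pair for the MSI
  if (is_motion[best]) {
    ic <- find_control(best)[1]
    s_m <- tab$response[best]; s_c <- tab$response[ic]
    pk_m <- peaks[[best]]; pk_c <- peaks[[ic]]
  } else {
    # best is a control: counterpart motion stimulus of the same polarity
    cand <- which(is_motion & tab$polarity == tab$polarity[best] &
                    tab$speed_s == tab$speed_s[best] &
                    motion_control_kind(tab$kind, tab$polarity) ==
                      tab$kind[best])
    ic <- if (length(cand)) cand[which.max(tab$response[cand])] else NA
    s_m <- if (is.na(ic)) 0 else tab$response[ic]
    s_c <- tab$response[best]
    pk_m <- if (is.na(ic)) 0 else peaks[[ic]]
    pk_c <- peaks[[best]]
  }
  msi <- msi_index(s_m, s_c)
  p_vs <- tryCatch(stats::t.test(pk_m, pk_c)$p.value, error = function(e)
    NA_real_)
  motion_sel <- is_motion[best] && !is.na(p_vs) && p_vs < alpha_motion &&
    s_m > s_c
  cls <- "none"
  if (motion_sel) {
    passes <- function(knd) {
      ii <- which(tab$kind == knd)
      if (!length(ii)) return(FALSE)
      ib <- ii[which.max(tab$response[ii])]
      ctl <- find_control(ib)[1]
      p <- tryCatch(stats::t.test(peaks[[ib]], peaks[[ctl]])$p.value,
                    error = function(e) NA_real_)
      !is.na(p) && p < alpha_motion && tab$response[ib] > tab$response[ctl]
    }
    app <- passes("expand"); rec <- passes("contract")
    cls <- if (app && rec) "approach+recede" else if (app) "approach" else
      if (rec) "recede" else
        if (tab$kind[best] == "expand") "approach" else "recede"
  } else if (any(!is.na(tab$p_any) &
                   stats::p.adjust(tab$p_any, "BH") < alpha_response)) {
    lum_dir <- if (tab$kind[best] %in% c("lum_up", "lum_down")) {
      tab$kind[best]
    } else {
      motion_control_kind(tab$kind[best], tab$polarity[best])
    }
    cls <- if (identical(lum_dir, "lum_up")) "luminance ON" else
      "luminance OFF"
  }
  structure(list(table = tab, s_motion = s_m, s_control = s_c, msi = msi,
                 p_vs_control = p_vs, class = cls),
            class = "motion_selectivity")
}

#' Assign a cell to one of the six functional groups
#'
#' Precedence: direction-tuned (Group V: grating DSI > 0.33) first, then
#' complex-motion selective (Group VI: selective approach/recede responses),
#' then full-field classes by response to light steps (Group I sustained;
#' Groups II/III ON- vs OFF-biased transient, by the larger of the absolute
#' ON and OFF peaks), then spatial-contrast selective (Group IV: no
#' full-field response but a detectable bar, grating or spot response), else
#' unresponsive. Components that were not tested may be passed as `NULL`.
#'
#' @param response list from [test_light_responsive()] plus `kind` from
#'   [classify_sustained_transient()] (or `kind = "none"`).
#' @param step list from [quantify_step_response()] (needed to split Groups
#'   II/III), or `NULL`.
#' @param grating a `grating_tuning` or `NULL`.
#' @param motion a `motion_selectivity` or `NULL`.
#' @param rf an `rf_profile` or `NULL`.
#' @param dsi_threshold Group V threshold.
#' @return list with `group` (`"I"` ... `"VI"` or `"unresponsive"`) and
#'   `provenance` (which rule fired).
#' @export
assign_functional_group <- function(response, step = NULL, grating = NULL,
                                    motion = NULL, rf = NULL,
                                    dsi_threshold = 0.33) {
  if (!is.null(response$kind) && response$kind != "none" &&
      !isTRUE(response$responsive)) {
    stop("contradictory inputs: kind = ", response$kind,
         " but responsive = FALSE")
  }
  if (!is.null(grating) && isTRUE(grating$responsive) &&
      !is.na(grating$dsi) && grating$dsi > dsi_threshold) {
    return(list(group = "V", provenance = "grating DSI > threshold"))
  }
  if (!is.null(motion) &&
      motion$class %in% c("approach", "recede", "approach+recede")) {
    return(list(group = "VI", provenance = paste0("motion-selective (",
                                                  motion$class, ")")))
  }
  if (isTRUE(response$responsive)) {
    if (identical(response$kind, "sustained")) {
      return(list(group = "I", provenance = "sustained full-field response"))
    }
    if (is.null(step)) {
      stop("step measures required to split ON/OFF-biased transient groups")
    }
    off <- if (is.na(step$off_peak)) 0 else abs(step$off_peak)
    if (abs(step$on_peak) >= off) {
      return(list(group = "II", provenance = "ON-biased transient"))
    }
    return(list(group = "III", provenance = "OFF-biased transient"))
  }
  any_spatial <- (!is.null(rf) && isTRUE(rf$detectable)) ||
    (!is.null(grating) && isTRUE(grating$responsive)) ||
    (!is.null(motion) && motion$class != "none")
  if (any_spatial) {
    return(list(group = "IV",
                provenance = "no full-field response but spatial response"))
  }
  list(group = "unresponsive", provenance = "no response to any stimulus")
}
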