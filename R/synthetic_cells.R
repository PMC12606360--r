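# Ground-truth-labelled synthetic spiking data: inhomogeneous-Poisson cells
# of the six functional classes under the recording protocols.

#' Inhomogeneous Poisson spike train by thinning
#'
#' Candidate spikes are drawn from a homogeneous Poisson process at the rate
#' upper bound and kept with probability `rate(t)/rmax`, with the rate
#' evaluated at 1 ms resolution.
#'
#' @param rate_fn vectorised rate function of time, spikes/s.
#' @param duration s.
#' @param rmax upper bound on the rate over `[0, duration]`.
#' @param res evaluation resolution, s.
#' @return sorted spike times in `[0, duration)`.
#' @export
poisson_train <- function(rate_fn, duration, rmax, res = 0.001) {
  n <- stats::rpois(1, rmax * duration)
  if (n == 0) return(numeric(0))
  tt <- sort(stats::runif(n, 0, duration))
  tsnap <- (floor(tt / res) + 0.5) * res
  keep <- stats::runif(n) < rate_fn(tsnap) / rmax
  tt[keep]
}

gen_raster <- function(rate_fn, pre, dur, post, n_trials, rmax,
                       condition = NA_character_, unit_id = NA_character_) {
  trials <- lapply(seq_len(n_trials), function(i) {
    poisson_train(function(t) rate_fn(t - pre), pre + dur + post, rmax) - pre
  })
  event_raster(trials, pre_window = pre, stim_duration = dur,
               post_window = post, unit_id = unit_id, condition = condition)
}

#' Parameter specification for one synthetic cell
#'
#' Encodes the defining response structure of the six functional classes:
#' sustained tonic elevation (with a melanopsin-dependent slow component) for
#' Group I; ON/OFF transients for Groups II/III; spatial responses without
#' net full-field drive for Group IV; cosine direction tuning hitting a DSI
#' target for Group V; a looming-kernel drive for Group VI.
#'
#' @param group `"I"`..`"VI"`.
#' @param baseline spikes/s.
#' @param step_sustained,step_on_transient,step_off_transient step-response
#'   gains, spikes/s.
#' @param transience_tau transient decay time constant, s.
#' @param mel_gain extra slow tonic gain under the melanopsin-high stimulus.
#' @param mel_tau melanopsin component time constant, s.
#' @param cone_w_L,cone_w_S signed cone weights in `[-1, 1]`.
#' @param rf_centre (azimuth, elevation) deg; `rf_sigma` deg; `rf_gain`
#'   spikes/s; `rf_polarity` `"light"`/`"dark"`.
#' @param grating_amp grating modulation amplitude, spikes/s.
#' @param pref_direction deg; `dsi_target` in `[0, 1]`.
#' @param loom_gain spikes/s; `loom_polarity` spot polarity driving the cell.
#' @param lum_gain luminance (full-field/spot control) transient gain.
#' @param lum_sign +1 for ON, -1 for OFF.
#' @return list of class `cell_spec`.
#' @export
cell_spec <- function(group, baseline = 5, step_sustained = 0,
                      step_on_transient = 0, step_off_transient = 0,
                      transience_tau = 0.3, mel_gain = 0, mel_tau = 2,
                      cone_w_L = 0, cone_w_S = 0,
                      rf_centre = c(0, 0), rf_sigma = 3, rf_gain = 0,
                      rf_polarity = "light",
                      grating_amp = 0, pref_direction = 0, dsi_target = 0,
                      loom_gain = 0, loom_polarity = "dark",
                      lum_gain = 0, lum_sign = 1) {
  if (dsi_target < 0 || dsi_target > 1) {
    stop("DSI target ", dsi_target, " unreachable with the cosine tuning ",
         "kernel; the feasible range is [0, 1]")
  }
  structure(as.list(environment()), class = "cell_spec")
}

#' Default labelled population: 40 cells per functional group
#'
#' The 240-cell population used throughout the tests: baseline 5 spikes/s,
#' sustained steps to 30 spikes/s (Group I, with a melanopsin-dependent
#' tonic component), ON/OFF transients peaking near 50 spikes/s (II/III),
#' spatial-contrast cells with no net full-field drive (IV), cosine-tuned
#' direction-selective cells at DSI 0.6 (V) and looming-selective cells (VI).
#'
#' @param n_per_group cells per group.
#' @return list of [cell_spec()]s with names `cell_001` ...
#' @export
default_population_specs <- function(n_per_group = 40) {
  proto <- list(
    I = cell_spec("I", step_sustained = 25, step_on_transient = 10,
                  mel_gain = 10, cone_w_L = 0.6, cone_w_S = 0.2,
                  grating_amp = 10, lum_gain = 20, lum_sign = 1),
    II = cell_spec("II", step_on_transient = 45, step_off_transient = 10,
                   cone_w_L = 0.5, cone_w_S = -0.3, grating_amp = 10,
                   lum_gain = 25, lum_sign = 1),
    III = cell_spec("III", step_on_transient = 10, step_off_transient = 45,
                    cone_w_L = -0.5, cone_w_S = -0.2, grating_amp = 10,
                    lum_gain = 25, lum_sign = -1),
    IV = cell_spec("IV", grating_amp = 20, rf_gain = 20),
    V = cell_spec("V", step_on_transient = 20, grating_amp = 20,
                  dsi_target = 0.6, pref_direction = 180),
    VI = cell_spec("VI", loom_gain = 30))
  specs <- list()
  dirs <- seq(0, 315, by = 45)
  for (g in names(proto)) {
    for (i in seq_len(n_per_group)) {
      sp <- proto[[g]]
      if (g == "V") sp$pref_direction <- dirs[(i - 1) %% 8 + 1]
      sp$rf_centre <- c(((i * 7) %% 21) - 10, ((i * 5) %% 21) - 10)
      specs[[length(specs) + 1L]] <- sp
    }
  }
  names(specs) <- sprintf("cell_%03d", seq_along(specs))
  specs
}

#' Recording-session protocol specification
#'
#' Which stimulus elements to simulate and at what size. Defaults follow the
#' recording protocols: 2 s full-field steps, 10 s melanopsin-high/low
#' steps, 0.25 Hz cone-isolating square waves, flashing bars (~7 deg, 0.25 s)
#' over a contiguous position grid, the 5 spatial frequency x 5 speed x 8
#' direction drifting-grating battery (8-64 deg/cycle, 30-240 deg/s), and
#' expanding/contracting 2-60 deg spots with luminance-matched controls at
#' 0.5 and 0.1 s transition times.
#'
#' @param elements subset of
#'   `c("step", "mel_steps", "cone_waves", "bars", "gratings", "spots")`.
#' @param step_trials,step_duration full-field step protocol.
#' @param grating_trials repeats per grating stimulus.
#' @param grating_cycles complete stimulus cycles per grating trial.
#' @param spot_trials repeats per spot stimulus.
#' @param bar_trials repeats per bar condition.
#' @param bar_positions position grid, deg (used for both axes).
#' @param cone_trials,cone_cycles cone square-wave protocol (cycles per
#'   trial at 0.25 Hz).
#' @return list of class `session_spec`.
#' @export
session_spec <- function(elements = c("step", "gratings", "spots"),
                         step_trials = 10, step_duration = 2,
                         grating_trials = 4, grating_cycles = 8,
                         spot_trials = 20, bar_trials = 8,
                         bar_positions = seq(-31, 31, by = 1),
                         cone_trials = 2, cone_cycles = 5) {
  sf <- c(8, 16, 32, 48, 64)
  speed <- c(30, 60, 120, 180, 240)
  dirs <- seq(0, 315, by = 45)
  gratings <- expand.grid(sf_deg_per_cycle = sf, speed_deg_per_s = speed,
                          direction_deg = dirs)
  spots <- expand.grid(kind = c("expand", "contract", "lum_up", "lum_down"),
                       polarity = c("light", "dark"), speed_s = c(0.5, 0.1),
                       stringsAsFactors = FALSE)
  structure(list(elements = elements, step_trials = step_trials,
                 step_duration = step_duration,
                 grating_trials = grating_trials,
                 grating_cycles = grating_cycles, gratings = gratings,
                 spot_trials = spot_trials, spots = spots,
                 bar_trials = bar_trials, bar_positions = bar_positions,
                 bar_width = 7, bar_duration = 0.25,
                 cone_trials = cone_trials, cone_cycles = cone_cycles,
                 cone_freq = 0.25),
            class = "session_spec")
}

#' Simulate a labelled population of synthetic cells
#'
#' Generates inhomogeneous-Poisson spike rasters for every cell under every
#' element of the session protocol, together with a ground-truth label
#' table. Identical seeds give identical output.
#'
#' @param specs list of [cell_spec()]s (named).
#' @param session a [session_spec()].
#' @param seed integer seed.
#' @param out_dir optional directory: writes `truth.csv` (the ground-truth
#'   sidecar) and per-cell spike CSVs.
#' @return list with `cells` (per cell: rasters per protocol element) and
#'   `truth` (data.frame of cell ids, groups and generative parameters).
#' @export
simulate_cell_population <- function(specs, session = session_spec(),
                                     seed = 20251111, out_dir = NULL) {
  set.seed(seed)
  if (is.null(names(specs))) {
    names(specs) <- sprintf("cell_%03d", seq_along(specs))
  }
  cells <- list()
  for (id in names(specs)) {
    sp <- specs[[id]]
    cell <- list(spec = sp)
    if ("step" %in% session$elements) {
      cell$step <- sim_step_raster(sp, session$step_trials,
                                   session$step_duration, mel = "high",
                                   unit_id = id)
    }
    if ("mel_steps" %in% session$elements) {
      cell$mel_high <- sim_step_raster(sp, session$step_trials, 10,
                                       mel = "high", unit_id = id)
      cell$mel_low <- sim_step_raster(sp, session$step_trials, 10,
                                      mel = "low", unit_id = id)
    }
    if ("cone_waves" %in% session$elements) {
      cell$cone <- sim_cone_rasters(sp, session, unit_id = id)
    }
    if ("bars" %in% session$elements) {
      cell$bars <- sim_bar_rasters(sp, session, unit_id = id)
    }
    if ("gratings" %in% session$elements) {
      cell$gratings <- sim_grating_rasters(sp, session, unit_id = id)
    }
    if ("spots" %in% session$elements) {
      cell$spots <- sim_spot_rasters(sp, session, unit_id = id)
    }
    cells[[id]] <- cell
  }
  truth <- do.call(rbind, lapply(names(specs), function(id) {
    sp <- specs[[id]]
    data.frame(cell = id, group = sp$group, baseline = sp$baseline,
               dsi_target = sp$dsi_target,
               pref_direction = sp$pref_direction,
               rf_azimuth = sp$rf_centre[1], rf_elevation = sp$rf_centre[2],
               rf_sigma = sp$rf_sigma)
  }))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(truth, file.path(out_dir, "truth.csv"),
                     row.names = FALSE)
  }
  list(cells = cells, truth = truth)
}

sim_step_raster <- function(sp, n_trials, dur, mel = "high", pre = 2,
                            post = 1, unit_id = NA_character_) {
  mel_on <- (mel == "high") * sp$mel_gain
  rate_fn <- function(t) {
    on <- as.numeric(t > 0 & t <= dur)
    off <- as.numeric(t > dur)
    pmax(0, sp$baseline +
           on * (sp$step_sustained +
                   sp$step_on_transient * exp(-t / sp$transience_tau) +
                   mel_on * (1 - exp(-t / sp$mel_tau))) +
           off * sp$step_off_transient *
             exp(-(t - dur) / sp$transience_tau))
  }
  rmax <- sp$baseline + sp$step_sustained + sp$step_on_transient +
    sp$step_off_transient + sp$mel_gain + 1
  gen_raster(rate_fn, pre, dur, post, n_trials, rmax,
             condition = paste0("step_mel_", mel), unit_id = unit_id)
}

sim_cone_rasters <- function(sp, session, unit_id = NA_character_) {
  period <- 1 / session$cone_freq
  dur <- session$cone_cycles * period
  stim_w <- list(S_only = c(L = 0, S = 1), L_only = c(L = 1, S = 0),
                 L_plus_S = c(L = 1, S = 1), L_minus_S = c(L = 1, S = -1))
  out <- lapply(names(stim_w), function(nm) {
    w <- stim_w[[nm]]
    drive <- sp$cone_w_L * w["L"] + sp$cone_w_S * w["S"]
    rate_fn <- function(t) {
      phase <- ((t %% period) < period / 2)
      sq <- ifelse(t < 0 | t >= dur, 0, ifelse(phase, 1, -1))
      pmax(0, sp$baseline * (1 + drive * sq))
    }
    gen_raster(rate_fn, pre = 0, dur = dur, post = 0.01,
               n_trials = session$cone_trials,
               rmax = sp$baseline * 2 + 1, condition = nm, unit_id = unit_id)
  })
  names(out) <- names(stim_w)
  out
}

sim_bar_rasters <- function(sp, session, unit_id = NA_character_) {
  stimuli <- expand.grid(position_deg = session$bar_positions,
                         axis = c("azimuth", "elevation"),
                         polarity = c("light", "dark"),
                         stringsAsFactors = FALSE)
  rasters <- lapply(seq_len(nrow(stimuli)), function(i) {
    st <- stimuli[i, ]
    centre <- if (st$axis == "azimuth") sp$rf_centre[1] else sp$rf_centre[2]
    amp <- if (st$polarity == sp$rf_polarity) {
      sp$rf_gain * exp(-(st$position_deg - centre)^2 / (2 * sp$rf_sigma^2))
    } else 0
    rate_fn <- function(t) {
      pmax(0, sp$baseline + amp * (t > 0 & t <= session$bar_duration))
    }
    gen_raster(rate_fn, pre = 0.25, dur = session$bar_duration, post = 0.25,
               n_trials = session$bar_trials,
               rmax = sp$baseline + abs(sp$rf_gain) + 1,
               condition = sprintf("bar_%s_%s_%g", st$axis, st$polarity,
                                   st$position_deg),
               unit_id = unit_id)
  })
  list(rasters = rasters, stimuli = stimuli)
}

sim_grating_rasters <- function(sp, session, unit_id = NA_character_) {
  g <- session$gratings
  k <- sp$dsi_target
  rasters <- lapply(seq_len(nrow(g)), function(i) {
    tf <- g$speed_deg_per_s[i] / g$sf_deg_per_cycle[i]
    dur <- session$grating_cycles / tf
    amp <- if (sp$grating_amp == 0) 0 else {
      dthe <- (g$direction_deg[i] - sp$pref_direction) * pi / 180
      sp$grating_amp * (1 + k * cos(dthe)) / (1 + k)
    }
    rate_fn <- function(t) {
      pmax(0, sp$baseline + amp * (1 + sin(2 * pi * tf * t)) / 2 *
             (t > 0 & t <= dur))
    }
    gen_raster(rate_fn, pre = 0, dur = dur, post = 0.01,
               n_trials = session$grating_trials,
               rmax = sp$baseline + abs(sp$grating_amp) + 1,
               condition = sprintf("grating_%g_%g_%g", g$sf_deg_per_cycle[i],
                                   g$speed_deg_per_s[i], g$direction_deg[i]),
               unit_id = unit_id)
  })
  list(rasters = rasters, stimuli = g)
}

sim_spot_rasters <- function(sp, session, unit_id = NA_character_) {
  st <- session$spots
  rasters <- lapply(seq_len(nrow(st)), function(i) {
    kind <- st$kind[i]; pol <- st$polarity[i]; sp_s <- st$speed_s[i]
    # looming drive: transient peaking at the end of the size transition
    loom_amp <- if (kind == "expand" && pol == sp$loom_polarity)
      sp$loom_gain else 0
    # luminance drive: transient whenever display luminance changes in the
    # preferred direction (controls included, matched). A light spot
    # brightens the display as it expands; a dark spot brightens as it
    # contracts; lum_up/lum_down controls change luminance directly.
    brighten <- kind == "lum_up" ||
      (kind == "expand" && pol == "light") ||
      (kind == "contract" && pol == "dark")
    lum_amp <- if ((brighten && sp$lum_sign > 0) ||
                   (!brighten && sp$lum_sign < 0)) sp$lum_gain else 0
    rate_fn <- function(t) {
      drive <- loom_amp * exp(-(t - sp_s)^2 / (2 * 0.05^2)) +
        lum_amp * exp(-pmax(0, t) / sp$transience_tau) * (t > 0)
      pmax(0, sp$baseline + drive * (t > 0))
    }
    gen_raster(rate_fn, pre = 0.5, dur = max(sp_s, 0.65), post = 0.2,
               n_trials = session$spot_trials,
               rmax = sp$baseline + abs(sp$loom_gain) + abs(sp$lum_gain) + 1,
               condition = sprintf("spot_%s_%s_%g", kind, pol, sp_s),
               unit_id = unit_id)
  })
  list(rasters = rasters, stimuli = st)
}

#' Run the full classification battery on one simulated cell
#'
#' Applies the pipeline end to end: full-field responsiveness and
#' sustained/transient classification, step measures, grating tuning, motion
#' selectivity and RF mapping (whichever elements the session produced), and
#' the functional-group assignment.
#'
#' @param cell one element of `simulate_cell_population()$cells` (or any
#'   list with the same raster fields).
#' @return list with `response`, `kind`, `step`, `grating`, `motion`, `rf`
#'   and `group`.
#' @export
classify_cell_battery <- function(cell) {
  lr <- test_light_responsive(cell$step)
  kind <- if (lr$responsive) {
    classify_sustained_transient(cell$step)$kind
  } else "none"
  response <- c(lr, list(kind = kind))
  step <- quantify_step_response(cell$step)
  grating <- if (!is.null(cell$gratings)) {
    tuning_surface(cell$gratings$rasters, cell$gratings$stimuli)
  }
  motion <- if (!is.null(cell$spots)) {
    motion_selectivity(cell$spots$rasters, cell$spots$stimuli)
  }
  rf <- if (!is.null(cell$bars)) {
    map_receptive_field(cell$bars$rasters, cell$bars$stimuli)
  }
  grp <- assign_functional_group(response, step = step, grating = grating,
                                 motion = motion, rf = rf)
  list(response = response, step = step, grating = grating, motion = motion,
       rf = rf, group = grp$group, provenance = grp$provenance)
}
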