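# Quantification of light stimuli in photoreceptor-effective units and design
# of opsin-isoluminant stimulus pairs.

#' Default peak wavelengths for mouse opsins (human L-opsin knock-in line)
#'
#' Peak sensitivities (nm) for the photopigments relevant to recordings in the
#' red-cone knock-in mouse: rod opsin, S-cone opsin, the human L-cone opsin
#' replacing mouse M-opsin, and melanopsin. Values are configuration, not
#' hard-coded into any computation, and can be overridden wherever an opsin
#' template is built.
#'
#' @return named numeric vector of lambda_max values in nm.
#' @export
#' @examples
#' default_lambda_max()
default_lambda_max <- function() {
  c(rod = 498, S = 365, L = 556, melanopsin = 480)
}

#' Build an opsin spectral-sensitivity template
#'
#' Constructs a relative spectral sensitivity curve (peak normalised to 1) on
#' a wavelength grid, either from the standard vitamin-A1 visual pigment
#' nomogram (Govardovskii-style alpha + beta band) or from a pure Gaussian
#' approximation. An optional prereceptoral transmission curve (e.g. lens
#' filtering) can be attached; it defaults to identity.
#'
#' @param lambda_max peak wavelength, nm; must lie within `grid`.
#' @param grid strictly increasing wavelength grid, nm.
#' @param form `"a1"` (default) for the A1 nomogram or `"gaussian"`.
#' @param beta_band include the A1 beta band (short-wavelength shoulder);
#'   `FALSE` gives a strictly unimodal alpha-band template.
#' @param gaussian_sd standard deviation (nm) of the Gaussian form.
#' @param prereceptoral_filter transmission in `[0, 1]` on the same grid, or
#'   `NULL` for identity.
#' @param name text label.
#' @return an object of class `opsin_template` with fields `name`,
#'   `lambda_max`, `wavelength`, `sensitivity`, `prereceptoral_filter`.
#' @export
#' @examples
#' tpl <- opsin_nomogram(500, seq(300, 700, by = 1))
#' tpl$sensitivity[tpl$wavelength == 500]  # 1 at the peak
opsin_nomogram <- function(lambda_max, grid, form = c("a1", "gaussian"),
                           beta_band = TRUE, gaussian_sd = 40,
                           prereceptoral_filter = NULL,
                           name = paste0("opsin_", lambda_max)) {
  form <- match.arg(form)
  if (any(diff(grid) <= 0)) stop("wavelength grid must be strictly increasing")
  if (lambda_max < min(grid) || lambda_max > max(grid)) {
    stop("lambda_max (", lambda_max, " nm) lies outside the wavelength grid [",
         min(grid), ", ", max(grid), "] nm")
  }
  sens <- switch(form,
    a1 = govardovskii_a1(grid, lambda_max, beta_band),
    gaussian = exp(-(grid - lambda_max)^2 / (2 * gaussian_sd^2))
  )
  sens <- sens / max(sens)
  if (is.null(prereceptoral_filter)) {
    prereceptoral_filter <- rep(1, length(grid))
  } else {
    stopifnot(length(prereceptoral_filter) == length(grid),
              all(prereceptoral_filter >= 0 & prereceptoral_filter <= 1))
  }
  structure(list(name = name, lambda_max = lambda_max, wavelength = grid,
                 sensitivity = sens,
                 prereceptoral_filter = prereceptoral_filter),
            class = "opsin_template")
}

# Vitamin-A1 pigment template (alpha band plus beta band), x = lambda_max/lambda.
# Standard constants: A = 69.7, B = 28, C = -14.9, D = 0.674, b = 0.922,
# c = 1.104, a = 0.8795 + 0.0459 exp(-(lambda_max - 300)^2 / 11940);
# beta band: A_b = 0.26, lm_b = 189 + 0.315 lambda_max,
# b_b = -40.5 + 0.195 lambda_max.
govardovskii_a1 <- function(lambda, lambda_max, beta_band = TRUE) {
  x <- lambda_max / lambda
  a <- 0.8795 + 0.0459 * exp(-(lambda_max - 300)^2 / 11940)
  alpha <- 1 / (exp(69.7 * (a - x)) + exp(28 * (0.922 - x)) +
                  exp(-14.9 * (1.104 - x)) + 0.674)
  if (!beta_band) return(alpha)
  lm_b <- 189 + 0.315 * lambda_max
  b_b <- -40.5 + 0.195 * lambda_max
  alpha + 0.26 * exp(-((lambda - lm_b) / b_b)^2)
}

#' Construct a light spectrum
#'
#' A spectral power distribution in photon units. A single-wavelength input is
#' treated as a monochromatic line whose `photon_flux_density` is the total
#' photon flux (photons/cm^2/s) rather than a density.
#'
#' @param wavelength nm grid (strictly increasing) or a single wavelength.
#' @param photon_flux_density photons/cm^2/s/nm per grid point (or total
#'   photons/cm^2/s for a monochromatic line).
#' @return object of class `light_spectrum`.
#' @export
light_spectrum <- function(wavelength, photon_flux_density) {
  stopifnot(length(wavelength) == length(photon_flux_density),
            all(photon_flux_density >= 0))
  if (length(wavelength) > 1 && any(diff(wavelength) <= 0)) {
    stop("wavelength grid must be strictly increasing")
  }
  structure(list(wavelength = wavelength,
                 photon_flux_density = photon_flux_density,
                 monochromatic = length(wavelength) == 1L),
            class = "light_spectrum")
}

#' Read a spectrum from a two-column CSV
#'
#' Expects columns `wavelength_nm` and `photon_flux_density`.
#' @param path CSV file.
#' @return a [light_spectrum()].
#' @export
read_spectrum_csv <- function(path) {
  d <- utils::read.csv(path)
  stopifnot(all(c("wavelength_nm", "photon_flux_density") %in% names(d)))
  light_spectrum(d$wavelength_nm, d$photon_flux_density)
}

#' Effective photon flux of a spectrum for an opsin
#'
#' Integrates spectrum x prereceptoral transmission x relative sensitivity by
#' trapezoidal quadrature on the spectrum's native grid; the opsin template is
#' resampled onto that grid by linear interpolation (zero outside its
#' support). Monochromatic lines are evaluated directly.
#'
#' @param spectrum a [light_spectrum()].
#' @param opsin an [opsin_nomogram()] template.
#' @return effective photon flux, photons/cm^2/s (non-negative). Disjoint
#'   wavelength supports return 0 with a warning.
#' @export
effective_photon_flux <- function(spectrum, opsin) {
  stopifnot(inherits(spectrum, "light_spectrum"),
            inherits(opsin, "opsin_template"))
  weight <- function(wl) {
    s <- stats::approx(opsin$wavelength, opsin$sensitivity, xout = wl,
                       yleft = 0, yright = 0)$y
    f <- stats::approx(opsin$wavelength, opsin$prereceptoral_filter, xout = wl,
                       yleft = 0, yright = 0)$y
    s * f
  }
  if (spectrum$monochromatic) {
    return(spectrum$photon_flux_density * weight(spectrum$wavelength))
  }
  if (max(spectrum$wavelength) < min(opsin$wavelength) ||
      min(spectrum$wavelength) > max(opsin$wavelength)) {
    warning("spectrum and opsin template have disjoint wavelength supports")
    return(0)
  }
  y <- spectrum$photon_flux_density * weight(spectrum$wavelength)
  pracma::trapz(spectrum$wavelength, y)
}

#' Effective fluxes of a spectrum for a set of opsins
#'
#' @param spectrum a [light_spectrum()].
#' @param opsins list of opsin templates (named, or names taken from the
#'   templates).
#' @return data.frame with columns `opsin`, `effective_flux`, `log10_flux`.
#' @export
effective_flux_set <- function(spectrum, opsins) {
  nm <- names(opsins) %||% vapply(opsins, `[[`, "", "name")
  flux <- vapply(opsins, function(o) effective_photon_flux(spectrum, o), 0)
  data.frame(opsin = nm, effective_flux = flux,
             log10_flux = ifelse(flux > 0, log10(flux), -Inf),
             row.names = NULL)
}

#' Design a pair of opsin-isoluminant multi-LED stimuli
#'
#' Finds two non-negative LED weight vectors (each weight in `[0, 1]`, i.e. a
#' fraction of the LED's full output) whose summed spectra have equal
#' effective flux for every opsin in `match_opsins` while maximising Michelson
#' contrast for `contrast_opsin`. This is the construction behind
#' cone-isoluminant stimulus pairs that differ in melanopsin excitation
#' ("melanopsin high" vs "melanopsin low").
#'
#' With `length(led_spectra) == length(match_opsins) + 1` the solution space
#' for a fixed matched-flux target is one dimensional and the extremes of the
#' contrast opsin's flux along it are found exactly; larger LED sets are
#' solved by penalised numerical optimisation. The matched-flux target is the
#' flux produced by running every LED at half power (deterministic; Michelson
#' contrast is invariant to the scale of the target).
#'
#' @param led_spectra list of [light_spectrum()], one per LED.
#' @param match_opsins list of opsin templates whose effective flux must be
#'   equal between the two stimuli (relative error < 1e-6).
#' @param contrast_opsin opsin template whose Michelson contrast is maximised.
#' @return list with `weights_high`, `weights_low`, `matched_flux`,
#'   `contrast_flux` (length-2, high/low), `michelson`, and `flux_table`
#'   (per-opsin effective fluxes of both stimuli).
#' @export
design_isoluminant_pair <- function(led_spectra, match_opsins, contrast_opsin) {
  n_led <- length(led_spectra)
  m <- length(match_opsins)
  if (n_led < m + 1) stop("need at least one more LED than matched opsins")
  # effective flux per unit weight: rows = opsins (matched then contrast)
  M <- vapply(led_spectra, function(sp) {
    vapply(match_opsins, function(o) effective_photon_flux(sp, o), 0)
  }, numeric(m))
  M <- matrix(M, nrow = m)
  cvec <- vapply(led_spectra, function(sp)
    effective_photon_flux(sp, contrast_opsin), 0)
  qrM <- qr(t(M))
  if (qrM$rank < m) {
    dep <- which(abs(diag(qr.R(qr(M)))) < 1e-12 * max(abs(M)))
    stop("matching constraints are rank deficient; opsin constraint(s) ",
         paste(dep, collapse = ", "), " depend on the others")
  }
  w0 <- rep(0.5, n_led)
  target <- drop(M %*% w0)
  if (n_led == m + 1) {
    v <- qr.Q(qrM, complete = TRUE)[, n_led]       # null space of M, 1-D
    cv <- sum(cvec * v)
    # admissible t keeping w0 + t v within [0, 1]^n
    tmax <- tmin <- c(0, 0)
    up <- ifelse(v > 0, (1 - w0) / v, ifelse(v < 0, (0 - w0) / v, Inf))
    lo <- ifelse(v > 0, (0 - w0) / v, ifelse(v < 0, (1 - w0) / v, -Inf))
    thi <- min(up); tlo <- max(lo)
    w_a <- w0 + thi * v
    w_b <- w0 + tlo * v
    if (sum(cvec * w_a) >= sum(cvec * w_b)) {
      w_high <- w_a; w_low <- w_b
    } else {
      w_high <- w_b; w_low <- w_a
    }
  } else {
    obj <- function(par) {
      w1 <- stats::plogis(par[seq_len(n_led)])
      w2 <- stats::plogis(par[n_led + seq_len(n_led)])
      c1 <- sum(cvec * w1); c2 <- sum(cvec * w2)
      mich <- (c1 - c2) / (c1 + c2 + 1e-300)
      pen <- sum((drop(M %*% w1) / target - 1)^2) +
        sum((drop(M %*% w2) / target - 1)^2)
      -mich + 1e6 * pen
    }
    fit <- stats::optim(rep(0, 2 * n_led), obj, method = "BFGS",
                        control = list(maxit = 2000, reltol = 1e-14))
    w_high <- stats::plogis(fit$par[seq_len(n_led)])
    w_low <- stats::plogis(fit$par[n_led + seq_len(n_led)])
  }
  mix <- function(w) {
    wl <- led_spectra[[1]]$wavelength
    dens <- Reduce(`+`, Map(function(sp, wi) {
      stats::approx(sp$wavelength, sp$photon_flux_density, xout = wl,
                    yleft = 0, yright = 0)$y * wi
    }, led_spectra, as.list(w)))
    light_spectrum(wl, dens)
  }
  sp_high <- mix(w_high); sp_low <- mix(w_low)
  all_ops <- c(match_opsins, list(contrast = contrast_opsin))
  tab <- data.frame(
    opsin = c(vapply(match_opsins, `[[`, "", "name"), contrast_opsin$name),
    flux_high = vapply(all_ops, function(o)
      effective_photon_flux(sp_high, o), 0),
    flux_low = vapply(all_ops, function(o)
      effective_photon_flux(sp_low, o), 0))
  mism <- with(tab[seq_len(m), , drop = FALSE],
               abs(flux_high - flux_low) / pmax(flux_high, flux_low))
  if (any(mism > 1e-6)) {
    warning("matched-opsin relative mismatch up to ",
            signif(max(mism), 3))
  }
  ch <- sum(cvec * w_high); cl <- sum(cvec * w_low)
  list(weights_high = w_high, weights_low = w_low,
       matched_flux = target, contrast_flux = c(high = ch, low = cl),
       michelson = (ch - cl) / (ch + cl), flux_table = tab)
}
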