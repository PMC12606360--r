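# Irradiance-response sigmoid fitting and curve comparison.

sigmoid_fun <- function(I, lower, upper, log_ec50, slope) {
  lower + (upper - lower) / (1 + 10^(slope * (log_ec50 - I)))
}

#' Fit a 4-parameter sigmoid irradiance-response curve
#'
#' Least-squares fit of
#' `r(I) = lower + (upper - lower) / (1 + 10^(slope * (log_ec50 - I)))`
#' with irradiance `I` on a log10 photons/cm^2/s scale and a Hill slope, by
#' Levenberg-Marquardt with multi-start initialisation (starting values from
#' data quantiles, 5 starts).
#'
#' @param irradiance log10 photons/cm^2/s, one value per observation
#'   (repeated measures are simply stacked). At least 4 distinct irradiances.
#' @param response spikes/s, same length.
#' @return object of class `sigmoid_fit`: list with `lower`, `upper`,
#'   `log_ec50`, `slope`, `residual_ss`, `converged`, `n`, and the data.
#' @export
fit_sigmoid <- function(irradiance, response) {
  stopifnot(length(irradiance) == length(response))
  ok <- is.finite(irradiance) & is.finite(response)
  irradiance <- irradiance[ok]; response <- response[ok]
  if (length(unique(irradiance)) < 4) {
    stop("need at least 4 distinct irradiances")
  }
  qs <- stats::quantile(irradiance, c(0.25, 0.4, 0.5, 0.6, 0.75),
                        names = FALSE)
  lo0 <- stats::quantile(response, 0.05, names = FALSE)
  up0 <- stats::quantile(response, 0.95, names = FALSE)
  starts <- Map(function(ec, sl) c(lower = lo0, upper = up0, log_ec50 = ec,
                                   slope = sl),
                qs, c(1, 0.5, 1, 2, 1))
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        response ~ sigmoid_fun(irradiance, lower, upper, log_ec50, slope),
        start = as.list(st),
        control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-10,
                                             ptol = 1e-10)),
      error = function(e) NULL)
    if (is.null(fit)) next
    ss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || ss < best$residual_ss) {
      cf <- stats::coef(fit)
      best <- list(lower = unname(cf["lower"]), upper = unname(cf["upper"]),
                   log_ec50 = unname(cf["log_ec50"]),
                   slope = unname(cf["slope"]),
                   residual_ss = ss, converged = fit$convInfo$isConv)
    }
  }
  if (is.null(best)) {
    best <- list(lower = lo0, upper = up0, log_ec50 = stats::median(irradiance),
                 slope = 1, converged = FALSE)
    best$residual_ss <- sum((response - do.call(
      sigmoid_fun, c(list(irradiance), best[1:4])))^2)
  }
  # canonical orientation: positive slope, lower <= upper (the curve is
  # invariant to flipping both)
  if (best$slope < 0) {
    tmp <- best$lower; best$lower <- best$upper; best$upper <- tmp
    best$slope <- -best$slope
  }
  best$n <- length(response)
  best$irradiance <- irradiance
  best$response <- response
  class(best) <- "sigmoid_fit"
  best
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  cat(sprintf(
    "<sigmoid_fit> lower %.3g upper %.3g log_ec50 %.3g slope %.3g (SS %.3g%s)\n",
    x$lower, x$upper, x$log_ec50, x$slope, x$residual_ss,
    if (x$converged) "" else ", NOT converged"))
  invisible(x)
}

#' Predict from a sigmoid fit
#' @param object a `sigmoid_fit`.
#' @param newdata irradiance vector (log10 units); defaults to the fitted data.
#' @param ... unused.
#' @export
predict.sigmoid_fit <- function(object, newdata = NULL, ...) {
  I <- newdata %||% object$irradiance
  sigmoid_fun(I, object$lower, object$upper, object$log_ec50, object$slope)
}

# Joint sum of squares for two datasets with some parameters shared.
# par layout: shared params first, then per-dataset free params (a then b).
sigmoid_joint_ss <- function(par, da, db, shared, free) {
  ns <- length(shared)
  nf <- length(free)
  get <- function(offset) {
    p <- c(par[seq_len(ns)], par[ns + offset + seq_len(nf)])
    names(p) <- c(shared, free)
    p[c("lower", "upper", "log_ec50", "slope")]
  }
  pa <- get(0); pb <- get(nf)
  sum((da$response - sigmoid_fun(da$irradiance, pa[1], pa[2], pa[3], pa[4]))^2) +
    sum((db$response - sigmoid_fun(db$irradiance, pb[1], pb[2], pb[3], pb[4]))^2)
}

#' Compare two sigmoid fits by extra-sum-of-squares F-test
#'
#' Tests whether the parameters in `test_params` differ between two
#' irradiance-response datasets: the null model shares those parameters
#' across datasets (all other parameters free per dataset), the alternative
#' fits all parameters separately. The F statistic is
#' `((SS_shared - SS_separate)/df1) / (SS_separate/df2)` with `df1` the number
#' of tested parameters and `df2 = n_total - 8`; p is the upper tail of the F
#' distribution (the standard form of this comparison).
#'
#' @param data_a,data_b lists or data.frames with `irradiance` and `response`.
#' @param test_params character subset of
#'   `c("lower", "upper", "log_ec50", "slope")` shared under the null.
#' @return list with `F`, `df`, `p`, `ss_shared`, `ss_separate` and the two
#'   separate fits.
#' @export
compare_sigmoids_ftest <- function(data_a, data_b,
                                   test_params = c("log_ec50", "slope")) {
  all_par <- c("lower", "upper", "log_ec50", "slope")
  stopifnot(all(test_params %in% all_par), length(test_params) >= 1)
  da <- list(irradiance = data_a$irradiance, response = data_a$response)
  db <- list(irradiance = data_b$irradiance, response = data_b$response)
  fa <- fit_sigmoid(da$irradiance, da$response)
  fb <- fit_sigmoid(db$irradiance, db$response)
  ss_sep <- fa$residual_ss + fb$residual_ss
  n_tot <- fa$n + fb$n
  df2 <- n_tot - 2 * length(all_par)
  df1 <- length(test_params)
  if (df2 <= 0) stop("saturated model: no residual degrees of freedom")
  free <- setdiff(all_par, test_params)
  p0 <- c(vapply(test_params, function(p) mean(c(fa[[p]], fb[[p]])), 0),
          vapply(free, function(p) fa[[p]], 0),
          vapply(free, function(p) fb[[p]], 0))
  fit0 <- stats::optim(p0, sigmoid_joint_ss, da = da, db = db,
                       shared = test_params, free = free, method = "BFGS",
                       control = list(maxit = 2000, reltol = 1e-14))
  fit0 <- stats::optim(fit0$par, sigmoid_joint_ss, da = da, db = db,
                       shared = test_params, free = free,
                       method = "Nelder-Mead",
                       control = list(maxit = 5000, reltol = 1e-14))
  ss_sh <- fit0$value
  Fstat <- max(0, (ss_sh - ss_sep) / df1 / (ss_sep / df2))
  list(F = Fstat, df = c(df1, df2),
       p = stats::pf(Fstat, df1, df2, lower.tail = FALSE),
       ss_shared = ss_sh, ss_separate = ss_sep, fit_a = fa, fit_b = fb)
}
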