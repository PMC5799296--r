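#' @export
print.tdp43_model <- function(x, ...) {
  cat("Calibrated TDP-43 autoregulation model\n")
  cat("  NMD flux fraction: ", 100 * x$constraints$nmd_fraction,
      "%   C/N ratio: ", x$constraints$cn_ratio,
      "   half-life: ", x$half_life, " r.t.u.\n", sep = "")
  cat("  fitted validation observables (target in brackets):\n")
  tv <- tuning_target_vector(x$tuning_targets)
  for (nm in names(x$fitted_observables)) {
    cat(sprintf("    %-14s %6.1f%%", nm, 100 * x$fitted_observables[[nm]]))
    if (nm %in% names(tv)) cat(sprintf("  [%g%%]", 100 * tv[[nm]]))
    cat("\n")
  }
  invisible(x)
}

#' @export
summary.tdp43_model <- function(object, ...) {
  structure(list(model = object), class = "summary.tdp43_model")
}

#' @export
print.summary.tdp43_model <- function(x, ...) {
  m <- x$model
  print(m)
  cat("\nBaseline steady state (r.u.):\n")
  print(round(m$baseline, 5))
  cat("\nKinetic parameters:\n")
  print(signif(coef(m), 5))
  cat("\nCalibration: ", m$optim$counts[["function"]],
      " objective evaluations, final value ",
      format(m$optim$value, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Kinetic parameters of a calibrated model
#' @param object A `tdp43_model`.
#' @param ... Unused.
#' @return Named numeric vector of all kinetic constants.
#' @export
coef.tdp43_model <- function(object, ...) {
  unlist(object$params[names(object$params)])
}

#' Calibration residuals
#'
#' Differences between the fitted validation observables and their published
#' target values (on the relative scale of the targets).
#' @param object A `tdp43_model`.
#' @param ... Unused.
#' @return Named numeric vector.
#' @export
residuals.tdp43_model <- function(object, ...) object$residuals

#' @export
fitted.tdp43_model <- function(object, ...) object$fitted_observables

#' Simulate a calibrated model
#'
#' Integrates the model forward from its baseline steady state (or a given
#' state) under a perturbation schedule. Deterministic: `nsim` and `seed`
#' are accepted for generic consistency but the model has no stochastic
#' component, so they are ignored beyond the first replicate.
#'
#' @param object A `tdp43_model`.
#' @param nsim,seed Ignored (deterministic model).
#' @param schedule List of [perturbation()]s.
#' @param horizon End time (relative time units).
#' @param mode A [regulation_mode()] or mode string; `"NAR_OFF"` uses the
#'   model's frozen baseline repression factor.
#' @param s0 Initial state; defaults to the calibrated baseline.
#' @param ... Passed to [integrate_model()].
#' @return A `tdp43_trajectory`.
#' @export
simulate.tdp43_model <- function(object, nsim = 1, seed = NULL,
                                 schedule = list(), horizon = 1000,
                                 mode = "NAR_ON", s0 = object$baseline, ...) {
  integrate_model(object$params, s0 = s0,
                  mode = model_mode(object, mode),
                  schedule = schedule, horizon = horizon, ...)
}

#' Predict the settled state under a perturbation schedule
#'
#' Settles the model under persistent perturbations and returns the steady
#' state (the model's "prediction" for that condition).
#'
#' @param object A `tdp43_model`.
#' @param schedule List of [perturbation()]s (persistent ones are typical).
#' @param mode A [regulation_mode()] or mode string.
#' @param ... Passed to [settle()].
#' @return A `tdp43_steady` object.
#' @export
predict.tdp43_model <- function(object, schedule = list(),
                                mode = "NAR_ON", ...) {
  settle(object$params, s0 = object$baseline,
         mode = model_mode(object, mode), schedule = as_schedule(schedule),
         ...)
}

#' @export
plot.tdp43_model <- function(x, schedule = list(), horizon = 2000,
                             mode = "NAR_ON", ...) {
  traj <- simulate(x, schedule = schedule, horizon = horizon, mode = mode)
  plot(traj, ...)
}

model_mode <- function(object, mode) {
  if (inherits(mode, "regulation_mode")) return(mode)
  regulation_mode(mode, nar_off_factor = object$nar_off_factor)
}
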