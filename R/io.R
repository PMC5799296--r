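#' Write a trajectory to CSV
#'
#' Comma-separated, header row, '.' decimal, UTF-8: columns `time`, the 8
#' pools, and one 0/1 activity flag per scheduled perturbation.
#'
#' @param traj A `tdp43_trajectory`.
#' @param file Output path.
#' @return The path, invisibly.
#' @export
write_trajectory_csv <- function(traj, file) {
  utils::write.csv(as.data.frame(traj), file, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(file)
}

#' Serialize a parameter set (with provenance) to JSON
#'
#' Flat key-value document carrying every kinetic constant, the calibration
#' flag, and - for fitted models - the constraint values used, optimizer
#' diagnostics and target residuals, so that any result file embeds the
#' exact parameters that produced it.
#'
#' @param x A `tdp43_model` or [tdp43_params()] object.
#' @param file Output path, or `NULL` to return the JSON string.
#' @return The JSON string (invisibly when written to file).
#' @export
params_to_json <- function(x, file = NULL) {
  if (inherits(x, "tdp43_model")) {
    payload <- list(
      parameters = x$params[names(x$params)],
      calibrated = is_calibrated(x$params),
      baseline_state = as.list(x$baseline),
      constraints = x$constraints[names(x$constraints)],
      nar_off_factor = x$nar_off_factor,
      fitted_observables = as.list(x$fitted_observables),
      target_residuals = as.list(x$residuals),
      optimizer = list(value = x$optim$value,
                       evaluations = unname(x$optim$counts[["function"]]),
                       convergence = x$optim$convergence,
                       n_agg = x$optim$n_agg, F_half = x$optim$F_half)
    )
  } else {
    stopifnot(inherits(x, "tdp43_params"))
    payload <- list(parameters = x[names(x)], calibrated = is_calibrated(x))
    b <- attr(x, "baseline")
    if (!is.null(b)) payload$baseline_state <- as.list(b)
  }
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
  if (!is.null(file)) {
    writeLines(json, file, useBytes = TRUE)
    return(invisible(as.character(json)))
  }
  as.character(json)
}

#' Rebuild a parameter set from its JSON serialization
#'
#' @param file Path to a document written by [params_to_json()] (or the JSON
#'   string itself).
#' @return A [tdp43_params()] object (baseline state reattached if present).
#' @export
params_from_json <- function(file) {
  payload <- jsonlite::fromJSON(file)
  args <- payload$parameters
  args$calibrated <- isTRUE(payload$calibrated)
  p <- do.call(tdp43_params, args)
  if (!is.null(payload$baseline_state))
    attr(p, "baseline") <- do.call(cell_state, payload$baseline_state)
  p
}

#' Short hash of a parameter set
#'
#' Deterministic 8-hex-digit digest of the kinetic constants (a polynomial
#' rolling hash over their full-precision decimal representation); carried
#' in CLI log lines and results metadata so outputs are traceable to the
#' exact parameters.
#'
#' @param p A [tdp43_params()] object or `tdp43_model`.
#' @return Character scalar, e.g. `"1a2b3c4d"`.
#' @export
params_hash <- function(p) {
  if (inherits(p, "tdp43_model")) p <- p$params
  # 15 significant digits: stable across a JSON serialisation round trip
  txt <- paste(names(p), vapply(unlist(p), format, "", digits = 15),
               collapse = ";")
  bytes <- utf8ToInt(txt)
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}
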