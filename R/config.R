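#' Run configuration
#'
#' A fully serializable description of a batch run: calibration constraints,
#' classifier thresholds, and a list of scenarios with their arguments and
#' output paths. A run is reproducible from its configuration alone; every
#' result file written embeds the exact calibrated parameters used.
#'
#' @param constraints A [calibration_constraints()] object.
#' @param scenarios List of scenario entries; each a list with fields
#'   `name` (one of `"het_ko"`, `"transgenic"`, `"sweep"`, `"therapy"`,
#'   `"propagation"`, `"estimate_redundancy"`, `"export_sbml"`),
#'   `args` (named list passed to the scenario function) and `out`
#'   (output path for the scenario's JSON/CSV/XML result).
#' @param thresholds Classifier thresholds (`floor`, `ceiling`).
#' @param params_out Optional path for the calibrated parameter document.
#' @return An object of class `tdp43_run_config`.
#' @export
run_config <- function(constraints = calibration_constraints(),
                       scenarios = list(),
                       thresholds = list(floor = 0.5, ceiling = 0.1),
                       params_out = NULL) {
  for (sc in scenarios) {
    if (is.null(sc$name) || is.null(sc$out))
      stop("each scenario entry needs 'name' and 'out'")
  }
  structure(list(constraints = constraints, scenarios = scenarios,
                 thresholds = thresholds, params_out = params_out),
            class = "tdp43_run_config")
}

#' @rdname run_config
#' @param config A `tdp43_run_config`.
#' @param file Path to write to (JSON), or `NULL` for the string.
#' @export
write_run_config <- function(config, file = NULL) {
  stopifnot(inherits(config, "tdp43_run_config"))
  payload <- list(constraints = config$constraints[names(config$constraints)],
                  scenarios = config$scenarios,
                  thresholds = config$thresholds,
                  params_out = config$params_out)
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, null = "null")
  if (!is.null(file)) {
    writeLines(json, file, useBytes = TRUE)
    return(invisible(as.character(json)))
  }
  as.character(json)
}

#' @rdname run_config
#' @export
read_run_config <- function(file) {
  payload <- jsonlite::fromJSON(file, simplifyDataFrame = FALSE)
  cc <- payload$constraints
  run_config(
    constraints = calibration_constraints(
      nmd_fraction = cc$nmd_fraction, cn_ratio = cc$cn_ratio,
      halflife_target = cc$halflife_target, trace_bound = cc$trace_bound),
    scenarios = payload$scenarios %||% list(),
    thresholds = payload$thresholds %||% list(floor = 0.5, ceiling = 0.1),
    params_out = payload$params_out
  )
}

#' Execute a run configuration
#'
#' Calibrates (or reuses) a model under the configuration's constraints and
#' runs each scenario entry, writing its machine-readable result.
#'
#' @param config A `tdp43_run_config` (or path to one).
#' @param model Optional pre-calibrated `tdp43_model`; calibrated from the
#'   configuration's constraints when omitted.
#' @return Invisibly, the list of output paths written.
#' @export
execute_run_config <- function(config, model = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "tdp43_run_config"))
  if (is.null(model)) model <- calibrate_tdp43(config$constraints)
  if (!is.null(config$params_out)) params_to_json(model, config$params_out)
  written <- character(0)
  for (sc in config$scenarios) {
    a <- sc$args %||% list()
    res <- switch(
      sc$name,
      het_ko = {
        st <- do.call(heterozygous_ko, c(list(model), a))
        list(scenario = "het_ko", state = as.list(st$state),
             settled = st$settled)
      },
      transgenic = {
        st <- do.call(transgenic, c(list(model), a))
        list(scenario = "transgenic", state = as.list(st$state),
             settled = st$settled)
      },
      sweep = {
        sw <- do.call(parameter_sweep, c(list(model), a))
        list(scenario = "sweep", parameter = attr(sw, "parameter"),
             mode = attr(sw, "mode"), grid = as.data.frame(sw))
      },
      therapy = {
        th <- do.call(therapy, c(list(model), a))
        list(scenario = "therapy", onset = th$onset,
             disease_reached = th$disease_reached,
             final_class = th$final_class$label,
             final_state = as.list(th$final_state))
      },
      propagation = {
        pr <- do.call(propagation, c(list(model), a))
        list(scenario = "propagation", k_upt = attr(pr, "k_upt"),
             results = pr)
      },
      estimate_redundancy = {
        Y <- estimate_spliced_fraction(a$f, a$k)
        list(scenario = "estimate_redundancy", f = a$f, k = a$k, Y = Y,
             R = transcriptional_redundancy(Y))
      },
      export_sbml = {
        export_sbml(model, mode = a$mode %||% "NAR_ON", file = sc$out)
        NULL
      },
      stop("unknown scenario in config: ", sc$name)
    )
    if (!is.null(res)) {
      res$parameters <- model$params[names(model$params)]
      res$parameter_hash <- params_hash(model$params)
      writeLines(jsonlite::toJSON(res, auto_unbox = TRUE, digits = NA,
                                  pretty = TRUE), sc$out, useBytes = TRUE)
    }
    written <- c(written, sc$out)
  }
  invisible(written)
}
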