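as_params <- function(x) {
  if (inherits(x, "tdp43_model")) x$params
  else if (inherits(x, "tdp43_params")) x
  else stop("expected a tdp43_model or tdp43_params object")
}

#' Heterozygous knockout scenario
#'
#' Halves the pre-mRNA supply (one functional allele) and settles the model.
#' Under NAR(+) the autoregulatory loop partially restores canonical mRNA
#' (to about 79% of baseline) and nuclear protein (about 82%); under NAR(-)
#' nuclear TDP-43 falls to roughly half.
#'
#' @param model A `tdp43_model` (or calibrated [tdp43_params()]).
#' @param mode A [regulation_mode()] or mode string.
#' @param factor Transcription factor (0.5 = heterozygous knockout).
#' @return A `tdp43_steady` object (see [settle()]).
#' @export
heterozygous_ko <- function(model, mode = "NAR_ON", factor = 0.5) {
  p <- as_params(model)
  settle(scale_param(p, "transcription", factor),
         s0 = baseline_state(p), mode = as_regulation_mode(mode, p))
}

#' Transgenic (3'-UTR-less) expression scenario
#'
#' Switches on an exogenous mRNA without autoregulation whose isolated steady
#' level equals `exo_level` (`k_tc_ex = exo_level * d_m_ex`). The exogenous
#' protein shares all kinetics with the endogenous protein and represses
#' endogenous production through total nuclear TDP-43.
#'
#' @param model A `tdp43_model` (or calibrated [tdp43_params()]).
#' @param exo_level Steady exogenous mRNA level in isolation (r.u., >= 0).
#' @param mode A [regulation_mode()] or mode string.
#' @return A `tdp43_steady` object; endogenous and exogenous pools are
#'   reported separately in its `state`.
#' @export
transgenic <- function(model, exo_level = 1, mode = "NAR_ON") {
  stopifnot(exo_level >= 0)
  p <- as_params(model)
  mode <- as_regulation_mode(mode, p)
  p_tg <- p
  p_tg$k_tc_ex <- exo_level * p$d_m_ex
  attr(p_tg, "calibrated") <- FALSE
  settle(p_tg, s0 = baseline_state(p), mode = mode)
}

#' Transgene dose-response
#'
#' Maps [transgenic()] over a grid of exogenous expression levels.
#'
#' @inheritParams transgenic
#' @param levels Increasing grid of exogenous levels (r.u.).
#' @return Data frame with per-level endogenous/total nuclear TDP-43,
#'   fragment and aggregate amounts, settled flag and state class.
#' @export
transgenic_dose_response <- function(model, levels = seq(0, 2, by = 0.25),
                                     mode = "NAR_ON") {
  p <- as_params(model)
  b <- baseline_state(p)
  rows <- lapply(levels, function(lv) {
    st <- transgenic(model, lv, mode)
    cls <- classify_state(st$state, b)
    data.frame(exo_level = lv,
               nTDP_endo = st$state[["nTDP"]],
               nTDP_total = st$state[["nTDP"]] + st$state[["nTDP_ex"]],
               frag = st$state[["frag"]], agg = st$state[["agg"]],
               settled = st$settled, class = cls$label)
  })
  do.call(rbind, rows)
}

#' Parameter sweep
#'
#' Settles the model from the baseline state at each point of a linear factor
#' grid applied to one parameter, in either regulation mode. This is the
#' robustness/fragility scan: under NAR(+) nuclear TDP-43 stays near baseline
#' over wide ranges of most parameters, while fragility-type parameters
#' trigger a collapse into the aggregation-driven disease state.
#'
#' @param model A `tdp43_model` (or calibrated [tdp43_params()]).
#' @param parameter One of [sweepable_parameters()].
#' @param mode A [regulation_mode()] or mode string.
#' @param lo,hi Factor range (inclusive endpoints).
#' @param steps Number of grid points.
#' @param horizon_cap Settling horizon cap per point.
#' @return An object of class `tdp43_sweep`: data frame with columns
#'   `factor`, `nTDP`, `nTDP_total`, `frag`, `agg`, `mRNA`, `settled`;
#'   attributes `parameter` and `mode`.
#' @export
parameter_sweep <- function(model, parameter, mode = "NAR_ON",
                            lo = 0.5, hi = 2.0, steps = 100,
                            horizon_cap = 2e5) {
  if (!parameter %in% sweepable_parameters())
    stop("parameter must be one of: ",
         paste(sweepable_parameters(), collapse = ", "))
  stopifnot(lo <= hi, steps >= 1)
  p <- as_params(model)
  mode <- as_regulation_mode(mode, p)
  grid <- if (steps == 1) (lo + hi) / 2 else seq(lo, hi, length.out = steps)
  b <- baseline_state(p)
  rows <- lapply(grid, function(f) {
    st <- settle(scale_param(p, parameter, f), s0 = b, mode = mode,
                 horizon_cap = horizon_cap)
    data.frame(factor = f, nTDP = st$state[["nTDP"]],
               nTDP_total = st$state[["nTDP"]] + st$state[["nTDP_ex"]],
               frag = st$state[["frag"]], agg = st$state[["agg"]],
               mRNA = st$state[["mRNA"]], settled = st$settled)
  })
  out <- do.call(rbind, rows)
  attr(out, "parameter") <- parameter
  attr(out, "mode") <- mode$mode
  class(out) <- c("tdp43_sweep", "data.frame")
  out
}

#' Transcriptional-redundancy stages
#'
#' Re-derives the autoregulation parameters for a series of NMD fractions Y
#' while preserving the baseline steady state exactly: for each stage Knar is
#' re-solved from Y and the pre-mRNA supply is rescaled by
#' `(1 - Y_base) / (1 - Y)`, so canonical mRNA and all protein pools are
#' unchanged at baseline and only the production *reserve* (transcriptional
#' redundancy R = 1 / (1 - Y)) differs.
#'
#' @param model A `tdp43_model` (or calibrated [tdp43_params()]).
#' @param Y_values Increasing NMD fractions in (0, 1); default spans the
#'   published plausible range around the 0.65 baseline.
#' @return List of stages; each has fields `stage`, `Y`, `redundancy`,
#'   `params` (ready for [parameter_sweep()] or [settle()]).
#' @export
redundancy_stages <- function(model,
                              Y_values = c(0.20, 0.50, 0.65, 0.75, 0.80)) {
  if (any(Y_values <= 0 | Y_values >= 1)) stop("Y values must lie in (0, 1)")
  if (is.unsorted(Y_values, strictly = TRUE))
    stop("Y values must be strictly increasing")
  p <- as_params(model)
  Y_base <- if (inherits(model, "tdp43_model"))
    model$constraints$nmd_fraction else 0.65
  lapply(seq_along(Y_values), function(i) {
    Y <- Y_values[i]
    ps <- p
    ps$Knar <- solve_knar(Y, p$n_hill)
    ps$pre <- p$pre * (1 - Y_base) / (1 - Y)
    attr(ps, "calibrated") <- FALSE
    attr(ps, "baseline") <- baseline_state(p)
    list(stage = i, Y = Y, redundancy = 1 / (1 - Y), params = ps)
  })
}

#' Transcription-reduction therapy scenario
#'
#' Applies a persistent pathogenic disturbance from t = 0 (by default the
#' aggregation-prone condition, `agg_K` at 0.6 times its calibrated value),
#' waits until the classifier first reports a disease state, then reduces
#' transcription to `reduction` times its level. Returns the full time
#' course for classification.
#'
#' @param model A `tdp43_model` (or calibrated [tdp43_params()]).
#' @param disturbance A [perturbation()] driving the system towards disease.
#' @param reduction Transcription multiplier applied as therapy, in (0, 1].
#' @param onset Therapy onset time; `NULL` (default) = first time the disease
#'   classifier fires.
#' @param mode A [regulation_mode()] or mode string.
#' @param thresholds Classifier thresholds, see [classify_state()].
#' @param horizon Post-onset horizon for the reported trajectory.
#' @return A list of class `tdp43_therapy`: `trajectory`, `onset`,
#'   `disease_reached`, `final_class`, `final_state`.
#' @export
therapy <- function(model, disturbance = perturbation("agg_K", 0.6),
                    reduction = 0.4, onset = NULL, mode = "NAR_ON",
                    thresholds = list(floor = 0.5, ceiling = 0.1),
                    horizon = 30000) {
  stopifnot(reduction > 0, reduction <= 1)
  p <- as_params(model)
  mode <- as_regulation_mode(mode, p)
  b <- baseline_state(p)
  disease_reached <- FALSE
  if (is.null(onset)) {
    # run under the disturbance until the classifier fires
    t_now <- 0
    x <- b
    chunk <- 1000
    while (t_now < horizon * 10) {
      traj <- integrate_model(scale_param(p, disturbance$parameter,
                                          disturbance$factor),
                              x, mode, list(), horizon = chunk, n_out = 200)
      labels <- apply(traj$states, 1, function(s)
        classify_state(s, b, floor = thresholds$floor,
                       ceiling = thresholds$ceiling)$label)
      hit <- which(labels == "disease")[1]
      if (!is.na(hit)) {
        onset <- t_now + traj$times[hit]
        disease_reached <- TRUE
        break
      }
      x <- final_state(traj)
      t_now <- t_now + chunk
      r <- tdp43_rhs(scale_param(p, disturbance$parameter,
                                 disturbance$factor), x, mode)
      if (max(abs(r)) < 1e-10 * (1 + max(abs(x)))) break # settled healthy
      chunk <- chunk * 2
    }
    if (is.null(onset)) onset <- t_now # disturbance never caused disease
  } else {
    disease_reached <- TRUE
  }
  sched <- list(
    perturbation(disturbance$parameter, disturbance$factor, onset = 0),
    perturbation("transcription", reduction, onset = onset)
  )
  st <- settle(p, b, mode, sched)
  traj <- integrate_model(p, b, mode, sched, horizon = onset + horizon,
                          n_out = 600)
  final <- st$state
  cls <- classify_state(final, b, floor = thresholds$floor,
                        ceiling = thresholds$ceiling)
  structure(list(trajectory = traj, onset = onset,
                 disease_reached = disease_reached,
                 final_class = cls, final_state = final,
                 settled = st$settled),
            class = "tdp43_therapy")
}

#' @export
print.tdp43_therapy <- function(x, ...) {
  cat("Therapy scenario: disease ",
      if (x$disease_reached) paste0("reached at t = ",
                                    format(x$onset, digits = 4))
      else "never reached", "; final state: ", x$final_class$label,
      "\n", sep = "")
  print(round(x$final_state, 5))
  invisible(x)
}

#' Extracellular fragment propagation scenario
#'
#' Places fragmented TDP-43 outside the cell at each of several constant
#' levels, with uptake flux `k_upt * F_ext` into the intracellular fragment
#' pool, and settles the receiving cell with and without a transcription
#' reduction. Above a threshold level of extracellular fragments the
#' receiving cell switches into the disease state; reducing transcription
#' raises that threshold.
#'
#' @param model A `tdp43_model` (or calibrated [tdp43_params()]).
#' @param F_ext_levels Increasing extracellular fragment levels (r.u.).
#' @param reduction Transcription multiplier tested as therapy, in (0, 1].
#' @param k_upt Uptake rate coefficient; default scales with fragment
#'   turnover so the grid brackets the classification threshold.
#' @param mode A [regulation_mode()] or mode string.
#' @param thresholds Classifier thresholds, see [classify_state()].
#' @return Data frame with one row per (level, reduction in {1, reduction}):
#'   final pools, settled flag and classification.
#' @export
propagation <- function(model, F_ext_levels = c(0.5, 1, 2, 4, 6, 8),
                        reduction = 0.5, k_upt = NULL, mode = "NAR_ON",
                        thresholds = list(floor = 0.5, ceiling = 0.1)) {
  stopifnot(!is.unsorted(F_ext_levels, strictly = TRUE),
            reduction > 0, reduction <= 1)
  p <- as_params(model)
  mode <- as_regulation_mode(mode, p)
  if (is.null(k_upt)) k_upt <- p$d_f * p$F_half / 20
  stopifnot(k_upt > 0)
  b <- baseline_state(p)
  one <- function(level, red) {
    pp <- p
    pp$k_upt <- k_upt
    pp$F_ext <- level
    attr(pp, "calibrated") <- FALSE
    if (red < 1) pp <- scale_param(pp, "transcription", red)
    st <- settle(pp, b, mode, horizon_cap = 2e5)
    cls <- classify_state(st$state, b, floor = thresholds$floor,
                          ceiling = thresholds$ceiling)
    data.frame(F_ext = level, reduction = red,
               nTDP = st$state[["nTDP"]], mRNA = st$state[["mRNA"]],
               frag = st$state[["frag"]], agg = st$state[["agg"]],
               settled = st$settled, class = cls$label)
  }
  rows <- c(lapply(F_ext_levels, one, red = 1),
            lapply(F_ext_levels, one, red = reduction))
  out <- do.call(rbind, rows)
  attr(out, "k_upt") <- k_upt
  out
}
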