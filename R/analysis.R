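#' Classify a cell state as healthy or disease
#'
#' The disease state is characterised by loss of nuclear TDP-43 together
#' with accumulation of fragments or aggregates: a state is classified as
#' disease iff total nuclear TDP-43 is strictly below `floor` times the
#' baseline nuclear level AND fragments or aggregates strictly exceed
#' `ceiling` (r.u.). Both inequalities are strict, so a state exactly at the
#' thresholds is healthy. Thresholds are recorded with every classification.
#'
#' @param state A [cell_state()] vector.
#' @param baseline The calibrated healthy baseline state.
#' @param floor Nuclear TDP-43 floor, as a fraction of baseline.
#' @param ceiling Fragment/aggregate ceiling (r.u.).
#' @return A list of class `tdp43_state_class`: `label` ("healthy" or
#'   "disease"), `nTDP_rel`, `frag`, `agg`, `floor`, `ceiling`.
#' @export
classify_state <- function(state, baseline, floor = 0.5, ceiling = 0.1) {
  n_rel <- (state[["nTDP"]] + state[["nTDP_ex"]]) /
    (baseline[["nTDP"]] + baseline[["nTDP_ex"]])
  disease <- n_rel < floor &&
    (state[["frag"]] > ceiling || state[["agg"]] > ceiling)
  structure(list(label = if (disease) "disease" else "healthy",
                 nTDP_rel = n_rel, frag = state[["frag"]],
                 agg = state[["agg"]], floor = floor, ceiling = ceiling),
            class = "tdp43_state_class")
}

#' @export
print.tdp43_state_class <- function(x, ...) {
  cat(x$label, " (nuclear TDP-43 at ", round(100 * x$nTDP_rel, 1),
      "% of baseline; frag ", signif(x$frag, 3), ", agg ", signif(x$agg, 3),
      "; thresholds: floor ", x$floor, ", ceiling ", x$ceiling, ")\n",
      sep = "")
  invisible(x)
}

#' Hysteresis scan by quasi-static continuation
#'
#' Sweeps a factor applied to one parameter downwards from `hi` to `lo` and
#' back up, settling each grid point from the previous point's settled state
#' (warm-started continuation). The hysteresis window is the factor interval
#' on which the up-sweep and down-sweep classifications disagree; a
#' non-empty window demonstrates bistability between the healthy and disease
#' states. An empty window means the scanned range is monostable.
#'
#' @param model A `tdp43_model` (or calibrated [tdp43_params()]).
#' @param parameter One of [sweepable_parameters()].
#' @param lo,hi Factor range; the scan runs hi -> lo -> hi.
#' @param steps Grid points per direction.
#' @param mode A [regulation_mode()] or mode string.
#' @param thresholds Classifier thresholds, see [classify_state()].
#' @param horizon_cap Settling cap per point.
#' @return A list of class `tdp43_hysteresis`: `grid` (data frame with both
#'   directions), `window` (numeric length-2 factor interval or NULL),
#'   `bistable` (logical).
#' @export
bistability_scan <- function(model, parameter = "agg_K", lo = 0.4, hi = 1.0,
                             steps = 25, mode = "NAR_ON",
                             thresholds = list(floor = 0.5, ceiling = 0.1),
                             horizon_cap = 2e5) {
  stopifnot(lo < hi, steps >= 1)
  p <- as_params(model)
  mode <- as_regulation_mode(mode, p)
  b <- baseline_state(p)
  grid_down <- if (steps == 1) (lo + hi) / 2 else
    seq(hi, lo, length.out = steps)
  run_dir <- function(grid, x0) {
    x <- x0
    rows <- vector("list", length(grid))
    for (i in seq_along(grid)) {
      st <- settle(scale_param(p, parameter, grid[i]), s0 = x, mode = mode,
                   horizon_cap = horizon_cap)
      x <- st$state
      cls <- classify_state(x, b, floor = thresholds$floor,
                            ceiling = thresholds$ceiling)
      rows[[i]] <- data.frame(factor = grid[i], nTDP = x[["nTDP"]],
                              frag = x[["frag"]], agg = x[["agg"]],
                              mRNA = x[["mRNA"]], settled = st$settled,
                              class = cls$label)
    }
    list(rows = do.call(rbind, rows), last = x)
  }
  down <- run_dir(grid_down, b)
  down$rows$direction <- "down"
  up <- run_dir(rev(grid_down), down$last)
  up$rows$direction <- "up"
  grid <- rbind(down$rows, up$rows)
  down <- down$rows
  up <- up$rows
  merged <- merge(down[, c("factor", "class")], up[, c("factor", "class")],
                  by = "factor", suffixes = c("_down", "_up"))
  disagree <- merged$factor[merged$class_down != merged$class_up]
  window <- if (length(disagree)) range(disagree) else NULL
  structure(list(grid = grid, window = window,
                 bistable = !is.null(window), parameter = parameter),
            class = "tdp43_hysteresis")
}

#' @export
print.tdp43_hysteresis <- function(x, ...) {
  if (x$bistable) {
    cat("Hysteresis in ", x$parameter, ": window [",
        format(x$window[1], digits = 4), ", ",
        format(x$window[2], digits = 4), "] (bistable)\n", sep = "")
  } else {
    cat("No hysteresis in ", x$parameter,
        " over the scanned range (monostable)\n", sep = "")
  }
  invisible(x)
}

#' Estimate the alternatively spliced fraction of pre-mRNA
#'
#' Converts an observed steady-state abundance fraction `f` of
#' NMD-destined (alternatively spliced, intron-6-lacking) isoforms into the
#' production fraction Y of pre-mRNA that undergoes alternative splicing,
#' correcting for the k-fold faster degradation of the spliced isoform. At
#' steady state, abundances are production over degradation, so
#' `f = (Y/k) / (Y/k + (1-Y))`, giving `Y = f k / (1 - f + f k)`
#' (as a percentage). With the measured f = 0.36 in adult mouse cerebrum and
#' k between 3 and 5, Y is 63-74%.
#'
#' @param f Observed abundance fraction of the spliced isoform, in (0, 1).
#' @param k Degradation-rate ratio spliced/canonical (>= 1).
#' @return Y as a percentage.
#' @export
estimate_spliced_fraction <- function(f, k) {
  if (any(!is.finite(f)) || any(f <= 0) || any(f >= 1))
    stop("f must lie strictly inside (0, 1)")
  if (any(!is.finite(k)) || any(k < 1)) stop("k must be >= 1")
  100 * f * k / (1 - f + f * k)
}

#' Transcriptional redundancy
#'
#' `R = 100 / (100 - Y)`: the fold-excess of transcription over the amount
#' retained as canonical mRNA, where Y is the percentage of pre-mRNA that
#' undergoes alternative splicing.
#'
#' @param Y Alternatively spliced percentage, in \[0, 100).
#' @return Redundancy R (dimensionless fold).
#' @export
transcriptional_redundancy <- function(Y) {
  if (any(!is.finite(Y)) || any(Y < 0) || any(Y >= 100))
    stop("Y must lie in [0, 100) percent")
  100 / (100 - Y)
}

#' Convert relative time units to hours
#'
#' Anchors the model's relative time axis to a measured protein half-life:
#' returns the number of hours corresponding to 100 relative time units when
#' the model half-life (`model_halflife` r.u.) equals `hours_per_halflife`
#' hours. With measured half-lives of 4 to 34 h and the model value of
#' 110 r.u., 100 r.u. corresponds to roughly 3.6 to 31 h.
#'
#' @param hours_per_halflife Measured half-life in hours.
#' @param model_halflife Model half-life in relative time units.
#' @return Hours per 100 relative time units.
#' @export
time_unit_conversion <- function(hours_per_halflife, model_halflife = 110) {
  stopifnot(hours_per_halflife > 0, model_halflife > 0)
  100 * hours_per_halflife / model_halflife
}

#' Robustness/fragility typing across redundancy stages
#'
#' For each swept factor and each redundancy stage, settles the model at half
#' and at twice the factor's calibrated value and records (i) the largest
#' deviation of nuclear TDP-43 from its stage baseline and (ii) the largest
#' pathological burden (fragments + aggregates). A factor is typed
#' *fragility* when its pathological burden grows with transcriptional
#' redundancy and exceeds the classifier ceiling at the most redundant
#' stage; it is typed *robustness* when the nuclear deviation does not grow
#' with redundancy. The published typing: aggregation propensity (agg_K),
#' nuclear import, fragment degradation and autoregulation efficiency (Knar)
#' are fragility-type; transcription, mRNA degradation, translation and
#' protein degradation are robustness-type.
#'
#' @param model A `tdp43_model` (or calibrated [tdp43_params()]).
#' @param stages Stages from [redundancy_stages()] (>= 2 required).
#' @param factors Factors to type; defaults to [sweepable_parameters()].
#' @param ceiling Pathology ceiling used in the typing rule (r.u.).
#' @param horizon_cap Settling cap per point.
#' @return Data frame of class `tdp43_tradeoff`: one row per factor with its
#'   type and the per-stage extreme deviations/burdens (columns `dev_Y...`,
#'   `patho_Y...`).
#' @export
tradeoff_summary <- function(model, stages = redundancy_stages(model),
                             factors = sweepable_parameters(),
                             ceiling = 0.1, horizon_cap = 2e5) {
  if (length(stages) < 2)
    stop("typing requires at least two redundancy stages")
  rows <- lapply(factors, function(fac) {
    dev <- patho <- numeric(length(stages))
    for (i in seq_along(stages)) {
      ps <- stages[[i]]$params
      b <- baseline_state(ps)
      ex <- lapply(c(0.5, 2), function(f)
        settle(scale_param(ps, fac, f), s0 = b, mode = "NAR_ON",
               horizon_cap = horizon_cap)$state)
      dev[i] <- max(vapply(ex, function(s)
        abs(s[["nTDP"]] - b[["nTDP"]]), 0))
      patho[i] <- max(vapply(ex, function(s)
        s[["frag"]] + s[["agg"]], 0))
    }
    n <- length(stages)
    type <- if (patho[n] > ceiling && patho[n] > patho[1]) "fragility"
    else if (dev[n] <= dev[1] + 1e-9) "robustness"
    else "mixed"
    out <- data.frame(factor = fac, type = type)
    for (i in seq_along(stages)) {
      out[[paste0("dev_Y", stages[[i]]$Y)]] <- dev[i]
      out[[paste0("patho_Y", stages[[i]]$Y)]] <- patho[i]
    }
    out
  })
  out <- do.call(rbind, rows)
  class(out) <- c("tdp43_tradeoff", "data.frame")
  out
}
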