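#' Kinetic parameters of the TDP-43 reaction network
#'
#' Container for every rate constant and threshold of the model. All amounts
#' are in relative units (r.u.); baseline nuclear TDP-43 and canonical mRNA
#' are normalised to 1 by calibration. All per-time constants share one
#' relative time unit whose absolute scale is fixed by the translation-arrest
#' half-life (110 r.u. by default, see [calibrate_tdp43()]).
#'
#' A *calibrated baseline* set additionally satisfies the degradation-rate
#' ratio constraints `d_c = 5 d_n`, `d_n = 0.05 d_m`, `d_f = 3 d_c` and
#' `d_a = 0.2 d_n`. Scenario perturbations may break these ratios; the
#' `calibrated` flag records which kind of object this is.
#'
#' @param pre Pre-mRNA supply level (constant source, r.u.).
#' @param k2 Maximal canonical-mRNA production coefficient (per time);
#'   `k2 * pre` is the production flux at zero nuclear TDP-43.
#' @param Knar NAR suppression coefficient: the nuclear TDP-43 concentration
#'   that halves maximal canonical mRNA production (r.u.).
#' @param n_hill Hill coefficient of the NAR repression (dimensionless, >= 1).
#' @param d_m Canonical mRNA degradation rate (per time).
#' @param k_tl Translation rate (protein per mRNA per time).
#' @param k_imp,k_exp Nuclear import and export rates (per time).
#' @param d_n,d_c Nuclear and cytoplasmic protein degradation rates (per time).
#' @param k_frag Fragmentation rate coefficient on cytoplasmic TDP-43
#'   (per time).
#' @param d_f Fragment degradation rate (per time).
#' @param k_agg Maximal aggregation flux coefficient (per time).
#' @param agg_K Half-saturation threshold of the aggregation flux on
#'   cytoplasmic TDP-43 (r.u.). Lowering it models aggregation-prone protein.
#' @param n_agg Cooperativity exponent of the aggregation flux
#'   (dimensionless, >= 1).
#' @param frag_enh Maximal fold-enhancement (minus one) of aggregation by
#'   accumulated fragments (dimensionless).
#' @param F_half Fragment level at which the enhancement reaches half its
#'   maximum (r.u.).
#' @param n_seed Cooperativity exponent of the fragment-seeding enhancement
#'   (dimensionless, >= 1; nucleation-like).
#' @param k_fa Fragmentation rate of aggregates, feeding the fragment pool
#'   (per time).
#' @param k_tc_ex Production rate of an autoregulation-exempt (3'-UTR-less)
#'   exogenous mRNA (per time; 0 = no transgene).
#' @param d_m_ex Exogenous mRNA degradation rate (per time).
#' @param k_upt Uptake rate coefficient for extracellular fragments
#'   (per time; 0 = no propagation).
#' @param F_ext Extracellular fragmented TDP-43 level (r.u., held constant).
#' @param d_a Aggregate degradation rate (per time).
#' @param calibrated Logical; `TRUE` marks a calibrated baseline set for which
#'   the ratio invariants are enforced.
#'
#' @return An object of class `tdp43_params` (a named list).
#' @seealso [calibrate_tdp43()] which constructs a calibrated set from
#'   published constraints.
#' @export
tdp43_params <- function(pre = 1, k2 = 1 / 0.35, Knar = (0.35 / 0.65)^(1 / 4),
                         n_hill = 4, d_m = 1, k_tl = 0.1,
                         k_imp = 7, k_exp = 1, d_n = 0.05, d_c = 0.25,
                         k_frag = 0.0012, d_f = 0.75,
                         k_agg = 0.0127, agg_K = 0.29, n_agg = 2,
                         frag_enh = 600, F_half = 0.28, n_seed = 4,
                         k_fa = 0.38,
                         k_tc_ex = 0, d_m_ex = 1, k_upt = 0, F_ext = 0,
                         d_a = 0.01, calibrated = FALSE) {
  p <- list(pre = pre, k2 = k2, Knar = Knar, n_hill = n_hill, d_m = d_m,
            k_tl = k_tl, k_imp = k_imp, k_exp = k_exp, d_n = d_n, d_c = d_c,
            k_frag = k_frag, d_f = d_f, k_agg = k_agg, agg_K = agg_K,
            n_agg = n_agg, frag_enh = frag_enh, F_half = F_half,
            n_seed = n_seed, k_fa = k_fa,
            k_tc_ex = k_tc_ex, d_m_ex = d_m_ex, k_upt = k_upt, F_ext = F_ext,
            d_a = d_a)
  class(p) <- "tdp43_params"
  attr(p, "calibrated") <- isTRUE(calibrated)
  validate_params(p)
  p
}

#' @rdname tdp43_params
#' @param p A `tdp43_params` object.
#' @export
is_calibrated <- function(p) isTRUE(attr(p, "calibrated"))

# names of constants carrying units of 1/time; uniform scaling of these
# rescales the time axis and leaves every steady state unchanged
.rate_names <- c("k2", "d_m", "k_tl", "k_imp", "k_exp", "d_n", "d_c",
                 "k_frag", "d_f", "k_agg", "k_fa", "k_tc_ex", "d_m_ex",
                 "k_upt", "d_a")

validate_params <- function(p) {
  num <- unlist(p[setdiff(names(p), character())])
  if (any(!is.finite(num))) {
    stop("non-finite kinetic parameter: ",
         paste(names(num)[!is.finite(num)], collapse = ", "))
  }
  if (any(num < 0)) {
    stop("negative kinetic parameter: ",
         paste(names(num)[num < 0], collapse = ", "))
  }
  if (p$n_hill < 1) stop("n_hill must be >= 1")
  if (p$n_agg < 1) stop("n_agg must be >= 1")
  if (p$n_seed < 1) stop("n_seed must be >= 1")
  if (is_calibrated(p)) {
    ratios <- c(d_c_over_d_n = p$d_c / p$d_n - 5,
                d_n_over_d_m = p$d_n / p$d_m - 0.05,
                d_f_over_d_c = p$d_f / p$d_c - 3,
                d_a_over_d_n = p$d_a / p$d_n - 0.2)
    bad <- abs(ratios) > 1e-9 * c(5, 0.05, 3, 0.2)
    if (any(bad)) {
      stop("calibrated baseline violates degradation-rate ratio constraint: ",
           paste(names(ratios)[bad], collapse = ", "))
    }
  }
  invisible(p)
}

#' Scale selected parameters of a kinetic set
#'
#' Multiplies named parameters by factors, returning a perturbed (non-baseline)
#' copy. Aliases accepted for `name` match the quantities swept in the
#' robustness analysis: `"transcription"` (pre-mRNA supply),
#' `"mrna_degradation"`, `"translation"`, `"nuclear_import"`,
#' `"nuclear_export"`, `"protein_degradation"` (nuclear and cytoplasmic
#' jointly), `"fragment_degradation"`, `"agg_K"`, `"Knar"`, or any field of
#' [tdp43_params()].
#'
#' @param p A `tdp43_params` object.
#' @param name Parameter name or alias (character).
#' @param factor Multiplicative factor (finite, >= 0).
#' @return A perturbed `tdp43_params` object (`calibrated` flag cleared).
#' @export
scale_param <- function(p, name, factor) {
  stopifnot(inherits(p, "tdp43_params"), is.finite(factor), factor >= 0)
  fields <- param_alias(name)
  for (f in fields) p[[f]] <- p[[f]] * factor
  attr(p, "calibrated") <- FALSE
  validate_params(p)
  p
}

param_alias <- function(name) {
  alias <- list(
    transcription = "pre",
    mrna_degradation = "d_m",
    translation = "k_tl",
    nuclear_import = "k_imp",
    nuclear_export = "k_exp",
    protein_degradation = c("d_n", "d_c"),
    fragment_degradation = "d_f",
    aggregate_degradation = "d_a"
  )
  name <- gsub("-", "_", name)
  if (name %in% names(alias)) return(alias[[name]])
  if (name %in% names(formals(tdp43_params))) return(name)
  stop("unknown parameter or alias: ", name)
}

#' Sweepable parameter names
#'
#' The set of quantities varied in the robustness/fragility sweeps.
#' @return Character vector of aliases accepted by [parameter_sweep()].
#' @export
sweepable_parameters <- function() {
  c("transcription", "mrna_degradation", "translation", "nuclear_import",
    "nuclear_export", "protein_degradation", "fragment_degradation",
    "agg_K", "Knar")
}

#' Regulation mode: NAR(+) or NAR(-)
#'
#' In the NAR(+) model the canonical mRNA production is repressed by nuclear
#' TDP-43 through a Hill function. The NAR(-) control freezes production at
#' the baseline repression factor (`nar_off_factor`), so that the two
#' variants share an identical unperturbed steady state.
#'
#' @param mode `"NAR_ON"` or `"NAR_OFF"`.
#' @param nar_off_factor Frozen production multiplier used when
#'   `mode = "NAR_OFF"`; must lie in (0, 1]. For a baseline calibrated with
#'   NMD fraction Y this is `1 - Y` (0.35 by default).
#' @return An object of class `regulation_mode`.
#' @export
regulation_mode <- function(mode = c("NAR_ON", "NAR_OFF"),
                            nar_off_factor = 0.35) {
  mode <- match.arg(mode)
  if (!is.finite(nar_off_factor) || nar_off_factor <= 0 || nar_off_factor > 1)
    stop("nar_off_factor must lie in (0, 1]")
  structure(list(mode = mode, nar_off_factor = nar_off_factor),
            class = "regulation_mode")
}

as_regulation_mode <- function(mode, p = NULL) {
  if (inherits(mode, "regulation_mode")) return(mode)
  off <- if (!is.null(p)) hill_repression(p, 1) else 0.35
  regulation_mode(mode, nar_off_factor = off)
}

#' Cell state vector
#'
#' Constructs the 8-pool state of the model (all in relative units):
#' canonical endogenous mRNA, nuclear and cytoplasmic endogenous protein,
#' fragmented and aggregated TDP-43, and the exogenous (transgene) mRNA and
#' protein pools.
#'
#' @param mRNA,nTDP,cTDP,frag,agg,mRNA_ex,nTDP_ex,cTDP_ex Non-negative pool
#'   amounts (r.u.).
#' @return Named numeric vector of length 8.
#' @export
cell_state <- function(mRNA = 1, nTDP = 1, cTDP = 0.15, frag = 0, agg = 0,
                       mRNA_ex = 0, nTDP_ex = 0, cTDP_ex = 0) {
  s <- c(mRNA = mRNA, nTDP = nTDP, cTDP = cTDP, frag = frag, agg = agg,
         mRNA_ex = mRNA_ex, nTDP_ex = nTDP_ex, cTDP_ex = cTDP_ex)
  validate_state(s)
  s
}

state_names <- function() {
  c("mRNA", "nTDP", "cTDP", "frag", "agg", "mRNA_ex", "nTDP_ex", "cTDP_ex")
}

validate_state <- function(s) {
  if (!all(state_names() %in% names(s)))
    stop("cell state must contain pools: ",
         paste(state_names(), collapse = ", "))
  if (any(!is.finite(s))) stop("non-finite cell state component")
  if (any(s < 0)) stop("negative cell state component: ",
                       paste(names(s)[s < 0], collapse = ", "))
  invisible(s)
}
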