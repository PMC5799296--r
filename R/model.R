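#' @keywords internal
hill_repression <- function(p, nTDP_total) {
  Kn <- p$Knar^p$n_hill
  Kn / (Kn + nTDP_total^p$n_hill)
}

#' Canonical mRNA production flux under negative autoregulation
#'
#' Production of the canonical (translatable) TARDBP mRNA. Nuclear TDP-43
#' diverts pre-mRNA towards alternatively spliced isoforms destined for
#' nonsense-mediated decay; the surviving canonical flux is modelled as a
#' repressive Hill function of total nuclear TDP-43 (endogenous plus
#' exogenous, since exogenous protein participates in repression):
#' `k2 * pre * Knar^n / (Knar^n + N^n)`. In the NAR(-) control the factor is
#' frozen at `nar_off_factor`.
#'
#' @param p A [tdp43_params()] object.
#' @param nTDP_total Total nuclear TDP-43 (r.u., >= 0).
#' @param mode A [regulation_mode()] object or mode string.
#' @return Production flux (r.u. per time).
#' @export
nar_production_rate <- function(p, nTDP_total, mode = "NAR_ON") {
  if (any(!is.finite(nTDP_total)) || any(nTDP_total < 0))
    stop("nTDP_total must be finite and non-negative")
  mode <- as_regulation_mode(mode, p)
  if (mode$mode == "NAR_ON") {
    p$k2 * p$pre * hill_repression(p, nTDP_total)
  } else {
    rep(p$k2 * p$pre * mode$nar_off_factor, length(nTDP_total))
  }
}

#' Fragmentation flux
#'
#' First-order production of fragmented TDP-43 from the total cytoplasmic
#' pool: `k_frag * cTDP_total`.
#'
#' @param p A [tdp43_params()] object.
#' @param cTDP_total Total cytoplasmic TDP-43 (r.u., >= 0).
#' @return Fragment production flux (r.u. per time).
#' @export
fragmentation_rate <- function(p, cTDP_total) {
  if (any(!is.finite(cTDP_total)) || any(cTDP_total < 0))
    stop("cTDP_total must be finite and non-negative")
  p$k_frag * cTDP_total
}

#' Aggregation flux
#'
#' Concentration-dependent (phase-transition-like) aggregation of cytoplasmic
#' TDP-43, seeded cooperatively by accumulated fragments:
#' \deqn{k_{agg} \frac{c^{n_{agg}}}{aggK^{n_{agg}} + c^{n_{agg}}}
#'   \left(1 + frag\_enh \frac{F^{n_{seed}}}{F_{half}^{n_{seed}} +
#'   F^{n_{seed}}}\right)}
#' The flux is strictly increasing in both arguments, vanishes at zero
#' cytoplasmic protein, and is bounded by `k_agg * (1 + frag_enh)`. The
#' cooperative, saturating fragment term represents nucleation-like seeding:
#' together with fragmentation of aggregates (`k_fa`) it forms the
#' positive-feedback loop that gives the model its two stable (healthy and
#' pathological) regimes.
#'
#' @param p A [tdp43_params()] object.
#' @param cTDP_total Total cytoplasmic TDP-43 (r.u., >= 0).
#' @param frag Fragmented TDP-43 (r.u., >= 0).
#' @return Aggregate production flux (r.u. per time).
#' @export
aggregation_rate <- function(p, cTDP_total, frag) {
  if (any(!is.finite(cTDP_total)) || any(cTDP_total < 0))
    stop("cTDP_total must be finite and non-negative")
  if (any(!is.finite(frag)) || any(frag < 0))
    stop("frag must be finite and non-negative")
  cn <- cTDP_total^p$n_agg
  sat <- cn / (p$agg_K^p$n_agg + cn)
  sat[cTDP_total == 0] <- 0
  fn <- frag^p$n_seed
  enh <- 1 + p$frag_enh * fn / (p$F_half^p$n_seed + fn)
  p$k_agg * sat * enh
}

#' Time derivative of the cell state
#'
#' The right-hand side of the reaction network ODE. Loss fluxes shared by the
#' endogenous and exogenous cytoplasmic pools (fragmentation, aggregation)
#' are apportioned proportionally to pool size.
#'
#' @param p A [tdp43_params()] object.
#' @param s A [cell_state()] vector.
#' @param mode A [regulation_mode()] object or mode string.
#' @return Named numeric vector of derivatives (r.u. per time).
#' @export
tdp43_rhs <- function(p, s, mode = "NAR_ON") {
  mode <- as_regulation_mode(mode, p)
  n_tot <- s[["nTDP"]] + s[["nTDP_ex"]]
  c_tot <- s[["cTDP"]] + s[["cTDP_ex"]]
  prod <- nar_production_rate(p, n_tot, mode)
  fr <- fragmentation_rate(p, c_tot)
  ag <- aggregation_rate(p, c_tot, s[["frag"]])
  share_c <- if (c_tot > 0) s[["cTDP"]] / c_tot else 0
  share_ex <- if (c_tot > 0) s[["cTDP_ex"]] / c_tot else 0
  c(
    mRNA = prod - p$d_m * s[["mRNA"]],
    nTDP = p$k_imp * s[["cTDP"]] - (p$k_exp + p$d_n) * s[["nTDP"]],
    cTDP = p$k_tl * s[["mRNA"]] + p$k_exp * s[["nTDP"]] -
      (p$k_imp + p$d_c) * s[["cTDP"]] - share_c * (fr + ag),
    frag = fr + p$k_fa * s[["agg"]] + p$k_upt * p$F_ext - p$d_f * s[["frag"]],
    agg = ag - (p$k_fa + p$d_a) * s[["agg"]],
    mRNA_ex = p$k_tc_ex - p$d_m_ex * s[["mRNA_ex"]],
    nTDP_ex = p$k_imp * s[["cTDP_ex"]] - (p$k_exp + p$d_n) * s[["nTDP_ex"]],
    cTDP_ex = p$k_tl * s[["mRNA_ex"]] + p$k_exp * s[["nTDP_ex"]] -
      (p$k_imp + p$d_c) * s[["cTDP_ex"]] - share_ex * (fr + ag)
  )
}

# rhs in the argument order expected by deSolve; clips the tiny negative
# excursions an adaptive integrator can produce before evaluating rate laws
rhs_desolve <- function(t, y, parms) {
  names(y) <- state_names()
  y[y < 0] <- 0 # adaptive steps may probe slightly below zero
  list(unname(tdp43_rhs(parms$p, y, parms$mode)))
}

#' Numerical Jacobian of the network at a state
#'
#' Central finite differences of [tdp43_rhs()]; used for steady-state Newton
#' iterations and local stability analysis.
#'
#' @inheritParams tdp43_rhs
#' @param eps Relative step size.
#' @return 8 x 8 Jacobian matrix.
#' @export
tdp43_jacobian <- function(p, s, mode = "NAR_ON", eps = 1e-6) {
  mode <- as_regulation_mode(mode, p)
  n <- length(s)
  J <- matrix(0, n, n, dimnames = list(names(s), names(s)))
  for (j in seq_len(n)) {
    h <- eps * max(abs(s[[j]]), 1e-3)
    up <- s; up[[j]] <- s[[j]] + h
    dn <- s; dn[[j]] <- max(s[[j]] - h, 0)
    J[, j] <- (tdp43_rhs(p, up, mode) - tdp43_rhs(p, dn, mode)) /
      (up[[j]] - dn[[j]])
  }
  J
}
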