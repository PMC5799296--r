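#' Perturbation of a kinetic parameter over a time window
#'
#' A multiplicative scaling of one parameter (or alias, see [scale_param()])
#' switched on at `onset` and off at `offset` (never, by default). Factor 0
#' is allowed (e.g. translation arrest).
#'
#' @param parameter Parameter name or alias.
#' @param factor Multiplicative factor (finite, >= 0).
#' @param onset Switch-on time (relative time units).
#' @param offset Switch-off time (> onset), or `Inf`.
#' @return An object of class `tdp43_perturbation`.
#' @export
perturbation <- function(parameter, factor, onset = 0, offset = Inf) {
  param_alias(parameter) # validates the name
  if (!is.finite(factor) || factor < 0) stop("factor must be finite and >= 0")
  if (!is.finite(onset) || onset < 0) stop("onset must be finite and >= 0")
  if (offset <= onset) stop("offset must exceed onset")
  structure(list(parameter = parameter, factor = factor,
                 onset = onset, offset = offset),
            class = "tdp43_perturbation")
}

as_schedule <- function(schedule) {
  if (inherits(schedule, "tdp43_perturbation")) schedule <- list(schedule)
  stopifnot(all(vapply(schedule, inherits, TRUE, "tdp43_perturbation")))
  schedule
}

# parameters in force at time t (interval convention: [onset, offset))
effective_params <- function(p, schedule, t) {
  for (pert in schedule) {
    if (t >= pert$onset && t < pert$offset)
      p <- scale_param(p, pert$parameter, pert$factor)
  }
  p
}

schedule_switch_times <- function(schedule, horizon) {
  tt <- unlist(lapply(schedule, function(x) c(x$onset, x$offset)))
  sort(unique(c(0, tt[is.finite(tt) & tt < horizon], horizon)))
}

#' Integrate the model over a perturbation schedule
#'
#' Solves the network ODE with `deSolve::lsoda` (stiff-capable), holding
#' parameters piecewise-constant between perturbation switch points and
#' restarting the integrator at each switch, so pool values are continuous
#' across switches and only derivatives jump.
#'
#' @param p A [tdp43_params()] object.
#' @param s0 Initial [cell_state()].
#' @param mode A [regulation_mode()] or mode string.
#' @param schedule List of [perturbation()]s (possibly empty).
#' @param horizon End time (> 0).
#' @param n_out Approximate number of output points across the horizon.
#' @param rtol,atol Integration tolerances.
#' @return An object of class `tdp43_trajectory`: fields `times` (vector),
#'   `states` (matrix, one row per time point), `schedule`, `mode`,
#'   `clipped` (count of negative excursions below -1e-12 clipped to 0).
#' @export
integrate_model <- function(p, s0 = baseline_state(p), mode = "NAR_ON",
                            schedule = list(), horizon = 1000, n_out = 400,
                            rtol = 1e-10, atol = 1e-12) {
  stopifnot(horizon > 0)
  mode <- as_regulation_mode(mode, p)
  schedule <- as_schedule(schedule)
  validate_state(s0)
  switches <- schedule_switch_times(schedule, horizon)
  times_all <- NULL
  states_all <- NULL
  clipped <- 0L
  x <- s0
  for (k in seq_len(length(switches) - 1)) {
    t0 <- switches[k]
    t1 <- switches[k + 1]
    pk <- effective_params(p, schedule, t0)
    nt <- max(ceiling(n_out * (t1 - t0) / horizon), 2)
    tseq <- seq(t0, t1, length.out = nt)
    sol <- deSolve::lsoda(y = unname(x), times = tseq, func = rhs_desolve,
                          parms = list(p = pk, mode = mode),
                          rtol = rtol, atol = atol, maxsteps = 50000)
    if (attr(sol, "istate")[1] < 0)
      stop("integrator failure at t = ", format(max(sol[, 1]), digits = 6))
    states <- sol[, -1, drop = FALSE]
    colnames(states) <- state_names()
    if (any(!is.finite(states)) || any(states > 1e6)) {
      bad <- colnames(states)[apply(!is.finite(states) | states > 1e6, 2,
                                    any)]
      stop("divergence: pool(s) ", paste(bad, collapse = ", "),
           " exceeded 1e6 r.u.")
    }
    neg <- states < 0
    clipped <- clipped + sum(neg & states < -1e-12)
    states[neg] <- 0
    x <- stats::setNames(states[nrow(states), ], state_names())
    keep <- if (k == 1) seq_len(nrow(states)) else -1L
    times_all <- c(times_all, sol[keep, 1])
    states_all <- rbind(states_all, states[keep, , drop = FALSE])
  }
  structure(list(times = times_all, states = states_all,
                 schedule = schedule, mode = mode, clipped = clipped),
            class = "tdp43_trajectory")
}

#' Final state of a trajectory
#' @param traj A `tdp43_trajectory`.
#' @return Named state vector at the last time point.
#' @export
final_state <- function(traj) {
  stats::setNames(traj$states[nrow(traj$states), ], colnames(traj$states))
}

#' @export
as.data.frame.tdp43_trajectory <- function(x, ...) {
  df <- data.frame(time = x$times, x$states, check.names = FALSE)
  for (i in seq_along(x$schedule)) {
    pert <- x$schedule[[i]]
    df[[paste0("active_", pert$parameter, "_x", pert$factor)]] <-
      as.integer(x$times >= pert$onset & x$times < pert$offset)
  }
  df
}

#' @export
print.tdp43_trajectory <- function(x, ...) {
  cat("TDP-43 trajectory: ", length(x$times), " points over [",
      format(min(x$times)), ", ", format(max(x$times)), "] r.t.u., mode ",
      x$mode$mode, ", ", length(x$schedule), " perturbation(s)\n", sep = "")
  cat("final state:\n")
  print(round(final_state(x), 5))
  invisible(x)
}

#' @export
plot.tdp43_trajectory <- function(x, pools = c("mRNA", "nTDP", "cTDP",
                                               "frag", "agg"),
                                  log_time = FALSE, ...) {
  cols <- c(mRNA = "#4477AA", nTDP = "#CC3311", cTDP = "#EE7733",
            frag = "#AA3377", agg = "#228833", mRNA_ex = "#66CCEE",
            nTDP_ex = "#BBBBBB", cTDP_ex = "#999933")
  pools <- intersect(pools, colnames(x$states))
  graphics::matplot(x$times, x$states[, pools, drop = FALSE], type = "l",
                    lty = 1, lwd = 2, col = cols[pools],
                    xlab = "time (relative units)",
                    ylab = "amount (relative units)",
                    log = if (log_time) "x" else "", ...)
  graphics::legend("topright", legend = pools, col = cols[pools],
                   lwd = 2, bty = "n")
  invisible(x)
}

#' Settle the model to a steady state by integration
#'
#' Integrates past the last perturbation switch and then in growing chunks
#' until the rhs residual satisfies `max |rhs| < tol * (1 + max |state|)`,
#' a horizon cap is reached (reported as unsettled, never silently returned
#' as a steady state), or the trajectory diverges. Settling is defined by the
#' residual rather than pool-value flatness to avoid mistaking the long
#' quasi-plateau before an aggregation collapse for convergence.
#'
#' @inheritParams integrate_model
#' @param tol Residual tolerance.
#' @param horizon_cap Maximum total integration time.
#' @param cross_check Cross-check the settled point against a Newton root
#'   ([steady_state()]) started from it.
#' @return A `tdp43_steady` object with an extra logical field `settled`.
#' @export
settle <- function(p, s0 = baseline_state(p), mode = "NAR_ON",
                   schedule = list(), tol = 1e-8, horizon_cap = 1e6,
                   cross_check = FALSE) {
  mode <- as_regulation_mode(mode, p)
  schedule <- as_schedule(schedule)
  finite_sw <- unlist(lapply(schedule, function(x)
    c(x$onset, if (is.finite(x$offset)) x$offset)))
  t_sched <- if (length(finite_sw)) max(finite_sw) else 0
  x <- s0
  t_now <- 0
  if (t_sched > 0) {
    traj <- integrate_model(p, x, mode, schedule, horizon = t_sched,
                            n_out = 50)
    x <- final_state(traj)
    t_now <- t_sched
  }
  p_end <- effective_params(p, schedule, t_sched)
  chunk <- 500
  settled <- FALSE
  while (t_now < horizon_cap) {
    r <- tdp43_rhs(p_end, x, mode)
    if (max(abs(r)) < tol * (1 + max(abs(x)))) {
      settled <- TRUE
      break
    }
    chunk <- min(chunk, horizon_cap - t_now)
    traj <- integrate_model(p_end, x, mode, list(), horizon = chunk,
                            n_out = 8)
    x <- final_state(traj)
    t_now <- t_now + chunk
    chunk <- chunk * 2
  }
  r <- tdp43_rhs(p_end, x, mode)
  settled <- settled || max(abs(r)) < tol * (1 + max(abs(x)))
  ev <- eigen(tdp43_jacobian(p_end, x, mode), only.values = TRUE)$values
  out <- structure(list(state = x, residual = max(abs(r)),
                        stable = if (settled) max(Re(ev)) < tol else NA,
                        eigenvalues = ev, converged = settled,
                        settled = settled, time = t_now),
                   class = "tdp43_steady")
  if (!settled) return(out)
  if (cross_check) {
    root <- steady_state(p_end, mode, guess = x)
    if (root$converged &&
        max(abs(root$state - x)) > 1e-4 * (1 + max(abs(x))))
      warning("settled state and Newton root differ by more than 1e-4")
    if (root$converged) out$state <- root$state
  }
  out
}

#' Translation-arrest half-life assay
#'
#' From the calibrated baseline steady state, sets the translation rate to
#' zero at t = 0, tracks total soluble protein (nuclear + cytoplasmic,
#' endogenous + exogenous; fragments and aggregates excluded — they are at
#' most trace at baseline so the choice is numerically immaterial), and
#' returns the first time the total falls to half its initial value, located
#' by root-bracketing on a dense monotone stretch of the solution.
#'
#' @param p A calibrated [tdp43_params()] object or a `tdp43_model`.
#' @param mode A [regulation_mode()] or mode string.
#' @return Half-life in relative time units.
#' @export
half_life_assay <- function(p, mode = "NAR_ON") {
  if (inherits(p, "tdp43_model")) p <- p$params
  s0 <- baseline_state(p)
  total <- function(s) s[["nTDP"]] + s[["cTDP"]] + s[["nTDP_ex"]] +
    s[["cTDP_ex"]]
  t0_total <- total(s0)
  p0 <- scale_param(p, "translation", 0)
  # effective soluble decay rate sets the horizon scale
  r0 <- s0[["cTDP"]] / max(s0[["nTDP"]], 1e-12)
  lam <- (p$d_n + r0 * (p$d_c + p$k_frag)) / (1 + r0)
  horizon <- 3 * log(2) / lam
  for (i in 1:6) {
    traj <- integrate_model(p0, s0, mode, list(), horizon = horizon,
                            n_out = 1500)
    tot <- traj$states[, "nTDP"] + traj$states[, "cTDP"] +
      traj$states[, "nTDP_ex"] + traj$states[, "cTDP_ex"]
    if (tot[length(tot)] >= t0_total)
      stop("total soluble protein is non-decreasing under translation ",
           "arrest; parameters are mis-specified")
    idx <- which(tot <= t0_total / 2)[1]
    if (!is.na(idx)) {
      f <- stats::splinefun(traj$times, tot - t0_total / 2)
      return(stats::uniroot(f, lower = traj$times[max(idx - 1, 1)],
                            upper = traj$times[idx],
                            tol = 1e-10 * horizon)$root)
    }
    horizon <- horizon * 4
  }
  stop("total soluble protein did not reach half its initial value")
}
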