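test_that("baseline is invariant under integration", {
  p <- quick_params()
  traj <- integrate_model(p, horizon = 500)
  dev <- sweep(traj$states, 2, baseline_state(p), "-")
  expect_lt(max(abs(dev)), 1e-6)
})

test_that("perturbation schedules: validation and switch continuity", {
  expect_error(perturbation("transcription", -1), "factor")
  expect_error(perturbation("transcription", 0.5, onset = 10, offset = 5),
               "offset")
  p <- quick_params()
  sched <- list(perturbation("transcription", 0.5, onset = 50,
                             offset = 150))
  traj <- integrate_model(p, schedule = sched, horizon = 300, n_out = 600)
  # pools are continuous across the onset switch: the change over the first
  # post-switch step is bounded by the post-switch derivative (only the
  # derivative jumps, not the state)
  i_on <- max(which(traj$times <= 50))
  jump <- abs(traj$states[i_on + 1, ] - traj$states[i_on, ])
  dt <- traj$times[i_on + 1] - traj$times[i_on]
  p_on <- scale_param(p, "transcription", 0.5)
  rate <- max(abs(tdp43_rhs(p_on, stats::setNames(traj$states[i_on, ],
                                                  colnames(traj$states)))))
  expect_lt(max(jump), 2 * rate * dt + 1e-8)
  # mRNA drops after onset, recovers after offset
  expect_lt(min(traj$states[, "mRNA"]), 0.95)
  expect_equal(unname(traj$states[nrow(traj$states), "mRNA"]), 1,
               tolerance = 1e-2)
})

test_that("halving then restoring transcription returns to baseline", {
  p <- quick_params()
  sched <- list(perturbation("transcription", 0.5, onset = 0,
                             offset = 3000))
  traj <- integrate_model(p, schedule = sched, horizon = 9000)
  expect_state_equal(final_state(traj), baseline_state(p), tol = 1e-3)
})

test_that("settle agrees with the Newton root on monostable scenarios", {
  p <- quick_params()
  for (fac in c(0.6, 1.5)) {
    ps <- scale_param(p, "transcription", fac)
    st <- settle(ps, s0 = baseline_state(p))
    expect_true(st$settled)
    root <- steady_state(ps, guess = st$state)
    expect_true(root$converged)
    expect_lt(max(abs(root$state - st$state)), 1e-4)
  }
})

test_that("settling is reported honestly when the horizon cap is hit", {
  p <- quick_params()
  st <- settle(scale_param(p, "transcription", 0.5),
               s0 = baseline_state(p), horizon_cap = 5)
  expect_false(st$settled)
  expect_false(st$converged)
})

test_that("divergence is reported with the offending pool", {
  p <- quick_params()
  p$k_tc_ex <- 1e7 # absurd exogenous production
  attr(p, "calibrated") <- FALSE
  expect_error(integrate_model(p, horizon = 1000), "mRNA_ex")
})

test_that("steady-state solver: convergence, stability, error paths", {
  p <- quick_params()
  st <- steady_state(p, guess = baseline_state(p))
  expect_true(st$converged)
  expect_true(st$stable)
  expect_lt(st$residual, 1e-10)
  # from a nearby guess it recovers the same root
  st2 <- steady_state(p, guess = baseline_state(p) * 1.1 + 0.01)
  expect_lt(max(abs(st2$state - st$state)), 1e-6)
})

test_that("2-pool transport subsystem root matches the closed form", {
  # isolated linear subsystem: production k into cytoplasm, exchange,
  # first-order decay; steady state solvable by hand
  p <- tdp43_params(pre = 1, k2 = 1, Knar = 1e9, n_hill = 1, d_m = 1,
                    k_tl = 0.1, k_imp = 5, k_exp = 1, d_n = 0.05,
                    d_c = 0.25, k_frag = 0, k_agg = 0, k_fa = 0)
  st <- steady_state(p, guess = cell_state(1, 0.5, 0.5, 0, 0))
  m_ss <- 1 # production ~ k2*pre (Knar huge), d_m = 1
  # cTDP: k_tl*m + k_exp*n = (k_imp + d_c)*c ; nTDP: k_imp*c = (k_exp+d_n)*n
  c_ss <- 0.1 * m_ss / (5 + 0.25 - 5 * 1 / (1 + 0.05))
  n_ss <- 5 * c_ss / 1.05
  expect_equal(unname(st$state[["mRNA"]]), m_ss, tolerance = 1e-6)
  expect_equal(unname(st$state[["cTDP"]]), c_ss, tolerance = 1e-6)
  expect_equal(unname(st$state[["nTDP"]]), n_ss, tolerance = 1e-6)
})

test_that("half-life: single-pool decay gives ln 2 / d_n exactly", {
  p <- tdp43_params(k_imp = 0, k_exp = 0, d_n = 0.02, d_c = 0.1,
                    k_frag = 0, k_agg = 0, k_fa = 0)
  attr(p, "baseline") <- cell_state(mRNA = 1, nTDP = 1, cTDP = 0,
                                    frag = 0, agg = 0)
  expect_equal(half_life_assay(p), log(2) / 0.02, tolerance = 1e-4)
})

test_that("half-life: fast-exchange two-pool decay matches slow eigenvalue", {
  d_n <- 0.02
  d_c <- 0.1
  k_imp <- 50
  k_exp <- 10
  p <- tdp43_params(k_imp = k_imp, k_exp = k_exp, d_n = d_n, d_c = d_c,
                    k_frag = 0, k_agg = 0, k_fa = 0, k_tl = 0)
  r0 <- (k_exp + d_n) / k_imp
  attr(p, "baseline") <- cell_state(mRNA = 0, nTDP = 1, cTDP = r0,
                                    frag = 0, agg = 0)
  A <- matrix(c(-(k_exp + d_n), k_imp, k_exp, -(k_imp + d_c)), 2, 2,
              byrow = TRUE)
  lam_slow <- -max(eigen(A, only.values = TRUE)$values)
  expect_equal(half_life_assay(p), log(2) / lam_slow, tolerance = 1e-2)
})

test_that("integration tolerances do not move settled levels", {
  p <- quick_params()
  ps <- scale_param(p, "transcription", 0.7)
  t1 <- integrate_model(ps, s0 = baseline_state(p), horizon = 4000,
                        rtol = 1e-8, atol = 1e-10)
  t2 <- integrate_model(ps, s0 = baseline_state(p), horizon = 4000,
                        rtol = 1e-11, atol = 1e-13)
  expect_lt(max(abs(final_state(t1) - final_state(t2))), 1e-5)
})

test_that("trajectories are deterministic and non-negative", {
  p <- quick_params()
  sched <- list(perturbation("agg_K", 0.6, onset = 0))
  a <- integrate_model(p, schedule = sched, horizon = 2000)
  b <- integrate_model(p, schedule = sched, horizon = 2000)
  expect_identical(a$states, b$states)
  expect_true(all(a$states >= 0))
})

test_that("trajectory export carries pools and perturbation flags", {
  p <- quick_params()
  sched <- list(perturbation("transcription", 0.5, onset = 10))
  traj <- integrate_model(p, schedule = sched, horizon = 100)
  df <- as.data.frame(traj)
  expect_true(all(c("time", "mRNA", "nTDP", "cTDP", "frag", "agg",
                    "active_transcription_x0.5") %in% names(df)))
  expect_equal(df$active_transcription_x0.5,
               as.integer(df$time >= 10))
  f <- tempfile(fileext = ".csv")
  write_trajectory_csv(traj, f)
  back <- utils::read.csv(f)
  expect_equal(nrow(back), nrow(df))
  expect_equal(back$nTDP, unname(traj$states[, "nTDP"]), tolerance = 1e-12)
  unlink(f)
})
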