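# Scenario mechanics and qualitative structure. The quantitative agreement
# with published steady-state values is covered by test-acceptance.R; these
# tests exercise trivial anchors, monotonicity and algebraic
# self-consistency of each scenario.

test_that("unperturbed 'knockout' (factor 1) leaves the baseline unchanged", {
  m <- cached_model()
  st <- heterozygous_ko(m, factor = 1)
  expect_true(st$settled)
  expect_state_equal(st$state, m$baseline, tol = 1e-6)
})

test_that("NAR(-) heterozygous knockout drops nuclear TDP-43 to ~half", {
  m <- cached_model()
  st <- heterozygous_ko(m, mode = "NAR_OFF")
  expect_true(st$settled)
  expect_equal(unname(st$state[["nTDP"]]), 0.5, tolerance = 0.1)
})

test_that("transgenic at dose zero reproduces the baseline", {
  m <- cached_model()
  st <- transgenic(m, exo_level = 0)
  expect_true(st$settled)
  expect_state_equal(st$state, m$baseline, tol = 1e-6)
})

test_that("transgenic endogenous mRNA obeys the Hill flux balance", {
  m <- cached_model()
  p <- m$params
  st <- transgenic(m, exo_level = 1)
  N_tot <- st$state[["nTDP"]] + st$state[["nTDP_ex"]]
  m_expected <- nar_production_rate(p, N_tot) / p$d_m
  expect_equal(unname(st$state[["mRNA"]]), unname(m_expected),
               tolerance = 1e-6)
  # the exogenous mRNA settles at its isolated level
  expect_equal(unname(st$state[["mRNA_ex"]]), 1, tolerance = 1e-6)
})

test_that("transgene dose-response: endogenous repression and aggregation", {
  m <- cached_model()
  dr <- transgenic_dose_response(m, levels = c(0, 0.5, 1, 1.5))
  expect_equal(dr$exo_level, c(0, 0.5, 1, 1.5))
  # endogenous nuclear TDP-43 strictly decreasing with dose
  expect_true(all(diff(dr$nTDP_endo) < 0))
  # aggregates non-decreasing with dose
  expect_true(all(diff(dr$agg) > -1e-9))
  # dose 0 is the baseline
  expect_equal(dr$nTDP_endo[1], unname(m$baseline[["nTDP"]]),
               tolerance = 1e-6)
})

test_that("parameter sweep: grid, baseline anchor, degenerate cases", {
  m <- cached_model()
  sw <- parameter_sweep(m, "transcription", steps = 5, lo = 0.5, hi = 2)
  expect_equal(sw$factor, seq(0.5, 2, length.out = 5))
  expect_true(all(diff(sw$factor) > 0))
  expect_true(all(sw$settled))
  # nothing swept at factor 1: untouched baseline in both modes
  for (md in c("NAR_ON", "NAR_OFF")) {
    one <- parameter_sweep(m, "transcription", mode = md, lo = 1, hi = 1,
                           steps = 2)
    expect_equal(one$nTDP, rep(unname(m$baseline[["nTDP"]]), 2),
                 tolerance = 1e-6)
  }
  expect_error(parameter_sweep(m, "no_such_parameter"), "must be one of")
})

test_that("redundancy stages preserve the baseline steady state exactly", {
  m <- cached_model()
  stages <- redundancy_stages(m)
  expect_length(stages, 5)
  expect_equal(vapply(stages, `[[`, 0, "Y"), c(0.2, 0.5, 0.65, 0.75, 0.8))
  for (s in stages) {
    # the baseline state is an equilibrium of every stage's parameter set
    expect_lt(max(abs(tdp43_rhs(s$params, m$baseline))), 1e-9)
    # Knar re-solved so repression passes 1 - Y at baseline
    expect_equal(tdp43nar:::hill_repression(s$params, 1), 1 - s$Y,
                 tolerance = 1e-12)
    expect_equal(s$redundancy, 1 / (1 - s$Y))
  }
  # the Y = 0.65 stage is the calibrated default itself
  s3 <- stages[[3]]
  expect_equal(s3$params$Knar, m$params$Knar, tolerance = 1e-12)
  expect_equal(s3$params$pre, m$params$pre, tolerance = 1e-12)
  expect_error(redundancy_stages(m, c(0.5, 0.4)), "increasing")
  expect_error(redundancy_stages(m, c(0, 0.5)), "in \\(0, 1\\)")
})

test_that("untreated aggregation-prone disturbance stays in disease", {
  m <- cached_model()
  th <- therapy(m, reduction = 1)
  expect_true(th$disease_reached)
  expect_equal(th$final_class$label, "disease")
  # vicious-cycle signature: canonical mRNA above baseline while nuclear
  # TDP-43 is below it
  expect_gt(th$final_state[["mRNA"]], 1)
  expect_lt(th$final_state[["nTDP"]], 1)
})

test_that("propagation: zero extracellular fragments leave the baseline", {
  m <- cached_model()
  pr <- propagation(m, F_ext_levels = c(1e-6, 1), reduction = 0.5)
  expect_equal(nrow(pr), 4)
  base_row <- pr[pr$F_ext == 1e-6 & pr$reduction == 1, ]
  expect_equal(base_row$nTDP, unname(m$baseline[["nTDP"]]),
               tolerance = 1e-3)
  expect_equal(base_row$class, "healthy")
})

test_that("scenarios are pure: repeated calls agree exactly", {
  m <- cached_model()
  a <- heterozygous_ko(m)
  b <- heterozygous_ko(m)
  expect_identical(a$state, b$state)
})
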