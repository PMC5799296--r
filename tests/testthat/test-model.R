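test_that("NAR production follows the repressive Hill law", {
  p <- tdp43_params(k2 = 2, pre = 0.5, Knar = 0.8, n_hill = 4)
  # no repressor -> maximal production k2 * pre
  expect_equal(nar_production_rate(p, 0), 2 * 0.5)
  # at the suppression coefficient production is halved
  expect_equal(nar_production_rate(p, 0.8), 0.5 * 2 * 0.5)
  # deep repression: N = 10 Knar with n = 4 leaves 1/(1 + 10^4)
  expect_equal(nar_production_rate(p, 8), 2 * 0.5 / (1 + 1e4))
  # strictly decreasing in nuclear TDP-43
  N <- seq(0, 5, by = 0.01)
  expect_true(all(diff(nar_production_rate(p, N)) < 0))
  expect_error(nar_production_rate(p, -0.1))
})

test_that("calibrated baseline passes 1 - NMD fraction of maximal production", {
  p <- quick_params()
  expect_equal(nar_production_rate(p, 1) / (p$k2 * p$pre), 0.35,
               tolerance = 1e-12)
})

test_that("NAR(-) freezes production at the baseline repression factor", {
  p <- tdp43_params()
  off <- regulation_mode("NAR_OFF", nar_off_factor = 0.35)
  for (N in c(0, 0.5, 1, 3)) {
    expect_equal(nar_production_rate(p, N, off), 0.35 * p$k2 * p$pre)
  }
  # the frozen factor must make the two modes agree at baseline
  on_at_base <- nar_production_rate(tdp43_params(), 1)
  off_factor <- on_at_base / (tdp43_params()$k2 * tdp43_params()$pre)
  expect_equal(nar_production_rate(tdp43_params(), 1,
                                   regulation_mode("NAR_OFF", off_factor)),
               on_at_base)
  expect_error(regulation_mode("NAR_OFF", 0))
  expect_error(regulation_mode("NAR_OFF", 1.5))
})

test_that("fragmentation is first-order in cytoplasmic TDP-43", {
  p <- tdp43_params(k_frag = 0.02)
  expect_equal(fragmentation_rate(p, 0), 0)
  expect_equal(fragmentation_rate(p, 0.15), 0.02 * 0.15)
  expect_equal(fragmentation_rate(p, 0.30), 2 * fragmentation_rate(p, 0.15))
  expect_error(fragmentation_rate(p, -1))
})

test_that("aggregation flux: monotone, bounded, aggregation-prone shift", {
  p <- tdp43_params(k_agg = 0.01, agg_K = 0.3, n_agg = 2, frag_enh = 500,
                    F_half = 0.2, n_seed = 4)
  expect_equal(aggregation_rate(p, 0, 0), 0)
  expect_equal(aggregation_rate(p, 0, 5), 0)
  # strictly increasing in both arguments
  cc <- seq(0.01, 1, by = 0.01)
  expect_true(all(diff(aggregation_rate(p, cc, 0.1)) > 0))
  ff <- seq(0, 1, by = 0.01)
  expect_true(all(diff(aggregation_rate(p, 0.2, ff)) > 0))
  # bounded by the saturated flux
  expect_true(all(aggregation_rate(p, cc, 10) <
                    p$k_agg * (1 + p$frag_enh)))
  # lowering agg_K to 0.6x strictly increases the flux (aggregation-prone)
  p06 <- scale_param(p, "agg_K", 0.6)
  expect_true(all(aggregation_rate(p06, cc, 0.05) >
                    aggregation_rate(p, cc, 0.05)))
  # the seeding enhancement reaches half its maximum at F_half
  expect_equal(aggregation_rate(p, 0.2, p$F_half) /
                 aggregation_rate(p, 0.2, 0),
               1 + p$frag_enh / 2, tolerance = 1e-12)
})

test_that("rhs matches independent term-by-term hand arithmetic", {
  p <- tdp43_params(pre = 0.9, k2 = 2.5, Knar = 0.7, n_hill = 3, d_m = 0.8,
                    k_tl = 0.12, k_imp = 5, k_exp = 0.9, d_n = 0.04,
                    d_c = 0.2, k_frag = 0.03, d_f = 0.6, k_agg = 0.02,
                    agg_K = 0.25, n_agg = 2, frag_enh = 40, F_half = 0.15,
                    n_seed = 4, k_fa = 0.5, k_tc_ex = 0.3, d_m_ex = 0.8,
                    k_upt = 0.05, F_ext = 2, d_a = 0.01)
  s <- cell_state(mRNA = 0.7, nTDP = 0.6, cTDP = 0.2, frag = 0.09,
                  agg = 0.3, mRNA_ex = 0.4, nTDP_ex = 0.25, cTDP_ex = 0.1)
  # hand evaluation, written out without reusing package helpers
  N <- 0.6 + 0.25
  C <- 0.2 + 0.1
  hill <- 0.7^3 / (0.7^3 + N^3)
  prod <- 2.5 * 0.9 * hill
  fr <- 0.03 * C
  sat <- C^2 / (0.25^2 + C^2)
  enh <- 1 + 40 * 0.09^4 / (0.15^4 + 0.09^4)
  ag <- 0.02 * sat * enh
  share <- 0.2 / C
  expected <- c(
    mRNA = prod - 0.8 * 0.7,
    nTDP = 5 * 0.2 - (0.9 + 0.04) * 0.6,
    cTDP = 0.12 * 0.7 + 0.9 * 0.6 - (5 + 0.2) * 0.2 - share * (fr + ag),
    frag = fr + 0.5 * 0.3 + 0.05 * 2 - 0.6 * 0.09,
    agg = ag - (0.5 + 0.01) * 0.3,
    mRNA_ex = 0.3 - 0.8 * 0.4,
    nTDP_ex = 5 * 0.1 - (0.9 + 0.04) * 0.25,
    cTDP_ex = 0.12 * 0.4 + 0.9 * 0.25 - (5 + 0.2) * 0.1 -
      (1 - share) * (fr + ag)
  )
  expect_equal(tdp43_rhs(p, s), expected, tolerance = 1e-14)
})

test_that("empty-cell state has only production inflows", {
  p <- tdp43_params(k_tc_ex = 0.2)
  s0 <- cell_state(mRNA = 0, nTDP = 0, cTDP = 0, frag = 0, agg = 0)
  d <- tdp43_rhs(p, s0)
  expect_equal(unname(d[["mRNA"]]), p$k2 * p$pre)
  expect_equal(unname(d[["mRNA_ex"]]), 0.2)
  expect_true(all(d[c("nTDP", "cTDP", "frag", "agg")] == 0))
})

test_that("flux conservation at the constructed baseline", {
  p <- quick_params()
  b <- baseline_state(p)
  expect_lt(max(abs(tdp43_rhs(p, b))), 1e-12)
  # term-by-term: production into each pool equals loss out of it
  prod_mRNA <- nar_production_rate(p, b[["nTDP"]])
  expect_equal(prod_mRNA, p$d_m * b[["mRNA"]], tolerance = 1e-9)
  expect_equal(p$k_imp * b[["cTDP"]],
               (p$k_exp + p$d_n) * b[["nTDP"]], tolerance = 1e-9)
  expect_equal(fragmentation_rate(p, b[["cTDP"]]) +
                 p$k_fa * b[["agg"]],
               p$d_f * b[["frag"]], tolerance = 1e-9)
  expect_equal(aggregation_rate(p, b[["cTDP"]], b[["frag"]]),
               (p$k_fa + p$d_a) * b[["agg"]], tolerance = 1e-9)
})

test_that("parameter container enforces invariants", {
  expect_error(tdp43_params(d_m = -1), "negative")
  expect_error(tdp43_params(n_hill = 0.5), "n_hill")
  expect_error(cell_state(mRNA = -0.1), "negative")
  p <- quick_params()
  expect_true(is_calibrated(p))
  # perturbation clears the calibrated-baseline flag
  expect_false(is_calibrated(scale_param(p, "transcription", 0.5)))
  # ratio violation rejected for objects claiming calibration
  bad <- p
  bad$d_c <- bad$d_c * 2
  expect_error(tdp43nar:::validate_params(bad), "ratio")
})

test_that("aliases scale the intended fields", {
  p <- tdp43_params()
  expect_equal(scale_param(p, "transcription", 0.5)$pre, p$pre * 0.5)
  p2 <- scale_param(p, "protein_degradation", 2)
  expect_equal(p2$d_n, 2 * p$d_n)
  expect_equal(p2$d_c, 2 * p$d_c)
  expect_equal(scale_param(p, "Knar", 2)$Knar, 2 * p$Knar)
  expect_error(scale_param(p, "nonsense", 2), "unknown parameter")
})
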