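test_that("SBML export/import round-trips the rhs to machine precision", {
  p <- quick_params()
  doc <- export_sbml(p, mode = "NAR_ON")
  back <- import_sbml(doc)
  expect_true(back$report$ok)
  expect_equal(back$mode$mode, "NAR_ON")
  # identical derivatives on random non-negative states
  set.seed(42)
  for (i in 1:100) {
    s <- stats::setNames(stats::runif(8, 0, 2), tdp43nar:::state_names())
    expect_lt(max(abs(tdp43_rhs(p, s) - tdp43_rhs(back$params, s))), 1e-10)
  }
  # the reconstructed set carries the calibrated baseline
  expect_true(is_calibrated(back$params))
  expect_state_equal(baseline_state(back$params), baseline_state(p),
                     tol = 1e-12)
})

test_that("NAR(-) mode and its frozen factor survive the round trip", {
  p <- quick_params()
  off <- regulation_mode("NAR_OFF", nar_off_factor = 0.35)
  back <- import_sbml(export_sbml(p, mode = off))
  expect_equal(back$mode$mode, "NAR_OFF")
  expect_equal(back$mode$nar_off_factor, 0.35)
  set.seed(7)
  s <- stats::setNames(stats::runif(8, 0, 2), tdp43nar:::state_names())
  expect_lt(max(abs(tdp43_rhs(p, s, off) -
                      tdp43_rhs(back$params, s, back$mode))), 1e-10)
})

test_that("exported document is structurally complete SBML L3", {
  p <- quick_params()
  f <- tempfile(fileext = ".xml")
  export_sbml(p, file = f)
  doc <- xml2::read_xml(f)
  expect_match(xml2::xml_attr(doc, "level"), "3")
  ns <- xml2::xml_ns_strip(doc)
  species <- xml2::xml_attr(
    xml2::xml_find_all(doc, ".//listOfSpecies/species"), "id")
  expect_setequal(species, c(tdp43nar:::state_names(), "F_ext"))
  reactions <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  expect_equal(length(reactions),
               length(tdp43nar:::sbml_reaction_table()))
  # every reaction carries a kinetic law with MathML content
  laws <- xml2::xml_find_all(doc, ".//reaction/kineticLaw/*")
  expect_equal(length(laws), length(reactions))
  unlink(f)
})

test_that("structural mismatches produce a report, not a crash", {
  minimal <- xml2::read_xml(paste0(
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version2/core" ',
    'level="3" version="2"><model id="m">',
    '<listOfSpecies><species id="A" compartment="c" initialAmount="1" ',
    'hasOnlySubstanceUnits="true" boundaryCondition="false" ',
    'constant="false"/></listOfSpecies>',
    '<listOfParameters><parameter id="nar_on" value="1" constant="true"/>',
    "</listOfParameters>",
    '<listOfReactions><reaction id="decay" reversible="false">',
    "<listOfReactants>",
    '<speciesReference species="A" stoichiometry="1" constant="true"/>',
    "</listOfReactants></reaction></listOfReactions>",
    "</model></sbml>"))
  res <- import_sbml(minimal)
  expect_false(res$report$ok)
  expect_null(res$params)
  expect_true("decay" %in% res$report$extra_reactions)
  expect_true("mrna_production" %in% res$report$missing_reactions)
  expect_true("pre" %in% res$report$missing_parameters)
  expect_error(import_sbml(textConnection("not xml")))
})

test_that("parameter JSON round-trip is exact and carries provenance", {
  p <- quick_params()
  f <- tempfile(fileext = ".json")
  params_to_json(p, f)
  q <- params_from_json(f)
  expect_equal(unlist(p[names(p)]), unlist(q[names(q)]),
               tolerance = 1e-15)
  expect_true(is_calibrated(q))
  expect_state_equal(baseline_state(q), baseline_state(p), tol = 1e-15)
  unlink(f)
})

test_that("parameter hash is deterministic and value-sensitive", {
  p <- quick_params()
  expect_identical(params_hash(p), params_hash(p))
  q <- scale_param(p, "transcription", 0.5)
  expect_false(identical(params_hash(p), params_hash(q)))
  expect_match(params_hash(p), "^[0-9a-f]{8}$")
})
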