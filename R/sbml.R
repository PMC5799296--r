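# Minimal MathML builders (content MathML, as required inside <kineticLaw>)
mml_ci <- function(x) paste0("<ci> ", x, " </ci>")
mml_cn <- function(x) paste0("<cn> ", format(x, digits = 17), " </cn>")
mml_apply <- function(op, ...) {
  paste0("<apply><", op, "/>", paste0(..., collapse = ""), "</apply>")
}
mml_math <- function(body) {
  paste0('<math xmlns="http://www.w3.org/1998/Math/MathML">', body, "</math>")
}

# The reaction table: id, reactants, products, modifiers, kinetic law (MathML
# body built from parameter/species ids). share terms for the apportioned
# fragmentation/aggregation losses are written out explicitly.
sbml_reaction_table <- function(nar_on = TRUE) {
  hill <- mml_apply(
    "times", mml_ci("k2"), mml_ci("pre"),
    mml_apply("divide",
              mml_apply("power", mml_ci("Knar"), mml_ci("n_hill")),
              mml_apply("plus",
                        mml_apply("power", mml_ci("Knar"), mml_ci("n_hill")),
                        mml_apply("power",
                                  mml_apply("plus", mml_ci("nTDP"),
                                            mml_ci("nTDP_ex")),
                                  mml_ci("n_hill")))))
  frozen <- mml_apply("times", mml_ci("k2"), mml_ci("pre"),
                      mml_ci("nar_off_factor"))
  c_tot <- mml_apply("plus", mml_ci("cTDP"), mml_ci("cTDP_ex"))
  sat <- mml_apply(
    "divide",
    mml_apply("power", c_tot, mml_ci("n_agg")),
    mml_apply("plus", mml_apply("power", mml_ci("agg_K"), mml_ci("n_agg")),
              mml_apply("power", c_tot, mml_ci("n_agg"))))
  enh <- mml_apply(
    "plus", mml_cn(1),
    mml_apply("times", mml_ci("frag_enh"),
              mml_apply("divide",
                        mml_apply("power", mml_ci("frag"),
                                  mml_ci("n_seed")),
                        mml_apply("plus",
                                  mml_apply("power", mml_ci("F_half"),
                                            mml_ci("n_seed")),
                                  mml_apply("power", mml_ci("frag"),
                                            mml_ci("n_seed"))))))
  agg_flux <- function(pool) {
    mml_apply("times", mml_ci("k_agg"), sat, enh,
              mml_apply("divide", mml_ci(pool), c_tot))
  }
  first_order <- function(k, s) mml_apply("times", mml_ci(k), mml_ci(s))
  list(
    mrna_production = list(react = character(), prod = "mRNA",
                           mod = c("nTDP", "nTDP_ex"),
                           math = if (nar_on) hill else frozen),
    mrna_decay = list(react = "mRNA", prod = character(), mod = character(),
                      math = first_order("d_m", "mRNA")),
    translation = list(react = character(), prod = "cTDP", mod = "mRNA",
                       math = first_order("k_tl", "mRNA")),
    nuclear_import = list(react = "cTDP", prod = "nTDP", mod = character(),
                          math = first_order("k_imp", "cTDP")),
    nuclear_export = list(react = "nTDP", prod = "cTDP", mod = character(),
                          math = first_order("k_exp", "nTDP")),
    ntdp_decay = list(react = "nTDP", prod = character(), mod = character(),
                      math = first_order("d_n", "nTDP")),
    ctdp_decay = list(react = "cTDP", prod = character(), mod = character(),
                      math = first_order("d_c", "cTDP")),
    fragmentation = list(react = "cTDP", prod = "frag", mod = character(),
                         math = first_order("k_frag", "cTDP")),
    fragmentation_ex = list(react = "cTDP_ex", prod = "frag",
                            mod = character(),
                            math = first_order("k_frag", "cTDP_ex")),
    aggregation = list(react = "cTDP", prod = "agg",
                       mod = c("cTDP_ex", "frag"),
                       math = agg_flux("cTDP")),
    aggregation_ex = list(react = "cTDP_ex", prod = "agg",
                          mod = c("cTDP", "frag"),
                          math = agg_flux("cTDP_ex")),
    agg_fragmentation = list(react = "agg", prod = "frag", mod = character(),
                             math = first_order("k_fa", "agg")),
    agg_decay = list(react = "agg", prod = character(), mod = character(),
                     math = first_order("d_a", "agg")),
    frag_decay = list(react = "frag", prod = character(), mod = character(),
                      math = first_order("d_f", "frag")),
    fragment_uptake = list(react = character(), prod = "frag",
                           mod = "F_ext",
                           math = first_order("k_upt", "F_ext")),
    mrna_ex_production = list(react = character(), prod = "mRNA_ex",
                              mod = character(), math = mml_ci("k_tc_ex")),
    mrna_ex_decay = list(react = "mRNA_ex", prod = character(),
                         mod = character(),
                         math = first_order("d_m_ex", "mRNA_ex")),
    translation_ex = list(react = character(), prod = "cTDP_ex",
                          mod = "mRNA_ex",
                          math = first_order("k_tl", "mRNA_ex")),
    nuclear_import_ex = list(react = "cTDP_ex", prod = "nTDP_ex",
                             mod = character(),
                             math = first_order("k_imp", "cTDP_ex")),
    nuclear_export_ex = list(react = "nTDP_ex", prod = "cTDP_ex",
                             mod = character(),
                             math = first_order("k_exp", "nTDP_ex")),
    ntdp_ex_decay = list(react = "nTDP_ex", prod = character(),
                         mod = character(),
                         math = first_order("d_n", "nTDP_ex")),
    ctdp_ex_decay = list(react = "cTDP_ex", prod = character(),
                         mod = character(),
                         math = first_order("d_c", "cTDP_ex"))
  )
}

species_compartments <- function() {
  c(mRNA = "cytoplasm", nTDP = "nucleus", cTDP = "cytoplasm",
    frag = "cytoplasm", agg = "cytoplasm", mRNA_ex = "cytoplasm",
    nTDP_ex = "nucleus", cTDP_ex = "cytoplasm", F_ext = "extracellular")
}

#' Export the model as SBML Level 3
#'
#' Writes the full reaction network (species, compartments, parameters,
#' reactions with kinetic laws as content MathML) as an SBML Level 3
#' Version 2 core document. The regulation mode is encoded by the
#' `nar_on` parameter (1/0) together with `nar_off_factor`; species initial
#' amounts carry the calibrated baseline state when one is attached.
#'
#' @param p A [tdp43_params()] object or a `tdp43_model`.
#' @param mode A [regulation_mode()] or mode string.
#' @param file Path to write to, or `NULL` to return the `xml2` document.
#' @return The `xml2` document, invisibly if written to `file`.
#' @export
export_sbml <- function(p, mode = "NAR_ON", file = NULL) {
  if (inherits(p, "tdp43_model")) {
    mode <- model_mode(p, mode)
    p <- p$params
  }
  mode <- as_regulation_mode(mode, p)
  s0 <- attr(p, "baseline")
  if (is.null(s0)) s0 <- stats::setNames(rep(0, 8), state_names())
  comp <- species_compartments()
  amounts <- c(s0, F_ext = p$F_ext)

  species_xml <- paste0(vapply(names(comp), function(id) {
    sprintf(paste0('<species id="%s" compartment="%s" initialAmount="%s" ',
                   'hasOnlySubstanceUnits="true" boundaryCondition="%s" ',
                   'constant="%s"/>'),
            id, comp[[id]], format(amounts[[id]], digits = 17),
            tolower(id == "F_ext"), tolower(id == "F_ext"))
  }, character(1)), collapse = "")

  par_ids <- c(names(p), "nar_off_factor", "nar_on")
  par_vals <- c(unlist(p), nar_off_factor = mode$nar_off_factor,
                nar_on = as.numeric(mode$mode == "NAR_ON"))
  params_xml <- paste0(vapply(par_ids, function(id) {
    sprintf('<parameter id="%s" value="%s" constant="true"/>',
            id, format(par_vals[[id]], digits = 17))
  }, character(1)), collapse = "")

  refs <- function(ids, tag) {
    if (!length(ids)) return("")
    inner <- paste0(vapply(ids, function(s) {
      if (tag == "modifierSpeciesReference")
        sprintf('<%s species="%s"/>', tag, s)
      else
        sprintf('<%s species="%s" stoichiometry="1" constant="true"/>',
                tag, s)
    }, character(1)), collapse = "")
    inner
  }
  rx <- sbml_reaction_table(mode$mode == "NAR_ON")
  reactions_xml <- paste0(vapply(names(rx), function(id) {
    r <- rx[[id]]
    paste0(sprintf('<reaction id="%s" reversible="false">', id),
           if (length(r$react)) paste0("<listOfReactants>",
                                       refs(r$react, "speciesReference"),
                                       "</listOfReactants>") else "",
           if (length(r$prod)) paste0("<listOfProducts>",
                                      refs(r$prod, "speciesReference"),
                                      "</listOfProducts>") else "",
           if (length(r$mod)) paste0("<listOfModifiers>",
                                     refs(r$mod,
                                          "modifierSpeciesReference"),
                                     "</listOfModifiers>") else "",
           "<kineticLaw>", mml_math(r$math), "</kineticLaw>",
           "</reaction>")
  }, character(1)), collapse = "")

  doc_str <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version2/core" ',
    'level="3" version="2">',
    '<model id="tdp43_nar" name="TDP-43 autoregulation network">',
    "<listOfCompartments>",
    paste0(sprintf('<compartment id="%s" constant="true" size="1"/>',
                   unique(comp)), collapse = ""),
    "</listOfCompartments>",
    "<listOfSpecies>", species_xml, "</listOfSpecies>",
    "<listOfParameters>", params_xml, "</listOfParameters>",
    "<listOfReactions>", reactions_xml, "</listOfReactions>",
    "</model></sbml>")
  doc <- xml2::read_xml(doc_str)
  if (!is.null(file)) {
    xml2::write_xml(doc, file)
    return(invisible(doc))
  }
  doc
}

#' Import an SBML document of the TDP-43 network
#'
#' Reads parameters by id and verifies the reaction topology (reaction ids
#' and their reactant/product sets) against the expected network. When the
#' topology matches, a [tdp43_params()] object (with baseline state taken
#' from the species initial amounts, when consistent) and the regulation
#' mode are reconstructed; otherwise `params` is `NULL` and the structural
#' report names the missing/extra reactions.
#'
#' @param doc Path to an SBML file or an `xml2` document.
#' @return List with `params`, `mode`, and `report` (fields `ok`,
#'   `missing_reactions`, `extra_reactions`, `mismatched_reactions`,
#'   `missing_parameters`).
#' @export
import_sbml <- function(doc) {
  if (is.character(doc)) doc <- xml2::read_xml(doc)
  doc <- xml2::xml_ns_strip(doc)
  par_nodes <- xml2::xml_find_all(doc, ".//listOfParameters/parameter")
  vals <- stats::setNames(
    as.numeric(xml2::xml_attr(par_nodes, "value")),
    xml2::xml_attr(par_nodes, "id"))
  needed <- names(formals(tdp43_params))
  needed <- setdiff(needed, "calibrated")
  missing_par <- setdiff(needed, names(vals))

  rx_nodes <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  found <- lapply(rx_nodes, function(n) {
    list(id = xml2::xml_attr(n, "id"),
         react = sort(xml2::xml_attr(
           xml2::xml_find_all(n, "./listOfReactants/speciesReference"),
           "species")),
         prod = sort(xml2::xml_attr(
           xml2::xml_find_all(n, "./listOfProducts/speciesReference"),
           "species")))
  })
  names(found) <- vapply(found, `[[`, "", "id")
  nar_on <- isTRUE(vals[["nar_on"]] == 1)
  expected <- sbml_reaction_table(nar_on)
  missing_rx <- setdiff(names(expected), names(found))
  extra_rx <- setdiff(names(found), names(expected))
  common <- intersect(names(expected), names(found))
  mismatched <- common[vapply(common, function(id) {
    !identical(sort(expected[[id]]$react), found[[id]]$react) ||
      !identical(sort(expected[[id]]$prod), found[[id]]$prod)
  }, logical(1))]
  report <- list(ok = length(missing_rx) == 0 && length(extra_rx) == 0 &&
                   length(mismatched) == 0 && length(missing_par) == 0,
                 missing_reactions = missing_rx,
                 extra_reactions = extra_rx,
                 mismatched_reactions = mismatched,
                 missing_parameters = missing_par)
  if (!report$ok) return(list(params = NULL, mode = NULL, report = report))

  args <- as.list(vals[needed])
  p <- do.call(tdp43_params, args)
  sp_nodes <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  init <- stats::setNames(
    as.numeric(xml2::xml_attr(sp_nodes, "initialAmount")),
    xml2::xml_attr(sp_nodes, "id"))
  if (all(state_names() %in% names(init))) {
    s0 <- init[state_names()]
    if (all(is.finite(s0)) &&
        max(abs(tdp43_rhs(p, s0, "NAR_ON"))) < 1e-6)
      attr(p, "baseline") <- s0
  }
  ratio_ok <- abs(p$d_c / p$d_n - 5) < 1e-9 &&
    abs(p$d_n / p$d_m - 0.05) < 1e-9 &&
    abs(p$d_f / p$d_c - 3) < 1e-9 && abs(p$d_a / p$d_n - 0.2) < 1e-9
  attr(p, "calibrated") <- ratio_ok && !is.null(attr(p, "baseline"))
  mode <- regulation_mode(if (nar_on) "NAR_ON" else "NAR_OFF",
                          nar_off_factor = vals[["nar_off_factor"]])
  list(params = p, mode = mode, report = report)
}
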