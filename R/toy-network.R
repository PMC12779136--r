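#' Build the toy central-carbon metabolic network
#'
#' A desk-scale stoichiometric model used throughout the test surface of
#' the pipeline. The core carries glucose uptake, a lumped glycolysis,
#' lactate fermentation (so Warburg-like states are expressible), a lumped
#' TCA/oxidative branch, a pentose-phosphate-like NADPH producer, demand
#' reactions for the ATP/NADH/NADPH currency pools, an ATP-consuming
#' gluconeogenesis marker reaction, and a biomass objective. Optional
#' branches add a three-step lysosomal degradation chain (subsystem
#' "Heparan sulfate degradation") and an extracellular-to-cytosol
#' fatty-acid transport/activation pair with multi-gene isozyme GPRs —
#' the branches that carry planted signal in the simulation studies.
#'
#' Each metabolite carries a small integer conservation `tag` (its carbon
#' count; 0 for currency cofactors) so that mass balance of every
#' non-boundary reaction can be asserted exactly.
#'
#' @param include_gluconeogenesis_marker Include the pyruvate-to-G6P
#'   marker reaction (default `TRUE`).
#' @param include_lysosomal_branch Include the heparan-sulfate degradation
#'   chain (default `TRUE`).
#' @param include_fatty_acid_branch Include fatty-acid transport and
#'   activation (default `TRUE`).
#' @param flux_cap Default magnitude cap for internal reaction bounds
#'   (default 1000).
#' @return A [metabolic_network()] whose biomass optimum is strictly
#'   positive under default bounds.
#' @export
build_toy_network <- function(include_gluconeogenesis_marker = TRUE,
                              include_lysosomal_branch = TRUE,
                              include_fatty_acid_branch = TRUE,
                              flux_cap = 1000) {
  stopifnot(flux_cap > 0)
  met <- function(id, compartment, tag) {
    list(id = id, compartment = compartment, tag = tag)
  }
  mets <- list(
    met("glc_e", "e", 6), met("glc_c", "c", 6),
    met("g6p_c", "c", 6), met("pyr_c", "c", 3),
    met("lac_c", "c", 3), met("lac_e", "e", 3),
    met("atp_c", "c", 0), met("nadh_c", "c", 0), met("nadph_c", "c", 0),
    met("co2_c", "c", 1),
    met("biomass_c", "c", 6)
  )
  rx <- list()
  add <- function(id, stoich, lb, ub, subsystem, gpr = "") {
    rx[[length(rx) + 1L]] <<- list(
      id = id, stoichiometry = stoich, lower_bound = lb, upper_bound = ub,
      subsystem = subsystem, gpr_text = gpr
    )
  }
  cap <- flux_cap

  # boundary + core carbon metabolism
  add("EX_glc", c(glc_e = -1), -10, cap, "Exchange/demand reactions")
  add("GLCt", c(glc_e = -1, glc_c = 1), 0, cap, "Transport reactions",
      "SLC2A1")
  add("HK", c(glc_c = -1, atp_c = -1, g6p_c = 1), 0, cap,
      "Glycolysis / Gluconeogenesis", "HK1 or HK2")
  add("GLYC", c(g6p_c = -1, pyr_c = 2, atp_c = 3, nadh_c = 2), 0, cap,
      "Glycolysis / Gluconeogenesis", "GAPDH and PKM")
  add("LDH", c(pyr_c = -1, nadh_c = -1, lac_c = 1), 0, cap,
      "Glycolysis / Gluconeogenesis", "LDHA or LDHB")
  add("LACt", c(lac_c = -1, lac_e = 1), 0, cap, "Transport reactions",
      "SLC16A1")
  add("EX_lac", c(lac_e = -1), -cap, cap, "Exchange/demand reactions")
  add("TCA", c(pyr_c = -1, co2_c = 3, atp_c = 12, nadh_c = 4), 0, cap,
      "Tricarboxylic acid cycle", "CS and SDHA")
  add("DM_co2", c(co2_c = -1), 0, cap, "Exchange/demand reactions")
  add("PPP", c(g6p_c = -1, nadph_c = 2, pyr_c = 2), 0, cap,
      "Pentose phosphate pathway", "G6PD")
  add("DM_atp", c(atp_c = -1), 0, cap, "Exchange/demand reactions")
  add("DM_nadh", c(nadh_c = -1), 0, cap, "Exchange/demand reactions")
  add("DM_nadph", c(nadph_c = -1), 0, cap, "Exchange/demand reactions")

  if (include_gluconeogenesis_marker) {
    # ATP-consuming pyruvate -> G6P analog; active flux here marks a
    # gluconeogenic (biologically implausible "healthy, fed") state
    add("GNG", c(pyr_c = -2, atp_c = -6, g6p_c = 1), 0, cap,
        "Glycolysis / Gluconeogenesis", "PCK1 or FBP1")
  }

  if (include_lysosomal_branch) {
    mets <- c(mets, list(
      met("hs_e", "e", 12), met("hs_l", "l", 12),
      met("hsdeg1_l", "l", 12), met("hsdeg2_l", "l", 12)
    ))
    add("EX_hs", c(hs_e = -1), -5, cap, "Exchange/demand reactions")
    add("HSt", c(hs_e = -1, hs_l = 1), 0, cap, "Transport reactions")
    add("HSD1", c(hs_l = -1, hsdeg1_l = 1), 0, cap,
        "Heparan sulfate degradation", "SGSH")
    add("HSD2", c(hsdeg1_l = -1, hsdeg2_l = 1), 0, cap,
        "Heparan sulfate degradation", "NAGLU")
    # terminal step: degradation products are stored in the lysosome
    # (boundary-style sink), so branch activity does not feed carbon
    # back into central metabolism
    add("HSD3", c(hsdeg2_l = -1), 0, cap,
        "Heparan sulfate degradation", "GUSB")
  }

  if (include_fatty_acid_branch) {
    mets <- c(mets, list(met("fa_e", "e", 24), met("fa_c", "c", 24)))
    add("EX_fa", c(fa_e = -1), -5, cap, "Exchange/demand reactions")
    add("FAt", c(fa_e = -1, fa_c = 1), 0, cap, "Transport reactions",
        "FABP1 or FABP4 or SLC27A1")
    # lumped activation/commitment step (boundary-style sink):
    # activated fatty acid leaves the modeled pool toward membrane
    # synthesis, keeping branch flux decoupled from central carbon
    add("FAact", c(fa_c = -1), 0, cap,
        "Fatty acid activation", "ACSL1 or ACSBG1")
  }

  add("BIOMASS", c(atp_c = -10, pyr_c = -2, nadph_c = -1, biomass_c = 1),
      0, cap, "Artificial reactions")
  add("EX_biomass", c(biomass_c = -1), 0, cap, "Exchange/demand reactions")

  metabolites <- tibble::tibble(
    id = vapply(mets, `[[`, character(1), "id"),
    name = vapply(mets, `[[`, character(1), "id"),
    compartment = vapply(mets, `[[`, character(1), "compartment"),
    tag = vapply(mets, `[[`, numeric(1), "tag")
  )
  reactions <- tibble::tibble(
    id = vapply(rx, `[[`, character(1), "id"),
    lower_bound = vapply(rx, `[[`, numeric(1), "lower_bound"),
    upper_bound = vapply(rx, `[[`, numeric(1), "upper_bound"),
    subsystem = vapply(rx, `[[`, character(1), "subsystem"),
    gpr_text = vapply(rx, `[[`, character(1), "gpr_text"),
    stoichiometry = lapply(rx, `[[`, "stoichiometry")
  )
  metabolic_network(
    id = "toy_ccm",
    metabolites = metabolites,
    reactions = reactions,
    objective = "BIOMASS",
    bound_cap = flux_cap
  )
}

#' Genes appearing in the toy network's GPR rules
#'
#' @param net A `metabolic_network` (defaults to the full toy network).
#' @return Sorted character vector of gene ids.
#' @export
network_genes <- function(net = build_toy_network()) {
  sort(unique(unlist(lapply(net$reactions$gpr, gpr_genes))))
}
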