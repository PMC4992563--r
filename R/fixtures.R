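# The toy overflow model: an analytically tractable stand-in for the core
# model used in fast tests. Respiration yields 3 biomass precursors per
# glucose; the overflow route yields 1 precursor plus one secreted acetate
# (itself worth 1 precursor when respired), so full respiration strictly
# beats overflow + acetate respiration and the parsimonious optimum is
# unique for generic bounds. The biomass drain consumes 30 precursors per
# unit growth flux, giving mu = 1/h at a glucose cap of 10 mmol/gDW/h.
# Carbon is balanced (glucose C6, acetate C2, precursor C2, CO2 C1), so
# carbon accounting is testable.

#' Build the toy overflow-metabolism model
#'
#' Deterministic, no I/O. Metabolites: glucose, acetate, oxygen, CO2
#' (external) and a biomass precursor; reactions: respiration
#' (glc + o2 -> 3 prec), overflow (glc -> prec + ac + 2 co2), acetate
#' respiration (ac + o2 -> prec), a biomass drain (30 prec -> growth) and 4
#' exchange reactions (glucose, acetate, oxygen, CO2; CO2 is unlimited).
#'
#' @return an `evofba_model` with 8 reactions, 5 metabolites, 4 exchanges.
#' @export
make_toy_model <- function() {
  mets <- c("glc_e", "ac_e", "o2_e", "co2_e", "prec_c")
  formula <- c("C6H12O6", "C2H3O2", "O2", "CO2", "C2H4O")
  rxns <- c("RESP", "OVER", "ACRESP", "BIOMASS_toy",
            "EX_glc_e", "EX_ac_e", "EX_o2_e", "EX_co2_e")
  S <- matrix(0, length(mets), length(rxns), dimnames = list(mets, rxns))
  S["glc_e", "RESP"] <- -1; S["o2_e", "RESP"] <- -1; S["prec_c", "RESP"] <- 3
  S["glc_e", "OVER"] <- -1; S["prec_c", "OVER"] <- 1
  S["ac_e", "OVER"] <- 1; S["co2_e", "OVER"] <- 2
  S["ac_e", "ACRESP"] <- -1; S["o2_e", "ACRESP"] <- -1
  S["prec_c", "ACRESP"] <- 1
  S["prec_c", "BIOMASS_toy"] <- -30
  S["glc_e", "EX_glc_e"] <- -1
  S["ac_e", "EX_ac_e"] <- -1
  S["o2_e", "EX_o2_e"] <- -1
  S["co2_e", "EX_co2_e"] <- -1
  lb <- c(0, 0, 0, 0, -10, -10, -20, -1000)
  ub <- c(1000, 1000, 1000, 1000, 1000, 1000, 1000, 1000)
  new_evofba_model("toy_overflow", mets, stats::setNames(formula, mets),
                   S, lb, ub, "BIOMASS_toy")
}

#' Path to a packaged model fixture
#'
#' @param name `"core_json"`, `"toy_sbml"` or `"toy_json"`.
#' @return file path inside the installed package.
#' @export
fixture_path <- function(name = c("core_json", "toy_sbml", "toy_json")) {
  name <- match.arg(name)
  fn <- switch(name, core_json = "e_coli_core.json",
               toy_sbml = "toy_overflow.xml", toy_json = "toy_overflow.json")
  system.file("extdata", fn, package = "evofba")
}
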