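# Stoichiometric model input: the constraint-based JSON dialect and SBML
# Level 3 + FBC. Models are plain lists of class "evofba_model"; fluxes use
# the toolchain sign convention internally (exchange flux < 0 = uptake); the
# single adapter to the simulator's uptake-positive convention lives in
# solve_fba().

# exchange ids that are never uptake-limited (phosphate, ammonia, water,
# protons, CO2): carbon and oxygen are the only budgeted resources
UNLIMITED_EXCHANGE_IDS <- c("EX_pi_e", "EX_nh4_e", "EX_h2o_e", "EX_h_e", "EX_co2_e")

# friendly substrate names accepted in configs and media, mapped to candidate
# exchange ids (core model first, toy fixture second where they differ)
SUBSTRATE_ALIASES <- list(
  glucose = c("EX_glc__D_e", "EX_glc_e"),
  acetate = "EX_ac_e",
  oxygen = "EX_o2_e",
  acetaldehyde = "EX_acald_e",
  alpha_ketoglutarate = "EX_akg_e",
  akg = "EX_akg_e",
  ethanol = "EX_etoh_e",
  formate = "EX_for_e",
  fructose = "EX_fru_e",
  fumarate = "EX_fum_e",
  glutamine = "EX_gln__L_e",
  glutamate = "EX_glu__L_e",
  lactate = "EX_lac__D_e",
  malate = "EX_mal__L_e",
  pyruvate = "EX_pyr_e",
  succinate = "EX_succ_e",
  phosphate = "EX_pi_e",
  ammonia = "EX_nh4_e",
  water = "EX_h2o_e",
  protons = "EX_h_e",
  co2 = "EX_co2_e"
)

#' Resolve a substrate name to an exchange reaction id
#'
#' Accepts either an exchange reaction id already present in the model or a
#' friendly substrate name such as `"glucose"`, `"acetate"`, `"oxygen"`.
#'
#' @param model an `evofba_model`.
#' @param name character vector of names or exchange ids.
#' @return character vector of exchange reaction ids.
#' @export
resolve_exchange <- function(model, name) {
  vapply(name, function(nm) {
    if (nm %in% model$reactions) return(nm)
    cand <- SUBSTRATE_ALIASES[[nm]]
    hit <- cand[cand %in% model$exchange_reactions]
    if (length(hit) == 0)
      stop("unknown substrate or exchange id: ", nm, call. = FALSE)
    hit[[1L]]
  }, character(1), USE.NAMES = TRUE)
}

new_evofba_model <- function(model_id, met_ids, met_formula, S, lb, ub,
                             biomass_reaction) {
  rxn_ids <- colnames(S)
  nz_per_col <- colSums(S != 0)
  # boundary reactions (one nonzero coefficient) are exchanges; the biomass
  # drain is a boundary pseudo-reaction but not an exchange
  exchange <- setdiff(rxn_ids[nz_per_col == 1L], biomass_reaction)
  unlimited <- intersect(UNLIMITED_EXCHANGE_IDS, exchange)
  m <- structure(list(
    model_id = model_id,
    metabolites = met_ids,
    met_formula = met_formula,
    reactions = rxn_ids,
    S = S,
    lb = stats::setNames(lb, rxn_ids),
    ub = stats::setNames(ub, rxn_ids),
    exchange_reactions = exchange,
    biomass_reaction = biomass_reaction,
    unlimited_exchanges = unlimited,
    mutable_exchanges = setdiff(exchange, unlimited),
    env = new.env(parent = emptyenv())
  ), class = "evofba_model")
  validate_model(m)
  m
}

#' Validate a stoichiometric model
#'
#' Checks the structural invariants: matrix dimensions match the metabolite
#' and reaction lists, the biomass reaction exists, and exchange subsets are
#' consistent.
#'
#' @param model an `evofba_model`.
#' @return the model, invisibly; errors otherwise.
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "evofba_model"))
  if (nrow(model$S) != length(model$metabolites))
    stop("stoichiometry rows != number of metabolites", call. = FALSE)
  if (ncol(model$S) != length(model$reactions))
    stop("stoichiometry columns != number of reactions", call. = FALSE)
  if (!model$biomass_reaction %in% model$reactions)
    stop("configuration error: biomass reaction '", model$biomass_reaction,
         "' not in model", call. = FALSE)
  if (!all(model$exchange_reactions %in% model$reactions))
    stop("exchange_reactions not a subset of reactions", call. = FALSE)
  if (!all(model$unlimited_exchanges %in% model$exchange_reactions))
    stop("unlimited_exchanges not a subset of exchange_reactions", call. = FALSE)
  invisible(model)
}

#' Load a stoichiometric model from file
#'
#' Reads either the JSON dialect used by constraint-based toolchains or SBML
#' Level 3 with the FBC package. Exchange reactions are identified as
#' boundary reactions (a single nonzero stoichiometric coefficient); the
#' exchanges for phosphate, ammonia, water, protons and CO2 are marked
#' unlimited, and the remaining exchanges (14 carbon sources plus oxygen for
#' the packaged core model) form the mutable uptake set.
#'
#' @param path file path.
#' @param format `"json"` or `"sbml"`; guessed from the file extension by
#'   default.
#' @return an `evofba_model`.
#' @export
load_model <- function(path, format = c("auto", "json", "sbml")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) "sbml" else "json"
  }
  if (!file.exists(path)) stop("model file not found: ", path, call. = FALSE)
  switch(format, json = load_model_json(path), sbml = load_model_sbml(path))
}

load_model_json <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(doc$metabolites) || is.null(doc$reactions))
    stop("format error: JSON model lacks 'metabolites' or 'reactions'",
         call. = FALSE)
  met_ids <- vapply(doc$metabolites, function(m) m$id, character(1))
  met_formula <- vapply(doc$metabolites, function(m) {
    f <- m$formula
    if (is.null(f)) "" else as.character(f)
  }, character(1))
  rxn_ids <- vapply(doc$reactions, function(r) r$id, character(1))
  S <- matrix(0, length(met_ids), length(rxn_ids),
              dimnames = list(met_ids, rxn_ids))
  lb <- numeric(length(rxn_ids)); ub <- numeric(length(rxn_ids))
  biomass <- character(0)
  for (k in seq_along(doc$reactions)) {
    r <- doc$reactions[[k]]
    mets <- r$metabolites
    bad <- setdiff(names(mets), met_ids)
    if (length(bad))
      stop("format error: reaction '", r$id,
           "' references undeclared metabolite '", bad[[1L]], "'",
           call. = FALSE)
    for (mid in names(mets)) S[mid, k] <- as.numeric(mets[[mid]])
    lb[k] <- if (is.null(r$lower_bound)) -1000 else as.numeric(r$lower_bound)
    ub[k] <- if (is.null(r$upper_bound)) 1000 else as.numeric(r$upper_bound)
    oc <- r$objective_coefficient
    if (!is.null(oc) && as.numeric(oc) != 0) biomass <- c(biomass, r$id)
  }
  if (length(biomass) == 0)
    stop("configuration error: no biomass (objective) reaction in model",
         call. = FALSE)
  mid <- if (is.null(doc$id)) tools::file_path_sans_ext(basename(path)) else doc$id
  new_evofba_model(mid, met_ids, met_formula, S, lb, ub, biomass[[1L]])
}

xattr <- function(attrs, name) {
  for (nm in c(paste0("fbc:", name), name)) {
    if (nm %in% names(attrs)) return(attrs[[nm]])
  }
  NA_character_
}

strip_sbml_prefix <- function(x, prefix) {
  sub(paste0("^", prefix, "_"), "", x)
}

load_model_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("format error: not parseable SBML: ",
                                           conditionMessage(e), call. = FALSE))
  sp_nodes <- xml2::xml_find_all(doc, ".//*[local-name()='species']")
  if (length(sp_nodes) == 0)
    stop("format error: SBML file declares no species", call. = FALSE)
  sp_attrs <- lapply(sp_nodes, xml2::xml_attrs)
  boundary <- vapply(sp_attrs, function(a)
    identical(a[["boundaryCondition"]], "true"), logical(1))
  raw_ids <- vapply(sp_attrs, function(a) a[["id"]], character(1))
  met_ids <- strip_sbml_prefix(raw_ids[!boundary], "M")
  met_formula <- vapply(sp_attrs[!boundary], function(a) {
    f <- xattr(a, "chemicalFormula")
    if (is.na(f)) "" else f
  }, character(1))
  # flux bound parameters
  par_nodes <- xml2::xml_find_all(doc, ".//*[local-name()='parameter']")
  par_val <- stats::setNames(
    vapply(par_nodes, function(p) as.numeric(xml2::xml_attr(p, "value")), numeric(1)),
    vapply(par_nodes, function(p) xml2::xml_attr(p, "id"), character(1)))
  rx_nodes <- xml2::xml_find_all(doc, ".//*[local-name()='reaction']")
  if (length(rx_nodes) == 0)
    stop("format error: SBML file declares no reactions", call. = FALSE)
  rxn_ids <- character(length(rx_nodes))
  S <- matrix(0, length(met_ids), length(rx_nodes))
  rownames(S) <- met_ids
  lb <- numeric(length(rx_nodes)); ub <- numeric(length(rx_nodes))
  for (k in seq_along(rx_nodes)) {
    node <- rx_nodes[[k]]
    attrs <- xml2::xml_attrs(node)
    rid <- strip_sbml_prefix(attrs[["id"]], "R")
    rxn_ids[k] <- rid
    add_side <- function(tag, sign) {
      refs <- xml2::xml_find_all(
        node, paste0("./*[local-name()='", tag, "']/*[local-name()='speciesReference']"))
      for (ref in refs) {
        sid <- strip_sbml_prefix(xml2::xml_attr(ref, "species"), "M")
        sto <- xml2::xml_attr(ref, "stoichiometry")
        sto <- if (is.na(sto)) 1 else as.numeric(sto)
        if (!sid %in% met_ids) {
          if (sid %in% strip_sbml_prefix(raw_ids[boundary], "M")) return(invisible())
          stop("format error: reaction '", rid,
               "' references undeclared metabolite '", sid, "'", call. = FALSE)
        }
        S[sid, k] <<- S[sid, k] + sign * sto
      }
    }
    add_side("listOfReactants", -1)
    add_side("listOfProducts", +1)
    lbp <- xattr(attrs, "lowerFluxBound"); ubp <- xattr(attrs, "upperFluxBound")
    lb[k] <- if (!is.na(lbp) && lbp %in% names(par_val)) par_val[[lbp]] else -1000
    ub[k] <- if (!is.na(ubp) && ubp %in% names(par_val)) par_val[[ubp]] else 1000
    rev <- attrs[["reversible"]]
    if (is.na(lbp) && identical(rev, "false")) lb[k] <- 0
  }
  colnames(S) <- rxn_ids
  fo <- xml2::xml_find_first(doc, ".//*[local-name()='fluxObjective']")
  if (inherits(fo, "xml_missing"))
    stop("configuration error: no biomass (objective) reaction in SBML model",
         call. = FALSE)
  biomass <- strip_sbml_prefix(xml2::xml_attr(fo, "reaction"), "R")
  mid <- xml2::xml_attr(xml2::xml_find_first(doc, ".//*[local-name()='model']"), "id")
  if (is.na(mid)) mid <- tools::file_path_sans_ext(basename(path))
  new_evofba_model(mid, met_ids, met_formula, S, lb, ub, biomass)
}

#' The packaged ancestor model (E. coli core metabolism)
#'
#' Loads the E. coli core metabolic model vendored with the package (95
#' reactions, 20 exchange reactions; central carbon metabolism with a biomass
#' pseudo-reaction). This is the ancestral "chassis" whose uptake capacities
#' evolve.
#'
#' @return an `evofba_model`.
#' @export
core_model <- function() {
  load_model(system.file("extdata", "e_coli_core.json", package = "evofba"),
             format = "json")
}

#' Carbon atoms per metabolite
#'
#' Parsed from chemical formulas; used for carbon accounting tests.
#'
#' @param model an `evofba_model`.
#' @return named numeric vector (NA where no formula is given).
#' @export
carbon_content <- function(model) {
  f <- model$met_formula
  n <- vapply(f, function(x) {
    if (is.na(x) || !nzchar(x)) return(NA_real_)
    m <- regmatches(x, regexec("C([0-9]*)([A-Z]|$)", x))[[1]]
    if (length(m) == 0) return(0)
    if (m[2] == "") 1 else as.numeric(m[2])
  }, numeric(1))
  stats::setNames(n, model$metabolites)
}
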