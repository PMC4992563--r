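# Post-processing: survivor statistics, lineage graphs, diauxic-shift
# detection, the 10-day flux-snapshot protocol and generation arithmetic.

# reactions of interest: glycolysis entry, TCA (aconitase), glyoxylate shunt
# (malate synthase) and acetate kinase — the reactions whose fluxes separate
# glucose and acetate specialists
REACTIONS_OF_INTEREST <- c("PGI", "ACONTb", "MALS", "ACKr")

#' Genotypes that survived at least `min_cycles` transfers
#'
#' @param result an `evofba_experiment`.
#' @param min_cycles minimum number of cycles with a post-dilution count of
#'   at least one cell.
#' @return integer vector of genotype ids, sorted.
#' @export
survivors <- function(result, min_cycles = 1L) {
  tab <- survivors_table(result, "post")
  if (is.null(tab)) return(integer(0))
  tab <- tab[tab$cells >= 1, ]
  cnt <- table(tab$genotype_id)
  sort(as.integer(names(cnt)[cnt >= min_cycles]))
}

peak_population <- function(result, which = "end") {
  tab <- survivors_table(result, which)
  if (is.null(tab)) return(numeric(0))
  tapply(tab$cells, tab$genotype_id, max)
}

#' Build the thresholded lineage graph
#'
#' Restricts the genotype registry to genotypes whose peak population reached
#' `min_peak_cells` (the ancestor is always retained as root), reconnects
#' each retained genotype to its nearest retained ancestor, and annotates
#' nodes with peak population and relative uptake capacities (v_max /
#' C_total) for glucose, acetate and oxygen. Edge weights are the log10 peak
#' start-of-cycle (post-dilution) population of the child.
#'
#' @param result an `evofba_experiment`.
#' @param min_peak_cells population threshold (the published figure uses
#'   1e5 cells at full scale).
#' @return an igraph graph of class `lineage_graph`.
#' @export
build_lineage_graph <- function(result, min_peak_cells = 1e5) {
  reg <- result$genotypes
  ids <- sort(vapply(reg, `[[`, integer(1), "id"))
  parent <- stats::setNames(
    vapply(reg, function(g) as.integer(g$parent_id), integer(1)),
    vapply(reg, function(g) as.character(g$id), character(1)))
  for (g in reg) {
    pid <- g$parent_id
    if (!is.na(pid) && !as.character(pid) %in% names(parent))
      stop("data-integrity error: genotype ", g$id,
           " has parent ", pid, " missing from registry", call. = FALSE)
  }
  peak_end <- peak_population(result, "end")
  peak_post <- peak_population(result, "post")
  peak_of <- function(id) {
    k <- as.character(id)
    max(if (k %in% names(peak_end)) peak_end[[k]] else 0,
        if (k %in% names(peak_post)) peak_post[[k]] else 0)
  }
  keep <- vapply(ids, function(id) id == 1L || peak_of(id) >= min_peak_cells,
                 logical(1))
  kept <- ids[keep]
  nearest_kept <- function(id) {
    p <- parent[[as.character(id)]]
    while (!is.na(p) && !(p %in% kept)) p <- parent[[as.character(p)]]
    p
  }
  model <- resolve_model(result$config$model)
  cfgC <- result$config$C_total
  glc <- resolve_exchange(model, "glucose")
  ace <- resolve_exchange(model, "acetate")
  oxy <- resolve_exchange(model, "oxygen")
  vm <- function(id, ex) reg[[as.character(id)]]$v_max[[ex]]
  nodes <- data.frame(
    name = as.character(kept),
    peak_cells = vapply(kept, peak_of, numeric(1)),
    rel_glucose = vapply(kept, vm, numeric(1), ex = glc) / cfgC,
    rel_acetate = vapply(kept, vm, numeric(1), ex = ace) / cfgC,
    rel_oxygen = vapply(kept, vm, numeric(1), ex = oxy) / cfgC,
    stringsAsFactors = FALSE)
  ek <- kept[kept != 1L]
  epar <- vapply(ek, nearest_kept, integer(1))
  edges <- if (length(ek))
    data.frame(from = as.character(epar), to = as.character(ek),
               weight = log10(1 + vapply(ek, function(id) {
                 k <- as.character(id)
                 if (k %in% names(peak_post)) peak_post[[k]] else 0
               }, numeric(1))),
               stringsAsFactors = FALSE)
  else data.frame(from = character(0), to = character(0), weight = numeric(0))
  g <- igraph::graph_from_data_frame(edges, directed = TRUE, vertices = nodes)
  attr(g, "min_peak_cells") <- min_peak_cells
  class(g) <- c("lineage_graph", class(g))
  g
}

#' Export a lineage graph
#'
#' @param graph a `lineage_graph`.
#' @param path output file.
#' @param format `"graphml"` or `"dot"`.
#' @export
write_lineage_graph <- function(graph, path, format = c("graphml", "dot")) {
  format <- match.arg(format)
  g <- graph
  class(g) <- setdiff(class(g), "lineage_graph")
  igraph::write_graph(g, path, format = format)
  invisible(path)
}

#' Detect the diauxic shift in a cycle trajectory
#'
#' Returns the first minute at which the genotype's acetate exchange switches
#' from secretion (or zero) to uptake while its glucose uptake has fallen
#' below 1 % of its maximum over the cycle; `NA` if no such switch occurs
#' (e.g. for glucose specialists that lost acetate uptake).
#'
#' @param traj a `cycle_trajectory` recorded with `record_fluxes_for`
#'   including the genotype.
#' @param genotype_id genotype id (integer or character).
#' @return shift time in minutes, or `NA_real_`.
#' @export
detect_diauxic_shift <- function(traj, genotype_id = "1") {
  gid <- as.character(genotype_id)
  fl <- traj$fluxes[[gid]]
  if (is.null(fl))
    stop("trajectory has no recorded fluxes for genotype ", gid, call. = FALSE)
  al <- traj$aliases
  glc_up <- -fl[, al[["glucose"]]]      # uptake-positive
  ac_up <- -fl[, al[["acetate"]]]
  tol <- 1e-6
  gmax <- max(glc_up, na.rm = TRUE)
  if (!is.finite(gmax) || gmax <= tol) return(NA_real_)
  prev_ac <- c(0, ac_up[-length(ac_up)])
  shift <- which(ac_up > tol & prev_ac <= tol & glc_up < 0.01 * gmax)
  if (length(shift) == 0) return(NA_real_)
  traj$time[shift[[1L]] + 1L]           # flux row t covers step t (time index t+1)
}

#' Ten-day flux snapshot protocol
#'
#' Grows the genotype alone (mutation off, deterministic 1:100 transfers) in
#' glucose medium for ten daily cycles to wash out initial conditions, then
#' captures the full parsimonious flux vector on day 10: once in the glucose
#' phase (minute 10 from the start of the cycle; the model has no lag phase)
#' and once in the acetate phase (default minute 388) provided acetate is
#' present and being consumed then. Reactions of interest (PGI, ACONTb,
#' MALS, ACKr) are flagged when the model contains them.
#'
#' @param genotype a genotype (see [ancestor_genotype()]).
#' @param model an `evofba_model`.
#' @param config an `evofba_config`; `fresh_medium` should contain glucose
#'   at 0.1389 mmol/l.
#' @param glucose_minute,acetate_minute capture minutes on the final day.
#' @param days number of daily cycles (default 10).
#' @return list with elements `glucose` and `acetate`, each a
#'   `flux_snapshot` (fields `genotype_id`, `phase`, `minute`, `fluxes`,
#'   `reactions_of_interest`) or `NULL` when the phase never occurs.
#' @export
flux_snapshot_protocol <- function(genotype, model, config = evofba_config(),
                                   glucose_minute = 10, acetate_minute = 388,
                                   days = 10) {
  gid <- as.character(genotype$id)
  env <- make_medium(model, config$fresh_medium, config$volume)
  fresh <- env$conc
  genotypes <- stats::setNames(list(genotype), gid)
  biomass <- stats::setNames(config$inoculum_cells * config$cell_mass, gid)
  traj <- NULL
  for (day in seq_len(days)) {
    res <- run_cycle(model, env, biomass, genotypes, config, evolve = FALSE,
                     record_fluxes_for = if (day == days) gid else NULL,
                     cycle = day)
    if (day == days) { traj <- res$trajectory; break }
    d <- dilute(res$biomass, res$env, config$dilution_fraction, fresh,
                config$cell_mass, deterministic = TRUE)
    biomass <- d$biomass; env <- d$env
    if (length(biomass) == 0 || sum(res$trajectory$growth[, gid]) <= 0)
      stop("no growth under protocol", call. = FALSE)
  }
  if (max(traj$growth[, gid]) <= 0) stop("no growth under protocol", call. = FALSE)
  snap <- function(minute, phase) {
    step <- which.min(abs(traj$time[-1L] - minute))  # flux row index
    fl <- traj$fluxes[[gid]][step, ]
    if (phase == "acetate") {
      ac <- traj$aliases[["acetate"]]
      if (-fl[[ac]] <= 1e-9) return(NULL)   # no acetate uptake at that minute
    }
    structure(list(
      genotype_id = genotype$id, phase = phase, minute = traj$time[step + 1L],
      fluxes = fl,
      reactions_of_interest = intersect(REACTIONS_OF_INTEREST,
                                        names(fl)[abs(fl) > 1e-9])
    ), class = "flux_snapshot")
  }
  list(glucose = snap(glucose_minute, "glucose"),
       acetate = snap(acetate_minute, "acetate"))
}

#' Write a flux snapshot as TSV
#'
#' Columns `reaction_id`, `flux`, `is_reaction_of_interest`.
#'
#' @param snapshot a `flux_snapshot`.
#' @param path output file.
#' @export
write_flux_snapshot <- function(snapshot, path) {
  df <- data.frame(reaction_id = names(snapshot$fluxes),
                   flux = as.numeric(snapshot$fluxes),
                   is_reaction_of_interest =
                     names(snapshot$fluxes) %in% REACTIONS_OF_INTEREST)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert transfer cycles to generations
#'
#' Each 1:100 transfer cycle corresponds to log2(1/fraction) doublings
#' (about 6.64 generations per day at 1 %).
#'
#' @param cycles number of cycles.
#' @param dilution_fraction transfer fraction in (0, 1).
#' @return generations (real).
#' @export
cycles_to_generations <- function(cycles, dilution_fraction = 0.01) {
  stopifnot(dilution_fraction > 0, dilution_fraction < 1)
  cycles * log2(1 / dilution_fraction)
}
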