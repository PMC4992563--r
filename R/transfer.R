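# The serial-transfer experiment: repeated 24-h growth cycles, 1 % binomial
# sampling of cells at transfer, 99 %/1 % mixing of fresh and spent medium.

#' Simulation configuration
#'
#' All parameters of the serial-transfer evolution experiment, with defaults
#' matching the published in-silico protocol: 550 daily cycles in a 10-ml
#' reactor, glucose at 0.1389 mmol/l, 1 % transfers, a 40 mmol/gDW/h total
#' uptake budget initially split 10/10/20 over glucose/acetate/oxygen,
#' K_m = 0.01 mmol/l, mutation rate 1e-6 per cell per generation, mutation
#' step bound 10 mmol/gDW/h, cell mass 600 fg.
#'
#' @param model model source: `"core"`, `"toy"`, or a file path.
#' @param cycles number of transfer cycles.
#' @param cycle_hours length of one growth cycle (h).
#' @param dt_min Euler step (min).
#' @param volume reactor volume (l).
#' @param dilution_fraction fraction of cells (and spent medium) transferred.
#' @param fresh_medium named list/vector, fresh-medium concentrations
#'   (mmol/l).
#' @param C_total global uptake budget (mmol/gDW/h).
#' @param initial_v_max named list/vector, the ancestor's maximum uptake
#'   rates; must sum to `C_total`.
#' @param K_m shared Michaelis-Menten half-saturation constant (mmol/l).
#' @param mutation_rate mutations per cell per generation.
#' @param mutation_step bound A of the uniform mutation step (mmol/gDW/h).
#' @param cell_mass gDW per cell.
#' @param seed RNG seed for the whole experiment.
#' @param growth_update `"paper"` (linearised with the ln 2 divisor, as
#'   published) or `"exponential"`.
#' @param inoculum_cells cells founding the burn-in cycle (cycle 0).
#' @param deterministic_dilution if `TRUE`, transfer exactly
#'   `dilution_fraction` of each genotype's biomass instead of binomial cell
#'   sampling (used by deterministic protocols and tests).
#' @param snapshot_cycles integer cycles whose full trajectories are kept.
#' @param checkpoint_every write a JSON state checkpoint every k cycles (0 =
#'   never).
#' @param checkpoint_dir directory for checkpoints.
#' @return an object of class `evofba_config`.
#' @export
evofba_config <- function(model = "core", cycles = 550, cycle_hours = 24,
                          dt_min = 1, volume = 0.01, dilution_fraction = 0.01,
                          fresh_medium = list(glucose = 0.1389), C_total = 40,
                          initial_v_max = list(glucose = 10, acetate = 10,
                                               oxygen = 20),
                          K_m = 0.01, mutation_rate = 1e-6, mutation_step = 10,
                          cell_mass = 6e-13, seed = 1L,
                          growth_update = c("paper", "exponential"),
                          inoculum_cells = 1e6,
                          deterministic_dilution = FALSE,
                          snapshot_cycles = integer(0),
                          checkpoint_every = 0L, checkpoint_dir = NULL) {
  growth_update <- match.arg(growth_update)
  cfg <- structure(list(
    model = model, cycles = as.integer(cycles), cycle_hours = cycle_hours,
    dt_min = dt_min, volume = volume, dilution_fraction = dilution_fraction,
    fresh_medium = as.list(fresh_medium), C_total = C_total,
    initial_v_max = as.list(initial_v_max), K_m = K_m,
    mutation_rate = mutation_rate, mutation_step = mutation_step,
    cell_mass = cell_mass, seed = as.integer(seed),
    growth_update = growth_update, inoculum_cells = inoculum_cells,
    deterministic_dilution = isTRUE(deterministic_dilution),
    snapshot_cycles = as.integer(snapshot_cycles),
    checkpoint_every = as.integer(checkpoint_every),
    checkpoint_dir = checkpoint_dir
  ), class = "evofba_config")
  validate_config(cfg)
}

#' Validate a simulation configuration
#'
#' Checks positivity of the numeric fields, the (0,1) range of the dilution
#' fraction, and that the initial v_max sums to `C_total`.
#'
#' @param cfg an `evofba_config`.
#' @return the config, invisibly; errors with the offending field otherwise.
#' @export
validate_config <- function(cfg) {
  num_pos <- c("cycle_hours", "dt_min", "volume", "C_total", "K_m",
               "cell_mass")
  for (f in num_pos)
    if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0)
      stop("config error: field '", f, "' must be a positive number",
           call. = FALSE)
  if (cfg$cycles < 0) stop("config error: field 'cycles' must be >= 0",
                           call. = FALSE)
  if (cfg$dilution_fraction <= 0 || cfg$dilution_fraction >= 1)
    stop("config error: field 'dilution_fraction' must lie in (0, 1)",
         call. = FALSE)
  if (cfg$mutation_rate < 0)
    stop("config error: field 'mutation_rate' must be >= 0", call. = FALSE)
  s <- sum(unlist(cfg$initial_v_max))
  if (abs(s - cfg$C_total) > 1e-9)
    stop("uptake budget violated: initial_v_max sums to ", s,
         ", expected C_total = ", cfg$C_total, call. = FALSE)
  cfg
}

#' Load a simulation configuration from JSON
#'
#' Missing fields are filled with the published defaults (an empty file gives
#' the full default configuration). The field `A` is accepted as an alias
#' for `mutation_step`.
#'
#' @param path JSON file.
#' @return an `evofba_config`.
#' @export
load_config <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  vals <- if (nzchar(trimws(txt))) jsonlite::fromJSON(txt, simplifyVector = TRUE)
          else list()
  if (!is.list(vals)) stop("config error: top level must be a JSON object",
                           call. = FALSE)
  if (!is.null(vals$A) && is.null(vals$mutation_step)) {
    vals$mutation_step <- vals$A
  }
  vals$A <- NULL
  known <- names(formals(evofba_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("config error: unknown field '", unknown[[1L]], "'", call. = FALSE)
  do.call(evofba_config, vals)
}

#' Write a configuration as JSON
#'
#' @param config an `evofba_config`.
#' @param path output file.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Scale presets
#'
#' Named parameter bundles: `"paper"` is the full published protocol (550
#' cycles, 10-ml reactor — roughly 20 HPC-days at the original scale);
#' `"desk"` shrinks the reactor to 0.1 ml and runs 150 cycles (hours on one
#' CPU); `"smoke"` runs the toy overflow model in 1 ul for 10 cycles at 5-min
#' steps (seconds; used in CI).
#'
#' @param name one of `"paper"`, `"desk"`, `"smoke"`.
#' @param ... further overrides passed to [evofba_config()].
#' @return an `evofba_config`.
#' @export
scale_preset <- function(name = c("paper", "desk", "smoke"), ...) {
  if (!is.character(name) || !name[[1L]] %in% c("paper", "desk", "smoke"))
    stop("unknown preset '", name[[1L]],
         "'; available presets: paper, desk, smoke", call. = FALSE)
  name <- name[[1L]]
  over <- switch(name,
    paper = list(),
    desk  = list(volume = 1e-4, cycles = 150L),
    smoke = list(model = "toy", volume = 1e-6, cycles = 10L, dt_min = 5))
  evofba_config(...)[] -> base
  cfg <- utils::modifyList(base, over)
  dots <- list(...)
  cfg[names(dots)] <- dots
  validate_config(structure(cfg, class = "evofba_config"))
}

resolve_model <- function(spec) {
  if (inherits(spec, "evofba_model")) return(spec)
  switch(spec,
         core = core_model(),
         toy = make_toy_model(),
         load_model(spec))
}

#' Serial transfer: sample survivors and mix media
#'
#' Each genotype's surviving cell count is Binomial(N, fraction) (or exactly
#' `fraction` of its biomass in deterministic mode); biomass is reset to
#' survivors times the cell mass; the next cycle's medium is
#' `(1 - fraction) * fresh + fraction * spent`, so secreted byproducts carry
#' over at 1 %. Genotypes drawn to zero cells go extinct.
#'
#' @param biomass named biomass vector (gDW per genotype).
#' @param env spent medium (`evofba_env`).
#' @param fraction transfer fraction in (0, 1).
#' @param fresh_medium named vector over the tracked substrates (mmol/l).
#' @param cell_mass gDW per cell.
#' @param deterministic exact fractional transfer instead of binomial
#'   sampling.
#' @return list with `biomass` (survivors only), `env` (mixed medium) and
#'   `survivors` (named integer cell counts, zero entries dropped).
#' @export
dilute <- function(biomass, env, fraction = 0.01,
                   fresh_medium = numeric(0), cell_mass = 6e-13,
                   deterministic = FALSE) {
  stopifnot(fraction > 0, fraction < 1)
  fresh <- stats::setNames(rep(0, length(env$conc)), names(env$conc))
  if (length(fresh_medium)) fresh[names(fresh_medium)] <- unlist(fresh_medium)
  env$conc <- (1 - fraction) * fresh + fraction * env$conc
  if (deterministic) {
    bm <- biomass * fraction
    surv <- floor(bm / cell_mass)
    keep <- bm > 0
    return(list(biomass = bm[keep], env = env,
                survivors = stats::setNames(as.integer(surv[keep]),
                                            names(bm)[keep])))
  }
  N <- floor(biomass / cell_mass)
  surv <- stats::rbinom(length(N), size = as.integer(pmin(N, .Machine$integer.max)),
                        prob = fraction)
  names(surv) <- names(biomass)
  keep <- surv > 0
  list(biomass = stats::setNames(surv[keep] * cell_mass, names(biomass)[keep]),
       env = env, survivors = surv[keep])
}

#' Run the full serial-transfer evolution experiment
#'
#' Initializes the ancestor in fresh medium, runs one un-evolved burn-in
#' cycle from a configurable inoculum (so day 1 starts from a steady
#' transfer regime), then loops growth cycles and transfers for
#' `config$cycles` cycles with mutation enabled. Deterministic given the
#' config seed.
#'
#' @param config an `evofba_config`.
#' @param progress print a one-line summary per cycle.
#' @param resume_from path to a checkpoint JSON written by a previous run
#'   (see `checkpoint_every`); the experiment continues from the cycle after
#'   the checkpoint. The RNG is reseeded from `seed + cycle`, so a resumed
#'   run is reproducible given the checkpoint but not bit-identical to an
#'   uninterrupted one.
#' @return an object of class `evofba_experiment` with fields:
#'   `config`; `model_id`; `genotypes` (registry, all genotypes ever
#'   created); `events` (mutation events); `counts_post` (per-cycle named
#'   post-dilution cell counts, the survivors series); `counts_end`
#'   (end-of-cycle, pre-dilution counts); `medium` (matrix, end-of-cycle
#'   concentrations); `trajectories` (kept cycles); `final` (biomass, env);
#'   `seed`.
#' @export
run_experiment <- function(config = evofba_config(), progress = FALSE,
                           resume_from = NULL) {
  validate_config(config)
  model <- resolve_model(config$model)
  prob <- get_problem(model, config$C_total)
  set.seed(config$seed)
  env <- make_medium(model, config$fresh_medium, config$volume)
  fresh <- env$conc
  first_cycle <- 1L
  if (!is.null(resume_from)) {
    st <- jsonlite::fromJSON(resume_from, simplifyVector = FALSE)
    genotypes <- lapply(st$genotypes, function(g)
      new_genotype(g$id,
                   if (is.null(g$parent_id)) NA_integer_ else g$parent_id,
                   unlist(g$v_max), unlist(g$birth)))
    names(genotypes) <- vapply(genotypes, function(g) as.character(g$id),
                               character(1))
    biomass <- unlist(st$biomass)
    env$conc[names(st$conc)] <- unlist(st$conc)
    next_id <- st$next_id
    first_cycle <- st$cycle + 1L
    set.seed(config$seed + st$cycle)
  } else {
    anc <- ancestor_genotype(model, unlist(config$initial_v_max),
                             config$C_total)
    genotypes <- stats::setNames(list(anc), "1")
    biomass <- c("1" = config$inoculum_cells * config$cell_mass)
    next_id <- 2

    # burn-in cycle 0: un-evolved growth + transfer
    cyc0 <- run_cycle(model, env, biomass, genotypes, config, evolve = FALSE,
                      cycle = 0L, next_id = next_id)
    d0 <- dilute(cyc0$biomass, cyc0$env, config$dilution_fraction, fresh,
                 config$cell_mass, config$deterministic_dilution)
    biomass <- d0$biomass; env <- d0$env
  }

  counts_post <- vector("list", config$cycles)
  counts_end <- vector("list", config$cycles)
  medium <- matrix(NA_real_, config$cycles, length(fresh),
                   dimnames = list(NULL, names(fresh)))
  trajectories <- list()
  events <- list()
  alive_prev <- names(biomass)

  cycles_todo <- if (first_cycle > config$cycles) integer(0)
                 else seq.int(first_cycle, config$cycles)
  for (cyc in cycles_todo) {
    if (length(biomass) == 0) break   # total extinction (tiny reactors)
    res <- run_cycle(model, env, biomass, genotypes, config,
                     evolve = config$mutation_rate > 0,
                     cycle = cyc, next_id = next_id)
    genotypes <- res$genotypes
    next_id <- res$next_id
    events <- c(events, res$events)
    counts_end[[cyc]] <- floor(res$biomass / config$cell_mass)
    medium[cyc, ] <- res$env$conc
    if (cyc %in% config$snapshot_cycles)
      trajectories[[as.character(cyc)]] <- res$trajectory
    d <- dilute(res$biomass, res$env, config$dilution_fraction, fresh,
                config$cell_mass, config$deterministic_dilution)
    biomass <- d$biomass; env <- d$env
    counts_post[[cyc]] <- d$survivors
    # free solver bases of extinct genotypes
    gone <- setdiff(alive_prev, names(biomass))
    if (length(gone)) forget_warm_keys(prob, as.integer(gone))
    alive_prev <- names(biomass)
    if (progress)
      cat(sprintf("cycle %d: %d genotypes, %.3g cells, glc %.4g ac %.4g\n",
                  cyc, length(biomass), sum(d$survivors),
                  env$conc[[resolve_exchange(model, "glucose")]],
                  env$conc[[resolve_exchange(model, "acetate")]]))
    if (config$checkpoint_every > 0 && cyc %% config$checkpoint_every == 0 &&
        !is.null(config$checkpoint_dir))
      write_checkpoint(config, cyc, biomass, env, genotypes, next_id)
  }

  structure(list(
    config = config, model_id = model$model_id,
    genotypes = genotypes, events = events,
    counts_post = counts_post, counts_end = counts_end,
    medium = medium, trajectories = trajectories,
    final = list(biomass = biomass, env = env),
    seed = config$seed, version = as.character(utils::packageVersion("evofba"))
  ), class = "evofba_experiment")
}

write_checkpoint <- function(config, cyc, biomass, env, genotypes, next_id) {
  dir.create(config$checkpoint_dir, showWarnings = FALSE, recursive = TRUE)
  state <- list(cycle = cyc, next_id = next_id,
                biomass = as.list(biomass), conc = as.list(env$conc),
                genotypes = lapply(genotypes, function(g)
                  list(id = g$id, parent_id = g$parent_id,
                       v_max = as.list(g$v_max), birth = g$birth)))
  jsonlite::write_json(state,
                       file.path(config$checkpoint_dir,
                                 sprintf("checkpoint_%05d.json", cyc)),
                       auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}

#' Per-cycle survivor table
#'
#' @param result an `evofba_experiment`.
#' @param which `"post"` (post-dilution survivors, the published per-cycle
#'   series) or `"end"` (end-of-cycle, pre-dilution).
#' @return data.frame with columns `cycle`, `genotype_id`, `cells`.
#' @export
survivors_table <- function(result, which = c("post", "end")) {
  which <- match.arg(which)
  lst <- if (which == "post") result$counts_post else result$counts_end
  rows <- lapply(seq_along(lst), function(cyc) {
    v <- lst[[cyc]]
    if (is.null(v) || length(v) == 0) return(NULL)
    data.frame(cycle = cyc, genotype_id = as.integer(names(v)),
               cells = as.numeric(v))
  })
  do.call(rbind, rows)
}

#' Write experiment outputs to a directory
#'
#' Writes `registry.jsonl` (one genotype per line), `survivors.tsv`
#' (cycle x genotype cell counts), `medium.tsv` (end-of-cycle
#' concentrations) and `metadata.json` (seed, config, version).
#'
#' @param result an `evofba_experiment`.
#' @param dir output directory (created if needed).
#' @export
write_result <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  reg <- file(file.path(dir, "registry.jsonl"), "w")
  for (g in result$genotypes) {
    writeLines(jsonlite::toJSON(list(
      genotype_id = g$id, parent_id = g$parent_id,
      birth_cycle = g$birth[[1L]], birth_step = g$birth[[2L]],
      v_max = as.list(g$v_max)), auto_unbox = TRUE, digits = NA, na = "null"), reg)
  }
  close(reg)
  utils::write.table(survivors_table(result), file.path(dir, "survivors.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(survivors_table(result, "end"),
                     file.path(dir, "counts_end.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  med <- data.frame(cycle = seq_len(nrow(result$medium)), result$medium,
                    check.names = FALSE)
  utils::write.table(med, file.path(dir, "medium.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(seed = result$seed, model = result$model_id,
                            version = result$version,
                            config = unclass(result$config)),
                       file.path(dir, "metadata.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(dir)
}

#' Reload an experiment result directory
#'
#' Reconstructs the parts of an `evofba_experiment` needed by [survivors()]
#' and [build_lineage_graph()] from the files written by [write_result()].
#'
#' @param dir directory written by [write_result()].
#' @return an `evofba_experiment` (without trajectories or final state).
#' @export
read_result_dir <- function(dir) {
  meta <- jsonlite::fromJSON(file.path(dir, "metadata.json"),
                             simplifyVector = TRUE)
  cfg <- meta$config
  cfg$snapshot_cycles <- as.integer(unlist(cfg$snapshot_cycles))
  cfg <- do.call(evofba_config, cfg[names(cfg) %in% names(formals(evofba_config))])
  lines <- readLines(file.path(dir, "registry.jsonl"), warn = FALSE)
  genotypes <- list()
  for (ln in lines) {
    g <- jsonlite::fromJSON(ln, simplifyVector = TRUE)
    genotypes[[as.character(g$genotype_id)]] <-
      new_genotype(g$genotype_id,
                   if (is.null(g$parent_id)) NA_integer_ else g$parent_id,
                   unlist(g$v_max), c(g$birth_cycle, g$birth_step))
  }
  to_counts <- function(path) {
    tab <- utils::read.delim(path)
    out <- vector("list", max(c(0L, tab$cycle)))
    for (cyc in unique(tab$cycle)) {
      d <- tab[tab$cycle == cyc, ]
      out[[cyc]] <- stats::setNames(d$cells, d$genotype_id)
    }
    out
  }
  structure(list(
    config = cfg, model_id = meta$model, genotypes = genotypes,
    events = list(),
    counts_post = to_counts(file.path(dir, "survivors.tsv")),
    counts_end = to_counts(file.path(dir, "counts_end.tsv")),
    medium = as.matrix(utils::read.delim(file.path(dir, "medium.tsv"))[, -1]),
    trajectories = list(), final = NULL, seed = meta$seed,
    version = meta$version
  ), class = "evofba_experiment")
}
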