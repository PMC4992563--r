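# Batch-culture dynamics: Michaelis-Menten uptake capacities, 1-min Euler
# stepping of biomass and medium concentrations, one 24-h cycle.
#
# Units: biomass BM in absolute gDW (not per litre); concentrations in
# mmol/l; fluxes in mmol/gDW/h; growth rate in 1/h; volume in litres; time
# step dt in minutes. With these units the medium update
#   S[j] <- S[j] - sum_i BM_i * v_{j,i} * dt / (60 * V)
# is dimensionally consistent (mmol/l per step).

LN2 <- log(2)

#' Michaelis-Menten uptake capacity
#'
#' The per-step uptake bound for a substrate's exchange reaction:
#' `v = v_max * S / (K_m + S)` (mmol/gDW/h). Non-depleting substrates
#' (oxygen) bypass this and use `v_max` directly.
#'
#' @param v_max maximum uptake rate (mmol/gDW/h, `>= 0`).
#' @param S substrate concentration (mmol/l, `>= 0`).
#' @param K_m half-saturation constant (mmol/l, `> 0`).
#' @return uptake capacity, same shape as the inputs.
#' @export
uptake_capacity <- function(v_max, S, K_m = 0.01) {
  if (any(v_max < 0) || any(S < 0) || any(K_m <= 0))
    stop("uptake_capacity: v_max and S must be >= 0 and K_m > 0", call. = FALSE)
  v_max * S / (K_m + S)
}

#' Construct a batch-reactor medium
#'
#' @param model an `evofba_model`; the tracked substrates are the model's
#'   mutable carbon exchanges (all mutable exchanges except oxygen).
#' @param concentrations named numeric vector or list, names are friendly
#'   substrate names or exchange ids (mmol/l); unlisted substrates start at 0.
#' @param volume reactor volume in litres.
#' @return object of class `evofba_env` with fields `conc` (named by exchange
#'   id), `volume`, `oxygen` (the non-depleting oxygen exchange id).
#' @export
make_medium <- function(model, concentrations = c(glucose = 0.1389),
                        volume = 0.01) {
  stopifnot(volume > 0)
  oxy <- resolve_exchange(model, "oxygen")
  tracked <- setdiff(model$mutable_exchanges, oxy)
  conc <- stats::setNames(rep(0, length(tracked)), tracked)
  if (length(concentrations)) {
    concentrations <- unlist(concentrations)
    ids <- resolve_exchange(model, names(concentrations))
    bad <- setdiff(ids, tracked)
    if (length(bad)) stop("not a tracked substrate: ", bad[[1L]], call. = FALSE)
    conc[ids] <- as.numeric(concentrations)
  }
  if (any(conc < 0)) stop("concentrations must be >= 0", call. = FALSE)
  structure(list(conc = conc, volume = volume, oxygen = oxy),
            class = "evofba_env")
}

# uptake caps for one genotype given the current medium
genotype_caps <- function(genotype, env, K_m) {
  v <- genotype$v_max
  caps <- v
  tracked <- names(env$conc)
  caps[tracked] <- uptake_capacity(v[tracked], env$conc[tracked], K_m)
  caps  # oxygen entry left at v_max (non-depleting)
}

#' One Euler step of dynamic FBA
#'
#' For every genotype with positive biomass: compute Michaelis-Menten uptake
#' caps from the current medium, solve the two-stage FBA, update biomass with
#' the linearised growth update `BM * (1 + mu * dt / (ln 2 * 60))` (or the
#' exponential alternative), and deplete/augment every tracked substrate by
#' the realized exchange fluxes. If a substrate would be driven negative, all
#' consumers' caps for it are scaled by available/demand, those genotypes are
#' re-solved once, and the concentration is clamped at exactly zero.
#'
#' @param env an `evofba_env`.
#' @param biomass named numeric vector, gDW per genotype id.
#' @param genotypes named list of genotypes (see [ancestor_genotype()]).
#' @param model_or_problem the shared metabolic chassis.
#' @param dt step length in minutes.
#' @param K_m half-saturation constant (mmol/l).
#' @param C_total global uptake budget (mmol/gDW/h).
#' @param growth_update `"paper"` (linearised, with the ln 2 divisor) or
#'   `"exponential"`.
#' @param warm use per-genotype warm-started LP bases (default `TRUE`).
#' @param memo optional environment carried across steps of one cycle; when a
#'   genotype's uptake caps are unchanged from the previous step (typically
#'   in stationary phase, where uptake is zero and the medium is static) the
#'   previous solution is reused instead of re-solving.
#' @return list with `env`, `biomass`, `growth` (named growth rates, 1/h),
#'   `uptake` (matrix genotype x tracked substrate, positive = uptake),
#'   `solutions` (named list of `fba_solution`).
#' @export
dfba_step <- function(env, biomass, genotypes, model_or_problem, dt = 1,
                      K_m = 0.01, C_total = 40,
                      growth_update = c("paper", "exponential"),
                      warm = TRUE, memo = NULL) {
  growth_update <- match.arg(growth_update)
  stopifnot(dt > 0)
  prob <- get_problem(model_or_problem, C_total)
  tracked <- names(env$conc)
  ids <- names(biomass)[biomass > 0]
  growth <- stats::setNames(rep(0, length(biomass)), names(biomass))
  U <- matrix(0, length(ids), length(tracked),
              dimnames = list(ids, tracked))
  sols <- vector("list", length(ids)); names(sols) <- ids
  carbon_cap_total <- function(caps) sum(caps[tracked])

  solve_one <- function(gid, caps) {
    key <- if (warm) genotypes[[gid]]$id else -1L
    solve_fba(prob, caps, C_total = C_total, warm_key = key)
  }

  caps_list <- list()
  for (gid in ids) {
    caps <- genotype_caps(genotypes[[gid]], env, K_m)
    caps_list[[gid]] <- caps
    if (!is.null(memo)) {
      prev <- memo[[gid]]
      if (!is.null(prev) && isTRUE(all(abs(prev$caps - caps) < 1e-14))) {
        sols[[gid]] <- prev$sol
        next
      }
    }
    # below ~1e-6 mmol/gDW/h of total carbon uptake capacity no model can
    # meet maintenance ATP (and growth is negligible even without it)
    sols[[gid]] <- if (carbon_cap_total(caps) < 1e-6)
      empty_solution(prob$model, "no_substrate")
    else solve_one(gid, caps)
    if (!is.null(memo)) memo[[gid]] <- list(caps = caps, sol = sols[[gid]])
  }
  for (gid in ids) {
    U[gid, ] <- sols[[gid]]$exchange_fluxes[tracked]
    growth[gid] <- sols[[gid]]$growth_rate
  }

  demand <- as.numeric(crossprod(U, biomass[ids])) * dt / (60 * env$volume)
  names(demand) <- tracked
  over <- tracked[env$conc - demand < -1e-12 & demand > 0]
  if (length(over)) {
    for (j in over) {
      f <- env$conc[[j]] / demand[[j]]
      for (gid in ids) {
        if (U[gid, j] > 0) {
          caps <- caps_list[[gid]]
          caps[j] <- U[gid, j] * f
          caps_list[[gid]] <- caps
          sols[[gid]] <- solve_one(gid, caps)
          U[gid, ] <- sols[[gid]]$exchange_fluxes[tracked]
          growth[gid] <- sols[[gid]]$growth_rate
        }
      }
    }
    demand <- as.numeric(crossprod(U, biomass[ids])) * dt / (60 * env$volume)
    names(demand) <- tracked
  }
  env$conc <- pmax(env$conc - demand, 0)

  bm_new <- biomass
  fac <- switch(growth_update,
                paper = 1 + growth[names(biomass)] * dt / (LN2 * 60),
                exponential = exp(growth[names(biomass)] * dt / 60))
  bm_new <- biomass * fac
  list(env = env, biomass = bm_new, growth = growth, uptake = U,
       solutions = sols)
}

#' Run one batch-culture cycle of dynamic FBA
#'
#' Steps a multi-genotype culture through one growth cycle (default 24 h at
#' 1-min resolution), optionally interleaving mutation draws after each
#' step's biomass update, and records the trajectory.
#'
#' @param model an `evofba_model`.
#' @param env starting medium ([make_medium()]).
#' @param biomass named numeric vector of biomass (gDW) per genotype id.
#' @param genotypes named list of genotypes.
#' @param config an `evofba_config` (controls dt, cycle length, kinetics,
#'   mutation parameters and growth update); see [evofba_config()].
#' @param evolve draw mutations during the cycle (default `FALSE`).
#' @param record_fluxes_for character vector of genotype ids whose full flux
#'   vectors are recorded at every step (needed by
#'   [detect_diauxic_shift()] and [flux_snapshot_protocol()]).
#' @param cycle integer cycle index stamped on mutants born in this cycle.
#' @param next_id next free genotype id (mutants get sequential ids).
#' @return list with `trajectory` (a `cycle_trajectory`), final `env`,
#'   `biomass`, updated `genotypes`, `events` (list of mutation events) and
#'   `next_id`.
#' @export
run_cycle <- function(model, env, biomass, genotypes, config = evofba_config(),
                      evolve = FALSE, record_fluxes_for = NULL,
                      cycle = NA_integer_, next_id = NULL) {
  dt <- config$dt_min
  steps <- as.integer(round(config$cycle_hours * 60 / dt))
  prob <- get_problem(model, config$C_total)
  tracked <- names(env$conc)
  if (is.null(next_id))
    next_id <- max(vapply(genotypes, `[[`, numeric(1), "id")) + 1
  ids0 <- names(biomass)
  conc_rec <- matrix(NA_real_, steps + 1L, length(tracked),
                     dimnames = list(NULL, tracked))
  bm_rec <- list(); mu_rec <- list()
  flux_rec <- list()
  for (gid in record_fluxes_for)
    flux_rec[[gid]] <- matrix(NA_real_, steps, length(model$reactions),
                              dimnames = list(NULL, model$reactions))
  conc_rec[1L, ] <- env$conc
  bm_rec[[1L]] <- biomass
  events <- list()
  memo <- new.env(parent = emptyenv())

  for (t in seq_len(steps)) {
    st <- dfba_step(env, biomass, genotypes, prob, dt = dt, K_m = config$K_m,
                    C_total = config$C_total,
                    growth_update = config$growth_update, memo = memo)
    env <- st$env
    old_bm <- biomass
    biomass <- st$biomass
    if (evolve && config$mutation_rate > 0) {
      for (gid in names(old_bm)[old_bm > 0]) {
        mu_g <- st$growth[[gid]]
        if (mu_g <= 0) next
        N <- floor(biomass[[gid]] / config$cell_mass)
        Nm <- expected_mutants(N, mu_g, config$mutation_rate) * dt
        if (draw_mutation_count(Nm) > 0) {
          res <- mutate(genotypes[[gid]], A = config$mutation_step,
                        C_total = config$C_total, id = next_id,
                        birth = c(cycle, t))
          child <- res$genotype
          sp <- spawn_mutant(biomass, gid, child$id, config$cell_mass)
          if (!is.null(sp)) {
            biomass <- sp
            genotypes[[as.character(child$id)]] <- child
            events[[length(events) + 1L]] <- res$event
            next_id <- next_id + 1
          }
        }
      }
    }
    conc_rec[t + 1L, ] <- env$conc
    bm_rec[[t + 1L]] <- biomass
    mu_rec[[t]] <- st$growth
    for (gid in intersect(record_fluxes_for, names(st$solutions)))
      flux_rec[[gid]][t, ] <- st$solutions[[gid]]$fluxes
  }

  all_ids <- names(biomass)
  to_mat <- function(lst, n) {
    M <- matrix(0, n, length(all_ids), dimnames = list(NULL, all_ids))
    for (i in seq_along(lst)) {
      v <- lst[[i]]
      M[i, names(v)] <- v
    }
    M
  }
  traj <- structure(list(
    time = seq(0, steps * dt, by = dt),
    dt = dt,
    conc = conc_rec,
    biomass = to_mat(bm_rec, steps + 1L),
    growth = to_mat(mu_rec, steps),
    fluxes = flux_rec,
    volume = env$volume,
    aliases = c(glucose = unname(resolve_exchange(model, "glucose")),
                acetate = unname(resolve_exchange(model, "acetate")),
                oxygen = unname(resolve_exchange(model, "oxygen")))
  ), class = "cycle_trajectory")
  list(trajectory = traj, env = env, biomass = biomass, genotypes = genotypes,
       events = events, next_id = next_id)
}

#' Write a cycle trajectory as TSV
#'
#' Columns: `time_min`, one column per tracked substrate (mmol/l), then one
#' biomass column per genotype (gDW).
#'
#' @param traj a `cycle_trajectory`.
#' @param path output file.
#' @param flux_path optional second file receiving the recorded per-step
#'   fluxes in long format (`time_min`, `genotype_id`, `reaction_id`,
#'   `flux`).
#' @export
write_trajectory <- function(traj, path, flux_path = NULL) {
  df <- data.frame(time_min = traj$time, traj$conc,
                   check.names = FALSE)
  bm <- traj$biomass
  colnames(bm) <- paste0("BM_", colnames(bm))
  df <- cbind(df, bm)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(flux_path) && length(traj$fluxes)) {
    rows <- lapply(names(traj$fluxes), function(gid) {
      fl <- traj$fluxes[[gid]]
      data.frame(time_min = rep(traj$time[-1L], ncol(fl)),
                 genotype_id = gid,
                 reaction_id = rep(colnames(fl), each = nrow(fl)),
                 flux = as.vector(fl))
    })
    utils::write.table(do.call(rbind, rows), flux_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
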