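# Per-step FBA: maximize growth under per-substrate uptake caps and a global
# uptake budget, then minimize total absolute flux at fixed growth
# (parsimonious solution). The LP is posed once per model with every reaction
# split as v = v+ - v-, so that (i) uptake magnitudes of the mutable
# exchanges appear as plain variables in the explicit budget row
# sum(uptakes) <= C_total, and (ii) stage 2 is a linear objective over the
# split parts. Only the bounds and objective change between solves, which the
# compiled simplex exploits via warm-started bases.

#' Pose the FBA linear program for a model
#'
#' Builds the split-variable LP (steady state rows plus one global uptake
#' budget row) that [solve_fba()] re-solves with varying bounds. Users rarely
#' need to call this directly; it is cached on the model.
#'
#' @param model an `evofba_model`.
#' @param C_total global uptake budget over the mutable exchanges
#'   (mmol/gDW/h); default 40.
#' @return an object of class `fba_problem`.
#' @export
fba_problem <- function(model, C_total = 40) {
  R <- length(model$reactions)
  M <- length(model$metabolites)
  S <- model$S
  nv <- 2L * R + 1L                     # v+, v-, budget slack
  A <- matrix(0, M + 1L, nv)
  A[seq_len(M), seq_len(R)] <- S
  A[seq_len(M), R + seq_len(R)] <- -S
  mut_idx <- match(model$mutable_exchanges, model$reactions)
  A[M + 1L, R + mut_idx] <- 1          # uptake magnitudes of mutable exchanges
  A[M + 1L, nv] <- 1                   # slack
  b <- c(rep(0, M), C_total)

  lb <- numeric(nv); ub <- numeric(nv)
  lb[seq_len(R)] <- pmax(model$lb, 0)
  ub[seq_len(R)] <- pmax(model$ub, 0)
  lb[R + seq_len(R)] <- pmax(-model$ub, 0)
  ub[R + seq_len(R)] <- pmax(-model$lb, 0)
  # unlimited exchanges: free in both directions
  unl_idx <- match(model$unlimited_exchanges, model$reactions)
  lb[unl_idx] <- 0; ub[unl_idx] <- 1000
  lb[R + unl_idx] <- 0; ub[R + unl_idx] <- 1000
  # mutable exchanges: secretion free, uptake capped per solve (default 0)
  lb[mut_idx] <- 0; ub[mut_idx] <- 1000
  lb[R + mut_idx] <- 0; ub[R + mut_idx] <- 0
  lb[nv] <- 0; ub[nv] <- if (is.finite(C_total)) C_total else 1e6

  bio_idx <- match(model$biomass_reaction, model$reactions)
  c1 <- numeric(nv); c1[bio_idx] <- 1
  c2 <- c(rep(1, 2L * R), 0)

  structure(list(
    model = model, C_total = C_total, A = A, b = b,
    lb = lb, ub = ub, c_growth = c1, c_flux = c2,
    R = R, M = M, nv = nv,
    mut_idx = mut_idx, bio_idx = bio_idx,
    env = new.env(parent = emptyenv())
  ), class = "fba_problem")
}

problem_ws <- function(prob) {
  ws <- prob$env$ws
  if (is.null(ws)) {
    ws <- lp_new(prob$A, prob$b)
    prob$env$ws <- ws
  }
  ws
}

get_problem <- function(x, C_total = 40) {
  if (inherits(x, "fba_problem")) return(x)
  stopifnot(inherits(x, "evofba_model"))
  key <- paste0("prob_", format(C_total))
  p <- x$env[[key]]
  if (is.null(p)) {
    p <- fba_problem(x, C_total)
    x$env[[key]] <- p
  }
  p
}

#' Two-stage (parsimonious) flux balance analysis
#'
#' Stage 1 maximizes the biomass flux subject to steady state, default
#' reaction bounds, per-exchange uptake caps and the explicit global budget
#' row (total uptake over the mutable exchanges at most `C_total`). Stage 2
#' fixes the optimal growth rate (within 1e-9) and minimizes the sum of
#' absolute fluxes. Uptake caps use the simulator's uptake-positive
#' convention; this function is the single adapter between that convention
#' and the toolchain's negative-exchange-flux-equals-uptake convention.
#'
#' @param x an `evofba_model` or `fba_problem`.
#' @param uptake_bounds named numeric vector: max uptake (mmol/gDW/h,
#'   `>= 0`) per exchange id or friendly substrate name. Mutable exchanges
#'   not listed get cap 0; unlimited exchanges must not be listed.
#' @param C_total global uptake budget (used when `x` is a model).
#' @param pfba run the stage-2 flux minimization (default `TRUE`).
#' @param warm_key non-negative integer identifying a cached basis for warm
#'   starts (use a distinct key per genotype), or -1 for a cold solve.
#' @return an object of class `fba_solution`: fields `status` (`"optimal"` or
#'   `"infeasible"`), `growth_rate` (1/h), `fluxes` (named, toolchain sign
#'   convention), `exchange_fluxes` (named, positive = uptake, negative =
#'   secretion), `total_flux` (sum of absolute fluxes).
#' @export
solve_fba <- function(x, uptake_bounds = numeric(0), C_total = 40,
                      pfba = TRUE, warm_key = -1L) {
  prob <- get_problem(x, C_total)
  model <- prob$model
  if (length(uptake_bounds)) {
    names(uptake_bounds) <- resolve_exchange(model, names(uptake_bounds))
    if (any(uptake_bounds < 0))
      stop("uptake bounds must be >= 0 (uptake-positive convention)",
           call. = FALSE)
    bad <- setdiff(names(uptake_bounds), model$exchange_reactions)
    if (length(bad)) stop("not an exchange reaction: ", bad[[1L]], call. = FALSE)
    if (any(names(uptake_bounds) %in% model$unlimited_exchanges))
      stop("unlimited exchanges cannot be capped", call. = FALSE)
  }
  R <- prob$R
  lb <- prob$lb; ub <- prob$ub
  caps <- stats::setNames(rep(0, length(prob$mut_idx)), model$mutable_exchanges)
  hit <- intersect(names(uptake_bounds), names(caps))
  caps[hit] <- uptake_bounds[hit]
  ub[R + prob$mut_idx] <- caps
  # non-mutable capped exchanges (none in the packaged models, but allowed)
  other <- setdiff(names(uptake_bounds), names(caps))
  if (length(other)) ub[R + match(other, model$reactions)] <- uptake_bounds[other]

  ws <- problem_ws(prob)
  k1 <- if (warm_key >= 0) 2L * warm_key else -1L
  s1 <- lp_workspace_solve(ws, prob$c_growth, lb, ub, TRUE, k1)
  if (s1$status == 1L) return(empty_solution(model, "infeasible"))
  if (s1$status != 0L)
    stop("FBA solver failure (stage 1, status ", s1$status, ")", call. = FALSE)
  mu <- s1$obj
  x1 <- s1$x
  if (!pfba) {
    v <- x1[seq_len(R)] - x1[R + seq_len(R)]
    return(make_solution(model, mu, v, sum(abs(v)), mu))
  }
  lb2 <- lb; ub2 <- ub
  lb2[prob$bio_idx] <- max(0, mu - 1e-9)
  ub2[prob$bio_idx] <- mu + 1e-9
  k2 <- if (warm_key >= 0) 2L * warm_key + 1L else -1L
  s2 <- lp_workspace_solve(ws, prob$c_flux, lb2, ub2, FALSE, k2)
  if (s2$status != 0L) {
    # stage-2 failure: fall back to the stage-1 fluxes (recorded in status)
    v <- x1[seq_len(R)] - x1[R + seq_len(R)]
    sol <- make_solution(model, mu, v, sum(abs(v)), mu)
    sol$status <- "optimal_stage1_only"
    return(sol)
  }
  v <- s2$x[seq_len(R)] - s2$x[R + seq_len(R)]
  make_solution(model, v[prob$bio_idx], v, s2$obj, mu)
}

empty_solution <- function(model, status) {
  v <- stats::setNames(rep(0, length(model$reactions)), model$reactions)
  structure(list(
    status = status, growth_rate = 0, fluxes = v,
    exchange_fluxes = -v[model$exchange_reactions],
    total_flux = 0, stage1_growth = 0
  ), class = "fba_solution")
}

make_solution <- function(model, mu, v, total_flux, mu1) {
  names(v) <- model$reactions
  structure(list(
    status = "optimal", growth_rate = mu, fluxes = v,
    exchange_fluxes = -v[model$exchange_reactions],
    total_flux = total_flux, stage1_growth = mu1
  ), class = "fba_solution")
}

#' Drop cached warm-start bases for genotypes
#'
#' Frees the per-genotype bases held by the compiled solver workspace once
#' genotypes go extinct; called by [run_experiment()].
#'
#' @param prob an `fba_problem`.
#' @param keys integer genotype keys.
#' @keywords internal
forget_warm_keys <- function(prob, keys) {
  ws <- prob$env$ws
  if (!is.null(ws) && length(keys))
    lp_workspace_forget(ws, as.integer(c(2 * keys, 2 * keys + 1)))
  invisible(NULL)
}
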