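# The evolvable unit: a genotype is a vector of maximum uptake rates (v_max)
# over the mutable exchanges (14 carbon sources + oxygen for the core model),
# summing exactly to the global budget C_total. Mutations perturb one entry
# and renormalize the rest so the budget is conserved.

#' Create the ancestral genotype
#'
#' @param model an `evofba_model`.
#' @param v_max named numeric vector of initial maximum uptake rates; names
#'   are friendly substrate names or exchange ids. Unlisted mutable
#'   exchanges get 0. Must sum to `C_total` (within 1e-9).
#' @param C_total global uptake budget (mmol/gDW/h).
#' @return a genotype: list with `id` (1), `parent_id` (NA), `v_max` (named
#'   over all mutable exchange ids), `birth` (cycle 0, step 0).
#' @export
ancestor_genotype <- function(model, v_max = c(glucose = 10, acetate = 10,
                                               oxygen = 20), C_total = 40) {
  v_max <- unlist(v_max)
  ids <- resolve_exchange(model, names(v_max))
  full <- stats::setNames(rep(0, length(model$mutable_exchanges)),
                          model$mutable_exchanges)
  full[ids] <- as.numeric(v_max)
  g <- new_genotype(1L, NA_integer_, full, c(0L, 0L))
  check_genotype(g, C_total)
  g
}

new_genotype <- function(id, parent_id, v_max, birth) {
  structure(list(id = as.integer(id), parent_id = parent_id, v_max = v_max,
                 birth = birth), class = "evofba_genotype")
}

check_genotype <- function(g, C_total = 40) {
  if (abs(sum(g$v_max) - C_total) > 1e-9)
    stop("uptake budget violated: sum(v_max) = ", sum(g$v_max),
         " != ", C_total, call. = FALSE)
  if (any(g$v_max < -1e-12) || any(g$v_max > C_total + 1e-12))
    stop("v_max entries must lie in [0, C_total]", call. = FALSE)
  invisible(g)
}

#' Expected number of mutants produced in one time step
#'
#' `N_m = N * mu / (ln 2 * 60) * rate`: the number of cell divisions in one
#' simulated minute times the per-cell per-generation mutation rate.
#'
#' @param N population size (cells).
#' @param mu growth rate (1/h).
#' @param rate mutations per cell per generation (default 1e-6).
#' @return expected mutants (real).
#' @export
expected_mutants <- function(N, mu, rate = 1e-6) {
  if (any(N < 0) || any(mu < 0) || any(rate <= 0))
    stop("expected_mutants: N, mu must be >= 0 and rate > 0", call. = FALSE)
  N * mu / (LN2 * 60) * rate
}

#' Draw the number of mutants introduced this step
#'
#' At most one mutant per genotype per step: returns 1 with probability
#' `N_m` when `N_m < 1`, always 1 when `N_m >= 1`, else 0.
#'
#' @param N_m expected mutants (`>= 0`).
#' @return integer 0 or 1.
#' @export
draw_mutation_count <- function(N_m) {
  if (N_m < 0) stop("N_m must be >= 0", call. = FALSE)
  if (N_m >= 1) return(1L)
  if (N_m > 0 && stats::runif(1) < N_m) 1L else 0L
}

#' Mutate a genotype's uptake capacities
#'
#' Picks one mutable exchange uniformly at random, perturbs its v_max by
#' `a ~ Uniform(-A, A)`, clamps the result to `[0, C_total]`, and rescales
#' every other mutable exchange proportionally so the total stays exactly
#' `C_total`. If all other entries are zero, the remaining budget is spread
#' uniformly over them.
#'
#' @param parent parent genotype.
#' @param A maximum mutation step size (mmol/gDW/h); 10 by default, 1 in the
#'   small-step variant.
#' @param C_total global uptake budget.
#' @param id id to assign to the child (sequential by creation).
#' @param birth `c(cycle, step)` stamp.
#' @param target,a override the random choice of mutated exchange (id or
#'   index) and step size; both are drawn randomly when `NULL` (the normal
#'   evolutionary use).
#' @return list with `genotype` (the child) and `event` (list with
#'   `parent_id`, `child_id`, `mutated_exchange`, `a`, `v_max`).
#' @export
mutate <- function(parent, A = 10, C_total = 40, id = parent$id + 1L,
                   birth = c(NA_integer_, NA_integer_), target = NULL,
                   a = NULL) {
  v <- parent$v_max
  m <- if (is.null(target)) sample(length(v), 1L)
       else if (is.character(target)) match(target, names(v))
       else as.integer(target)
  if (is.na(m)) stop("unknown mutation target", call. = FALSE)
  if (is.null(a)) a <- stats::runif(1, -A, A)
  vm_new <- min(max(v[[m]] + a, 0), C_total)
  rest <- sum(v[-m])
  v_new <- v
  v_new[[m]] <- vm_new
  if (rest > 0) {
    v_new[-m] <- v[-m] / rest * (C_total - vm_new)
  } else {
    v_new[-m] <- (C_total - vm_new) / (length(v) - 1L)
  }
  # guard against drift: renormalize the non-mutated block exactly
  child <- new_genotype(id, parent$id, v_new, birth)
  check_genotype(child, C_total)
  list(genotype = child,
       event = list(parent_id = parent$id, child_id = as.integer(id),
                    mutated_exchange = names(v)[[m]], a = a,
                    v_max = v_new))
}

#' Seed a freshly arisen mutant into the population
#'
#' The mutant starts as exactly one cell; the parent loses one cell's worth
#' of biomass so total biomass is conserved. If the parent holds less than
#' one cell the event is a no-op and `NULL` is returned (caller logs it).
#'
#' @param biomass named biomass vector (gDW by genotype id).
#' @param parent_id id (as character or integer) of the parent.
#' @param child_id id of the new genotype.
#' @param cell_mass mass of one cell in gDW (default 6e-13, i.e. 600 fg).
#' @return updated biomass vector, or `NULL` when the parent is below one
#'   cell.
#' @export
spawn_mutant <- function(biomass, parent_id, child_id, cell_mass = 6e-13) {
  pid <- as.character(parent_id)
  if (!pid %in% names(biomass) || biomass[[pid]] < cell_mass) return(NULL)
  biomass[[pid]] <- biomass[[pid]] - cell_mass
  biomass[[as.character(child_id)]] <- cell_mass
  biomass
}
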