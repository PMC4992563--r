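# Independent brute-force LP oracle for the toy overflow model, written
# before (and independently of) the package's simplex: enumerates all basic
# solutions of the stage-1 FBA polytope and returns the best feasible
# objective. Variables (all bounded):
#   r = respiration, f = overflow, g = acetate respiration, z = growth,
#   u_glc, u_ac, u_o2 = uptakes, s_ac = acetate secretion,
#   e_co2 = CO2 secretion, slack = unused uptake budget.
# Metabolite balances are written out by hand from the toy stoichiometry;
# glucose/oxygen secretion variables are omitted (never beneficial, zero at
# any optimum).
toy_oracle_mu <- function(cap_glc, cap_ac, cap_o2, C_total = 40) {
  A <- rbind(
    glc  = c(r = -1, f = -1, g = 0, z = 0,   u_glc = 1, u_ac = 0, u_o2 = 0,
             s_ac = 0, e_co2 = 0, slack = 0),
    ac   = c(0, 1, -1, 0, 0, 1, 0, -1, 0, 0),
    o2   = c(-1, 0, -1, 0, 0, 0, 1, 0, 0, 0),
    co2  = c(0, 2, 0, 0, 0, 0, 0, 0, -1, 0),
    prec = c(3, 1, 1, -30, 0, 0, 0, 0, 0, 0),
    bud  = c(0, 0, 0, 0, 1, 1, 1, 0, 0, 1))
  b <- c(0, 0, 0, 0, 0, C_total)
  lb <- rep(0, 10)
  ub <- c(1000, 1000, 1000, 1000, cap_glc, cap_ac, cap_o2, 1000, 1000, C_total)
  m <- nrow(A); n <- ncol(A)
  best <- -Inf
  combs <- utils::combn(n, m)
  corners <- as.matrix(expand.grid(rep(list(c(0, 1)), n - m)))
  for (k in seq_len(ncol(combs))) {
    B <- combs[, k]
    AB <- A[, B, drop = FALSE]
    if (abs(det(AB)) < 1e-10) next
    Nn <- setdiff(seq_len(n), B)
    for (ci in seq_len(nrow(corners))) {
      xN <- ifelse(corners[ci, ] == 1, ub[Nn], lb[Nn])
      xB <- solve(AB, b - A[, Nn, drop = FALSE] %*% xN)
      if (any(xB < lb[B] - 1e-9) || any(xB > ub[B] + 1e-9)) next
      x <- numeric(n); x[B] <- xB; x[Nn] <- xN
      if (x[4] > best) best <- x[4]
    }
  }
  if (!is.finite(best)) return(NA_real_)   # infeasible (cannot happen: 0 works)
  best
}

# caps in the package's named convention, for convenience in tests
toy_caps <- function(glc, ac, o2) c(EX_glc_e = glc, EX_ac_e = ac, EX_o2_e = o2)

# a toy genotype with v_max summing to C_total
toy_genotype <- function(glc, ac, o2, id = 1L, C_total = 40) {
  m <- make_toy_model()
  stopifnot(abs(glc + ac + o2 - C_total) < 1e-9)
  g <- ancestor_genotype(m, c(glucose = glc, acetate = ac, oxygen = o2),
                         C_total)
  g$id <- as.integer(id)
  g
}

# one cached smoke-scale evolution run, shared across test files
smoke_run <- local({
  cache <- NULL
  function(seed = 42L, ...) {
    key <- paste(seed, ...)
    if (is.null(cache) || !identical(attr(cache, "key"), key)) {
      res <- run_experiment(scale_preset("smoke", seed = seed, ...))
      attr(res, "key") <- key
      cache <<- res
    }
    cache
  }
})
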