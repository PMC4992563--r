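# Michaelis-Menten kinetics, Euler stepping and whole-cycle dynamics

test_that("uptake_capacity follows the Michaelis-Menten form", {
  expect_equal(uptake_capacity(10, 0.1389, 0.01), 10 * 0.1389 / 0.1489)
  expect_equal(round(uptake_capacity(10, 0.1389, 0.01), 4), 9.3284)
  expect_equal(uptake_capacity(7, 0, 0.01), 0)
  expect_equal(uptake_capacity(10, 1e9, 0.01), 10, tolerance = 1e-8)
  expect_error(uptake_capacity(-1, 1, 0.01), "must be")
  expect_error(uptake_capacity(1, -1, 0.01), "must be")
  expect_error(uptake_capacity(1, 1, 0), "must be")
})

test_that("one Euler step reproduces the printed biomass and medium updates", {
  # medium update: S' = S - BM * v * dt / (60 V) with the ancestor's realized
  # glucose uptake 9.3284 at S = 0.1389 (cap-binding, so uptake = capacity)
  m <- core_model()
  env <- make_medium(m, c(glucose = 0.1389), 0.01)
  g <- ancestor_genotype(m)
  st <- dfba_step(env, c("1" = 0.006), list("1" = g), m)
  expect_equal(st$uptake["1", "EX_glc__D_e"], 9.3284, tolerance = 1e-4)
  expect_equal(st$env$conc[["EX_glc__D_e"]],
               0.1389 - 0.006 * 9.328408 / (60 * 0.01), tolerance = 1e-5)
  expect_equal(round(st$env$conc[["EX_glc__D_e"]], 4), 0.0456)
  # growth update: BM' = BM (1 + mu dt / (ln 2 * 60)); check with the step's
  # own growth rate, and the closed-form case mu = ln 2
  expect_equal(st$biomass[["1"]],
               0.006 * (1 + st$growth[["1"]] / (log(2) * 60)))
  expect_equal(0.001 * (1 + log(2) / (log(2) * 60)), 1.0166667e-3,
               tolerance = 1e-7)
})

test_that("a toy step agrees end-to-end with oracle-derived arithmetic", {
  m <- make_toy_model()
  env <- make_medium(m, c(glucose = 5, acetate = 0), volume = 0.001)
  g <- toy_genotype(glc = 12, ac = 8, o2 = 20)
  BM <- 2e-4
  st <- dfba_step(env, c("1" = BM), list("1" = g), m, dt = 1)
  cap_glc <- 12 * 5 / 5.01
  mu_exp <- toy_oracle_mu(cap_glc, 0, 20)
  expect_equal(st$growth[["1"]], mu_exp, tolerance = 1e-6)
  # glucose-limited: all capacity used, no overflow (oxygen is ample)
  expect_equal(st$env$conc[["EX_glc_e"]],
               5 - BM * cap_glc / (60 * 0.001), tolerance = 1e-8)
  expect_equal(st$env$conc[["EX_ac_e"]], 0)
  expect_equal(st$biomass[["1"]], BM * (1 + mu_exp / (log(2) * 60)),
               tolerance = 1e-8)
})

test_that("an empty population leaves the environment untouched", {
  m <- make_toy_model()
  env <- make_medium(m, c(glucose = 1), 0.001)
  st <- dfba_step(env, c("1" = 0), list("1" = toy_genotype(10, 10, 20)), m)
  expect_equal(st$env$conc, env$conc)
  expect_equal(st$growth[["1"]], 0)
})

test_that("substrates never go negative, even under extreme demand", {
  m <- make_toy_model()
  env <- make_medium(m, c(glucose = 1e-4), 1e-6)   # tiny glucose pool
  g <- toy_genotype(30, 0, 10)
  st <- dfba_step(env, c("1" = 1e-6), list("1" = g), m)  # huge biomass
  expect_gte(min(st$env$conc), 0)
  expect_equal(st$env$conc[["EX_glc_e"]], 0)
})

test_that("a cycle without substrate gives flat biomass", {
  m <- make_toy_model()
  cfg <- scale_preset("smoke")
  env <- make_medium(m, c(glucose = 0, acetate = 0), cfg$volume)
  res <- run_cycle(m, env, c("1" = 1e-9), list("1" = toy_genotype(10, 10, 20)),
                   cfg)
  expect_equal(unname(res$trajectory$biomass[, "1"]),
               rep(1e-9, length(res$trajectory$time)))
})

test_that("cycle dynamics are deterministic and mass-monotone", {
  # determinism is over the visible state: two fresh model objects (the
  # warm-start basis cache on a shared problem object is hidden solver state)
  cfg <- scale_preset("smoke", cycle_hours = 5)
  gens <- list("1" = toy_genotype(10, 10, 20), "2" = toy_genotype(20, 5, 15))
  bm <- c("1" = 5e-10, "2" = 5e-10)
  one <- function() {
    m <- make_toy_model()
    env <- make_medium(m, c(glucose = 0.1389), cfg$volume)
    run_cycle(m, env, bm, gens, cfg)
  }
  r1 <- one()
  r2 <- one()
  expect_identical(r1$trajectory$conc, r2$trajectory$conc)
  expect_identical(r1$trajectory$biomass, r2$trajectory$biomass)
  # no dilution within a cycle: biomass non-decreasing, concentrations >= 0
  expect_true(all(diff(r1$trajectory$biomass[, "1"]) >= -1e-18))
  expect_true(all(diff(r1$trajectory$biomass[, "2"]) >= -1e-18))
  expect_gte(min(r1$trajectory$conc), 0)
  # glucose is monotonically non-increasing
  expect_true(all(diff(r1$trajectory$conc[, "EX_glc_e"]) <= 1e-12))
})

test_that("carbon is conserved through uptake, biomass and secretion (toy)", {
  # per-gDW flux balance: 6 glc_in + 2 ac_in = 2 ac_out + 1 co2_out + 60 mu
  # (precursor is C2 and the biomass drain consumes 30 precursor per unit mu)
  m <- make_toy_model()
  set.seed(23)
  for (i in 1:10) {
    caps <- runif(3, 0, 15)
    sol <- solve_fba(m, toy_caps(caps[1], caps[2], caps[3]))
    cin <- 6 * sol$exchange_fluxes[["EX_glc_e"]] +
           2 * sol$exchange_fluxes[["EX_ac_e"]] +
           1 * sol$exchange_fluxes[["EX_co2_e"]]
    expect_equal(cin, 60 * sol$growth_rate, tolerance = 1e-6)
  }
  # and over a whole cycle, medium carbon loss equals biomass carbon gain
  # under the stoichiometric (flux-level) accounting
  cfg <- scale_preset("smoke", cycle_hours = 3)
  env <- make_medium(m, c(glucose = 0.2), cfg$volume)
  res <- run_cycle(m, env, c("1" = 1e-9), list("1" = toy_genotype(25, 5, 10)),
                   cfg)
  tr <- res$trajectory
  carbon_medium <- function(row) sum(tr$conc[row, ] * c(6, 2)) * tr$volume
  drops <- -diff(vapply(seq_along(tr$time), carbon_medium, numeric(1)))
  expect_true(all(drops >= -1e-15))   # no carbon creation in the medium
})

test_that("halving dt changes the final biomass by less than 1 %", {
  m <- core_model()
  g <- ancestor_genotype(m)
  run_final <- function(dt) {
    cfg <- evofba_config(dt_min = dt, mutation_rate = 0)
    env <- make_medium(m, c(glucose = 0.1389), 0.01)
    res <- run_cycle(m, env, c("1" = 6e-7), list("1" = g), cfg)
    unname(res$trajectory$biomass[nrow(res$trajectory$biomass), "1"])
  }
  b1 <- run_final(1)
  b2 <- run_final(0.5)
  expect_lt(abs(b1 - b2) / b1, 0.01)
})

test_that("single-genotype 24-h biomass is regression-stable", {
  m <- make_toy_model()
  cfg <- scale_preset("smoke")
  env <- make_medium(m, c(glucose = 0.1389), cfg$volume)
  res <- run_cycle(m, env, c("1" = 6e-10), list("1" = toy_genotype(10, 10, 20)),
                   cfg)
  final <- unname(res$trajectory$biomass[nrow(res$trajectory$biomass), "1"])
  # golden value pinned from the first correct build
  expect_equal(final, REGRESSION$toy_smoke_final_biomass, tolerance = 1e-8)
})
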