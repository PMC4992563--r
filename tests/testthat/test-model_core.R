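# model loading and the two-stage FBA solve

test_that("packaged core model loads with the expected structure", {
  m <- core_model()
  expect_s3_class(m, "evofba_model")
  expect_length(m$reactions, 95)
  expect_length(m$exchange_reactions, 20)
  expect_length(m$mutable_exchanges, 15)
  expect_length(m$unlimited_exchanges, 5)
  expect_true(m$biomass_reaction %in% m$reactions)
  expect_identical(dim(m$S),
                   c(length(m$metabolites), length(m$reactions)))
  # the mutable set is exactly the 14 carbon sources plus oxygen
  expect_setequal(m$mutable_exchanges,
                  c("EX_ac_e", "EX_acald_e", "EX_akg_e", "EX_etoh_e",
                    "EX_for_e", "EX_fru_e", "EX_fum_e", "EX_glc__D_e",
                    "EX_gln__L_e", "EX_glu__L_e", "EX_lac__D_e",
                    "EX_mal__L_e", "EX_pyr_e", "EX_succ_e", "EX_o2_e"))
})

test_that("SBML (L3+FBC) and built-in constructors agree on the toy model", {
  m1 <- make_toy_model()
  m2 <- load_model(fixture_path("toy_sbml"), "sbml")
  m3 <- load_model(fixture_path("toy_json"), "json")
  for (m in list(m2, m3)) {
    expect_setequal(m$reactions, m1$reactions)
    expect_setequal(m$metabolites, m1$metabolites)
    expect_equal(m$S[m1$metabolites, m1$reactions], m1$S)
    expect_equal(m$lb[m1$reactions], m1$lb)
    expect_equal(m$biomass_reaction, m1$biomass_reaction)
    expect_setequal(m$exchange_reactions, m1$exchange_reactions)
  }
  expect_length(m1$exchange_reactions, 4)
})

test_that("malformed models raise named format errors", {
  bad <- tempfile(fileext = ".json")
  writeLines(jsonlite::toJSON(list(
    id = "bad",
    metabolites = list(list(id = "a_c")),
    reactions = list(list(id = "R1", metabolites = list(ghost_c = -1),
                          lower_bound = 0, upper_bound = 10,
                          objective_coefficient = 1))),
    auto_unbox = TRUE), bad)
  expect_error(load_model(bad, "json"), "undeclared metabolite.*ghost_c|ghost_c")
  nobio <- tempfile(fileext = ".json")
  writeLines(jsonlite::toJSON(list(
    id = "nobio",
    metabolites = list(list(id = "a_c")),
    reactions = list(list(id = "R1", metabolites = list(a_c = -1),
                          lower_bound = 0, upper_bound = 10))),
    auto_unbox = TRUE), nobio)
  expect_error(load_model(nobio, "json"), "biomass")
  expect_error(load_model(tempfile(), "json"), "not found")
})

test_that("toy FBA optima match the independent brute-force LP oracle", {
  m <- make_toy_model()
  # spec'd spot checks
  sol <- solve_fba(m, toy_caps(10, 0, 20))
  expect_equal(sol$growth_rate, 1.0, tolerance = 1e-9)  # 3 * 10 / 30
  expect_equal(sol$growth_rate, toy_oracle_mu(10, 0, 20), tolerance = 1e-6)
  sol2 <- solve_fba(m, toy_caps(10, 10, 20))
  expect_equal(sol2$growth_rate, toy_oracle_mu(10, 10, 20), tolerance = 1e-6)
  # random caps, including budget-binding regimes
  set.seed(7)
  for (i in 1:25) {
    caps <- runif(3, 0, 20)
    mu_pkg <- solve_fba(m, toy_caps(caps[1], caps[2], caps[3]))$growth_rate
    mu_orc <- toy_oracle_mu(caps[1], caps[2], caps[3])
    expect_equal(mu_pkg, mu_orc, tolerance = 1e-6,
                 label = paste("caps", paste(round(caps, 3), collapse = "/")))
  }
})

test_that("zero uptake caps give zero growth and zero exchange", {
  for (m in list(make_toy_model(), core_model())) {
    sol <- solve_fba(m, setNames(rep(0, length(m$mutable_exchanges)),
                                 m$mutable_exchanges))
    expect_equal(sol$growth_rate, 0)
    expect_true(all(abs(sol$exchange_fluxes[m$mutable_exchanges]) < 1e-9))
  }
})

test_that("ancestral core model secretes acetate under glucose-replete bounds", {
  m <- core_model()
  sol <- solve_fba(m, c(glucose = 10, acetate = 10, oxygen = 20))
  expect_equal(sol$status, "optimal")
  expect_gt(sol$growth_rate, 0.5)
  # uptake-positive convention: secretion is negative
  expect_lt(sol$exchange_fluxes[["EX_ac_e"]], -1e-6)
})

test_that("late-phase acetate co-consumption is strictly growth-optimal", {
  # with the oxygen bound no longer saturated by glucose, taking up available
  # acetate raises mu; this is why the ancestor consumes its acetate pool
  # concurrently with the glucose tail rather than strictly after it
  m <- core_model()
  with_ac <- solve_fba(m, c(glucose = 9, acetate = 0.5, oxygen = 20))
  no_ac <- solve_fba(m, c(glucose = 9, acetate = 0, oxygen = 20))
  expect_gt(with_ac$exchange_fluxes[["EX_ac_e"]], 1e-3)   # uptake
  expect_gt(with_ac$growth_rate, no_ac$growth_rate + 1e-6)
  # whereas at a saturated oxygen bound the same pool is left untouched
  sat <- solve_fba(m, c(glucose = 10, acetate = 0.5, oxygen = 20))
  expect_lt(sat$exchange_fluxes[["EX_ac_e"]], 1e-9)       # secretion instead
})

test_that("optimal solutions satisfy steady state, bounds and the budget", {
  m <- core_model()
  set.seed(11)
  for (i in 1:10) {
    caps <- setNames(runif(15, 0, 8), m$mutable_exchanges)
    sol <- solve_fba(m, caps)
    if (sol$status != "optimal") next
    expect_lt(max(abs(m$S %*% sol$fluxes)), 1e-6)
    up <- pmax(sol$exchange_fluxes[m$mutable_exchanges], 0)
    expect_lt(sum(up), 40 + 1e-6)
    expect_true(all(up <= caps[names(up)] + 1e-6))
    expect_true(all(sol$fluxes >= m$lb - 1e-6 | names(sol$fluxes) %in% m$exchange_reactions))
  }
})

test_that("raising a single uptake cap never decreases the optimum", {
  m <- make_toy_model()
  set.seed(13)
  for (i in 1:20) {
    caps <- runif(3, 0, 15)
    mu0 <- solve_fba(m, toy_caps(caps[1], caps[2], caps[3]))$growth_rate
    j <- sample(3, 1)
    caps2 <- caps; caps2[j] <- caps2[j] + runif(1, 0, 10)
    mu1 <- solve_fba(m, toy_caps(caps2[1], caps2[2], caps2[3]))$growth_rate
    expect_gte(mu1, mu0 - 1e-8)
  }
})

test_that("stage 2 only ever shrinks total absolute flux at fixed growth", {
  m <- core_model()
  set.seed(17)
  for (i in 1:5) {
    caps <- setNames(runif(15, 0, 8), m$mutable_exchanges)
    s1 <- solve_fba(m, caps, pfba = FALSE)
    s2 <- solve_fba(m, caps, pfba = TRUE)
    expect_equal(s2$growth_rate, s1$growth_rate, tolerance = 1e-7)
    expect_lte(s2$total_flux, sum(abs(s1$fluxes)) + 1e-6)
  }
})
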