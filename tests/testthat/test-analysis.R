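# survivor statistics, lineage graphs, diauxie detection, flux snapshots

# minimal synthetic experiment results for graph/survivor logic
fake_result <- function(parents, counts_post, counts_end = counts_post,
                        vmax = NULL) {
  m <- make_toy_model()
  ids <- seq_along(parents)
  gens <- stats::setNames(lapply(ids, function(i) {
    v <- if (is.null(vmax)) c(EX_glc_e = 20, EX_ac_e = 10, EX_o2_e = 10)
         else vmax[[i]]
    evofba:::new_genotype(i, parents[[i]], v, c(0L, 0L))
  }), as.character(ids))
  structure(list(
    config = scale_preset("smoke"), model_id = "toy_overflow",
    genotypes = gens, events = list(),
    counts_post = counts_post, counts_end = counts_end,
    medium = matrix(0, length(counts_post), 2,
                    dimnames = list(NULL, c("EX_glc_e", "EX_ac_e"))),
    trajectories = list(), final = NULL, seed = 1L, version = "0"
  ), class = "evofba_experiment")
}

test_that("survivors counts genotypes by post-dilution persistence", {
  res <- fake_result(parents = c(NA, 1L, 1L),
                     counts_post = list(c("1" = 10, "2" = 1),
                                        c("1" = 12),
                                        c("1" = 9, "3" = 2)))
  expect_equal(survivors(res, 1L), c(1L, 2L, 3L))
  expect_equal(survivors(res, 2L), 1L)
  # a genotype extinct at its first dilution never appears in counts
  res2 <- fake_result(parents = c(NA, 1L),
                      counts_post = list(c("1" = 10), c("1" = 10)))
  expect_equal(survivors(res2, 1L), 1L)
})

test_that("survivors agrees with an independent tally of the written table", {
  res <- smoke_run(seed = 42L)
  dir <- tempfile(); write_result(res, dir)
  tsv <- read.delim(file.path(dir, "survivors.tsv"))
  tally <- table(tsv$genotype_id[tsv$cells >= 1])
  expect_equal(survivors(res, 1L), sort(as.integer(names(tally))))
  expect_equal(survivors(res, 3L), sort(as.integer(names(tally)[tally >= 3]))
  )
})

test_that("lineage graphs restrict and reconnect through missing ancestors", {
  chain <- fake_result(parents = c(NA, 1L, 2L),
                       counts_post = list(c("1" = 100, "2" = 30, "3" = 50)))
  g0 <- build_lineage_graph(chain, min_peak_cells = 0)
  expect_setequal(igraph::V(g0)$name, c("1", "2", "3"))
  ed <- igraph::as_edgelist(g0)
  expect_setequal(paste(ed[, 1], ed[, 2]), c("1 2", "2 3"))
  # node 2 below threshold: edge contracts to 1 -> 3
  g1 <- build_lineage_graph(chain, min_peak_cells = 40 * 0 + 31)
  expect_setequal(igraph::V(g1)$name, c("1", "3"))
  ed1 <- igraph::as_edgelist(g1)
  expect_equal(paste(ed1[, 1], ed1[, 2]), "1 3")
  # the ancestor is retained even when below threshold
  g2 <- build_lineage_graph(chain, min_peak_cells = 1e9)
  expect_true("1" %in% igraph::V(g2)$name)
  # orphan parent is a data-integrity error
  orphan <- fake_result(parents = c(NA, 7L),
                        counts_post = list(c("1" = 10, "2" = 10)))
  expect_error(build_lineage_graph(orphan, 0), "data-integrity")
})

test_that("contraction preserves ancestor-descendant reachability", {
  # brute-force oracle: walk parent chains in the full registry
  set.seed(53)
  for (rep in 1:5) {
    n <- sample(10:50, 1)
    parents <- c(NA_integer_, vapply(2:n, function(i) sample(i - 1L, 1L),
                                     integer(1)))
    counts <- stats::setNames(sample(0:100, n, replace = TRUE), seq_len(n))
    counts["1"] <- 100
    res <- fake_result(parents, counts_post = list(counts))
    thr <- sample(0:80, 1)
    g <- build_lineage_graph(res, thr)
    kept <- as.integer(igraph::V(g)$name)
    anc_of <- function(i) {
      out <- integer(0); p <- parents[[i]]
      while (!is.na(p)) { out <- c(out, p); p <- parents[[p]] }
      out
    }
    d <- igraph::distances(g, mode = "out")
    for (v in kept) {
      anc_kept <- intersect(anc_of(v), kept)
      reach <- kept[is.finite(d[, as.character(v)]) &
                      kept != v]
      expect_setequal(reach, anc_kept)
    }
  }
})

test_that("the diauxic-shift detector reads engineered trajectories correctly", {
  mk_traj <- function(glc_up, ac_up) {
    n <- length(glc_up)
    fl <- matrix(0, n, 3, dimnames = list(NULL, c("EX_glc__D_e", "EX_ac_e",
                                                  "EX_o2_e")))
    fl[, 1] <- -glc_up; fl[, 2] <- -ac_up
    structure(list(time = 0:n, dt = 1, conc = NULL, biomass = NULL,
                   growth = NULL, fluxes = list("1" = fl), volume = 0.01,
                   aliases = c(glucose = "EX_glc__D_e", acetate = "EX_ac_e",
                               oxygen = "EX_o2_e")),
              class = "cycle_trajectory")
  }
  # classic diauxie: glucose phase then acetate phase
  tr <- mk_traj(glc_up = c(10, 10, 10, 0.05, 0, 0),
                ac_up = c(-1, -1, 0, 0, 2, 2))
  expect_equal(detect_diauxic_shift(tr, 1), 5)
  # co-consumption while glucose is still high: no qualifying switch
  tr2 <- mk_traj(glc_up = c(10, 10, 10, 10), ac_up = c(-1, 2, 2, 2))
  expect_true(is.na(detect_diauxic_shift(tr2, 1)))
  # no acetate at all
  tr3 <- mk_traj(glc_up = c(10, 10, 0, 0), ac_up = rep(0, 4))
  expect_true(is.na(detect_diauxic_shift(tr3, 1)))
})

test_that("glucose specialists show no diauxic shift in real dynamics", {
  m <- core_model()
  spec <- ancestor_genotype(m, c(glucose = 15, oxygen = 25))
  cfg <- evofba_config(mutation_rate = 0)
  env <- make_medium(m, c(glucose = 0.1389), 0.01)
  res <- run_cycle(m, env, c("1" = 6e-7), list("1" = spec), cfg,
                   record_fluxes_for = "1")
  expect_true(is.na(detect_diauxic_shift(res$trajectory, 1)))
  # it secreted acetate but never took it up
  ac <- -res$trajectory$fluxes[["1"]][, "EX_ac_e"]
  expect_lt(min(ac, na.rm = TRUE), 0)
  expect_lt(max(ac, na.rm = TRUE), 1e-6)
})

test_that("the 10-day protocol captures steady-state flux snapshots", {
  m <- core_model()
  anc <- ancestor_genotype(m)
  cfg <- evofba_config(mutation_rate = 0)
  snaps <- flux_snapshot_protocol(anc, m, cfg)
  g <- snaps$glucose
  expect_s3_class(g, "flux_snapshot")
  expect_equal(g$minute, 10)
  expect_gt(g$fluxes[["PGI"]], 1e-6)            # forward glycolysis
  expect_gt(g$fluxes[["EX_ac_e"]], 1e-6)        # acetate secretion (model conv)
  expect_lt(max(abs(m$S %*% g$fluxes)), 1e-6)   # steady state
  # a pure glucose specialist has no acetate phase
  spec <- ancestor_genotype(m, c(glucose = 15, oxygen = 25))
  snaps2 <- flux_snapshot_protocol(spec, m, cfg)
  expect_null(snaps2$acetate)
  # a genotype that cannot grow errors out
  dead <- ancestor_genotype(m, c(fumarate = 20, oxygen = 20))
  dead$v_max["EX_fum_e"] <- 0; dead$v_max["EX_o2_e"] <- 40
  expect_error(flux_snapshot_protocol(dead, m, cfg), "no growth")
})

test_that("acetate growth engages the glyoxylate shunt", {
  # grow on acetate alone: the acetate-phase biochemistry of the specialists
  m <- core_model()
  sol <- solve_fba(m, c(acetate = 10, oxygen = 30))
  expect_gt(sol$growth_rate, 0)
  expect_gt(sol$fluxes[["MALS"]], 1e-6)     # malate synthase (glyoxylate shunt)
  expect_gt(sol$fluxes[["ACONTb"]], 1e-6)   # full TCA
})

test_that("cycle counts convert to generations via the dilution factor", {
  expect_equal(round(cycles_to_generations(300, 0.01), 1), 1993.2)
  expect_equal(round(cycles_to_generations(550, 0.01), 1), 3654.1)
  expect_equal(cycles_to_generations(0, 0.5), 0)
  expect_error(cycles_to_generations(10, 1.2))
})
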