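# evofba

Evolutionary dynamic flux balance analysis (dFBA) of serial-transfer batch
cultures, for systems and evolutionary biologists who want to ask: *when does
a clonal population on a single limiting resource split into stably
coexisting cross-feeding specialists?*

The package simulates a daily 1:100 serial-transfer culture in glucose
minimal medium (the regime of the long-term *E. coli* evolution experiment).
Each genotype is a stoichiometric metabolic model — by default the *E. coli*
core model — carrying its own maximum uptake rates `v_max[j]` over 14 carbon
sources and oxygen, constrained by a fixed total budget:

    sum_j v_max[j] = C_total = 40 mmol/gDW/h

Within each 1-min step, uptake bounds follow Michaelis–Menten kinetics
`v_j = v_max[j]·S_j/(K_m + S_j)`, growth is computed by two-stage FBA
(maximize biomass, then minimize total |flux| at fixed growth, subject to an
explicit budget row `Σ uptake ≤ C_total`), and biomass and medium follow the
published Euler updates

    BM'   = BM · (1 + μ/(ln2·60))
    S_j'  = S_j − Σ_i BM_i · v_ji / (60·V)

Mutations strike each genotype with expected count
`N·μ/(ln2·60)·1e-6` per minute, perturb one uptake capacity by
Uniform(−10, 10), clamp to [0, 40], and renormalize the rest so the budget is
exact. At 24 h, survivors are drawn Binomial(N, 0.01) and the next day's
medium is 99 % fresh glucose (0.1389 mmol/l) + 1 % spent — so secreted
acetate carries over, and fast glucose consumers that overflow acetate
construct a niche for acetate specialists.

There is no LP solver in the supported R stack, so the package ships its own
bounded-variable revised simplex (Rcpp) with per-genotype warm starts; the
test suite validates it against an independently coded brute-force LP oracle
(vertex enumeration) on an analytically tractable toy overflow model.

## Worked example

```r
library(evofba)

m <- core_model()                       # packaged E. coli core model
m
#> Stoichiometric model: e_coli_core
#>   reactions:   95
#>   metabolites: 72
#>   exchanges:   20 (15 mutable, 5 unlimited)
#>   biomass:     Biomass_Ecoli_core

## ancestral physiology: glucose-replete bounds, oxygen capped at 20
solve_fba(m, c(glucose = 10, acetate = 10, oxygen = 20))
#> FBA solution: optimal
#>   growth rate: 0.832614 1/h
#>   ...
#>   secretion: EX_ac_e 1.803, ...
```

The ancestor grows at 0.83/h and — because its oxygen capacity cannot fully
respire 10 mmol/gDW/h of glucose — secretes 1.8 mmol/gDW/h of acetate:
overflow metabolism, the raw material of the cross-feeding niche.

```r
## a scaled-down evolution experiment (0.1-ml reactor, 20 cycles, ~1 min)
cfg <- scale_preset("desk", cycles = 20L, seed = 1L)
res <- run_experiment(cfg)
summary(res)
#> evoFBA experiment summary
#>   cycles run:            20
#>   genotypes created:     63
#>   survived >=1 transfer: 1
#>   final population:
#>  genotype_id cells v_max_glucose v_max_acetate
#>            1 28534            10            10

survivors(res, 1)                        # ids surviving >= 1 transfer
g <- build_lineage_graph(res, min_peak_cells = 1e3)
write_lineage_graph(g, "lineage.graphml")
cycles_to_generations(300, 0.01)         # 1993.2 generations
```

At full scale (`scale_preset("paper")`: 10 ml, 550 cycles) the published
protocol produced two coexisting lineages — a glucose specialist with
acetate uptake lost, and an acetate specialist retaining reduced glucose
uptake. The desk preset carries a 100-fold smaller mutation supply, so in
150 cycles it typically shows the early stages of the same process:
establishment of faster glucose consumers, a large rise in spent-medium
acetate, and divergence of coexisting lineages along the glucose/acetate
axis (see the methods vignette for what desk-scale runs do and do not
establish).

A thin CLI wraps the same functions:

```sh
Rscript inst/cli/evofba run --scale desk --cycles 20 --seed 1 --out out/
Rscript inst/cli/evofba survivors --dir out/
```

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

runs the full pipeline from scratch at a desk scale — a seeded
serial-transfer evolution experiment on the packaged core model followed by
the standard survivor analysis — and writes the results JSON.

## Layout

* `R/` — model I/O, FBA, batch-culture dynamics, mutation engine, transfer
  experiment, analysis; `src/simplex.cpp` — the LP solver.
* `inst/extdata/` — the vendored core model (JSON) and the toy overflow
  fixture (JSON + SBML).
* `vignettes/evofba-methods.Rmd` — the model, its assumptions, numerical
  choices and known limitations.
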