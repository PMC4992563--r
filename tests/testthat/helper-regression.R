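# Golden regression values pinned from the first correct build (toy model,
# smoke preset). These detect unintended behavioural drift, not correctness;
# the oracles in helper-oracle.R do that.
REGRESSION <- list(
  toy_smoke_final_biomass = 2.06390341154819e-08,
  smoke42_n_genotypes = 3L,
  smoke42_final_ids = 1L,
  smoke42_first_final_vmax = c(10, 10, 20)
)
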