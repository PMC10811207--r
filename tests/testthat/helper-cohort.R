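# Shared fixtures, built in code. Small enough to keep every unit file fast.

small_reference <- function(n = 10, seed = 2) {
  generate_reference_table(n, seed = seed)
}

# A compact cohort for structural tests: 20 foods, 10 parameters.
small_cohort <- function(n = 200, seed = 42, ...) {
  ref <- small_reference()
  cfg <- simulation_config(n, n_foods = 20, n_nutrients = 10,
                           seed = seed, ...)
  list(cfg = cfg, ref = ref, cohort = generate_cohort(cfg, ref))
}

# Matrix views used by the model fits.
cohort_matrices <- function(sc) {
  co <- sc$cohort
  list(G = as.matrix(co$grams[-1]),
       comp = as.matrix(co$composition[-1]),
       C = as.matrix(co$covariates[names(sc$cfg$covariate_effects)]),
       nutr = as.matrix(co$intakes[-1]),
       w = sc$ref$effect_score)
}
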