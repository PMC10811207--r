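# diinest

Dietary Inflammatory Index (DII) scoring and hierarchical regression for
nested dietary exposures, with DASS-42 mental-disorder scores as the
motivating outcomes.

## The problem

Estimating how a pro-inflammatory diet relates to depression, anxiety and
stress is confounded by the rest of the diet: foods are strongly
correlated (pro- and anti-inflammatory foods are eaten together), nutrient
intakes are exact linear functions of food intakes through the composition
matrix, and the DII is itself a function of the nutrients. A simple
regression of outcome on DII ignores this; a conventional multiple
regression that adjusts for all foods and nutrients at once is nearly
collinear and produces wide, unstable intervals.

`diinest` implements the hierarchical (semi-Bayes) middle ground. Exposures
enter at three nested levels — foods at level 1, nutrients at level 2, the
DII at level 3:

    y    = α + C c + F β + ε,           ε ~ N(0, σ² I)
    β    = Z π + δ,                     δ ~ N(0, τ²_f I)   (foods ← nutrients)
    π    = w γ + θ,                     θ ~ N(0, τ²_n I)   (nutrients ← DII weights)

where `F` holds standardized daily food grams, `Z` the standardized
per-100 g composition bridge, `w` the inflammatory effect scores, and `γ`
is the diet-level (DII) effect. Equivalently this is the linear mixed model
`y = α + Cc + (FZw)γ + (FZ)θ + Fδ + ε` with marginal covariance
`V = σ²I + τ²_f FF' + τ²_n (FZ)(FZ)'`. Variance components are estimated
by REML (the empirical-Bayes step), fixed effects by GLS, and the residual
effects `δ̂, θ̂` as posterior means from Henderson's equations; food
effects are thereby shrunk toward their nutrient-composition predictions.
Intervals for the DII effect use a Kenward–Roger-style adjusted covariance
with Satterthwaite degrees of freedom (see the methods vignette for why).

The package also provides the surrounding pipeline: FFQ → daily grams →
nutrient intakes, a ±3 SD energy exclusion rule, DASS-42 subscale scoring,
the DII engine (Z-score → centered percentile → effect-score weighting →
sum → quartiles), conventional simple/multiple baselines, a three-model
comparison report, and a synthetic cohort generator (no cohort data are
deposited; the generator emulates the full structure with recorded ground
truth).

## Worked example

A collinear synthetic cohort (intake correlation 0.9), the energy filter,
DII scoring, and the three fits for the stress subscale:

```r
library(diinest)

ref    <- generate_reference_table(25, seed = 1)
cfg    <- simulation_config(n_participants = 500, intake_correlation = 0.9, seed = 1)
cohort <- generate_cohort(cfg, ref)

excl <- energy_exclusion(cohort$intakes)          # +/-3 SD on kcal/day
keep <- excl$retained$participant_id
dii  <- compute_dii(excl$retained, ref)           # normal-CDF percentiles

idx <- match(keep, cohort$outcomes$participant_id)
y   <- score_dass(cohort$dass_items)[idx, ]       # 0-42 subscale totals
G   <- as.matrix(cohort$grams[idx, -1])
Cv  <- as.matrix(cohort$covariates[idx, names(cfg$covariate_effects)])

spec <- hier_spec(G, as.matrix(cohort$composition[-1]), ref$effect_score,
                  covariates = Cv)
fh <- fit_hierarchical(spec, y$stress, "stress")
fs <- fit_simple(y$stress, dii$dii$dii, "stress")
fm <- fit_multiple(y$stress, dii$dii$dii, covariates = Cv,
                   nutrients = as.matrix(excl$retained[-1]), foods = G,
                   outcome_name = "stress")
compare_models(fs, fm, fh)
```

which prints:

```
excluded 7 of 500 participants (1.4%)
DII scores for 493 participants over 25 parameters (normal_cdf)
  overall DII: mean -0.029, sd 0.206, range [-0.650, 0.348]
hierarchical model fit (stress), n = 493
  DII coefficient: 0.0717 (se 0.0588, 95% CI -0.0469 to 0.1904)
  tau2 (food, nutrient): 0.00050, 0.00050; residual 71.5181
DII coefficient across models (outcome: stress)
        model outcome estimate      se   lower  upper ci_width dii_sd
       simple  stress -0.26633 1.91402 -4.0178 3.4852   7.5030 0.2057
     multiple  stress -2.92073 2.48603 -7.7934 1.9519   9.7452 0.2057
 hierarchical  stress  0.07173 0.05876 -0.0469 0.1904   0.2373 6.7529
hierarchical CI narrower than multiple (per-SD scale): TRUE
```

Reading this: the 7 planted energy outliers are exactly the participants
the ±3 SD rule removes. The conventional multiple model — DII plus 12
covariates, 116 foods and 25 nutrients jointly — returns a DII coefficient
of −2.9 with a CI spanning ±5 points of stress score: collinearity has
destroyed it. The hierarchical fit shrinks the food effects toward their
nutrient predictions and returns a far tighter interval (widths are
compared per SD of each model's own DII variable, since the composite
`FZw` and the percentile-based DII are on different scales); its estimate
0.072 ± 0.059 sits near the generator's true diet-level effect of 0.10 per
composite unit. With `run_pipeline()` the same stages run end to end from
the five CSV inputs and emit `table1/2/3.csv` reports, `fits.json`, and a
deterministic manifest; `inst/scripts/pipeline.R` wraps it for the shell.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

runs the installed package's full pipeline on a simulated cohort
(simulate → intakes → energy filter → DASS scoring → DII → the three model
fits and comparison reports) and writes the acceptance report to `--out`.
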