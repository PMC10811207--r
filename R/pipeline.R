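## End-to-end pipeline: (simulate ->) intake -> exclusion -> DASS -> DII ->
## three model fits per outcome -> comparison reports + manifest. Every
## stage consumes the previous stage's files/tables unchanged, and a run is
## a pure function of (config, seed): manifests carry content hashes and
## counts, never timestamps.

#' Build a pipeline run configuration
#'
#' Exactly one of `input_dir` (a directory holding `ffq.csv`,
#' `composition.csv`, `reference.csv`, `covariates.csv`, `dass_items.csv`)
#' or `simulate` (a [simulation_config()]) must be supplied.
#'
#' @param out_dir Output directory for all stage outputs and the manifest.
#' @param input_dir Directory with the five input CSVs, or NULL.
#' @param simulate A [simulation_config()], or NULL.
#' @param dii_method Percentile method for the DII engine.
#' @param units_scale Units scaling passed to [compute_dii()].
#' @param tau2 `"estimate"` or a fixed value, applied to both levels.
#' @param shared_tau2 Estimate one common tau2 (default TRUE).
#' @param energy_filter Apply the +/-3 SD energy exclusion (default TRUE).
#' @param seed Integer seed for any simulation.
#' @return List of class `run_config`.
#' @export
pipeline_config <- function(out_dir, input_dir = NULL, simulate = NULL,
                            dii_method = c("normal_cdf", "empirical"),
                            units_scale = 1, tau2 = "estimate",
                            shared_tau2 = TRUE, energy_filter = TRUE,
                            seed = 1L) {
  dii_method <- match.arg(dii_method)
  assert_that(xor(is.null(input_dir), is.null(simulate)),
              paste("exactly one of input_dir or simulate must be given",
                    "(input tables or a simulation config, never neither)"))
  if (!is.null(simulate))
    assert_that(inherits(simulate, "simulation_config"),
                "simulate must come from simulation_config()")
  structure(list(out_dir = out_dir, input_dir = input_dir,
                 simulate = simulate, dii_method = dii_method,
                 units_scale = units_scale, tau2 = tau2,
                 shared_tau2 = isTRUE(shared_tau2),
                 energy_filter = isTRUE(energy_filter),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys mirror [pipeline_config()] arguments; a `simulate:` block
#' is passed to [simulation_config()].
#'
#' @param path YAML file.
#' @param out_dir Optional override of the configured output directory.
#' @param seed Optional override of the configured seed.
#' @return A `run_config`.
#' @export
read_run_config <- function(path, out_dir = NULL, seed = NULL) {
  raw <- yaml::read_yaml(path)
  sim <- NULL
  if (!is.null(raw$simulate)) {
    if (!is.null(seed)) raw$simulate$seed <- seed
    sim <- do.call(simulation_config, raw$simulate)
  }
  pipeline_config(
    out_dir = if (!is.null(out_dir)) out_dir else raw$out_dir,
    input_dir = raw$input_dir, simulate = sim,
    dii_method = raw$dii_method %||% "normal_cdf",
    units_scale = raw$units_scale %||% 1,
    tau2 = raw$tau2 %||% "estimate",
    shared_tau2 = raw$shared_tau2 %||% TRUE,
    energy_filter = raw$energy_filter %||% TRUE,
    seed = if (!is.null(seed)) seed else raw$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stopf("[stage:%s] %s", name, conditionMessage(e))
  })
}

#' Run the full pipeline
#'
#' @param config A [pipeline_config()] or path to a YAML file for
#'   [read_run_config()].
#' @return Invisibly, the run manifest (also written to
#'   `out_dir/manifest.json`): input hashes, participant counts at every
#'   stage (examined -> excluded -> analyzed), seed and settings. Stage
#'   outputs written under `out_dir`: `intakes.csv`, `excluded.txt`,
#'   `outcomes.csv`, `dii.csv`, `fits.json`, `table1.csv`, `table2.csv`,
#'   `table3.csv`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  assert_that(inherits(config, "run_config"),
              "config must come from pipeline_config()")
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  ## stage: inputs ----------------------------------------------------------
  input_dir <- config$input_dir
  if (!is.null(config$simulate)) {
    input_dir <- file.path(out, "input")
    run_stage("simulate", {
      cohort <- generate_cohort(config$simulate,
                                generate_reference_table(
                                  config$simulate$n_nutrients,
                                  seed = config$simulate$seed))
      write_cohort(cohort, input_dir)
    })
  }
  paths <- file.path(input_dir, c("ffq.csv", "composition.csv",
                                  "reference.csv", "covariates.csv",
                                  "dass_items.csv"))
  names(paths) <- c("ffq", "composition", "reference", "covariates",
                    "dass_items")
  missing <- paths[!file.exists(paths)]
  assert_that(length(missing) == 0, "[stage:inputs] missing input file(s): %s",
              paste(missing, collapse = ", "))
  tabs <- run_stage("inputs", lapply(paths, utils::read.csv,
                                     check.names = FALSE,
                                     stringsAsFactors = FALSE))

  ## stage: intake ----------------------------------------------------------
  intakes <- run_stage("intake", {
    grams <- ffq_daily_grams(tabs$ffq)
    nutrient_intakes(grams, tabs$composition)
  })
  utils::write.csv(intakes, file.path(out, "intakes.csv"), row.names = FALSE)

  ## stage: energy exclusion ------------------------------------------------
  examined <- nrow(intakes)
  if (config$energy_filter) {
    excl <- run_stage("energy_filter", energy_exclusion(intakes))
    intakes <- excl$retained
    excluded_ids <- excl$excluded_ids
  } else {
    excluded_ids <- character(0)
  }
  writeLines(as.character(excluded_ids), file.path(out, "excluded.txt"))
  analyzed <- nrow(intakes)

  ## stage: DASS scoring ----------------------------------------------------
  outcomes <- run_stage("dass", score_dass(tabs$dass_items))
  outcomes <- outcomes[outcomes$participant_id %in% intakes$participant_id, ]
  utils::write.csv(outcomes, file.path(out, "outcomes.csv"),
                   row.names = FALSE)

  ## stage: DII -------------------------------------------------------------
  dii_res <- run_stage("dii", compute_dii(intakes, tabs$reference,
                                          method = config$dii_method,
                                          units_scale = config$units_scale))
  dii_tab <- cbind(dii_res$dii,
                   as.data.frame(dii_res$scores, check.names = FALSE))
  utils::write.csv(dii_tab, file.path(out, "dii.csv"), row.names = FALSE)

  ## stage: model fits ------------------------------------------------------
  fits <- run_stage("fit", {
    ids <- intakes$participant_id
    m <- match(ids, outcomes$participant_id)
    assert_that(!anyNA(m), "outcomes missing for some analyzed participants")
    cov_tab <- tabs$covariates[match(ids, tabs$covariates$participant_id), ]
    cov_cols <- setdiff(names(cov_tab), "participant_id")
    C <- as.matrix(cov_tab[cov_cols])
    grams <- ffq_daily_grams(tabs$ffq)
    G <- as.matrix(grams[match(ids, grams$participant_id),
                         setdiff(names(grams), "participant_id")])
    comp <- tabs$composition
    comp_m <- as.matrix(comp[setdiff(names(comp), "food_id")])
    rownames(comp_m) <- comp$food_id
    comp_m <- comp_m[colnames(G), tabs$reference$parameter, drop = FALSE]
    nutr <- as.matrix(intakes[match(ids, intakes$participant_id),
                              tabs$reference$parameter])
    dii_v <- dii_res$dii$dii[match(ids, dii_res$dii$participant_id)]
    spec <- hier_spec(G, comp_m, tabs$reference$effect_score,
                      covariates = C, tau2_food = config$tau2,
                      tau2_nutrient = config$tau2,
                      shared_tau2 = config$shared_tau2)
    lapply(stats::setNames(nm = c("stress", "anxiety", "depression")),
           function(oc) {
             y <- outcomes[[oc]][m]
             list(simple = fit_simple(y, dii_v, oc),
                  multiple = fit_multiple(y, dii_v, covariates = C,
                                          nutrients = nutr, foods = G,
                                          outcome_name = oc),
                  hierarchical = fit_hierarchical(spec, y, oc))
           })
  })
  jsonlite::write_json(fits_to_list(fits), file.path(out, "fits.json"),
                       digits = NA, auto_unbox = TRUE)

  ## stage: reports ---------------------------------------------------------
  baseline <- run_stage("baseline", {
    cov_types <- intersect(names(cohort_covariate_types()),
                           names(tabs$covariates))
    baseline_associations(outcomes, tabs$covariates,
                          cohort_covariate_types()[cov_types])
  })
  run_stage("reports", render_reports(fits, baseline, out))

  manifest <- list(
    package_version = as.character(utils::packageVersion("diinest")),
    seed = config$seed,
    settings = list(dii_method = config$dii_method,
                    units_scale = config$units_scale,
                    tau2 = config$tau2, shared_tau2 = config$shared_tau2,
                    energy_filter = config$energy_filter),
    counts = list(examined = examined, excluded = length(excluded_ids),
                  analyzed = analyzed),
    input_hashes = as.list(stats::setNames(unname(tools::md5sum(paths)),
                                           basename(paths))),
    output_hashes = local({
      files <- file.path(out, c("intakes.csv", "excluded.txt",
                                "outcomes.csv", "dii.csv", "fits.json",
                                "table1.csv", "table2.csv", "table3.csv"))
      as.list(stats::setNames(unname(tools::md5sum(files)), basename(files)))
    }))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

# Serializable view of the nested fit list.
fits_to_list <- function(fits) {
  lapply(fits, function(per_outcome) {
    lapply(per_outcome, function(f) {
      keep <- list(model = f$model, outcome = f$outcome,
                   coefficients = f$coefficients, gamma = f$gamma,
                   se_gamma = f$se_gamma, n = f$n,
                   residual_variance = f$residual_variance,
                   converged = f$converged)
      if (!is.null(f$tau2)) keep$tau2 <- as.list(f$tau2)
      if (!is.null(f$dropped)) keep$dropped <- f$dropped
      keep
    })
  })
}

#' Render Table-1/2/3-shaped reports
#'
#' @param fits Nested list `fits[[outcome]][[model]]` of `dii_fit` objects
#'   (as produced inside [run_pipeline()]).
#' @param baseline Output of [baseline_associations()], or NULL to skip the
#'   Table-1 report.
#' @param out_dir Directory for `table1.csv`, `table2.csv`, `table3.csv`.
#' @return Invisibly, the list of report data.frames. `table2` has one row
#'   per outcome x model (DII coefficient, 95% CI, formatted p); `table3`
#'   has the hierarchical fit's covariate coefficients per outcome.
#' @export
render_reports <- function(fits, baseline, out_dir) {
  assert_that(length(fits) >= 1, "no fits to report")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  t2 <- do.call(rbind, lapply(names(fits), function(oc) {
    do.call(rbind, lapply(names(fits[[oc]]), function(mod) {
      f <- fits[[oc]][[mod]]
      data.frame(outcome = oc, model = mod, exposure = "DII",
                 coefficient = f$gamma, se = f$se_gamma,
                 lower = unname(f$ci_gamma["lower"]),
                 upper = unname(f$ci_gamma["upper"]),
                 p = fmt_p(f$p_gamma),
                 stringsAsFactors = FALSE)
    }))
  }))
  utils::write.csv(t2, file.path(out_dir, "table2.csv"), row.names = FALSE)

  t3 <- do.call(rbind, lapply(names(fits), function(oc) {
    f <- fits[[oc]]$hierarchical
    if (is.null(f)) return(NULL)
    co <- f$coefficients
    co <- co[!co$term %in% c("(Intercept)", "dii"), , drop = FALSE]
    if (!nrow(co)) return(NULL)
    cbind(outcome = oc, co, p_display = fmt_p(co$p))
  }))
  if (is.null(t3) || !nrow(t3)) {
    message("no covariates in the hierarchical fits; table3 report omitted")
    t3 <- NULL
  } else {
    utils::write.csv(t3, file.path(out_dir, "table3.csv"), row.names = FALSE)
  }

  t1 <- NULL
  if (!is.null(baseline)) {
    t1 <- baseline$tests
    t1$p_display <- fmt_p(t1$p)
    utils::write.csv(t1, file.path(out_dir, "table1.csv"), row.names = FALSE)
  } else {
    message("no baseline associations supplied; table1 report omitted")
  }
  # make sure all report files exist even when a section is omitted
  for (f in c("table1.csv", "table3.csv")) {
    p <- file.path(out_dir, f)
    if (!file.exists(p)) writeLines("omitted", p)
  }
  invisible(list(table1 = t1, table2 = t2, table3 = t3))
}
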