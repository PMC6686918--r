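#' Pipeline configuration
#'
#' Bundles every stage's settings for [run_pipeline()]: the simulation
#' config, marker-filter thresholds (mean depth 25, MAF 1%, missingness 5%),
#' the VCOV candidate lists for the stage-1 model search, the prediction
#' models to evaluate and the cross-validation plan. A single global seed
#' drives every stage deterministically.
#'
#' @param sim a [sim_config()].
#' @param min_mean_depth,min_maf,max_missing marker QC thresholds.
#' @param seq_error,min_posterior dosage-caller settings.
#' @param g_candidates,r_candidates VCOV structure names for [select_vcov()]
#'   (set to `NULL` to skip the search and fit `CS`/`ID` directly).
#' @param models character vector of prediction models for the TD/DD
#'   comparison.
#' @param cv a [cv_plan()].
#' @param mcmc list `list(niter =, burnin =)` applied to the Bayesian models
#'   (the reference protocol is 20000/2000; the default here is a fast
#'   profile).
#' @param seed global seed.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            min_mean_depth = 25, min_maf = 0.01,
                            max_missing = 0.05, seq_error = NULL,
                            min_posterior = 0.8,
                            g_candidates = NULL, r_candidates = NULL,
                            models = "GBLUP", cv = cv_plan(),
                            mcmc = list(niter = 4000L, burnin = 1000L),
                            seed = 20260101L) {
  sim$seed <- sim$seed %||% seed
  structure(list(sim = sim, min_mean_depth = min_mean_depth,
                 min_maf = min_maf, max_missing = max_missing,
                 seq_error = seq_error %||% sim$seq_error,
                 min_posterior = min_posterior,
                 g_candidates = g_candidates, r_candidates = r_candidates,
                 models = models, cv = cv, mcmc = mcmc, seed = seed),
            class = "pipeline_config")
}

#' Run the full two-stage genomic-selection analysis
#'
#' Executes, in order: population simulation, read-count simulation, dosage
#' calling, the marker QC cascade (mean depth, MAF, missingness, imputation),
#' population diagnostics (PCA, redundancy), the stage-1 longitudinal fit
#' (with optional hierarchical VCOV selection) and adjusted entry means,
#' relationship matrices (A, K, K*), GBLUP heritability, and the replicated
#' cross-validation comparison of tetraploid versus diploid dosage coding.
#' All randomness derives from the config seed, so a rerun reproduces the
#' report exactly.
#'
#' @param config a [pipeline_config()].
#' @param report_path optional path; when given the report is also written
#'   as JSON.
#' @return list of class `pipeline_report` with elements `marker_counts`
#'   (markers surviving each stage), `vcov_selection` (AIC/BIC trace, when a
#'   search was run), `heritability` (`H2`, `h2`), `prediction` (per-model
#'   TD/DD abilities and superiority), `diagnostics` (PCA explained
#'   fractions, redundancy percentages) and the underlying objects.
#' @export
run_pipeline <- function(config, report_path = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config$sim
  pop <- simulate_population(cfg)

  counts0 <- pop$reads
  counts <- filter_min_depth(counts0, config$min_mean_depth)
  called <- call_dosages(counts, ploidy = cfg$ploidy,
                         seq_error = config$seq_error,
                         min_posterior = config$min_posterior)
  dos <- called$dosages
  dos_maf <- filter_maf(dos, config$min_maf)
  dos_miss <- filter_missing(dos_maf, config$max_missing)
  dos_imp <- impute_dose_frequency(dos_miss, seed = config$seed + 4L)
  marker_counts <- c(simulated = ncol(counts0$ref),
                     depth = ncol(counts$ref),
                     called = ncol(dos),
                     maf = ncol(dos_maf),
                     missing = ncol(dos_miss),
                     imputed = ncol(dos_imp))

  red <- redundancy_groups(dos_imp)
  pca <- pca_dosage(dos_imp, n_components = min(3L, nrow(dos_imp) - 1L))

  # stage 1: longitudinal model and adjusted entry means
  if (!is.null(config$g_candidates)) {
    sel <- select_vcov(pop$phenotypes, config$g_candidates,
                       config$r_candidates %||% "ID")
    vcov_trace <- sel$trace
  } else {
    sel <- NULL
    vcov_trace <- NULL
  }
  fit_h <- fit_longitudinal(pop$phenotypes, "CS", "ID")
  H2 <- generalized_heritability(fit_h)
  y <- adjusted_entry_means(if (is.null(sel)) fit_h else sel$fit)

  # stage 2: relationship matrices, heritability, TD/DD comparison
  ids <- rownames(dos_imp)
  y <- y[ids]
  A_full <- build_a_tetraploid(pop$pedigree)
  A <- A_full[ids, ids]
  K <- build_k(dos_imp)
  Ks <- blend_kinship(K, A)
  gfit <- fit_gblup(y, Ks)
  h2 <- narrow_heritability(gfit)

  plan <- config$cv
  plan$seed <- plan$seed %||% (config$seed + 5L)
  models <- lapply(config$models, function(m) {
    s <- wgr_spec(m)
    if (s$model != "GBLUP") {
      s$niter <- as.integer(config$mcmc$niter)
      s$burnin <- as.integer(config$mcmc$burnin)
    }
    s
  })
  cmp <- compare_td_dd(dos_imp, y, models, plan, A = A,
                       families = pop$families)

  report <- list(
    marker_counts = as.list(marker_counts),
    vcov_selection = if (!is.null(vcov_trace)) vcov_trace else NULL,
    heritability = list(H2 = H2$H2, h2 = h2),
    prediction = list(table = cmp$table, mean_td = cmp$mean_td,
                      mean_dd = cmp$mean_dd,
                      superiority_pct = cmp$superiority_pct,
                      n_markers = cmp$n_markers),
    diagnostics = list(pca_explained = pca$explained,
                       pct_unique_markers = red$pct_unique),
    seed = config$seed)
  if (!is.null(report_path)) {
    jsonlite::write_json(
      report[c("marker_counts", "heritability", "prediction", "diagnostics",
               "seed")],
      report_path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  structure(list(report = report, population = pop, dosages = dos_imp,
                 entry_means = y, A = A, K = K, K_star = Ks,
                 longitudinal = if (is.null(sel)) fit_h else sel$fit,
                 selection = sel, gblup = gfit, comparison = cmp),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  r <- x$report
  cat("<pipeline_report>\n  markers: ",
      paste(sprintf("%s=%d", names(r$marker_counts),
                    unlist(r$marker_counts)), collapse = " -> "), "\n",
      sprintf("  H2 = %.3f, h2 = %.3f\n", r$heritability$H2,
              r$heritability$h2),
      sprintf("  TD %.4f vs DD %.4f (superiority %.2f%%)\n",
              r$prediction$mean_td, r$prediction$mean_dd,
              r$prediction$superiority_pct), sep = "")
  invisible(x)
}
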