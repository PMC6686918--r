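#' Cross-validation plan
#'
#' @param n_folds number of folds (default 5, i.e. 80/20 training/validation).
#' @param n_reps number of replications of the whole k-fold split (the
#'   reference protocol repeats fivefold CV 100 times for the Bayesian models
#'   and 1,000 times for GBLUP; scale down for interactive use).
#' @param sampling `"random"` or `"stratified"` (balance each half-sib family
#'   across folds).
#' @param seed optional seed for the fold draws.
#' @return list of class `cv_plan`.
#' @export
cv_plan <- function(n_folds = 5L, n_reps = 10L,
                    sampling = c("random", "stratified"), seed = NULL) {
  structure(list(n_folds = as.integer(n_folds), n_reps = as.integer(n_reps),
                 sampling = match.arg(sampling), seed = seed),
            class = "cv_plan")
}

#' Build fold assignments
#'
#' Per replication, partitions the genotypes into `n_folds` disjoint subsets
#' whose sizes differ by at most one. Stratified sampling partitions within
#' each family so every family is represented in (nearly) every fold.
#'
#' @param ids character vector of genotype ids.
#' @param plan a [cv_plan()].
#' @param families named vector id -> family (required for stratified
#'   sampling).
#' @return list of length `n_reps`; each element is an integer fold label
#'   (1..n_folds) named by genotype id.
#' @export
make_folds <- function(ids, plan, families = NULL) {
  n <- length(ids)
  if (n < plan$n_folds) stopf("need at least n_folds genotypes")
  if (plan$sampling == "stratified" && is.null(families))
    stopf("stratified sampling requires a family mapping")
  set_seed_if(plan$seed)
  lapply(seq_len(plan$n_reps), function(r) {
    if (plan$sampling == "random") {
      f <- rep_len(seq_len(plan$n_folds), n)
      assign <- sample(f)
    } else {
      fam <- families[ids]
      assign <- integer(n)
      offset <- 0L
      for (g in unique(fam)) {
        idx <- which(fam == g)
        # rotate the fold sequence so leftover sizes spread across folds
        f <- ((seq_along(idx) - 1L + offset) %% plan$n_folds) + 1L
        assign[idx] <- sample(f)
        offset <- offset + length(idx)
      }
    }
    setNames(assign, ids)
  })
}

#' Predicted residual error sum of squares
#'
#' `PRESS = sum((predicted - observed)^2)`; the standardized variant divides
#' by the total sum of squares of the observed values about their mean, so
#' the mean-only predictor scores 1.
#'
#' @param observed,predicted numeric vectors of equal length.
#' @param standardize divide by the observed total sum of squares.
#' @return a single number.
#' @export
press <- function(observed, predicted, standardize = FALSE) {
  if (length(observed) != length(predicted))
    stopf("observed and predicted must have equal length")
  out <- sum((predicted - observed)^2)
  if (standardize) out <- out / sum((observed - mean(observed))^2)
  out
}

# fit on the training subset and predict the validation subset; shared by
# run_cv for all six models. A is an optional pedigree matrix for the K* blend.
cv_predict_fold <- function(model_spec, X, y, train, test, A = NULL,
                            seed = NULL) {
  if (model_spec$model == "GBLUP") {
    Xtr <- X[train, , drop = FALSE]
    mu_tr <- colMeans(Xtr)
    Wtr <- sweep(Xtr, 2, mu_tr)
    Wte <- sweep(X[test, , drop = FALSE], 2, mu_tr)
    c_tr <- sum(Wtr * Wtr) / length(train)
    if (c_tr <= 0) stopf("training markers all monomorphic")
    Ktr <- tcrossprod(Wtr) / c_tr
    Kte <- tcrossprod(Wte, Wtr) / c_tr
    if (!is.null(A)) {
      Ktr <- 0.99 * Ktr + 0.01 * A[train, train]
      Kte <- 0.99 * Kte + 0.01 * A[test, train]
    } else {
      Ktr <- Ktr + diag(1e-8, nrow(Ktr))
    }
    fit <- fit_gblup(y[train], Ktr)
    fit$mu + predict_gebv(fit, K_cross = Kte)
  } else {
    fit <- fit_wgr_bayes(y[train], X[train, , drop = FALSE], model_spec,
                         seed = seed)
    fit$mu + predict_gebv(fit, X_new = X[test, , drop = FALSE])
  }
}

#' Replicated k-fold cross-validation of a prediction model
#'
#' For each replication and fold, trains on the remaining folds and predicts
#' the held-out genotypes; all out-of-fold predictions of a replication are
#' pooled and correlated with the observed values (one Pearson correlation
#' per replication). Predictive ability is the mean of these correlations.
#' Replications whose pooled predictions are constant (undefined correlation)
#' or whose fold fits fail are excluded with a message.
#'
#' @param y named numeric vector of adjusted entry means.
#' @param X complete dosage matrix aligned with `y` (rows named).
#' @param model a [wgr_spec()] (or model name).
#' @param plan a [cv_plan()].
#' @param A optional pedigree relationship matrix over the same ids (used in
#'   the GBLUP blend `K* = 0.99 K + 0.01 A`).
#' @param families family mapping for stratified plans.
#' @param folds optional precomputed [make_folds()] output (overrides the
#'   plan's own draw; used to share folds across model/coding arms).
#' @return object of class `cv_result`: per-replication correlations and
#'   PRESS, `predictive_ability` (their mean), `press_mean`,
#'   `press_std_mean`, the fold assignments and pooled predictions.
#' @export
run_cv <- function(y, X, model = wgr_spec("GBLUP"), plan = cv_plan(),
                   A = NULL, families = NULL, folds = NULL) {
  if (is.character(model)) model <- wgr_spec(model)
  X <- as.matrix(unclass(X))
  ids <- names(y) %||% rownames(X)
  if (is.null(ids)) stopf("y (or rownames of X) must carry genotype ids")
  names(y) <- ids
  if (nrow(X) != length(y)) stopf("X and y are not aligned")
  if (is.null(folds)) folds <- make_folds(ids, plan, families)
  cors <- rep(NA_real_, length(folds))
  pres <- rep(NA_real_, length(folds))
  pres_std <- rep(NA_real_, length(folds))
  preds <- matrix(NA_real_, length(y), length(folds),
                  dimnames = list(ids, NULL))
  excluded <- character(0)
  for (r in seq_along(folds)) {
    fr <- folds[[r]]
    yhat <- rep(NA_real_, length(y))
    ok <- TRUE
    for (k in sort(unique(fr))) {
      test <- which(fr == k); train <- which(fr != k)
      ph <- tryCatch(
        cv_predict_fold(model, X, y, train, test, A = A,
                        seed = if (!is.null(plan$seed))
                          plan$seed + 1000L * r + k else NULL),
        error = function(e) NULL)
      if (is.null(ph)) { ok <- FALSE; break }
      yhat[test] <- ph
    }
    if (!ok) {
      excluded <- c(excluded, sprintf("replication %d: fold fit failed", r))
      next
    }
    cr <- suppressWarnings(cor(y, yhat))
    if (sd(yhat) < 1e-12 || is.na(cr)) {
      excluded <- c(excluded,
                    sprintf("replication %d: constant predictions", r))
      next
    }
    preds[, r] <- yhat
    cors[r] <- cr
    pres[r] <- press(y, yhat)
    pres_std[r] <- press(y, yhat, standardize = TRUE)
  }
  if (length(excluded)) message(paste(excluded, collapse = "\n"))
  structure(list(model = model$model,
                 correlations = cors, press = pres, press_std = pres_std,
                 predictive_ability = mean(cors, na.rm = TRUE),
                 press_mean = mean(pres, na.rm = TRUE),
                 press_std_mean = mean(pres_std, na.rm = TRUE),
                 folds = folds, predictions = preds,
                 excluded = excluded),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s: predictive ability %.4f over %d replications (PRESS %.3f)\n",
              x$model, x$predictive_ability,
              sum(!is.na(x$correlations)), x$press_mean))
  invisible(x)
}

#' Percent superiority of tetraploid over diploid coding
#'
#' @param mean_td,mean_dd mean predictive abilities under tetraploid and
#'   diploid dosage coding.
#' @return `100 * (mean_td / mean_dd - 1)`.
#' @export
dosage_superiority <- function(mean_td, mean_dd) 100 * (mean_td / mean_dd - 1)

#' Average predictive ability across models
#'
#' @param per_model_abilities numeric vector (one value per model).
#' @return arithmetic mean.
#' @export
model_average <- function(per_model_abilities) {
  if (length(per_model_abilities) == 0) stopf("nonempty input required")
  mean(per_model_abilities)
}

#' Compare tetraploid and diploid dosage coding by cross-validation
#'
#' Restricts the tetraploid matrix to markers informative under diploidized
#' coding ([filter_dd_informative()]), then runs every requested model twice
#' on the same marker panel — tetraploid codes 0..4 and diploidized codes
#' 0..2 — with identical fold assignments in both arms. Reports per-model
#' predictive abilities for both codings, the per-coding averages and the
#' percent superiority of the tetraploid coding.
#'
#' @param dosages complete tetraploid [dosage_matrix()].
#' @param y named adjusted entry means aligned with the rows.
#' @param models list of [wgr_spec()]s (or model names).
#' @param plan a [cv_plan()].
#' @param A,families passed to [run_cv()].
#' @return list of class `td_dd_comparison`: `table` (`data.frame` model /
#'   ability_td / ability_dd), `mean_td`, `mean_dd`, `superiority_pct`,
#'   `n_markers`, and the per-model `cv_result`s.
#' @export
compare_td_dd <- function(dosages, y, models = list(wgr_spec("GBLUP")),
                          plan = cv_plan(), A = NULL, families = NULL) {
  if (ploidy_of(dosages) != 4L) stopf("tetraploid dosages required")
  panel <- filter_dd_informative(dosages)
  if (ncol(panel) == 0) stopf("no markers remain after the informativeness filter")
  td <- unclass(panel)
  dd <- unclass(diploidize(panel))
  ids <- rownames(td)
  folds <- make_folds(ids, plan, families)
  models <- lapply(models, function(m) if (is.character(m)) wgr_spec(m) else m)
  res <- lapply(models, function(m) {
    list(td = run_cv(y, td, m, plan, A = A, folds = folds),
         dd = run_cv(y, dd, m, plan, A = A, folds = folds))
  })
  names(res) <- vapply(models, `[[`, "", "model")
  tab <- data.frame(
    model = names(res),
    ability_td = vapply(res, function(r) r$td$predictive_ability, 0),
    ability_dd = vapply(res, function(r) r$dd$predictive_ability, 0),
    stringsAsFactors = FALSE, row.names = NULL)
  mean_td <- model_average(tab$ability_td)
  mean_dd <- model_average(tab$ability_dd)
  structure(list(table = tab, mean_td = mean_td, mean_dd = mean_dd,
                 superiority_pct = dosage_superiority(mean_td, mean_dd),
                 n_markers = ncol(panel), folds = folds, results = res),
            class = "td_dd_comparison")
}

#' @export
print.td_dd_comparison <- function(x, ...) {
  print(x$table, row.names = FALSE)
  cat(sprintf("Average TD %.4f, DD %.4f, superiority %.2f%% (%d markers)\n",
              x$mean_td, x$mean_dd, x$superiority_pct, x$n_markers))
  invisible(x)
}
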