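#' Specification of a whole-genome prediction model
#'
#' Names one of the six dosage-aware models and its hyperparameters. The
#' Bayesian models share the linear model `y = 1 mu + X beta + eps` and
#' differ in the prior on the marker effects: a common normal (BRR),
#' per-marker normal variances (BayesA), spike-and-slab mixtures with the
#' spike an exact point mass at zero (BayesB with per-marker slab variances,
#' BayesC with a common slab variance), or the Bayesian LASSO (per-marker
#' variances `sigma2_eps * tau2_j` with exponential prior). GBLUP is the
#' frequentist model `y = 1 mu + Z g + eps`, `g ~ MVN(0, K* sigma2_g)`.
#'
#' @param model one of `"BRR"`, `"BA"`, `"BB"`, `"BC"`, `"BL"`, `"GBLUP"`.
#' @param niter,burnin,thin Gibbs protocol (defaults 20000 / 2000 / 1).
#' @param df_beta,df_eps degrees of freedom of the scaled-inverse-chi-squared
#'   hyperpriors (default 5).
#' @param S_beta,S_eps scale parameters; `NULL` (default) sets them from the
#'   data so the prior modes split the phenotypic variance half genetic, half
#'   residual.
#' @param pi spike (zero-effect) mixture proportion for BB/BC (default 0.5).
#' @param lambda Bayesian-LASSO rate; `NULL` sets the default from the
#'   half-genetic variance split. `lambda_prior` `"gamma"` (default) places a
#'   Gamma hyperprior on `lambda^2` centred on that value; `"fixed"` keeps it
#'   fixed.
#' @return list of class `wgr_spec`.
#' @export
wgr_spec <- function(model = c("GBLUP", "BRR", "BA", "BB", "BC", "BL"),
                     niter = 20000L, burnin = 2000L, thin = 1L,
                     df_beta = 5, df_eps = 5, S_beta = NULL, S_eps = NULL,
                     pi = 0.5, lambda = NULL,
                     lambda_prior = c("gamma", "fixed")) {
  model <- match.arg(toupper(model[1]), c("GBLUP", "BRR", "BA", "BB", "BC", "BL"))
  if (niter <= burnin) stopf("niter must exceed burnin")
  if (pi < 0 || pi > 1) stopf("pi must lie in [0, 1]")
  structure(list(model = model, niter = as.integer(niter),
                 burnin = as.integer(burnin), thin = as.integer(thin),
                 df_beta = df_beta, df_eps = df_eps,
                 S_beta = S_beta, S_eps = S_eps, pi = pi, lambda = lambda,
                 lambda_prior = match.arg(lambda_prior)),
            class = "wgr_spec")
}

model_code <- function(model) {
  match(model, c("BRR", "BA", "BB", "BC", "BL"))
}

#' Fit a Bayesian whole-genome regression by Gibbs sampling
#'
#' Runs the Gibbs sampler for the marker-effect models (BRR, BayesA, BayesB,
#' BayesC, Bayesian LASSO) on dosage codes. Default hyperparameters follow
#' the usual convention: `df = 5` and scales chosen so the prior modes
#' partition the phenotypic variance equally between markers and residual.
#' Use `set.seed()` (or the `seed` argument) for reproducible chains.
#'
#' @param y numeric response (adjusted entry means), length `n`.
#' @param X complete dosage matrix (`n x p`), any numeric coding.
#' @param spec a [wgr_spec()] with `model != "GBLUP"`; or a model name.
#' @param fixed_var optional list `list(beta = , eps = )` fixing the marker
#'   and residual variances (degenerate hyperpriors); used for closed-form
#'   verification.
#' @param store_beta keep the thinned marker-effect samples.
#' @param seed optional integer seed.
#' @return object of class `wgr_posterior`: posterior means/SDs of `mu` and
#'   `beta`, variance summaries, posterior inclusion probabilities (BB/BC),
#'   GEBVs (`X %*% beta_mean`) and thinned variance samples.
#' @export
fit_wgr_bayes <- function(y, X, spec = wgr_spec("BRR"), fixed_var = NULL,
                          store_beta = FALSE, seed = NULL) {
  if (is.character(spec)) spec <- wgr_spec(spec)
  if (spec$model == "GBLUP") stopf("use fit_gblup() for the GBLUP model")
  X <- as.matrix(unclass(X)); storage.mode(X) <- "double"
  y <- as.numeric(y)
  if (length(y) != nrow(X)) stopf("length(y) must equal nrow(X)")
  if (length(y) < 2) stopf("need at least 2 observations")
  if (any(!is.finite(y))) stopf("y must be finite")
  if (anyNA(X)) stopf("X must be complete; impute first")
  set_seed_if(seed)

  vy <- var(y); R2 <- 0.5
  msx <- sum(apply(X, 2, var))
  if (msx <= 0) msx <- 1
  S_eps <- spec$S_eps %||% (vy * (1 - R2) * (spec$df_eps + 2) / spec$df_eps)
  vb_target <- R2 * vy / msx
  if (spec$model %in% c("BB", "BC") && spec$pi < 1)
    vb_target <- vb_target / (1 - spec$pi)
  S_beta <- spec$S_beta %||% (vb_target * (spec$df_beta + 2) / spec$df_beta)
  lambda2 <- if (!is.null(spec$lambda)) spec$lambda^2
  else 2 * msx * (1 - R2) / R2
  update_lambda <- spec$model == "BL" && spec$lambda_prior == "gamma"
  lambda_shape <- 1.1
  lambda_rate <- if (update_lambda) (lambda_shape - 1) / lambda2 else 0

  fb <- fixed_var$beta %||% -1
  fe <- fixed_var$eps %||% -1
  res <- .wgr_gibbs(y, X, model_code(spec$model),
                    spec$niter, spec$burnin, spec$thin,
                    spec$df_beta, S_beta, spec$df_eps, S_eps,
                    spec$pi, lambda2, lambda_shape, lambda_rate,
                    update_lambda, fb, fe, store_beta)
  gebv <- drop(X %*% res$beta_mean)
  names(gebv) <- rownames(X)
  out <- list(model = spec$model, spec = spec,
              mu = res$mu_mean, mu_sd = res$mu_sd,
              beta = setNames(drop(res$beta_mean), colnames(X)),
              beta_sd = drop(res$beta_sd),
              pip = if (spec$model %in% c("BB", "BC"))
                setNames(drop(res$pip), colnames(X)) else NULL,
              sigma2_eps = res$sigma2_eps_mean,
              sigma2_beta = res$sigma2_beta_mean,
              lambda2 = if (spec$model == "BL") res$lambda2_mean else NULL,
              gebv = gebv,
              n_saved = res$n_saved,
              samples = list(mu = res$mu_samples,
                             sigma2_eps = res$sigma2_eps_samples,
                             sigma2_beta = res$sigma2_beta_samples,
                             beta = if (store_beta) res$beta_samples else NULL),
              markers = colnames(X))
  class(out) <- "wgr_posterior"
  out
}

#' @export
print.wgr_posterior <- function(x, ...) {
  cat(sprintf("<wgr_posterior> %s: %d markers, mu = %.4f, sigma2_eps = %.4f, sigma2_beta = %.3g\n",
              x$model, length(x$beta), x$mu, x$sigma2_eps, x$sigma2_beta))
  invisible(x)
}

#' Fit GBLUP by REML
#'
#' `y = 1 mu + g + eps`, `g ~ MVN(0, K sigma2_g)`, `eps ~ MVN(0, I
#' sigma2_eps)`. Variance components are estimated by restricted maximum
#' likelihood via the eigendecomposition of `K`: after rotating by the
#' eigenvectors the covariance is diagonal, so the restricted likelihood is
#' profiled over a single variance ratio and maximized by one-dimensional
#' search.
#'
#' @param y numeric response.
#' @param K positive-definite relationship matrix aligned with `y` (blend
#'   with the pedigree matrix first when the genomic matrix is singular).
#' @param fixed_var optional `c(g = , e = )` to skip REML and compute BLUPs
#'   at known variances.
#' @return object of class `gblup_fit`: `sigma2_g`, `sigma2_eps`, `mu`,
#'   BLUPs `g`, fitted GEBVs, restricted log-likelihood and the eigen pieces
#'   needed for prediction.
#' @export
fit_gblup <- function(y, K, fixed_var = NULL) {
  y <- as.numeric(y)
  K <- as.matrix(unclass(K))
  n <- length(y)
  if (!identical(dim(K), c(n, n))) stopf("K must be n x n aligned with y")
  eg <- eigen(K, symmetric = TRUE)
  if (min(eg$values) < -1e-8 * max(eg$values))
    stopf("K is not positive semi-definite")
  if (min(eg$values) < 1e-12 * max(eg$values))
    stopf("K is numerically singular; blend with the pedigree matrix (blend_kinship)")
  U <- eg$vectors; d <- eg$values
  yt <- drop(crossprod(U, y))
  xt <- drop(crossprod(U, rep(1, n)))

  # restricted likelihood profiled over sigma2_g at ratio delta = s2e/s2g
  reml_delta <- function(log_delta) {
    delta <- exp(log_delta)
    w <- d + delta                       # V = s2g * diag(w) after rotation
    xwx <- sum(xt^2 / w)
    bhat <- sum(xt * yt / w) / xwx
    r <- yt - xt * bhat
    quad <- sum(r^2 / w)
    s2g <- max(quad / (n - 1), 1e-300)
    ll <- -0.5 * ((n - 1) * log(s2g) + sum(log(w)) + log(xwx) +
                    (n - 1) + (n - 1) * log(2 * pi))
    if (!is.finite(ll)) ll <- -1e300
    list(ll = ll, s2g = s2g, bhat = bhat, delta = delta)
  }
  if (is.null(fixed_var)) {
    opt <- optimize(function(ld) -reml_delta(ld)$ll, c(-12, 12))
    sol <- reml_delta(opt$minimum)
    s2g <- sol$s2g; s2e <- sol$delta * s2g
    mu <- sol$bhat; ll <- sol$ll
  } else {
    s2g <- fixed_var[["g"]]; s2e <- fixed_var[["e"]]
    delta <- s2e / s2g
    w <- d + delta
    xwx <- sum(xt^2 / w)
    mu <- sum(xt * yt / w) / xwx
    r <- yt - xt * mu
    ll <- -0.5 * (n * log(s2g) + sum(log(w)) + log(xwx) - log(s2g) +
                    sum(r^2 / w) / s2g + (n - 1) * log(2 * pi))
  }
  # BLUP: g = K (K + delta I)^-1 (y - mu) in rotated coordinates
  delta <- s2e / s2g
  rt <- yt - xt * mu
  g <- drop(U %*% (d * rt / (d + delta)))
  names(g) <- rownames(K) %||% names(y)
  out <- list(sigma2_g = s2g, sigma2_eps = s2e, mu = mu, g = g,
              gebv = g, loglik = ll, eigen = list(U = U, d = d),
              y = y, ids = rownames(K))
  class(out) <- "gblup_fit"
  out
}

#' @export
print.gblup_fit <- function(x, ...) {
  cat(sprintf("<gblup_fit> n = %d, sigma2_g = %.4f, sigma2_eps = %.4f, h2 = %.3f\n",
              length(x$y), x$sigma2_g, x$sigma2_eps, narrow_heritability(x)))
  invisible(x)
}

#' Predict genomic estimated breeding values
#'
#' Marker models predict `X_new %*% beta_mean`; GBLUP predicts
#' `K_cross %*% K_train^-1 %*% g_train` where `K_cross` holds the
#' relationships between new and training individuals.
#'
#' @param fit a [fit_wgr_bayes()] or [fit_gblup()] object.
#' @param X_new marker matrix with the training panel's columns
#'   (marker models).
#' @param K_cross cross-relationship matrix, columns = training individuals
#'   (GBLUP).
#' @return numeric GEBV vector (deviations from the population mean).
#' @export
predict_gebv <- function(fit, X_new = NULL, K_cross = NULL) {
  if (inherits(fit, "wgr_posterior")) {
    if (is.null(X_new)) stopf("marker models need X_new")
    X_new <- as.matrix(unclass(X_new))
    if (ncol(X_new) != length(fit$beta))
      stopf("marker panel mismatch: training had %d markers, X_new has %d",
            length(fit$beta), ncol(X_new))
    if (!is.null(colnames(X_new)) && !is.null(fit$markers) &&
        !identical(colnames(X_new), fit$markers))
      stopf("marker panel mismatch: column names differ from training panel")
    return(drop(X_new %*% fit$beta))
  }
  if (inherits(fit, "gblup_fit")) {
    if (is.null(K_cross)) stopf("GBLUP prediction needs K_cross")
    K_cross <- as.matrix(unclass(K_cross))
    if (ncol(K_cross) != length(fit$g))
      stopf("K_cross columns must match training individuals")
    U <- fit$eigen$U; d <- fit$eigen$d
    gt <- drop(crossprod(U, fit$g))
    # pseudo-inverse on the eigenbasis: null directions carry no BLUP signal
    inv <- ifelse(d > max(d) * 1e-12, gt / d, 0)
    return(drop(K_cross %*% (U %*% inv)))
  }
  stopf("unsupported fit object")
}

#' Narrow-sense (genomic) heritability from a GBLUP fit
#'
#' `h2 = sigma2_A / sigma2_P` with `sigma2_A` the additive (genomic) variance
#' and `sigma2_P = sigma2_A + sigma2_eps` the phenotypic variance of the
#' GBLUP analysis.
#'
#' @param fit a [fit_gblup()] object.
#' @return heritability in `[0, 1]`.
#' @export
narrow_heritability <- function(fit) {
  s2p <- fit$sigma2_g + fit$sigma2_eps
  if (s2p <= 0) stopf("phenotypic variance is zero; heritability undefined")
  fit$sigma2_g / s2p
}
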