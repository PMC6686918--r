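#' Fit the longitudinal mixed model for a repeated-harvest trial
#'
#' Fits, by restricted maximum likelihood, the stage-1 model
#' `y_ijkl = mu + h_l + b_k(l) + p_j(l) + bp_kj(l) + t_il + e_ijkl`
#' where `h_l` are fixed harvest effects, `b_k(l)`, `p_j(l)` and `bp_kj(l)`
#' are independent random effects with variances `sigma2_b`, `sigma2_p`,
#' `sigma2_bp` (independent levels per harvest, common variance), and the
#' plant term `t_il` splits into random genotype effects `g_il` for offspring
#' (covariance `G_L` across harvests, independent across genotypes) and fixed
#' cultivar-by-harvest effects `c_il` for clonal checks. Residuals have
#' covariance `R_L` across harvests within a plant and are independent across
#' plants. The `G_L`/`R_L` structure parameters and the three scalar
#' variances are estimated jointly by direct maximization of the restricted
#' likelihood (quasi-Newton on log-variance / transformed-correlation scale);
#' the solver exploits the per-plant block-diagonal form of
#' `G_L (x) I + R_L (x) I` through the Woodbury identity, so each likelihood
#' evaluation costs `O(n L^2 + q^3)` with `q` the number of block/parent
#' levels rather than a dense `O(n^3)` factorization.
#'
#' Records must be complete: every plant observed at every harvest. With a
#' single harvest all structures collapse to `ID`.
#'
#' @param table phenotype `data.frame` with columns `plant`, `parent`,
#'   `block`, `harvest`, `is_check`, `value`.
#' @param g_structure,r_structure structure names (see [vcov_structure()]) or
#'   `vcov_structure` objects (their `times` are honoured; parameters are
#'   estimated).
#' @param n_starts number of optimizer starts (first from a variance-split
#'   heuristic, the rest perturbed).
#' @param max_iter,reltol optimizer iteration cap and relative convergence
#'   tolerance.
#' @param keep_design keep the design matrices in the returned object (used
#'   for dense-likelihood verification).
#' @return object of class `longitudinal_fit`: fixed-effect estimates (`mu`,
#'   `harvest`, `check`), variance components, `G_L`, `R_L` and their
#'   parameters, REML log-likelihood, `AIC`, `BIC`, `npar`, genotype BLUPs
#'   (`blups`, genotypes x harvests), the entry-mean prediction-error
#'   variance matrix summary, convergence and boundary flags.
#' @export
fit_longitudinal <- function(table, g_structure = "CS", r_structure = "ID",
                             n_starts = 2L, max_iter = 500L, reltol = 1e-10,
                             keep_design = FALSE) {
  d <- prepare_longitudinal(table)
  gs <- as_structure(g_structure, d$L)
  rs <- as_structure(r_structure, d$L)
  if (d$L == 1L) {
    gs <- as_structure("ID", 1L)
    rs <- as_structure("ID", 1L)
  }

  vy <- var(d$y)
  negll <- function(theta) {
    val <- reml_core(theta, d, gs, rs, what = "loglik")
    if (!is.finite(val)) 1e10 else -val
  }
  n_vc <- 3L
  best <- NULL
  for (s in seq_len(n_starts)) {
    init <- c(rep(log(vy / 10), n_vc),
              vcov_init(gs$name, d$L, vy / 3),
              vcov_init(rs$name, d$L, vy / 3))
    if (s > 1L) init <- init + rnorm(length(init), 0, 0.3)
    opt <- tryCatch(
      optim(init, negll, method = "BFGS",
            control = list(maxit = max_iter, reltol = reltol)),
      error = function(e) NULL)
    if (!is.null(opt) && (is.null(best) || opt$value < best$value)) best <- opt
  }
  if (is.null(best)) stopf("all optimizer starts failed")
  fit <- reml_core(best$par, d, gs, rs, what = "full")
  npar <- n_vc + n_vcov_par(gs$name, d$L) + n_vcov_par(rs$name, d$L)
  n_eff <- d$n - ncol(d$X)
  ll <- fit$loglik
  vc <- exp(best$par[seq_len(n_vc)])
  g_par <- vcov_report_params(gs$name, d$L,
                              best$par[n_vc + seq_len(length(vcov_init(gs$name, d$L, 1)))])
  r_par <- vcov_report_params(rs$name, d$L,
                              best$par[-seq_len(n_vc + length(vcov_init(gs$name, d$L, 1)))])
  boundary <- any(vc < 1e-6 * vy) ||
    has_boundary_cor(gs$name, g_par, d$L) || has_boundary_cor(rs$name, r_par, d$L)
  m <- rep(1 / d$L, d$L)
  out <- list(
    mu = fit$beta[1],
    harvest = setNames(c(0, fit$beta[1 + seq_len(d$L - 1)]),
                       paste0("h", seq_len(d$L))),
    check = fit$check_effects,
    varcomp = setNames(vc, c("sigma2_b", "sigma2_p", "sigma2_bp")),
    G_L = fit$G_L, R_L = fit$R_L,
    g_structure = gs$name, r_structure = rs$name,
    g_params = g_par, r_params = r_par,
    loglik = ll, npar = npar,
    AIC = -2 * ll + 2 * npar,
    BIC = -2 * ll + npar * log(n_eff),
    n_obs = d$n, n_eff = n_eff,
    blups = fit$blups,
    entry_pev = fit$entry_pev,
    pev_mean_contrast = fit$pev_mean_contrast,
    sigma2_entry = drop(crossprod(m, fit$G_L %*% m)),
    genotypes = d$off_ids,
    converged = best$convergence == 0,
    boundary = boundary,
    theta = best$par)
  if (keep_design) out$design <- c(d[c("X", "y", "n")],
                                   list(Z = d$Z, dsizes = d$dsizes,
                                        off = d$n_off, chk = d$n_chk,
                                        G_L = fit$G_L, R_L = fit$R_L,
                                        varcomp = vc))
  class(out) <- "longitudinal_fit"
  out
}

#' @export
print.longitudinal_fit <- function(x, ...) {
  cat(sprintf("<longitudinal_fit> G_L = %s, R_L = %s, logLik = %.3f, AIC = %.3f, BIC = %.3f\n",
              x$g_structure, x$r_structure, x$loglik, x$AIC, x$BIC))
  cat(sprintf("  %d genotypes, %d observations%s%s\n", length(x$genotypes),
              x$n_obs, if (!x$converged) ", NOT CONVERGED" else "",
              if (x$boundary) ", boundary estimate" else ""))
  invisible(x)
}

#' Restricted log-likelihood at fixed parameter values
#'
#' Evaluates the REML log-likelihood of the longitudinal model at given
#' variance components and structure parameters, without optimizing. Used to
#' verify the structured solver against a dense multivariate-normal restricted
#' likelihood.
#'
#' @inheritParams fit_longitudinal
#' @param varcomp numeric length-3 vector `(sigma2_b, sigma2_p, sigma2_bp)`.
#' @param g_params,r_params structure parameter vectors on the reporting
#'   scale of [build_vcov()].
#' @return the restricted log-likelihood (including its constant).
#' @export
longitudinal_loglik <- function(table, g_structure, r_structure, varcomp,
                                g_params, r_params) {
  d <- prepare_longitudinal(table)
  gs <- as_structure(g_structure, d$L)
  rs <- as_structure(r_structure, d$L)
  G_L <- build_vcov(vcov_structure(gs$name, d$L, params = g_params,
                                   times = gs$times))
  R_L <- build_vcov(vcov_structure(rs$name, d$L, params = r_params,
                                   times = rs$times))
  reml_fixed(d, G_L, R_L, varcomp)$loglik
}

# ---- internals -------------------------------------------------------------

as_structure <- function(x, L) {
  if (inherits(x, "vcov_structure")) {
    if (x$L != L) stopf("structure has L = %d but data have %d harvests", x$L, L)
    return(x)
  }
  vcov_structure(x, L = L)
}

has_boundary_cor <- function(name, params, L) {
  rho <- switch(name,
                CS = , AR1 = , Po = params[2],
                CSHet = , AR1Het = , PoHet = params[L + 1],
                return(FALSE))
  abs(rho) > 0.995
}

prepare_longitudinal <- function(table) {
  req <- c("plant", "parent", "block", "harvest", "is_check", "value")
  if (!all(req %in% names(table)))
    stopf("phenotype table needs columns: %s", paste(req, collapse = ", "))
  tb <- table
  tb$plant <- as.character(tb$plant)
  tb$parent <- as.character(tb$parent)
  L <- max(tb$harvest)
  if (any(sort(unique(tb$harvest)) != seq_len(L)))
    stopf("harvests must be indexed 1..L")
  cnt <- table(tb$plant)
  if (any(cnt != L))
    stopf("every plant must be observed at every harvest (complete records)")
  is_chk <- tapply(tb$is_check, tb$plant, `[`, 1L)
  off_ids <- sort(names(is_chk)[!is_chk])
  chk_ids <- sort(names(is_chk)[is_chk])
  ord <- order(match(tb$plant, c(off_ids, chk_ids)), tb$harvest)
  tb <- tb[ord, ]
  n <- nrow(tb)
  n_off <- length(off_ids); n_chk <- length(chk_ids)

  # fixed effects: intercept, harvest, check-cultivar x harvest
  H <- outer(tb$harvest, seq_len(L), `==`) * 1
  X <- cbind(`(Intercept)` = 1, H[, -1, drop = FALSE])
  if (L > 1) colnames(X)[-1] <- paste0("h", 2:L)
  if (n_chk > 0) {
    cu <- sort(unique(tb$parent[tb$is_check]))
    C <- NULL
    for (cc in cu) for (l in seq_len(L)) {
      col <- as.numeric(tb$parent == cc & tb$harvest == l)
      C <- cbind(C, col)
      colnames(C)[ncol(C)] <- paste0(cc, ".h", l)
    }
    X <- cbind(X, C)
  }

  fb <- factor(paste(tb$block, tb$harvest, sep = "."))
  fp <- factor(paste(tb$parent, tb$harvest, sep = "."))
  fbp <- factor(paste(tb$block, tb$parent, tb$harvest, sep = "."))
  Zb <- Matrix::t(Matrix::fac2sparse(fb))
  Zp <- Matrix::t(Matrix::fac2sparse(fp))
  Zbp <- Matrix::t(Matrix::fac2sparse(fbp))
  Z <- cbind(Zb, Zp, Zbp)
  list(y = tb$value, X = X, Z = Z,
       dsizes = c(ncol(Zb), ncol(Zp), ncol(Zbp)),
       n = n, L = L, n_off = n_off, n_chk = n_chk,
       off_ids = off_ids, chk_ids = chk_ids, table = tb)
}

# evaluate REML pieces from unconstrained theta
reml_core <- function(theta, d, gs, rs, what = "loglik") {
  n_vc <- 3L
  vc <- exp(theta[seq_len(n_vc)])
  nG <- length(vcov_init(gs$name, d$L, 1))
  uG <- theta[n_vc + seq_len(nG)]
  uR <- theta[-seq_len(n_vc + nG)]
  G_L <- tryCatch(vcov_materialize(gs$name, d$L, uG, gs$times),
                  error = function(e) NULL)
  R_L <- tryCatch(vcov_materialize(rs$name, d$L, uR, rs$times),
                  error = function(e) NULL)
  if (is.null(G_L) || is.null(R_L)) return(NA_real_)
  res <- tryCatch(reml_fixed(d, G_L, R_L, vc, what = what),
                  error = function(e) NULL)
  if (is.null(res)) return(if (what == "loglik") NA_real_ else NULL)
  if (what == "loglik") res$loglik else res
}

# REML machinery at fixed G_L, R_L, variance components.
# V = Z D Z' + B with B block-diagonal per plant: R_L + G_L for offspring
# plants, R_L for checks. Woodbury:
#   V^-1 = B^-1 - B^-1 Z (D^-1 + Z'B^-1 Z)^-1 Z' B^-1
#   log|V| = log|B| + log|D| + log|D^-1 + Z'B^-1 Z|
reml_fixed <- function(d, G_L, R_L, vc, what = "full") {
  L <- d$L
  S1 <- R_L + G_L
  S0 <- R_L
  ch1 <- chol(S1)
  S1inv <- chol2inv(ch1)
  ld1 <- 2 * sum(log(diag(ch1)))
  if (d$n_chk > 0) {
    ch0 <- chol(S0); S0inv <- chol2inv(ch0); ld0 <- 2 * sum(log(diag(ch0)))
  } else { S0inv <- NULL; ld0 <- 0 }
  Binv <- if (d$n_chk > 0)
    Matrix::bdiag(Matrix::kronecker(Matrix::Diagonal(d$n_off), S1inv),
                  Matrix::kronecker(Matrix::Diagonal(d$n_chk), S0inv))
  else Matrix::kronecker(Matrix::Diagonal(d$n_off), S1inv)
  logdetB <- d$n_off * ld1 + d$n_chk * ld0

  dvar <- rep(pmax(vc, 1e-12), d$dsizes)
  ZtBinv <- Matrix::crossprod(d$Z, Binv)
  Cmat <- as.matrix(ZtBinv %*% d$Z) + diag(1 / dvar)
  chC <- chol(Cmat)
  logdetC <- 2 * sum(log(diag(chC)))
  logdetD <- sum(log(dvar))
  logdetV <- logdetB + logdetD + logdetC

  vinv_mult <- function(M) {
    M <- as.matrix(M)
    BM <- as.matrix(Binv %*% M)
    ZtBM <- as.matrix(ZtBinv %*% M)
    sol <- backsolve(chC, forwardsolve(t(chC), ZtBM))
    BM - as.matrix(Binv %*% as.matrix(d$Z %*% sol))
  }

  y <- d$y; X <- d$X
  Vy <- vinv_mult(y)
  VX <- vinv_mult(X)
  XtVX <- crossprod(X, VX)
  chXtVX <- chol(XtVX)
  logdetXtVX <- 2 * sum(log(diag(chXtVX)))
  XtVy <- crossprod(X, Vy)
  beta <- backsolve(chXtVX, forwardsolve(t(chXtVX), XtVy))
  Py <- Vy - VX %*% beta
  quad <- sum(y * Py)
  pX <- ncol(X)
  loglik <- -0.5 * (logdetV + logdetXtVX + quad + (d$n - pX) * log(2 * pi))
  if (what == "loglik") return(list(loglik = loglik))

  # genotype BLUPs: u_i = G_L %*% Py[rows of plant i] for offspring plants
  W <- matrix(Py[seq_len(d$n_off * L)], nrow = L)
  blups <- t(G_L %*% W)
  dimnames(blups) <- list(d$off_ids, paste0("h", seq_len(L)))

  # entry-mean PEV matrix: a_i = mean_l g_il; Pi = v_a I - T' P T with
  # T = Z_g (G_L m) per plant
  m <- rep(1 / L, L)
  gm <- drop(G_L %*% m)
  Tmat <- matrix(0, d$n, d$n_off)
  for (i in seq_len(d$n_off)) Tmat[(i - 1) * L + seq_len(L), i] <- gm
  VT <- vinv_mult(Tmat)
  TVT <- crossprod(Tmat, VT)
  XtVT <- crossprod(X, VT)
  sol <- solve(XtVX, XtVT)
  TPT <- TVT - crossprod(XtVT, sol)
  v_a <- drop(crossprod(m, G_L %*% m))
  Pi <- v_a * diag(d$n_off) - TPT
  pev_diag <- diag(Pi)
  off_mean <- if (d$n_off > 1)
    (sum(Pi) - sum(pev_diag)) / (d$n_off * (d$n_off - 1)) else 0
  pev_mean_contrast <- 2 * (mean(pev_diag) - off_mean)

  check_effects <- if (d$n_chk > 0) {
    ce <- beta[-(seq_len(L))]
    names(ce) <- colnames(X)[-(seq_len(L))]
    ce
  } else NULL

  list(loglik = loglik, beta = drop(beta), G_L = G_L, R_L = R_L,
       blups = blups, entry_pev = pev_diag,
       pev_mean_contrast = pev_mean_contrast, check_effects = check_effects)
}

#' Hierarchical selection of VCOV structures
#'
#' Step 1 fits every candidate genetic structure with `R_L = ID` and picks the
#' best; step 2 keeps the chosen `G_L` and fits every candidate residual
#' structure. Within each step the best model is picked by AIC and by BIC;
#' when the two criteria disagree, the criterion whose difference between the
#' two candidate models is larger governs (see [criterion_tiebreak()]).
#'
#' @param table phenotype table (see [fit_longitudinal()]).
#' @param g_candidates,r_candidates character vectors of structure names.
#' @param ... passed to [fit_longitudinal()].
#' @return list with `fit` (the final [fit_longitudinal()] object),
#'   `g_structure`, `r_structure`, and `trace` (`data.frame` of step,
#'   structure, logLik, npar, AIC, BIC, chosen flag, plus the tie-break
#'   record per step).
#' @export
select_vcov <- function(table, g_candidates = c("ID", "CS", "AR1"),
                        r_candidates = c("ID", "DIAG", "AR1"), ...) {
  if (length(g_candidates) == 0 || length(r_candidates) == 0)
    stopf("candidate lists must be nonempty")
  run_step <- function(cands, fixed_g) {
    fits <- lapply(cands, function(s) {
      tryCatch(
        if (is.null(fixed_g)) fit_longitudinal(table, s, "ID", ...)
        else fit_longitudinal(table, fixed_g, s, ...),
        error = function(e) NULL)
    })
    ok <- !vapply(fits, is.null, TRUE)
    if (!any(ok)) stopf("all candidate fits failed")
    fits <- fits[ok]; cands <- cands[ok]
    aic <- vapply(fits, `[[`, 0, "AIC")
    bic <- vapply(fits, `[[`, 0, "BIC")
    tb <- criterion_tiebreak(aic, bic)
    list(fits = fits, cands = cands, aic = aic, bic = bic, tb = tb)
  }
  s1 <- run_step(g_candidates, NULL)
  g_chosen <- s1$cands[s1$tb$index]
  s2 <- run_step(r_candidates, g_chosen)
  r_chosen <- s2$cands[s2$tb$index]
  mk_trace <- function(step, s) data.frame(
    step = step, structure = s$cands,
    logLik = vapply(s$fits, `[[`, 0, "loglik"),
    npar = vapply(s$fits, `[[`, 0, "npar"),
    AIC = s$aic, BIC = s$bic,
    chosen = seq_along(s$cands) == s$tb$index,
    criterion = s$tb$criterion, stringsAsFactors = FALSE)
  trace <- rbind(mk_trace("G_L", s1), mk_trace("R_L", s2))
  list(fit = s2$fits[[s2$tb$index]], g_structure = g_chosen,
       r_structure = r_chosen, trace = trace,
       tiebreak = list(G_L = s1$tb, R_L = s2$tb))
}

#' AIC/BIC selection with larger-difference tie-break
#'
#' Selects among candidate models given their AIC and BIC values. If both
#' criteria prefer the same model it is selected ("agreement"). Otherwise the
#' AIC difference between the two disagreeing candidates (`AIC` of the BIC
#' winner minus `AIC` of the AIC winner) and the corresponding BIC difference
#' are compared: the criterion with the larger difference governs; an exact
#' tie defers to BIC (the more parsimonious criterion).
#'
#' @param aic,bic numeric vectors of criterion values, one per candidate.
#' @return list with `index` (selected candidate), `criterion` ("AIC", "BIC"
#'   or "agreement"), `aic_diff`, `bic_diff`, `aic_best`, `bic_best`.
#' @export
criterion_tiebreak <- function(aic, bic) {
  if (length(aic) != length(bic)) stopf("aic and bic must have equal length")
  ia <- which.min(aic); ib <- which.min(bic)
  if (ia == ib)
    return(list(index = ia, criterion = "agreement", aic_diff = 0,
                bic_diff = 0, aic_best = ia, bic_best = ib))
  aic_diff <- aic[ib] - aic[ia]
  bic_diff <- bic[ia] - bic[ib]
  if (bic_diff >= aic_diff)
    list(index = ib, criterion = "BIC", aic_diff = aic_diff,
         bic_diff = bic_diff, aic_best = ia, bic_best = ib)
  else
    list(index = ia, criterion = "AIC", aic_diff = aic_diff,
         bic_diff = bic_diff, aic_best = ia, bic_best = ib)
}

#' Generalized (broad-sense) heritability from a longitudinal fit
#'
#' Computes `H2 = 1 - PEV / (2 * sigma2_G)` where `PEV` is the average
#' prediction-error variance of pairwise genotype contrasts on the
#' entry-mean scale and `sigma2_G` the genetic variance on the same scale
#' (`m' G_L m` with `m` the harvest-averaging weights). By convention the fit
#' should use `G_L = CS` and `R_L = ID`.
#'
#' @param fit a [fit_longitudinal()] object.
#' @return list of class `heritability_estimate` with `H2` (clipped to
#'   `[0, 1]` with a warning when outside), `PEV`, `sigma2_G` and a `flagged`
#'   indicator (degenerate genetic variance).
#' @export
generalized_heritability <- function(fit) {
  if (fit$g_structure != "CS" || fit$r_structure != "ID")
    warnf("heritability convention assumes G_L = CS and R_L = ID (fit has %s/%s)",
          fit$g_structure, fit$r_structure)
  s2 <- fit$sigma2_entry
  if (s2 <= 1e-12) {
    return(structure(list(H2 = NA_real_, PEV = fit$pev_mean_contrast,
                          sigma2_G = s2, flagged = TRUE),
                     class = "heritability_estimate"))
  }
  H2 <- 1 - fit$pev_mean_contrast / (2 * s2)
  if (H2 < 0 || H2 > 1) {
    warnf("H2 = %.3f outside [0, 1]; clipped", H2)
    H2 <- min(max(H2, 0), 1)
  }
  structure(list(H2 = H2, PEV = fit$pev_mean_contrast, sigma2_G = s2,
                 flagged = FALSE), class = "heritability_estimate")
}

#' @export
print.heritability_estimate <- function(x, ...) {
  cat(sprintf("H2 = %.3f (PEV = %.4f, sigma2_G = %.4f)%s\n",
              x$H2, x$PEV, x$sigma2_G, if (x$flagged) " [flagged]" else ""))
  invisible(x)
}

#' Adjusted entry means
#'
#' The stage-2 response: per genotype, the mean over harvests of
#' `mu + h_l + g_il` (overall mean plus harvest effect plus genotype BLUP),
#' i.e. the marginal predicted value of each individual plant across
#' harvests. Check cultivars are excluded.
#'
#' @param fit a converged [fit_longitudinal()] object.
#' @return named numeric vector, one adjusted entry mean per genotype.
#' @export
adjusted_entry_means <- function(fit) {
  if (!fit$converged) warnf("fit did not converge; entry means may be unreliable")
  drop(fit$mu + mean(fit$harvest) + rowMeans(fit$blups))
}
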