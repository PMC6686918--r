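test_that("VCOV structures realize their defining forms", {
  expect_equal(unname(build_vcov(vcov_structure("CS", 2, c(1, 0.5)))),
               matrix(c(1, 0.5, 0.5, 1), 2))
  # AR1 with rho = 0 equals ID
  expect_equal(build_vcov(vcov_structure("AR1", 3, c(2, 0))),
               build_vcov(vcov_structure("ID", 3, 2)))
  expect_equal(n_vcov_par("US", 4), 10L)
  expect_equal(n_vcov_par("CSHet", 4), 5L)
  ar <- build_vcov(vcov_structure("AR1", 4, c(1.5, 0.6)))
  expect_equal(ar[1, 3], 1.5 * 0.36)
  po <- build_vcov(vcov_structure("Po", 4, c(1.5, 0.6)))
  expect_equal(unname(po), unname(ar))  # equally spaced coordinates
  pot <- build_vcov(vcov_structure("Po", 3, c(1, 0.5), times = c(1, 2, 4)))
  expect_equal(pot[1, 3], 0.5^3)
  expect_error(build_vcov(vcov_structure("US", 2, c(1, 2, 1))), "definite")
  expect_error(build_vcov(vcov_structure("AR1", 3, c(1, 1.2))), "correlation")
})

test_that("realized structures are PSD across random valid parameters", {
  set.seed(21)
  L <- 4L
  for (i in 1:200) {
    nm <- sample(c("ID", "DIAG", "CS", "CSHet", "AR1", "AR1Het", "Po", "PoHet"), 1)
    np <- n_vcov_par(nm, L)
    par <- switch(nm,
      ID = runif(1, 0.1, 3),
      DIAG = runif(L, 0.1, 3),
      CS = c(runif(1, 0.1, 3), runif(1, -1 / (L - 1) + 0.01, 0.98)),
      CSHet = c(runif(L, 0.3, 2), runif(1, -1 / (L - 1) + 0.01, 0.98)),
      AR1 = c(runif(1, 0.1, 3), runif(1, -0.98, 0.98)),
      AR1Het = c(runif(L, 0.3, 2), runif(1, -0.98, 0.98)),
      Po = c(runif(1, 0.1, 3), runif(1, 0.02, 0.98)),
      PoHet = c(runif(L, 0.3, 2), runif(1, 0.02, 0.98)))
    M <- build_vcov(vcov_structure(nm, L, par))
    ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-10 * max(ev))
  }
})

test_that("structured REML equals the dense restricted likelihood", {
  cfg <- sim_config(n_dams = 4L, n_sires = 5L, family_size = 4L,
                    n_blocks = 2L, plants_per_plot = 2L, n_checks = 1L,
                    n_markers = 20L, n_harvests = 2L, seed = 31)
  pop <- simulate_population(cfg)     # 40 observations
  tb <- pop$phenotypes
  vc <- c(0.1, 0.2, 0.05)
  gp <- c(0.8, 0.5); rp <- 1.1
  ll_structured <- longitudinal_loglik(tb, "CS", "ID", varcomp = vc,
                                       g_params = gp, r_params = rp)
  # dense oracle: V assembled explicitly, restricted likelihood by textbook
  # formula with generic solve()/determinant()
  fit <- fit_longitudinal(tb, "CS", "ID", n_starts = 1, keep_design = TRUE)
  d <- fit$design
  GL <- build_vcov(vcov_structure("CS", 2, gp))
  RL <- build_vcov(vcov_structure("ID", 2, rp))
  B <- matrix(0, d$n, d$n)
  for (i in seq_len(d$off)) B[(i - 1) * 2 + 1:2, (i - 1) * 2 + 1:2] <- RL + GL
  o0 <- d$off * 2
  for (i in seq_len(d$chk)) B[o0 + (i - 1) * 2 + 1:2, o0 + (i - 1) * 2 + 1:2] <- RL
  Z <- as.matrix(d$Z)
  V <- Z %*% diag(rep(vc, d$dsizes)) %*% t(Z) + B
  X <- d$X; y <- d$y
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(XtViX, t(X) %*% Vi)
  ll_dense <- -0.5 * (as.numeric(determinant(V)$modulus) +
                        as.numeric(determinant(XtViX)$modulus) +
                        drop(t(y) %*% P %*% y) +
                        (d$n - ncol(X)) * log(2 * pi))
  expect_lt(abs(ll_structured - ll_dense), 1e-6)
})

test_that("a null simulation yields near-zero genetic variance", {
  cfg <- small_config(seed = 41, n_markers = 30L, n_harvests = 2L,
                      h2 = 1e-4, sigma2_block = 0.01, sigma2_parent = 0.01,
                      sigma2_block_parent = 0.01,
                      residual_structure = "ID", residual_pars = 1)
  pop <- simulate_population(cfg)
  fit <- fit_longitudinal(pop$phenotypes, "CS", "ID", n_starts = 1)
  expect_lt(fit$sigma2_entry, 0.05)
  em <- adjusted_entry_means(fit)
  expect_lt(sd(em), 0.2)
})

test_that("CS genetic correlation is recovered from simulated trials", {
  # per-harvest genetic variance 1, rho 0.6, residual ID(1), L = 4
  rhos <- numeric(6)
  for (s in seq_along(rhos)) {
    cfg <- sim_config(n_dams = 10L, n_sires = 12L, family_size = 18L,
                      n_blocks = 3L, plants_per_plot = 6L, n_checks = 2L,
                      n_markers = 100L, n_harvests = 4L,
                      residual_structure = "ID", residual_pars = 1,
                      genetic_cor = 0.6, h2 = 0.7 / 0.95, seed = 200 + s)
    pop <- simulate_population(cfg)
    fit <- fit_longitudinal(pop$phenotypes, "CS", "ID", n_starts = 1)
    rhos[s] <- fit$g_params[2]
  }
  expect_lt(abs(mean(rhos) - 0.6), 0.15)
})

test_that("single-harvest fits collapse every structure to ID", {
  cfg <- small_config(seed = 51, n_markers = 30L, n_harvests = 1L)
  pop <- simulate_population(cfg)
  f_cs <- fit_longitudinal(pop$phenotypes, "CS", "ID", n_starts = 1)
  f_id <- fit_longitudinal(pop$phenotypes, "ID", "ID", n_starts = 1)
  expect_equal(f_cs$loglik, f_id$loglik, tolerance = 1e-6)
  expect_equal(f_cs$g_structure, "ID")
})

test_that("tie-break rule selects by the criterion with the larger difference", {
  # worked example: AIC prefers model 2, BIC prefers model 1; BIC difference
  # is larger so BIC governs and model 1 is selected
  tb <- criterion_tiebreak(aic = c(2782.262, 2774.400),
                           bic = c(2817.201, 2826.809))
  expect_equal(tb$aic_diff, 7.862, tolerance = 1e-9)
  expect_equal(tb$bic_diff, 9.608, tolerance = 1e-9)
  expect_equal(tb$criterion, "BIC")
  expect_equal(tb$index, 1L)
  # agreement case
  tb2 <- criterion_tiebreak(aic = c(10, 12), bic = c(11, 13))
  expect_equal(tb2$criterion, "agreement")
  expect_equal(tb2$index, 1L)
  # single candidate selected vacuously
  tb3 <- criterion_tiebreak(100, 120)
  expect_equal(tb3$index, 1L)
})

test_that("hierarchical selection runs and records a trace", {
  cfg <- small_config(seed = 61, n_markers = 40L, n_harvests = 3L,
                      residual_structure = "ID", residual_pars = 1)
  pop <- simulate_population(cfg)
  sel <- select_vcov(pop$phenotypes, c("ID", "CS"), c("ID", "DIAG"),
                     n_starts = 1)
  expect_true(sel$g_structure %in% c("ID", "CS"))
  expect_equal(nrow(sel$trace), 4L)
  expect_equal(sum(sel$trace$chosen), 2L)
  expect_true(all(c("AIC", "BIC", "logLik") %in% names(sel$trace)))
  # AIC/BIC bookkeeping: AIC = -2 logLik + 2 npar
  expect_equal(sel$trace$AIC,
               -2 * sel$trace$logLik + 2 * sel$trace$npar)
})

test_that("ID-generated data mostly select ID over CS", {
  wins <- 0L
  n_rep <- 8L
  for (s in seq_len(n_rep)) {
    cfg <- small_config(seed = 300 + s, n_markers = 30L, n_harvests = 3L,
                        genetic_cor = 1e-6, h2 = 0.4,
                        residual_structure = "ID", residual_pars = 1)
    pop <- simulate_population(cfg)
    sel <- tryCatch(select_vcov(pop$phenotypes, c("ID", "CS"), "ID",
                                n_starts = 1), error = function(e) NULL)
    if (!is.null(sel) && sel$g_structure == "ID") wins <- wins + 1L
  }
  expect_gte(wins / n_rep, 0.8)
})

test_that("generalized heritability follows its defining identity", {
  fit <- list(g_structure = "CS", r_structure = "ID",
              sigma2_entry = 2, pev_mean_contrast = 0)
  expect_equal(generalized_heritability(fit)$H2, 1)
  fit$pev_mean_contrast <- 4   # PEV = 2 sigma2_G -> H2 = 0
  expect_equal(generalized_heritability(fit)$H2, 0)
  fit$sigma2_entry <- 0
  expect_true(generalized_heritability(fit)$flagged)
})

test_that("heritability recovery near the simulated target", {
  h2s <- numeric(5)
  for (s in seq_along(h2s)) {
    cfg <- sim_config(n_dams = 10L, n_sires = 12L, family_size = 18L,
                      n_blocks = 3L, plants_per_plot = 6L, n_checks = 2L,
                      n_markers = 80L, n_harvests = 4L,
                      residual_structure = "ID", residual_pars = 1,
                      genetic_cor = 0.9, h2 = 0.85, seed = 400 + s)
    pop <- simulate_population(cfg)
    fit <- fit_longitudinal(pop$phenotypes, "CS", "ID", n_starts = 1)
    h2s[s] <- generalized_heritability(fit)$H2
  }
  expect_lt(abs(mean(h2s) - 0.85), 0.1)
})

test_that("adjusted entry means track the simulated genetic values", {
  cfg <- sim_config(n_dams = 10L, n_sires = 12L, family_size = 18L,
                    n_blocks = 3L, plants_per_plot = 6L, n_checks = 2L,
                    n_markers = 100L, n_harvests = 4L,
                    residual_structure = "ID", residual_pars = 1,
                    genetic_cor = 0.9, h2 = 0.8, seed = 71)
  pop <- simulate_population(cfg)
  fit <- fit_longitudinal(pop$phenotypes, "CS", "ID", n_starts = 1)
  em <- adjusted_entry_means(fit)
  expect_equal(sort(names(em)), sort(names(pop$truth$u)))
  expect_gte(cor(em[names(pop$truth$u)], pop$truth$u), 0.7)
  expect_false(any(grepl("^C", names(em))))  # checks excluded
})
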