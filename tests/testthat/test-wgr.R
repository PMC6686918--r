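ridge_instance <- function(seed = 2, n = 50, p = 20) {
  set.seed(seed)
  X <- scale(matrix(rbinom(n * p, 4, 0.5), n, p), center = TRUE, scale = FALSE)
  beta <- rnorm(p, 0, 0.3)
  y <- 5 + drop(X %*% beta) + rnorm(n)
  list(X = X, y = y, beta = beta)
}

test_that("BRR with fixed variances matches the closed-form ridge solution", {
  d <- ridge_instance()
  s2e <- 1; s2b <- 0.09
  fit <- fit_wgr_bayes(d$y, d$X, wgr_spec("BRR", niter = 50000, burnin = 2000),
                       fixed_var = list(beta = s2b, eps = s2e), seed = 3)
  ridge <- drop(solve(crossprod(d$X) + diag(s2e / s2b, ncol(d$X)),
                      crossprod(d$X, d$y - mean(d$y))))
  expect_lt(max(abs(fit$beta - ridge)), 0.02)
  expect_lt(abs(fit$mu - mean(d$y)), 0.05)
})

test_that("uninformative markers leave the intercept at the phenotype mean", {
  set.seed(5)
  y <- rnorm(30, 7)
  X <- matrix(0, 30, 4)
  fit <- fit_wgr_bayes(y, X, wgr_spec("BRR", niter = 3000, burnin = 500),
                       seed = 6)
  expect_lt(abs(fit$mu - mean(y)), 3 * sd(y) / sqrt(30))
  expect_lt(max(abs(fit$beta)), 0.05)
})

test_that("spike-and-slab with pi = 1 forces all effects to zero", {
  d <- ridge_instance(7)
  for (m in c("BB", "BC")) {
    fit <- fit_wgr_bayes(d$y, d$X, wgr_spec(m, niter = 1500, burnin = 300,
                                            pi = 1), seed = 8)
    expect_identical(max(abs(fit$beta)), 0)
  }
})

test_that("residual variance is consistent with no markers", {
  set.seed(9)
  y <- rnorm(500, 0, sqrt(2))
  fit <- fit_wgr_bayes(y, matrix(0, 500, 1),
                       wgr_spec("BRR", niter = 4000, burnin = 1000), seed = 10)
  expect_lt(abs(fit$sigma2_eps - 2) / 2, 0.1)
})

test_that("all samplers agree with each other and with GBLUP on additive data", {
  # matched fixed variance hyperparameters, no spike: the five priors
  # coincide, so all posterior means target the same ridge solution
  set.seed(11)
  n <- 150; p <- 300
  X <- matrix(rbinom(n * p, 4, runif(p, 0.1, 0.9)), n, p)
  rownames(X) <- sprintf("i%03d", 1:n)
  W <- scale(X, center = TRUE, scale = FALSE)
  g <- drop(W %*% rnorm(p, 0, 0.1)); g <- g / sd(g)
  y <- g + rnorm(n, 0, 1)
  msx <- sum(apply(X, 2, var))
  vb <- 0.5 * var(y) / msx
  gebvs <- sapply(c("BRR", "BA", "BB", "BC", "BL"), function(m)
    fit_wgr_bayes(y, X, wgr_spec(m, niter = 4000, burnin = 800, pi = 0),
                  fixed_var = list(beta = vb, eps = 0.5 * var(y)),
                  seed = 12)$gebv)
  c0 <- sum(W * W) / n
  gb <- fit_gblup(y, tcrossprod(W) / c0 + diag(1e-8, n),
                  fixed_var = c(g = vb * c0, e = 0.5 * var(y)))
  gebvs <- cbind(gebvs, GBLUP = gb$gebv + gb$mu)
  cc <- cor(gebvs)
  expect_gt(min(cc[lower.tri(cc)]), 0.98)
})

test_that("chains with different seeds agree within Monte Carlo error", {
  d <- ridge_instance(13, n = 40, p = 10)
  f1 <- fit_wgr_bayes(d$y, d$X, wgr_spec("BRR", niter = 8000, burnin = 1000),
                      seed = 1)
  f2 <- fit_wgr_bayes(d$y, d$X, wgr_spec("BRR", niter = 8000, burnin = 1000),
                      seed = 2)
  # effective-sample-size-deflated Monte Carlo standard error per effect
  mc_se <- pmax(f1$beta_sd, f2$beta_sd) / sqrt(7000 / 25)
  expect_true(all(abs(f1$beta - f2$beta) < 3 * (mc_se + 1e-3)))
  expect_gt(cor(f1$gebv, f2$gebv), 0.999)
})

test_that("column scaling divides effects by the scale, GEBVs unchanged", {
  d <- ridge_instance(14, n = 60, p = 15)
  c0 <- 2.5
  f1 <- fit_wgr_bayes(d$y, d$X, wgr_spec("BRR", niter = 12000, burnin = 2000),
                      seed = 15)
  f2 <- fit_wgr_bayes(d$y, d$X * c0,
                      wgr_spec("BRR", niter = 12000, burnin = 2000), seed = 15)
  expect_lt(max(abs(f2$beta * c0 - f1$beta)), 0.03)
  expect_lt(max(abs(f2$gebv - f1$gebv)), 0.1)
})

test_that("GBLUP eigen path matches the dense mixed-model solve", {
  set.seed(16)
  K <- crossprod(matrix(rnorm(25), 5)) / 5 + diag(0.5, 5)
  y <- rnorm(5)
  fit <- fit_gblup(y, K, fixed_var = c(g = 2, e = 1))
  V <- 2 * K + diag(1, 5)
  one <- rep(1, 5)
  mu_d <- drop(solve(t(one) %*% solve(V, one), t(one) %*% solve(V, y)))
  g_d <- drop(2 * K %*% solve(V, y - mu_d))
  expect_lt(max(abs(fit$g - g_d)), 1e-8)
  expect_lt(abs(fit$mu - mu_d), 1e-8)
})

test_that("ridge regression and GBLUP give identical predictions", {
  set.seed(17)
  n <- 30; p <- 100
  X <- matrix(rbinom(n * p, 4, 0.4), n, p)
  W <- scale(X, center = TRUE, scale = FALSE)
  y <- rnorm(n) + drop(W %*% rnorm(p, 0, 0.1))
  c0 <- sum(W * W) / n
  K <- tcrossprod(W) / c0 + diag(1e-10, n)
  s2g <- 1.3; s2e <- 0.7
  fit <- fit_gblup(y, K, fixed_var = c(g = s2g, e = s2e))
  lam <- s2e * c0 / s2g             # matched marker-level ridge penalty
  bt <- solve(crossprod(W) + diag(lam, p), crossprod(W, y - fit$mu))
  expect_lt(max(abs(drop(W %*% bt) - fit$g)), 1e-6)
})

test_that("GBLUP degenerates gracefully and recovers heritability", {
  K <- diag(4) + 0.1
  expect_silent(f0 <- fit_gblup(rep(1, 4) + c(0, 1e-10, 0, 0), K))
  expect_lt(f0$sigma2_g, 1e-6)
  set.seed(18)
  h2s <- replicate(10, {
    n <- 300
    Z <- matrix(rbinom(n * 400, 4, 0.5), n)
    W <- scale(Z, center = TRUE, scale = FALSE)
    K <- tcrossprod(W) / (sum(W * W) / n) + diag(1e-6, n)
    g <- drop(t(chol(K)) %*% rnorm(n))
    f <- fit_gblup(g + rnorm(n), K)
    narrow_heritability(f)
  })
  expect_lt(abs(mean(h2s) - 0.5), 0.1)
  # identities at the extremes
  expect_equal(narrow_heritability(list(sigma2_g = 2, sigma2_eps = 0)), 1)
  expect_equal(narrow_heritability(list(sigma2_g = 0, sigma2_eps = 1)), 0)
})

test_that("predictions reproduce training GEBVs and respect panels", {
  d <- ridge_instance(19, n = 40, p = 12)
  fit <- fit_wgr_bayes(d$y, d$X, wgr_spec("BRR", niter = 2000, burnin = 400),
                       seed = 20)
  expect_equal(predict_gebv(fit, X_new = d$X), unname(fit$gebv))
  expect_equal(predict_gebv(fit, X_new = matrix(0, 3, 12)), rep(0, 3))
  expect_error(predict_gebv(fit, X_new = d$X[, 1:5]), "panel mismatch")
  set.seed(21)
  K <- crossprod(matrix(rnorm(36), 6)) / 6 + diag(0.3, 6)
  gf <- fit_gblup(rnorm(6), K)
  expect_equal(predict_gebv(gf, K_cross = K), unname(gf$g), tolerance = 1e-8)
})
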