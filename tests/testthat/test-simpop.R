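test_that("founder simulation honours allele frequencies and the seed", {
  cfg <- small_config(seed = 3, n_markers = 5L)
  f0 <- simulate_founders(cfg, freqs = rep(0, 5))
  expect_true(all(unclass(f0) == 0L))
  f1 <- simulate_founders(cfg, freqs = rep(1, 5))
  expect_true(all(unclass(f1) == 4L))
  a <- simulate_founders(cfg)
  b <- simulate_founders(cfg)
  expect_identical(unclass(a), unclass(b))
  expect_equal(nrow(a), max(cfg$n_dams, cfg$n_sires))
  expect_error(sim_config(ploidy = 3), "even")
})

test_that("gamete dosages follow the exact hypergeometric distribution", {
  expect_identical(simulate_gamete(0, 4, n = 50), rep(0L, 50))
  expect_identical(simulate_gamete(4, 4, n = 50), rep(2L, 50))
  expect_equal(gamete_distribution(2, 4), c(1, 4, 1) / 6)
  set.seed(42)
  for (d in 0:4) {
    draws <- simulate_gamete(d, 4, n = 10000)
    probs <- gamete_distribution(d, 4)
    obs <- tabulate(draws + 1L, nbins = 3L)
    keep <- probs > 0
    if (sum(keep) > 1) {
      pval <- chisq.test(obs[keep], p = probs[keep])$p.value
      expect_gt(pval, 0.001)
    } else {
      expect_true(all(draws == which(keep) - 1L))
    }
  }
})

test_that("polycross produces half-sib families summing two gametes", {
  cfg <- small_config(seed = 5, n_markers = 40L)
  founders <- simulate_founders(cfg)
  cross <- simulate_polycross(founders, cfg)
  expect_equal(nrow(cross$dosages), cfg$n_dams * cfg$family_size)
  expect_equal(length(unique(cross$families)), cfg$n_dams)
  # no self-fertilization
  off <- cross$pedigree[!is.na(cross$pedigree$dam), ]
  expect_true(all(off$dam != off$sire))
  # dam 4 x sire 4 -> all offspring dose 4
  fA <- dosage_matrix(matrix(4L, 3, 2, dimnames = list(paste0("P", 1:3), c("mA", "mB"))), 4)
  cfgA <- sim_config(n_dams = 2L, n_sires = 3L, family_size = 4L,
                     n_blocks = 2L, plants_per_plot = 2L, n_markers = 2L,
                     seed = 1)
  crA <- simulate_polycross(fA, cfgA)
  expect_true(all(unclass(crA$dosages) == 4L))
  expect_error(simulate_polycross(fA[1, , drop = FALSE], cfgA), "2 founders")
})

test_that("dam 2 x sire 2 offspring match the gamete convolution", {
  # convolution of two hypergeometric gametes from dose-2 parents
  conv <- convolve(gamete_distribution(2, 4), rev(gamete_distribution(2, 4)),
                   type = "open")
  f2 <- dosage_matrix(matrix(2L, 4, 1, dimnames = list(paste0("P", 1:4), "m1")), 4)
  cfg2 <- sim_config(n_dams = 3L, n_sires = 4L, family_size = 200L,
                     n_blocks = 10L, plants_per_plot = 20L, n_markers = 1L,
                     seed = 8)
  cr <- simulate_polycross(f2, cfg2)
  obs <- tabulate(unclass(cr$dosages) + 1L, nbins = 5L)
  expect_gt(chisq.test(obs, p = conv)$p.value, 0.001)
})

test_that("offspring allele frequency matches mid-parent expectation", {
  cfg <- small_config(seed = 9, n_markers = 500L)
  founders <- simulate_founders(cfg)
  cross <- simulate_polycross(founders, cfg)
  dams <- unclass(founders)[seq_len(cfg$n_dams), ]
  sires <- unclass(founders)[seq_len(cfg$n_sires), ]
  # per offspring: E[dose] = (dam dose)/2 + mean sire dose/2; pool per marker
  midparent <- colMeans(dams) / 2 + colMeans(sires) / 2
  off_freq <- colMeans(unclass(cross$dosages))
  expect_gt(t.test(off_freq - midparent)$p.value, 0.001)
  expect_lt(mean(abs(off_freq - midparent)), 0.2)
})

test_that("read counts follow the dosage-determined reference fraction", {
  d <- dosage_matrix(matrix(c(4L, 0L, 2L), 3, 1,
                            dimnames = list(c("a", "b", "c"), "m1")), 4)
  rc <- simulate_read_counts(d, depth_mean = 50, seq_error = 0, seed = 2)
  expect_equal(rc$alt["a", 1], 0L)          # dose 4: all reads reference
  expect_equal(rc$ref["b", 1], 0L)          # dose 0: none
  # dose 2 at high depth: fraction near 1/2 within 3 binomial SE
  d2 <- dosage_matrix(matrix(2L, 1, 1), 4)
  rc2 <- simulate_read_counts(d2, depth_mean = 1000, seq_error = 0, seed = 3)
  n <- rc2$ref[1, 1] + rc2$alt[1, 1]
  se <- sqrt(0.25 / n)
  expect_lt(abs(rc2$ref[1, 1] / n - 0.5), 3 * se)
  # missing dosage -> zero depth
  dm <- dosage_matrix(matrix(NA_integer_, 1, 1), 4)
  rcm <- simulate_read_counts(dm, depth_mean = 50, seed = 4)
  expect_equal(rcm$ref[1, 1] + rcm$alt[1, 1], 0L)
  expect_error(simulate_read_counts(d, seq_error = 0.5), "seq_error")
})

test_that("reference fraction converges to q as depth grows", {
  set.seed(6)
  for (dose in c(1L, 3L)) {
    d <- dosage_matrix(matrix(dose, 400, 1), 4)
    rc <- simulate_read_counts(d, depth_mean = 400, seq_error = 0.01)
    q <- (dose / 4) * (1 - 0.01) + (1 - dose / 4) * 0.01
    frac <- sum(rc$ref) / sum(rc$ref + rc$alt)
    expect_lt(abs(frac - q), 0.005)
  }
})

test_that("trial layout reproduces the split-plot design and truth sidecar", {
  cfg <- small_config(seed = 4, n_markers = 50L)
  pop <- simulate_population(cfg)
  ph <- pop$phenotypes
  n_plants <- length(unique(ph$plant))
  expect_equal(n_plants,
               cfg$n_blocks * (cfg$n_dams + cfg$n_checks) * cfg$plants_per_plot)
  expect_equal(sum(!tapply(ph$is_check, ph$plant, `[`, 1)),
               cfg$n_dams * cfg$family_size)
  expect_equal(nrow(ph), n_plants * cfg$n_harvests)
  expect_length(pop$truth$beta, cfg$n_markers)
  expect_equal(dim(pop$truth$g),
               c(cfg$n_dams * cfg$family_size, cfg$n_harvests))
  # mismatch between offspring and config errors
  expect_error(simulate_trial(pop$dosages[1:10, ], cfg, pop$families),
               "offspring count")
})

test_that("simulated residuals reconstruct the records and match R_L", {
  pooled <- NULL
  for (s in 1:30) {
    cfg <- small_config(seed = 20 + s, n_markers = 10L, n_harvests = 3L,
                        residual_structure = "AR1", residual_pars = c(1.5, 0.4))
    founders <- simulate_founders(cfg)
    cross <- simulate_polycross(founders, cfg)
    trial <- simulate_trial(cross$dosages, cfg, cross$families)
    tr <- trial$truth
    if (s == 1) {
      # value decomposes exactly into the stored effects plus the residual
      ph <- trial$phenotypes[!trial$phenotypes$is_check, ]
      pj <- match(ph$parent, paste0("F", seq_len(cfg$n_dams)))
      eff <- tr$mu + tr$harvest[ph$harvest] +
        tr$block[cbind(ph$block, ph$harvest)] +
        tr$parent[cbind(pj, ph$harvest)] +
        tr$block_parent[cbind(ph$block, pj, ph$harvest)] +
        tr$g[cbind(match(ph$plant, rownames(tr$g)), ph$harvest)] +
        tr$residuals[cbind(match(ph$plant, rownames(tr$residuals)),
                           ph$harvest)]
      expect_lt(max(abs(ph$value - eff)), 1e-10)
    }
    pooled <- rbind(pooled, tr$residuals)
  }
  # > 4000 residual vectors: per-harvest variance within 10% of the AR1
  # diagonal, lag-1 correlation near 0.4
  v <- apply(pooled, 2, var)
  expect_true(all(abs(v - 1.5) / 1.5 < 0.10))
  expect_lt(abs(cor(pooled[, 1], pooled[, 2]) - 0.4), 0.05)
})

test_that("fixed seed gives byte-identical population output", {
  cfg <- small_config(seed = 99, n_markers = 25L)
  a <- simulate_population(cfg)
  b <- simulate_population(cfg)
  expect_identical(a$phenotypes, b$phenotypes)
  expect_identical(unclass(a$dosages), unclass(b$dosages))
  expect_identical(a$reads$ref, b$reads$ref)
})

test_that("double reduction shifts gametes toward homozygosity", {
  set.seed(13)
  g0 <- simulate_gamete(2, 4, n = 20000, double_reduction = 0)
  g1 <- simulate_gamete(2, 4, n = 20000, double_reduction = 1)
  # with full double reduction a dose-2 parent gives gametes 0 or 2 only
  expect_true(all(g1 %in% c(0L, 2L)))
  expect_gt(mean(g0 == 1L), 0.6)
})
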