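#' Simulation configuration for a polycross trial
#'
#' Defines the synthetic population and trial: a polycross of `n_dams`
#' recorded female parents mated to a pool of `n_sires` males, producing
#' half-sib families of `family_size` autotetraploid offspring, evaluated in a
#' split-plot randomized complete block design with `n_blocks` blocks, each
#' block holding one whole plot of `plants_per_plot` plants per family plus
#' `n_checks` clonal (apomictic) check cultivars, phenotyped over `n_harvests`
#' repeated harvests. Defaults reproduce the reference trial layout:
#' 19 dams x 30 offspring = 570 plants, plus 3 checks x 6 blocks x 5 clones =
#' 90, i.e. 660 plants in 6 blocks of 22 whole plots of 5 plants.
#'
#' @param n_dams number of recorded female parents (half-sib families).
#' @param n_sires number of pollen parents in the polycross.
#' @param family_size offspring per dam; must equal
#'   `n_blocks * plants_per_plot` so each family fills one plot per block.
#' @param ploidy even ploidy level (4 = autotetraploid).
#' @param n_markers number of simulated unlinked biallelic markers.
#' @param n_blocks,n_checks,plants_per_plot,n_harvests trial layout.
#' @param mu overall trait mean.
#' @param harvest_sd standard deviation of fixed harvest effects.
#' @param sigma2_block,sigma2_parent,sigma2_block_parent variances of the
#'   random block-within-harvest, parent-within-harvest and block-by-parent
#'   effects.
#' @param h2 target heritability of the genetic signal on the adjusted
#'   entry-mean scale (genetic variance relative to genetic-plus-residual on
#'   the across-harvest mean; design effects are removed by the stage-1 model
#'   and excluded from the target).
#' @param genetic_cor correlation of an individual's genetic effect across
#'   harvests (compound-symmetry; 1 = identical genetic value every harvest).
#' @param prop_nonzero proportion of markers with nonzero additive effect.
#' @param residual_structure,residual_pars residual variance-covariance across
#'   harvests (`R_L`), named per [vcov_structure()] vocabulary; defaults to
#'   first-order autoregressive with unit variance and correlation 0.3.
#' @param depth_mean,depth_dispersion negative-binomial read-depth model per
#'   genotype cell; `depth_dispersion = Inf` gives Poisson depths.
#' @param seq_error per-read miscall probability in `[0, 0.5)`.
#' @param missing_rate completely-at-random missing-dosage rate used when
#'   simulating incomplete matrices.
#' @param seed integer base seed; each stage derives its own stream from it.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_dams = 19L, n_sires = 20L, family_size = 30L,
                       ploidy = 4L, n_markers = 500L, n_blocks = 6L,
                       n_checks = 3L, plants_per_plot = 5L, n_harvests = 4L,
                       mu = 10, harvest_sd = 1,
                       sigma2_block = 0.1, sigma2_parent = 0.2,
                       sigma2_block_parent = 0.05,
                       h2 = 0.5, genetic_cor = 0.8, prop_nonzero = 0.1,
                       residual_structure = "AR1", residual_pars = c(1, 0.3),
                       depth_mean = 60, depth_dispersion = Inf,
                       seq_error = 0.005, missing_rate = 0,
                       seed = NULL) {
  if (!is_count(ploidy) || ploidy %% 2 != 0 || ploidy < 2)
    stopf("ploidy must be an even integer >= 2")
  if (seq_error < 0 || seq_error >= 0.5) stopf("seq_error must lie in [0, 0.5)")
  if (family_size != n_blocks * plants_per_plot)
    stopf("family_size (%d) must equal n_blocks * plants_per_plot (%d)",
          family_size, n_blocks * plants_per_plot)
  vars <- c(sigma2_block, sigma2_parent, sigma2_block_parent)
  if (any(vars < 0)) stopf("variance components must be >= 0")
  if (h2 <= 0 || h2 >= 1) stopf("h2 must lie in (0, 1)")
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate founder genotypes
#'
#' Draws founder allele dosages marker by marker: the reference-allele
#' frequency of each marker is Uniform(0.05, 0.95) and each founder's dosage
#' is Binomial(ploidy, p). Founders are the polycross parents; the first
#' `n_dams` double as recorded female parents.
#'
#' @param config a [sim_config()].
#' @param freqs optional vector of fixed per-marker allele frequencies
#'   (overrides the uniform draw; useful for degenerate checks).
#' @return a [dosage_matrix()] with `max(n_dams, n_sires)` rows.
#' @export
simulate_founders <- function(config, freqs = NULL) {
  set_seed_if(config$seed, 0L)
  n_f <- max(config$n_dams, config$n_sires)
  p <- ncol_mk <- config$n_markers
  if (p < 1) stopf("n_markers must be >= 1")
  if (is.null(freqs)) freqs <- runif(p, 0.05, 0.95)
  if (length(freqs) != p) stopf("freqs must have length n_markers")
  x <- vapply(freqs, function(f) rbinom(n_f, config$ploidy, f), numeric(n_f))
  x <- matrix(x, nrow = n_f)
  rownames(x) <- paste0("P", seq_len(n_f))
  colnames(x) <- paste0("m", seq_len(p))
  dosage_matrix(x, ploidy = config$ploidy,
                info = data.frame(marker = colnames(x), chrom = "chr1",
                                  pos = seq_len(p) * 10000L, ref = "sim"))
}

#' Simulate a gamete dosage under tetrasomic (bivalent) inheritance
#'
#' A gamete receives `ploidy/2` of the parent's `ploidy` chromosomes drawn
#' without replacement (random bivalent pairing), so the gamete dosage is
#' hypergeometric. `double_reduction` is the probability that a gamete carries
#' two copies of one parental chromosome; at the default 0 the model is pure
#' bivalent pairing.
#'
#' @param parent_dosage integer vector of parent dosages in `0..ploidy`.
#' @param ploidy even parent ploidy.
#' @param n draws per element of `parent_dosage` (recycled elementwise when
#'   `length(parent_dosage) > 1`, in which case `n` must be 1).
#' @param double_reduction probability of double reduction per meiosis.
#' @return integer vector of gamete dosages in `0..ploidy/2`.
#' @export
simulate_gamete <- function(parent_dosage, ploidy = 4L, n = 1L,
                            double_reduction = 0) {
  if (any(parent_dosage < 0 | parent_dosage > ploidy))
    stopf("parent_dosage must lie in 0..ploidy")
  half <- ploidy %/% 2L
  if (length(parent_dosage) > 1L) {
    if (n != 1L) stopf("n must be 1 when parent_dosage is a vector")
    out <- rhyper(length(parent_dosage), parent_dosage,
                  ploidy - parent_dosage, half)
  } else {
    out <- rhyper(n, parent_dosage, ploidy - parent_dosage, half)
  }
  if (double_reduction > 0) {
    # with probability dr, the gamete is ploidy/2 - 1 distinct chromosomes,
    # one doubled: draw one chromosome, duplicate it, fill the rest
    dr <- runif(length(out)) < double_reduction
    if (any(dr)) {
      pd <- rep_len(parent_dosage, length(out))[dr]
      first <- rhyper(sum(dr), pd, ploidy - pd, 1L)
      # the doubled chromosome contributes twice; any remaining slots are
      # filled from the other ploidy - 1 chromosomes
      rest <- if (half > 2L)
        rhyper(sum(dr), pd - first, (ploidy - 1L) - (pd - first), half - 2L)
      else 0L
      out[dr] <- 2L * first + rest
    }
  }
  as.integer(out)
}

#' Exact gamete dosage distribution
#'
#' Probability of each gamete dosage `0..ploidy/2` for a parent dosage under
#' bivalent tetrasomic inheritance (hypergeometric sampling of chromosomes).
#'
#' @inheritParams simulate_gamete
#' @return numeric vector of length `ploidy/2 + 1` summing to 1.
#' @export
gamete_distribution <- function(parent_dosage, ploidy = 4L) {
  half <- ploidy %/% 2L
  stats::dhyper(0:half, parent_dosage, ploidy - parent_dosage, half)
}

#' Simulate a polycross
#'
#' Each of the `n_dams` dams contributes `family_size` offspring. The sire of
#' every offspring is drawn uniformly (with replacement across offspring) from
#' the sire set excluding the dam itself, so families are half-sib on the dam
#' side; offspring dosage at every marker is the sum of one dam and one sire
#' gamete.
#'
#' @param founders founder [dosage_matrix()] from [simulate_founders()].
#' @param config the [sim_config()].
#' @return list with `dosages` (offspring [dosage_matrix()]), `pedigree`
#'   ([pedigree_table()] covering founders and offspring) and `families`
#'   (named character vector: offspring id -> dam id).
#' @export
simulate_polycross <- function(founders, config) {
  set_seed_if(config$seed, 1L)
  if (nrow(founders) < 2L) stopf("need at least 2 founders to avoid selfing")
  ploidy <- ploidy_of(founders)
  dams <- rownames(founders)[seq_len(config$n_dams)]
  sires <- rownames(founders)[seq_len(config$n_sires)]
  n_off <- config$n_dams * config$family_size
  off <- matrix(0L, n_off, ncol(founders))
  dam_id <- character(n_off); sire_id <- character(n_off)
  k <- 0L
  for (d in dams) {
    for (j in seq_len(config$family_size)) {
      k <- k + 1L
      s <- sample(setdiff(sires, d), 1L)
      dam_id[k] <- d; sire_id[k] <- s
      g_dam <- simulate_gamete(unclass(founders)[d, ], ploidy)
      g_sire <- simulate_gamete(unclass(founders)[s, ], ploidy)
      off[k, ] <- g_dam + g_sire
    }
  }
  ids <- sprintf("G%03d", seq_len(n_off))
  rownames(off) <- ids; colnames(off) <- colnames(founders)
  ped <- pedigree_table(
    id = c(rownames(founders), ids),
    dam = c(rep(NA_character_, nrow(founders)), dam_id),
    sire = c(rep(NA_character_, nrow(founders)), sire_id),
    ploidy = ploidy)
  list(dosages = dosage_matrix(off, ploidy = ploidy, info = marker_info(founders)),
       pedigree = ped,
       families = setNames(dam_id, ids))
}

#' Simulate GBS-like read counts from dosages
#'
#' Total depth per genotype cell is negative binomial with the configured mean
#' and dispersion (Poisson when dispersion is infinite); reference reads are
#' Binomial(depth, q) with `q = (d/ploidy) * (1 - seq_error) +
#' (1 - d/ploidy) * seq_error`, i.e. each read reports the wrong allele with
#' probability `seq_error`. Missing dosages yield depth 0.
#'
#' @param dosages a [dosage_matrix()].
#' @param depth_mean,depth_dispersion negative-binomial depth model.
#' @param seq_error per-read miscall probability in `[0, 0.5)`.
#' @param seed optional seed.
#' @return a [read_count_table()].
#' @export
simulate_read_counts <- function(dosages, depth_mean = 60,
                                 depth_dispersion = Inf, seq_error = 0.005,
                                 seed = NULL) {
  if (seq_error < 0 || seq_error >= 0.5) stopf("seq_error must lie in [0, 0.5)")
  set_seed_if(seed)
  ploidy <- ploidy_of(dosages)
  x <- unclass(dosages)
  n <- length(x)
  depth <- if (is.finite(depth_dispersion))
    rnbinom(n, size = depth_dispersion, mu = depth_mean)
  else rpois(n, depth_mean)
  depth[is.na(x)] <- 0L
  q <- (x / ploidy) * (1 - seq_error) + (1 - x / ploidy) * seq_error
  q[is.na(q)] <- 0
  ref <- rbinom(n, depth, q)
  ref_m <- matrix(ref, nrow(x), dimnames = dimnames(x))
  alt_m <- matrix(depth - ref, nrow(x), dimnames = dimnames(x))
  read_count_table(ref_m, alt_m, info = marker_info(dosages))
}

#' Sprinkle missing dosages completely at random
#'
#' @param dosages a [dosage_matrix()].
#' @param rate per-cell missing probability.
#' @param seed optional seed.
#' @return the matrix with a fraction `rate` of entries set to `NA`.
#' @export
add_missing <- function(dosages, rate, seed = NULL) {
  set_seed_if(seed)
  x <- unclass(dosages)
  x[runif(length(x)) < rate] <- NA_integer_
  dosage_matrix(x, ploidy = ploidy_of(dosages), info = marker_info(dosages))
}

#' Simulate the field trial phenotypes
#'
#' Lays the offspring and clonal checks out in the split-plot randomized
#' complete block design and generates phenotypes under the longitudinal
#' model: overall mean + fixed harvest effect + random block-within-harvest +
#' parent-within-harvest + block-by-parent + genetic value + residual. The
#' genetic value of individual i at harvest l is a compound-symmetry blend of
#' a marker-determined additive value (`W beta`, scaled so the target
#' entry-mean heritability holds) and harvest-specific deviations; residuals
#' follow the configured `R_L` across harvests, independent across plants.
#' Check cultivars are clones and receive fixed cultivar-by-harvest effects
#' instead of genetic values.
#'
#' @param offspring offspring [dosage_matrix()] (rows =
#'   `n_dams * family_size`).
#' @param config the [sim_config()].
#' @param families named vector offspring id -> dam id, as returned by
#'   [simulate_polycross()].
#' @return list with `phenotypes` (`data.frame`: plant, parent, block,
#'   harvest, is_check, value) and `truth` (true marker effects `beta`,
#'   per-offspring additive values `u`, genetic values `g` (plants x
#'   harvests), the drawn residuals (plants x harvests), all simulated
#'   effects, and the realized `R_L`).
#' @export
simulate_trial <- function(offspring, config, families) {
  set_seed_if(config$seed, 2L)
  n_off <- config$n_dams * config$family_size
  if (nrow(offspring) != n_off)
    stopf("offspring count %d does not equal n_dams * family_size = %d",
          nrow(offspring), n_off)
  L <- config$n_harvests
  K <- config$n_blocks
  ids <- rownames(offspring)
  fam <- families[ids]

  R_L <- build_vcov(vcov_structure(config$residual_structure, L = L,
                                   params = config$residual_pars))
  m <- rep(1 / L, L)
  v_e_entry <- drop(crossprod(m, R_L %*% m))
  v_g_entry <- config$h2 / (1 - config$h2) * v_e_entry
  c_g <- (1 + (L - 1) * config$genetic_cor) / L
  v_g <- v_g_entry / c_g   # per-harvest genetic variance

  # marker-determined additive values on the tetraploid dosage scale
  X <- unclass(offspring)
  X[is.na(X)] <- 0L
  beta <- rnorm(ncol(X)) * (runif(ncol(X)) < config$prop_nonzero)
  W <- scale(X, center = TRUE, scale = FALSE)
  u <- drop(W %*% beta)
  if (sd(u) > 0) u <- u * sqrt(v_g) / sd(u) else u <- rnorm(n_off, 0, sqrt(v_g))
  rho_g <- config$genetic_cor
  g <- sqrt(rho_g) * matrix(u, n_off, L) +
    sqrt(1 - rho_g) * matrix(rnorm(n_off * L, 0, sqrt(v_g)), n_off, L)
  dimnames(g) <- list(ids, paste0("h", seq_len(L)))

  h_eff <- rnorm(L, 0, config$harvest_sd)
  parents <- c(paste0("F", seq_len(config$n_dams)),
               paste0("CHK", seq_len(config$n_checks)))
  dams <- unique(fam)
  names(dams) <- paste0("F", seq_len(config$n_dams))
  b_eff <- matrix(rnorm(K * L, 0, sqrt(config$sigma2_block)), K, L)
  p_eff <- matrix(rnorm(length(parents) * L, 0, sqrt(config$sigma2_parent)),
                  length(parents), L, dimnames = list(parents, NULL))
  bp_eff <- array(rnorm(K * length(parents) * L, 0,
                        sqrt(config$sigma2_block_parent)),
                  dim = c(K, length(parents), L))
  c_eff <- matrix(rnorm(config$n_checks * L, 0, 1), config$n_checks, L)

  # layout: every family occupies one whole plot of plants_per_plot plants in
  # every block; family f's offspring are split across blocks in order
  chol_R <- chol(R_L)
  plant_rows <- list()
  resid_rows <- list()
  for (f in seq_len(config$n_dams)) {
    fam_ids <- ids[fam == dams[f]]
    for (k in seq_len(K)) {
      plot_ids <- fam_ids[((k - 1) * config$plants_per_plot + 1):(k * config$plants_per_plot)]
      for (pid in plot_ids) {
        e <- drop(crossprod(chol_R, rnorm(L)))
        resid_rows[[pid]] <- e
        val <- config$mu + h_eff + b_eff[k, ] + p_eff[f, ] + bp_eff[k, f, ] +
          g[pid, ] + e
        plant_rows[[pid]] <- data.frame(
          plant = pid, parent = names(dams)[f], block = k,
          harvest = seq_len(L), is_check = FALSE, value = val,
          stringsAsFactors = FALSE)
      }
    }
  }
  # clonal checks: plants_per_plot clones per check per block
  chk_count <- 0L
  for (cc in seq_len(config$n_checks)) {
    pj <- config$n_dams + cc
    for (k in seq_len(K)) {
      for (r in seq_len(config$plants_per_plot)) {
        chk_count <- chk_count + 1L
        pid <- sprintf("C%03d", chk_count)
        e <- drop(crossprod(chol_R, rnorm(L)))
        resid_rows[[pid]] <- e
        val <- config$mu + h_eff + b_eff[k, ] + p_eff[pj, ] + bp_eff[k, pj, ] +
          c_eff[cc, ] + e
        plant_rows[[pid]] <- data.frame(
          plant = pid, parent = paste0("CHK", cc), block = k,
          harvest = seq_len(L), is_check = TRUE, value = val,
          stringsAsFactors = FALSE)
      }
    }
  }
  pheno <- do.call(rbind, plant_rows)
  rownames(pheno) <- NULL
  resid <- do.call(rbind, resid_rows)
  colnames(resid) <- paste0("h", seq_len(L))
  list(phenotypes = pheno,
       truth = list(beta = beta, u = setNames(u, ids), g = g,
                    residuals = resid,
                    mu = config$mu, harvest = h_eff, block = b_eff,
                    parent = p_eff, block_parent = bp_eff, check = c_eff,
                    R_L = R_L, v_g = v_g, v_g_entry = v_g_entry,
                    v_e_entry = v_e_entry))
}

#' Simulate a complete population: founders, polycross, trial and reads
#'
#' Convenience wrapper running [simulate_founders()],
#' [simulate_polycross()], [simulate_read_counts()] and [simulate_trial()]
#' under the config's seed.
#'
#' @param config a [sim_config()].
#' @return list with `founders`, `dosages`, `pedigree`, `families`, `reads`,
#'   `phenotypes`, `truth`.
#' @export
simulate_population <- function(config) {
  founders <- simulate_founders(config)
  cross <- simulate_polycross(founders, config)
  dos <- cross$dosages
  if (config$missing_rate > 0)
    dos <- add_missing(dos, config$missing_rate,
                       seed = (config$seed %||% 0) + 6L)
  reads <- simulate_read_counts(dos, config$depth_mean,
                                config$depth_dispersion, config$seq_error,
                                seed = (config$seed %||% 0) + 3L)
  trial <- simulate_trial(cross$dosages, config, cross$families)
  list(founders = founders, dosages = cross$dosages, pedigree = cross$pedigree,
       families = cross$families, reads = reads,
       phenotypes = trial$phenotypes, truth = trial$truth)
}
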