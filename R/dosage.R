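#' Call allele dosages from biallelic read counts
#'
#' Per marker, fits a `(ploidy + 1)`-component binomial mixture to the
#' reference read fraction by EM. Component `d` (dosage `d` = copies of the
#' reference allele) has success probability
#' `q_d = (d/ploidy) * (1 - 2 * seq_error) + seq_error`; the mixing weights
#' (dosage-class frequencies in the population) are free. Each individual is
#' assigned the maximum-a-posteriori dosage; calls with posterior below
#' `min_posterior`, or zero depth, are set missing. Markers whose EM does not
#' converge are flagged and called entirely missing.
#'
#' @param counts a [read_count_table()].
#' @param ploidy even ploidy in `{2, 4, 6, 8}`.
#' @param seq_error per-read miscall probability.
#' @param min_posterior minimum posterior probability to retain a call.
#' @param max_iter,tol EM iteration cap and relative log-likelihood tolerance.
#' @param keep_posteriors keep the full per-individual posterior matrices
#'   (markers x individuals x classes) in the diagnostics.
#' @return list with `dosages` (a [dosage_matrix()]) and `diagnostics`
#'   (class `call_diagnostics`: per-marker `data.frame` plus fitted class
#'   weights; posterior arrays when requested).
#' @export
call_dosages <- function(counts, ploidy = 4L, seq_error = 0.01,
                         min_posterior = 0.8, max_iter = 200L, tol = 1e-8,
                         keep_posteriors = FALSE) {
  if (!ploidy %in% c(2L, 4L, 6L, 8L)) stopf("ploidy must be one of 2, 4, 6, 8")
  ref <- counts$ref; alt <- counts$alt
  depth <- ref + alt
  if (any(colSums(depth > 0) == 0))
    stopf("every marker needs at least one individual with depth > 0")
  n <- nrow(ref); p <- ncol(ref)
  q <- (0:ploidy) / ploidy * (1 - 2 * seq_error) + seq_error
  calls <- matrix(NA_integer_, n, p, dimnames = dimnames(ref))
  wts <- matrix(NA_real_, p, ploidy + 1,
                dimnames = list(colnames(ref), paste0("d", 0:ploidy)))
  conv <- logical(p); conf <- numeric(p); iters <- integer(p)
  posts <- if (keep_posteriors) vector("list", p) else NULL

  for (j in seq_len(p)) {
    rj <- ref[, j]; dj <- depth[, j]
    obs <- dj > 0
    # log-likelihood of each dosage class per observed individual
    ll <- outer(seq_len(sum(obs)), 0:ploidy, function(i, d)
      dbinom(rj[obs][i], dj[obs][i], q[d + 1], log = TRUE))
    w <- rep(1 / (ploidy + 1), ploidy + 1)
    prev <- -Inf; ok <- FALSE
    for (it in seq_len(max_iter)) {
      lw <- sweep(ll, 2, log(w), `+`)
      mx <- apply(lw, 1, max)
      pr <- exp(lw - mx)
      rs <- rowSums(pr)
      loglik <- sum(mx + log(rs))
      gamma <- pr / rs
      w <- colMeans(gamma)
      w <- pmax(w, 1e-12); w <- w / sum(w)
      if (is.finite(prev) && abs(loglik - prev) < tol * (abs(prev) + 1)) {
        ok <- TRUE; iters[j] <- it; break
      }
      prev <- loglik
    }
    conv[j] <- ok
    if (!ok) next
    map <- max.col(gamma, ties.method = "first") - 1L
    pmax_post <- gamma[cbind(seq_len(nrow(gamma)), map + 1L)]
    keep <- pmax_post >= min_posterior
    cj <- rep(NA_integer_, n)
    cj[which(obs)[keep]] <- map[keep]
    calls[, j] <- cj
    wts[j, ] <- w
    conf[j] <- mean(pmax_post)
    if (keep_posteriors) {
      full <- matrix(NA_real_, n, ploidy + 1)
      full[obs, ] <- gamma
      posts[[j]] <- full
    }
  }
  diag_df <- data.frame(marker = colnames(ref), converged = conv,
                        mean_depth = colMeans(depth),
                        mean_max_posterior = conf, em_iterations = iters,
                        stringsAsFactors = FALSE)
  diagnostics <- structure(list(markers = diag_df, weights = wts,
                                posteriors = posts),
                           class = "call_diagnostics")
  list(dosages = dosage_matrix(calls, ploidy = ploidy, info = counts$info),
       diagnostics = diagnostics)
}

#' Filter markers on mean read depth
#'
#' Keeps markers whose mean total depth across the population is at least
#' `min_mean_depth` (boundary inclusive); the default of 25 reads is the
#' conventional minimum average population depth for quantitative dosage
#' calling.
#'
#' @param counts a [read_count_table()].
#' @param min_mean_depth minimum mean total depth.
#' @return the filtered [read_count_table()].
#' @export
filter_min_depth <- function(counts, min_mean_depth = 25) {
  keep <- colMeans(counts$ref + counts$alt) >= min_mean_depth
  read_count_table(counts$ref[, keep, drop = FALSE],
                   counts$alt[, keep, drop = FALSE],
                   info = if (!is.null(counts$info))
                     counts$info[keep, , drop = FALSE] else NULL)
}

# reference-allele frequency per marker from observed dosages
ref_allele_freq <- function(dosages) {
  x <- unclass(dosages)
  colSums(x, na.rm = TRUE) / (ploidy_of(dosages) * colSums(!is.na(x)))
}

#' Filter markers on minor allele frequency
#'
#' The reference-allele frequency of a marker is the sum of observed dosages
#' divided by `ploidy * n_observed`; markers with
#' `min(p, 1 - p) < min_maf` are removed (boundary inclusive: a marker exactly
#' at the threshold is kept). All-missing markers are removed with a warning.
#'
#' @param dosages a [dosage_matrix()].
#' @param min_maf minimum minor allele frequency (default 0.01).
#' @return the filtered [dosage_matrix()].
#' @export
filter_maf <- function(dosages, min_maf = 0.01) {
  x <- unclass(dosages)
  n_obs <- colSums(!is.na(x))
  if (any(n_obs == 0)) warnf("%d all-missing marker(s) removed", sum(n_obs == 0))
  p <- ref_allele_freq(dosages)
  maf <- pmin(p, 1 - p)
  keep <- n_obs > 0 & !is.na(maf) & maf >= min_maf
  subset_markers(dosages, keep)
}

#' Filter markers on missing-data rate
#'
#' Removes markers with strictly more than `max_missing` missing calls
#' (a marker with exactly the threshold fraction missing is kept).
#'
#' @param dosages a [dosage_matrix()].
#' @param max_missing maximum tolerated missing fraction (default 0.05).
#' @return the filtered [dosage_matrix()].
#' @export
filter_missing <- function(dosages, max_missing = 0.05) {
  miss <- colMeans(is.na(unclass(dosages)))
  subset_markers(dosages, miss <= max_missing)
}

#' Impute missing dosages by dose-frequency sampling
#'
#' Every missing entry is replaced by a random draw from the marker's
#' empirical distribution of observed dosages; observed entries are untouched.
#'
#' @param dosages a [dosage_matrix()]; every marker must have at least one
#'   observed call.
#' @param seed optional seed for reproducible imputation.
#' @return a complete [dosage_matrix()].
#' @export
impute_dose_frequency <- function(dosages, seed = NULL) {
  set_seed_if(seed)
  x <- unclass(dosages)
  if (any(colSums(!is.na(x)) == 0))
    stopf("all-missing marker(s) present; filter before imputing")
  for (j in which(colSums(is.na(x)) > 0)) {
    obs <- x[!is.na(x[, j]), j]
    miss <- which(is.na(x[, j]))
    x[miss, j] <- sample(obs, length(miss), replace = TRUE)
  }
  dosage_matrix(x, ploidy = ploidy_of(dosages), info = marker_info(dosages))
}

#' Collapse tetraploid dosages to diploid coding
#'
#' Maps the three tetraploid heterozygote classes to a single diploid
#' heterozygote and the homozygotes to diploid homozygotes:
#' `0 -> 0, 1 -> 1, 2 -> 1, 3 -> 1, 4 -> 2`. Missing entries are preserved;
#' the output carries ploidy 2.
#'
#' @param dosages a tetraploid [dosage_matrix()].
#' @return a diploid-coded [dosage_matrix()].
#' @export
diploidize <- function(dosages) {
  if (ploidy_of(dosages) != 4L) stopf("diploidize requires tetraploid input")
  x <- unclass(dosages)
  map <- c(0L, 1L, 1L, 1L, 2L)
  y <- matrix(map[x + 1L], nrow(x), dimnames = dimnames(x))
  dosage_matrix(y, ploidy = 2L, info = marker_info(dosages))
}

#' Keep markers informative under diploidized coding
#'
#' Removes markers whose observed tetraploid dosages are confined to
#' `{0, 1}`: after diploidization such markers still segregate, but they carry
#' no extra information from the tetraploid coding, so the tetraploid/diploid
#' comparison is restricted to the remaining panel. Apply before
#' [diploidize()] to define the common marker panel.
#'
#' @param dosages a tetraploid [dosage_matrix()].
#' @return the filtered [dosage_matrix()].
#' @export
filter_dd_informative <- function(dosages) {
  if (ploidy_of(dosages) != 4L) stopf("requires tetraploid coding")
  x <- unclass(dosages)
  keep <- apply(x, 2, function(col) {
    obs <- col[!is.na(col)]
    length(obs) > 0 && any(obs > 1L)
  })
  subset_markers(dosages, keep)
}

#' Group markers with identical dosage vectors
#'
#' Partitions markers into redundancy groups: two markers are redundant when
#' their dosage vectors are identical, including the positions of missing
#' entries. The first marker (by column order) represents each group.
#'
#' @param dosages a [dosage_matrix()].
#' @return list with `groups` (named list: representative -> member ids),
#'   `n_unique`, `n_total`, `pct_unique` (percentage of markers carrying
#'   non-duplicated information, counting each group once).
#' @export
redundancy_groups <- function(dosages) {
  x <- unclass(dosages)
  key <- apply(x, 2, function(col) paste(ifelse(is.na(col), ".", col),
                                         collapse = ""))
  idx <- split(colnames(x), factor(key, levels = unique(key)))
  groups <- setNames(idx, vapply(idx, `[`, "", 1L))
  n_unique <- length(groups)
  list(groups = groups, n_unique = n_unique, n_total = ncol(x),
       pct_unique = 100 * n_unique / ncol(x))
}

#' Percentage of unique markers from printed counts
#'
#' @param n_unique,n_total marker counts.
#' @return `100 * n_unique / n_total`.
#' @export
pct_unique_markers <- function(n_unique, n_total) 100 * n_unique / n_total
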