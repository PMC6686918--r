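#' Short-range linkage disequilibrium (r-squared) between marker pairs
#'
#' For every pair of markers on the same chromosome whose positions differ by
#' at most `window_bp`, computes `r2`, the squared Pearson correlation of the
#' dosage vectors (pairwise-complete over non-missing individuals). Pairs
#' containing a zero-variance marker are skipped. Summaries pool pairs per
#' reference/chromosome label, report the average `r2` of adjacent marker
#' pairs, and the 90th percentile of the short-range values.
#'
#' @param dosages a [dosage_matrix()] whose marker metadata carries `chrom`
#'   and `pos` (and optionally `ref`).
#' @param window_bp maximum pair distance in base pairs (default 1500).
#' @return list of class `ld_report`: `pairs` (`data.frame`: marker1,
#'   marker2, ref, chrom, distance_bp, r2), `mean_r2`, `adjacent_mean_r2`,
#'   `q90_r2`, `per_ref` (mean per reference label), `n_skipped`.
#' @export
ld_r2 <- function(dosages, window_bp = 1500) {
  info <- marker_info(dosages)
  if (is.null(info) || !all(c("chrom", "pos") %in% names(info)))
    stopf("marker metadata with chrom and pos required")
  x <- unclass(dosages)
  refl <- info$ref %||% rep("all", nrow(info))
  rows <- list(); skipped <- 0L
  for (grp in split(seq_len(nrow(info)),
                    paste(refl, info$chrom, sep = "\r"))) {
    grp <- grp[order(info$pos[grp])]
    if (length(grp) < 2) next
    for (a in seq_len(length(grp) - 1)) {
      for (b in (a + 1):length(grp)) {
        j1 <- grp[a]; j2 <- grp[b]
        dist <- info$pos[j2] - info$pos[j1]
        if (dist > window_bp) break
        v1 <- x[, j1]; v2 <- x[, j2]
        obs <- !is.na(v1) & !is.na(v2)
        if (sum(obs) < 3 || sd(v1[obs]) == 0 || sd(v2[obs]) == 0) {
          skipped <- skipped + 1L
          next
        }
        rows[[length(rows) + 1L]] <- data.frame(
          marker1 = info$marker[j1], marker2 = info$marker[j2],
          ref = refl[j1], chrom = info$chrom[j1],
          distance_bp = dist, adjacent = (b == a + 1),
          r2 = cor(v1[obs], v2[obs])^2, stringsAsFactors = FALSE)
      }
    }
  }
  pairs <- if (length(rows)) do.call(rbind, rows) else
    data.frame(marker1 = character(), marker2 = character(),
               ref = character(), chrom = character(),
               distance_bp = numeric(), adjacent = logical(), r2 = numeric())
  per_ref <- if (nrow(pairs))
    tapply(pairs$r2, pairs$ref, mean) else numeric(0)
  structure(list(
    pairs = pairs,
    mean_r2 = if (nrow(pairs)) mean(pairs$r2) else NA_real_,
    adjacent_mean_r2 = if (any(pairs$adjacent))
      mean(pairs$r2[pairs$adjacent]) else NA_real_,
    q90_r2 = if (nrow(pairs))
      unname(stats::quantile(pairs$r2, 0.9)) else NA_real_,
    per_ref = per_ref, n_skipped = skipped, window_bp = window_bp),
    class = "ld_report")
}

#' @export
print.ld_report <- function(x, ...) {
  cat(sprintf("<ld_report> %d pairs within %d bp: mean r2 = %.4f (adjacent %.4f, q90 %.4f)\n",
              nrow(x$pairs), x$window_bp, x$mean_r2, x$adjacent_mean_r2,
              x$q90_r2))
  invisible(x)
}

#' Principal component analysis of dosage data
#'
#' Column-centers the complete dosage matrix and decomposes it, returning
#' individual scores and the fraction of variance explained per component.
#'
#' @param dosages complete [dosage_matrix()].
#' @param n_components number of components to return.
#' @return list with `scores` (individuals x components) and
#'   `explained` (variance fractions, non-increasing, summing to <= 1).
#' @export
pca_dosage <- function(dosages, n_components = 3L) {
  x <- unclass(dosages)
  if (anyNA(x)) stopf("complete matrix required; impute first")
  if (n_components > min(dim(x))) stopf("n_components exceeds matrix rank bound")
  if (all(apply(x, 2, var) == 0)) stopf("constant matrix has no principal components")
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x[, seq_len(n_components), drop = FALSE],
       explained = expl[seq_len(n_components)])
}
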