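#' Pedigree-based additive relationship matrix for autotetraploids
#'
#' Builds the additive relationship matrix `A = 4 * Theta` from a pedigree
#' under tetrasomic (bivalent) inheritance, where `Theta` is the kinship
#' matrix obtained by the standard recursion: a random gene of an offspring
#' comes from a random gene of its dam or sire with probability 1/2 each, and
#' a gamete carries two of the parent's four genes sampled without
#' replacement. `double_reduction` is the probability that the two genes of a
#' gamete are copies of one parental chromosome. Unknown parents are treated
#' as unrelated, non-inbred founders. A non-inbred founder has diagonal 1;
#' parent-offspring pairs (other parent unrelated) have 0.5.
#'
#' @param pedigree a [pedigree_table()] (topologically ordered).
#' @param double_reduction double-reduction probability in `[0, 1/6]`
#'   (0 = pure bivalent pairing).
#' @return symmetric matrix with class attribute `relationship_matrix`,
#'   provenance `"pedigree"`.
#' @export
build_a_tetraploid <- function(pedigree, double_reduction = 0) {
  if (any(pedigree$ploidy != 4L)) stopf("pedigree must be all tetraploid")
  ids <- pedigree$id
  nI <- length(ids)
  pos <- setNames(seq_len(nI), ids)
  theta <- matrix(0, nI, nI, dimnames = list(ids, ids))
  alpha <- double_reduction
  for (i in seq_len(nI)) {
    di <- pedigree$dam[i]; si <- pedigree$sire[i]
    d <- if (is.na(di)) NA_integer_ else pos[[di]]
    s <- if (is.na(si)) NA_integer_ else pos[[si]]
    # cross terms with all previous individuals
    if (i > 1) {
      prev <- seq_len(i - 1L)
      td <- if (is.na(d)) rep(0, i - 1L) else theta[prev, d]
      ts <- if (is.na(s)) rep(0, i - 1L) else theta[prev, s]
      theta[prev, i] <- theta[i, prev] <- (td + ts) / 2
    }
    # self-kinship: P(same gene) = 1/4; distinct genes are within-gamete
    # (IBD prob phi of each parent) or cross-gamete (theta_ds)
    phi_of <- function(p) {
      if (is.na(p)) return(alpha)          # unknown founder, F = 0
      Fp <- (4 * theta[p, p] - 1) / 3       # parental inbreeding
      alpha + (1 - alpha) * Fp
    }
    tds <- if (is.na(d) || is.na(s)) 0 else theta[d, s]
    founder <- is.na(d) && is.na(s) && alpha == 0
    if (founder) {
      theta[i, i] <- 1 / 4
    } else {
      theta[i, i] <- 1 / 4 + (3 / 4) * ((phi_of(d) + phi_of(s)) / 6 + (2 / 3) * tds)
    }
  }
  A <- 4 * theta
  attr(A, "provenance") <- "pedigree"
  attr(A, "ploidy") <- 4L
  class(A) <- c("relationship_matrix", "matrix", "array")
  A
}

#' Genomic relationship matrix from dosages
#'
#' `K = W W' / (tr(W W') / n)` where `W` is the column-centered dosage
#' matrix. The trace normalization makes `tr(K) = n` exactly, so the same
#' formula serves tetraploid (0..4) and diploid (0..2) codings. Monomorphic
#' markers contribute zero columns. With `center = "vanraden"` the columns
#' are centered at `ploidy * p_j` (allele-frequency expectation) instead of
#' the observed column mean.
#'
#' @param dosages a complete [dosage_matrix()] (impute first).
#' @param center `"mean"` (default) or `"vanraden"`.
#' @return `n x n` matrix of class `relationship_matrix`, provenance
#'   `"genomic"`.
#' @export
build_k <- function(dosages, center = c("mean", "vanraden")) {
  center <- match.arg(center)
  x <- unclass(dosages)
  if (anyNA(x)) stopf("dosage matrix has missing entries; impute first")
  if (ncol(x) < 2 || sum(apply(x, 2, var) > 0) < 2)
    stopf("need at least 2 markers with nonzero variance")
  W <- if (center == "mean") scale(x, center = TRUE, scale = FALSE)
  else sweep(x, 2, ploidy_of(dosages) * ref_allele_freq(dosages))
  WWt <- tcrossprod(W)
  tr <- sum(diag(WWt))
  if (tr <= 0) stopf("all markers monomorphic: trace of WW' is zero")
  K <- WWt / (tr / nrow(x))
  dimnames(K) <- list(rownames(x), rownames(x))
  attr(K, "provenance") <- "genomic"
  attr(K, "ploidy") <- ploidy_of(dosages)
  class(K) <- c("relationship_matrix", "matrix", "array")
  K
}

#' Blend genomic and pedigree relationship matrices
#'
#' `K* = w K + (1 - w) A`; the default `w = 0.99` adds 1% pedigree
#' information, enough to make the blended matrix positive definite (and thus
#' invertible in the mixed-model equations) whenever `A` is.
#'
#' @param K genomic [build_k()] matrix.
#' @param A pedigree [build_a_tetraploid()] matrix over the same individuals
#'   in the same order.
#' @param w genomic weight in `(0, 1]`.
#' @return matrix of class `relationship_matrix`, provenance `"blended"`.
#' @export
blend_kinship <- function(K, A, w = 0.99) {
  if (w <= 0 || w > 1) stopf("w must lie in (0, 1]")
  if (!identical(dim(K), dim(A)) ||
      !identical(rownames(K), rownames(A)))
    stopf("K and A must cover the same individuals in the same order")
  Ks <- w * unclass(K) + (1 - w) * unclass(A)
  attr(Ks, "provenance") <- "blended"
  attr(Ks, "ploidy") <- attr(K, "ploidy")
  class(Ks) <- c("relationship_matrix", "matrix", "array")
  Ks
}

#' @export
print.relationship_matrix <- function(x, ...) {
  cat(sprintf("<relationship_matrix> %d x %d, provenance %s, mean diagonal %.3f\n",
              nrow(x), ncol(x), attr(x, "provenance") %||% "?",
              mean(diag(unclass(x)))))
  invisible(x)
}
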