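# shared fixtures: small trial configurations and independent oracles

small_config <- function(seed = 1, n_markers = 60L, n_harvests = 3L, ...) {
  sim_config(n_dams = 6L, n_sires = 8L, family_size = 12L, n_blocks = 3L,
             plants_per_plot = 4L, n_checks = 2L, n_markers = n_markers,
             n_harvests = n_harvests, seed = seed, ...)
}

# gene-dropping estimate of the additive relationship between two relatives
# under bivalent tetrasomic inheritance: founder genes carry unique labels,
# each gamete is 2 of the parent's 4 genes without replacement, and
# A = 4 * P(random gene of x IBD to random gene of y).
gene_drop_A <- function(relationship = c("parent_offspring", "full_sibs",
                                         "self_noninbred"),
                        n_rep = 1e5) {
  relationship <- match.arg(relationship)
  dam <- matrix(1:4, n_rep, 4, byrow = TRUE)
  sire <- matrix(5:8, n_rep, 4, byrow = TRUE)
  gamete <- function(parent) {
    t(vapply(seq_len(nrow(parent)),
             function(i) parent[i, sample.int(4, 2)], integer(2)))
  }
  off1 <- cbind(gamete(dam), gamete(sire))
  ibd_frac <- function(a, b) {
    # mean over the 16 (gene of a, gene of b) pairs of IBD indicator
    m <- vapply(1:4, function(i)
      rowSums(b == a[, i]), numeric(nrow(a)))
    rowSums(m) / 16
  }
  theta <- switch(relationship,
    parent_offspring = ibd_frac(off1, dam),
    full_sibs = ibd_frac(off1, cbind(gamete(dam), gamete(sire))),
    self_noninbred = {
      # two independent with-replacement gene draws from the same founder
      i <- sample.int(4, n_rep, replace = TRUE)
      j <- sample.int(4, n_rep, replace = TRUE)
      (i == j) * 1
    })
  4 * mean(theta)
}
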