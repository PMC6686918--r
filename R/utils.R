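# internal helpers shared across modules

# set the RNG deterministically when a seed is supplied; seeds derived from a
# base seed use small fixed offsets so every pipeline stage has its own stream
set_seed_if <- function(seed, offset = 0L) {
  if (!is.null(seed) && !is.na(seed)) {
    set.seed((as.integer(seed) + as.integer(offset)) %% .Machine$integer.max)
  }
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 1 && x == round(x)
}

# scaled inverse chi-square draw: df * S / chisq_df
rinvchisq <- function(n, df, scale) df * scale / stats::rchisq(n, df)
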