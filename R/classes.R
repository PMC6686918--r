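#' Construct a dosage matrix
#'
#' An integer matrix of allele dosages (copies of the reference allele),
#' individuals in rows and markers in columns, with entries in
#' `0..ploidy` or `NA` for missing calls. Marker metadata (chromosome,
#' position, reference panel name) may be attached for LD and reporting.
#'
#' @param x numeric matrix (individuals x markers); rownames are individual
#'   ids, colnames marker ids.
#' @param ploidy even integer, the ploidy the dosages are coded on (4 for
#'   autotetraploids, 2 after diploidization).
#' @param info optional `data.frame` with one row per marker and columns
#'   `marker`, `chrom`, `pos` (1-based) and optionally `ref`.
#' @return an object of class `dosage_matrix`.
#' @export
dosage_matrix <- function(x, ploidy = 4L, info = NULL) {
  x <- as.matrix(x)
  if (!is_count(ploidy) || ploidy %% 2 != 0)
    stopf("ploidy must be a positive even integer, got %s", format(ploidy))
  bad <- !is.na(x) & (x < 0 | x > ploidy | x != round(x))
  if (any(bad)) stopf("dosages must be integers in 0..%d or NA", ploidy)
  storage.mode(x) <- "integer"
  if (is.null(rownames(x)) && nrow(x) > 0)
    rownames(x) <- paste0("ind", seq_len(nrow(x)))
  if (is.null(colnames(x)) && ncol(x) > 0)
    colnames(x) <- paste0("m", seq_len(ncol(x)))
  if (!is.null(info)) {
    if (nrow(info) != ncol(x)) stopf("marker info rows must match marker count")
    info$marker <- as.character(info$marker %||% colnames(x))
  }
  structure(x, ploidy = as.integer(ploidy), info = info,
            class = c("dosage_matrix", "matrix", "array"))
}

#' @export
print.dosage_matrix <- function(x, ...) {
  cat(sprintf("<dosage_matrix> %d individuals x %d markers, ploidy %d, %.1f%% missing\n",
              nrow(x), ncol(x), attr(x, "ploidy"), 100 * mean(is.na(x))))
  invisible(x)
}

ploidy_of <- function(x) attr(x, "ploidy") %||% 4L

marker_info <- function(x) attr(x, "info")

# rebuild a dosage_matrix after subsetting columns, keeping metadata aligned
subset_markers <- function(x, keep) {
  info <- marker_info(x)
  dosage_matrix(unclass(x)[, keep, drop = FALSE], ploidy = ploidy_of(x),
                info = if (!is.null(info)) info[keep, , drop = FALSE] else NULL)
}

#' Construct a read-count table
#'
#' Per individual x marker reference and alternative allele read depths, as
#' carried by the VCF `AD` field for biallelic SNPs.
#'
#' @param ref,alt integer matrices (individuals x markers) of reference and
#'   alternative read counts; identical dimnames.
#' @param info optional per-marker metadata `data.frame` (`marker`, `chrom`,
#'   `pos`, `ref`).
#' @return object of class `read_count_table` with elements `ref`, `alt`,
#'   `info`.
#' @export
read_count_table <- function(ref, alt, info = NULL) {
  ref <- as.matrix(ref); alt <- as.matrix(alt)
  if (!identical(dim(ref), dim(alt))) stopf("ref and alt must have equal dimensions")
  if (any(ref < 0, na.rm = TRUE) || any(alt < 0, na.rm = TRUE))
    stopf("read counts must be non-negative")
  ref[is.na(ref)] <- 0L; alt[is.na(alt)] <- 0L
  storage.mode(ref) <- "integer"; storage.mode(alt) <- "integer"
  if (is.null(rownames(ref))) rownames(ref) <- paste0("ind", seq_len(nrow(ref)))
  if (is.null(colnames(ref))) colnames(ref) <- paste0("m", seq_len(ncol(ref)))
  dimnames(alt) <- dimnames(ref)
  if (!is.null(info) && nrow(info) != ncol(ref))
    stopf("marker info rows must match marker count")
  if (anyDuplicated(colnames(ref))) stopf("marker ids must be unique")
  structure(list(ref = ref, alt = alt, info = info), class = "read_count_table")
}

#' @export
print.read_count_table <- function(x, ...) {
  cat(sprintf("<read_count_table> %d individuals x %d markers, mean depth %.1f\n",
              nrow(x$ref), ncol(x$ref), mean(x$ref + x$alt)))
  invisible(x)
}

#' Construct a pedigree table
#'
#' @param id character vector of individual ids, topologically ordered
#'   (parents before offspring).
#' @param dam,sire parent ids or `NA` for unknown.
#' @param ploidy integer ploidy per individual (default 4).
#' @return `data.frame` of class `pedigree` with columns id, dam, sire, ploidy.
#' @export
pedigree_table <- function(id, dam = NA, sire = NA, ploidy = 4L) {
  id <- as.character(id)
  if (anyDuplicated(id)) stopf("pedigree ids must be unique")
  dam <- as.character(dam); sire <- as.character(sire)
  ped <- data.frame(id = id, dam = rep_len(dam, length(id)),
                    sire = rep_len(sire, length(id)),
                    ploidy = rep_len(as.integer(ploidy), length(id)),
                    stringsAsFactors = FALSE)
  pos <- seq_along(id); names(pos) <- id
  for (col in c("dam", "sire")) {
    p <- ped[[col]]
    known <- !is.na(p)
    if (any(known & !(p %in% id)))
      stopf("unknown %s id(s): %s", col,
            paste(unique(p[known & !(p %in% id)]), collapse = ", "))
    if (any(known & pos[p] >= pos[id]))
      stopf("pedigree not topologically ordered: a %s appears after its offspring", col)
  }
  class(ped) <- c("pedigree", "data.frame")
  ped
}
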