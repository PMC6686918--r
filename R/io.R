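# File interchange: CSV for dosages / phenotypes / pedigrees / matrices,
# VCF (AD field) for read counts via vcfR.

#' Write and read a dosage matrix as CSV
#'
#' Rows are individuals, columns marker ids; the first column holds the
#' individual id. Ploidy is stored in a header comment.
#'
#' @param dosages a [dosage_matrix()].
#' @param path file path.
#' @export
write_dosage_csv <- function(dosages, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# ploidy=%d", ploidy_of(dosages)), con)
  df <- data.frame(id = rownames(dosages), unclass(dosages),
                   check.names = FALSE)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dosage_csv
#' @param info optional marker metadata to attach on read.
#' @export
read_dosage_csv <- function(path, info = NULL) {
  first <- readLines(path, n = 1L)
  ploidy <- if (grepl("^# ploidy=", first))
    as.integer(sub("^# ploidy=", "", first)) else 4L
  df <- read.csv(path, comment.char = "#", check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  dosage_matrix(m, ploidy = ploidy, info = info)
}

#' Write and read a phenotype table as CSV
#'
#' Columns: plant, parent, block, harvest, is_check, value.
#'
#' @param phenotypes phenotype `data.frame`.
#' @param path file path.
#' @export
write_phenotype_csv <- function(phenotypes, path) {
  write.csv(phenotypes, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotype_csv
#' @export
read_phenotype_csv <- function(path) {
  df <- read.csv(path)
  df$is_check <- as.logical(df$is_check)
  df
}

#' Write and read a pedigree as CSV
#'
#' Columns: id, dam, sire, ploidy; unknown parents are empty/NA.
#'
#' @param pedigree a [pedigree_table()].
#' @param path file path.
#' @export
write_pedigree_csv <- function(pedigree, path) {
  write.csv(as.data.frame(pedigree), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pedigree_csv
#' @export
read_pedigree_csv <- function(path) {
  df <- read.csv(path, colClasses = c(id = "character", dam = "character",
                                      sire = "character"))
  df$dam[df$dam == ""] <- NA_character_
  df$sire[df$sire == ""] <- NA_character_
  pedigree_table(df$id, df$dam, df$sire, df$ploidy)
}

#' Read biallelic read counts from a VCF with AD
#'
#' Accepts a VCF whose samples carry the `AD` (allele depth) FORMAT field.
#' Only biallelic records are kept; triallelic and other multi-allelic sites
#' are dropped with a message. Positions are 1-based as in the VCF.
#'
#' @param path VCF path (plain or gzipped).
#' @return a [read_count_table()] (individuals x markers).
#' @export
read_vcf_ad <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stopf("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  bi <- vcfR::is.biallelic(v)
  if (!all(bi)) {
    message(sprintf("dropping %d non-biallelic record(s)", sum(!bi)))
    v <- v[bi, ]
  }
  ad <- vcfR::extract.gt(v, element = "AD")
  ref <- vcfR::masplit(ad, record = 1, sort = 0, decreasing = 0)
  alt <- vcfR::masplit(ad, record = 2, sort = 0, decreasing = 0)
  ref[is.na(ref)] <- 0; alt[is.na(alt)] <- 0
  ids <- v@fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(v@fix[, "CHROM"], "_",
                                         v@fix[, "POS"])[is.na(ids) | ids == "."]
  info <- data.frame(marker = ids, chrom = v@fix[, "CHROM"],
                     pos = as.integer(v@fix[, "POS"]),
                     stringsAsFactors = FALSE)
  rc <- read_count_table(t(ref), t(alt), info = info)
  colnames(rc$ref) <- colnames(rc$alt) <- ids
  rc
}

#' Write read counts as a biallelic VCF with AD
#'
#' Emits a minimal VCF (GT omitted, `AD` populated with ref,alt depths) via
#' vcfR; the output is gzip-compressed (`.vcf.gz`).
#'
#' @param counts a [read_count_table()].
#' @param path output path (should end in `.vcf.gz`).
#' @export
write_vcf_ad <- function(counts, path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stopf("writing VCF requires the vcfR package")
  info <- counts$info
  p <- ncol(counts$ref)
  if (is.null(info))
    info <- data.frame(marker = colnames(counts$ref), chrom = "chr1",
                       pos = seq_len(p))
  fix <- cbind(CHROM = as.character(info$chrom), POS = as.character(info$pos),
               ID = info$marker, REF = "A", ALT = "C", QUAL = ".",
               FILTER = "PASS", INFO = ".")
  ad <- matrix(paste0(t(counts$ref), ",", t(counts$alt)), nrow = p)
  colnames(ad) <- rownames(counts$ref)
  gt <- cbind(FORMAT = "AD", ad)
  v <- new("vcfR",
           meta = c("##fileformat=VCFv4.2",
                    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">"),
           fix = fix, gt = gt)
  vcfR::write.vcf(v, file = path)
  invisible(path)
}
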