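# PLINK 1 binary (.bed/.bim/.fam) reader and writer.
#
# The .bed payload is SNP-major: a 3-byte header (0x6c 0x1b 0x01) followed by
# ceiling(n/4) bytes per marker, two bits per sample starting at the low bits
# of each byte. Two-bit codes: 00 = A1/A1, 01 = missing, 10 = het,
# 11 = A2/A2. Dosages count the A1 allele (the .bim fifth column), which this
# package treats as the alternate allele.

BED_MAGIC <- as.raw(c(0x6c, 0x1b, 0x01))
# code -> A1 dosage lookup for the four 2-bit values 00,01,10,11
BED_DECODE <- c(2, NA, 1, 0)

#' Read genotypes from PLINK .bed/.bim/.fam files
#'
#' @param prefix path prefix; `<prefix>.bed`, `.bim` and `.fam` must exist.
#' @return A [genotype_matrix()] with all markers labelled class `"SNP"`.
#' @export
read_plink <- function(prefix) {
  bed <- paste0(prefix, ".bed"); bim <- paste0(prefix, ".bim")
  fam <- paste0(prefix, ".fam")
  for (f in c(bed, bim, fam)) {
    if (!file.exists(f)) stop_svgp("missing PLINK file: ", f)
  }
  fam_df <- utils::read.table(fam, stringsAsFactors = FALSE)
  bim_df <- utils::read.table(bim, stringsAsFactors = FALSE)
  n <- nrow(fam_df); m <- nrow(bim_df)
  raw <- readBin(bed, "raw", n = 3 + ceiling(n / 4) * m)
  if (!identical(raw[1:3], BED_MAGIC)) {
    stop_svgp("not a SNP-major PLINK .bed file: ", bed)
  }
  payload <- raw[-(1:3)]
  bpm <- ceiling(n / 4)
  X <- matrix(NA_real_, n, m)
  for (j in seq_len(m)) {
    bytes <- as.integer(payload[((j - 1) * bpm + 1):(j * bpm)])
    codes <- c(rbind(bytes %% 4, (bytes %/% 4) %% 4,
                     (bytes %/% 16) %% 4, bytes %/% 64))
    X[, j] <- BED_DECODE[codes[seq_len(n)] + 1L]
  }
  markers <- data.frame(id = as.character(bim_df[[2]]),
                        chrom = as.character(bim_df[[1]]),
                        pos = as.integer(bim_df[[4]]),
                        class = "SNP", stringsAsFactors = FALSE)
  genotype_matrix(X, markers, as.character(fam_df[[2]]))
}

#' Write the SNP markers of a genotype matrix as PLINK .bed/.bim/.fam
#'
#' Non-SNP columns are ignored (use [write_sv_tsv()] for those). Missing
#' dosages are stored as the PLINK missing code; fractional dosages (e.g.
#' after mean imputation) cannot be represented and raise an error.
#'
#' @param G a [genotype_matrix()].
#' @param prefix output path prefix.
#' @return Invisibly, the prefix.
#' @export
write_plink <- function(G, prefix) {
  stopifnot(inherits(G, "genotype_matrix"))
  keep <- which(G$markers$class == "SNP")
  if (!length(keep)) stop_svgp("no SNP markers to write")
  X <- G$dosages[, keep, drop = FALSE]
  if (any(!is.na(X) & X != round(X))) {
    stop_svgp("fractional SNP dosages cannot be written to .bed")
  }
  n <- nrow(X)
  # dosage -> 2-bit code (A1 count 2,1,0 -> 00,10,11; NA -> 01)
  enc <- function(d) ifelse(is.na(d), 1L, c(3L, 2L, 0L)[d + 1L])
  bpm <- ceiling(n / 4)
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(BED_MAGIC, con)
  for (j in seq_len(ncol(X))) {
    codes <- c(enc(X[, j]), rep(0L, 4 * bpm - n))
    cm <- matrix(codes, nrow = 4)
    bytes <- cm[1, ] + cm[2, ] * 4L + cm[3, ] * 16L + cm[4, ] * 64L
    writeBin(as.raw(bytes), con)
  }
  md <- G$markers[keep, ]
  utils::write.table(
    data.frame(md$chrom, md$id, 0L, md$pos, "A", "G"),
    paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  utils::write.table(
    data.frame(G$accession_ids, G$accession_ids, 0L, 0L, 0L, -9L),
    paste0(prefix, ".fam"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}
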