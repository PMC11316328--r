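#' Read SNP genotypes from a VCF file
#'
#' Parses the GT field with `vcfR` and converts to alternate-allele dosages:
#' `0/0` is 0, `0/1` or `1/0` is 1, `1/1` is 2, `./.` is missing. Phased
#' separators are accepted. Only biallelic records are supported.
#'
#' @param path VCF file (plain or bgzipped).
#' @return A [genotype_matrix()] with all markers labelled class `"SNP"`.
#' @export
read_vcf_genotypes <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (any(grepl(",", fix[, "ALT"]))) {
    stop_svgp("multi-allelic VCF records are not supported")
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  to_dose <- function(g) {
    g <- sub("\\|", "/", g)
    out <- rep(NA_real_, length(g))
    out[g %in% "0/0"] <- 0
    out[g %in% c("0/1", "1/0")] <- 1
    out[g %in% "1/1"] <- 2
    out
  }
  X <- apply(gt, 2, to_dose)
  if (is.null(dim(X))) X <- matrix(X, nrow = 1, dimnames = list(NULL, colnames(gt)))
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(fix[, "CHROM"], ":", fix[, "POS"])[is.na(ids) | ids == "."]
  markers <- data.frame(id = ids, chrom = fix[, "CHROM"],
                        pos = as.integer(fix[, "POS"]), class = "SNP",
                        stringsAsFactors = FALSE)
  genotype_matrix(t(X), markers, colnames(gt))
}
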