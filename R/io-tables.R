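# TSV readers/writers for SV matrices, phenotypes, kernels and PC scores.

#' Read an SV presence/absence matrix from TSV
#'
#' Expected header: `marker_id`, `chrom`, `pos`, `class`, then one column
#' per accession. Dosages are 0/1 with `NA` for missing.
#'
#' @param path TSV file.
#' @return A [genotype_matrix()] of SV markers.
#' @export
read_sv_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("marker_id", "chrom", "pos", "class")
  if (!all(need %in% names(df))) {
    stop_svgp("SV TSV must start with columns: ", paste(need, collapse = ", "))
  }
  acc <- setdiff(names(df), need)
  if (!length(acc)) stop_svgp("SV TSV has no accession columns")
  X <- t(as.matrix(df[, acc, drop = FALSE]))
  markers <- data.frame(id = df$marker_id, chrom = as.character(df$chrom),
                        pos = df$pos, class = df$class, stringsAsFactors = FALSE)
  genotype_matrix(X, markers, acc)
}

#' Write the SV markers of a genotype matrix as TSV
#'
#' @param G a [genotype_matrix()].
#' @param path output file.
#' @param classes SV classes to include (default: all SV classes present).
#' @return Invisibly, the path.
#' @export
write_sv_tsv <- function(G, path, classes = SV_CLASSES) {
  keep <- which(G$markers$class %in% classes)
  if (!length(keep)) stop_svgp("no SV markers to write")
  md <- G$markers[keep, ]
  out <- cbind(data.frame(marker_id = md$id, chrom = md$chrom, pos = md$pos,
                          class = md$class, stringsAsFactors = FALSE),
               as.data.frame(t(G$dosages[, keep, drop = FALSE])))
  names(out)[-(1:4)] <- G$accession_ids
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a combined SNP + SV genotype panel
#'
#' Reads SNPs from PLINK (`.bed/.bim/.fam` prefix) or VCF and SVs from TSV,
#' checks that both files describe the same accessions, and concatenates
#' them into one matrix with class metadata.
#'
#' @param snp_path PLINK prefix or a `.vcf` file.
#' @param sv_path SV TSV (optional; `NULL` for SNPs only).
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(snp_path, sv_path = NULL) {
  snp <- if (grepl("\\.vcf(\\.gz)?$", snp_path)) {
    read_vcf_genotypes(snp_path)
  } else {
    read_plink(snp_path)
  }
  if (is.null(sv_path)) return(snp)
  sv <- read_sv_tsv(sv_path)
  only_snp <- setdiff(snp$accession_ids, sv$accession_ids)
  only_sv <- setdiff(sv$accession_ids, snp$accession_ids)
  if (length(only_snp) || length(only_sv)) {
    stop_svgp("accession sets differ between SNP and SV files; ",
              "only in SNP: [", paste(only_snp, collapse = ", "), "] ",
              "only in SV: [", paste(only_sv, collapse = ", "), "]")
  }
  sv_ord <- match(snp$accession_ids, sv$accession_ids)
  genotype_matrix(cbind(snp$dosages, sv$dosages[sv_ord, , drop = FALSE]),
                  rbind(snp$markers, sv$markers),
                  snp$accession_ids)
}

#' Write a phenotype table as TSV
#'
#' Trait kinds are preserved in a `# kinds:` comment line so that
#' [read_phenotypes()] round-trips losslessly.
#'
#' @param P a [phenotype_table()].
#' @param path output file.
#' @return Invisibly, the path.
#' @export
write_phenotypes <- function(P, path) {
  stopifnot(inherits(P, "phenotype_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# kinds: ", paste(names(P$kinds), P$kinds, sep = "=",
                                       collapse = ";")), con)
  out <- cbind(data.frame(accession_id = P$accession_ids, group = P$group,
                          stringsAsFactors = FALSE), P$traits)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a phenotype table from TSV
#'
#' @param path file written by [write_phenotypes()] (or any TSV with
#'   `accession_id`, `group` and trait columns plus a `# kinds:` line).
#' @return A [phenotype_table()].
#' @export
read_phenotypes <- function(path) {
  first <- readLines(path, n = 1L)
  if (!startsWith(first, "# kinds:")) {
    stop_svgp("phenotype TSV must start with a '# kinds:' line")
  }
  kv <- strsplit(trimws(sub("# kinds:", "", first)), ";")[[1]]
  kinds <- stats::setNames(sub(".*=", "", kv), sub("=.*", "", kv))
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE, check.names = FALSE)
  traits <- df[, setdiff(names(df), c("accession_id", "group")), drop = FALSE]
  phenotype_table(df$accession_id, df$group, traits, kinds)
}

#' Write a kernel matrix (with accession labels) as TSV
#' @param K a [kernel_matrix()].
#' @param path output file.
#' @return Invisibly, the path.
#' @export
write_kernel_tsv <- function(K, path) {
  stopifnot(inherits(K, "kernel_matrix"))
  out <- as.data.frame(K$values)
  utils::write.table(cbind(accession_id = rownames(K$values), out), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a kernel matrix written by [write_kernel_tsv()]
#' @param path TSV file.
#' @param kind kernel kind tag to attach.
#' @return A [kernel_matrix()].
#' @export
read_kernel_tsv <- function(path, kind = "additive") {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  ids <- df$accession_id
  V <- as.matrix(df[, -1, drop = FALSE])
  dimnames(V) <- list(ids, ids)
  kernel_matrix(V, kind = kind)
}
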