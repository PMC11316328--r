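#' Genotype matrix with per-marker class metadata
#'
#' The universal carrier between pipeline stages: an accessions x markers
#' dosage matrix plus a per-column metadata table. SNPs are diploid dosages
#' in \{0, 1, 2\} (count of the alternate allele); structural variants
#' (MITE-DTX, RLX-RIX, DEL, DUP, INV) are presence/absence in \{0, 1\}.
#' Missing genotypes are `NA`.
#'
#' @param dosages numeric matrix, accessions in rows, markers in columns.
#' @param markers data.frame with columns `id`, `chrom`, `pos` (1-based),
#'   `class` (one of `r paste(MARKER_CLASSES, collapse = ", ")`).
#' @param accession_ids character vector of unique accession ids; defaults
#'   to the rownames of `dosages`.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages, markers, accession_ids = rownames(dosages)) {
  dosages <- as.matrix(dosages)
  if (is.null(accession_ids)) {
    accession_ids <- paste0("acc", seq_len(nrow(dosages)))
  }
  accession_ids <- as.character(accession_ids)
  markers <- as.data.frame(markers, stringsAsFactors = FALSE)
  need <- c("id", "chrom", "pos", "class")
  if (!all(need %in% names(markers))) {
    stop_svgp("marker metadata must have columns: ", paste(need, collapse = ", "))
  }
  if (nrow(markers) != ncol(dosages)) {
    stop_svgp("marker metadata rows (", nrow(markers),
              ") must equal dosage columns (", ncol(dosages), ")")
  }
  if (anyDuplicated(accession_ids)) stop_svgp("duplicate accession ids")
  if (anyDuplicated(markers$id)) stop_svgp("duplicate marker ids")
  bad <- setdiff(unique(markers$class), MARKER_CLASSES)
  if (length(bad)) {
    stop_svgp("malformed marker class label(s): ", paste(bad, collapse = ", "))
  }
  if (length(accession_ids) != nrow(dosages)) {
    stop_svgp("accession_ids length must equal number of dosage rows")
  }
  check_dosage_ranges(dosages, markers$class)
  rownames(dosages) <- accession_ids
  colnames(dosages) <- markers$id
  markers$pos <- as.integer(markers$pos)
  markers$chrom <- as.character(markers$chrom)
  structure(
    list(dosages = dosages, markers = markers, accession_ids = accession_ids),
    class = "genotype_matrix"
  )
}

check_dosage_ranges <- function(dosages, classes) {
  is_sv <- classes %in% SV_CLASSES
  if (any(is_sv)) {
    sv <- dosages[, is_sv, drop = FALSE]
    if (any(!is.na(sv) & !(sv %in% c(0, 1)))) {
      stop_svgp("SV dosages must be 0/1 (or NA)")
    }
  }
  if (any(!is_sv)) {
    snp <- dosages[, !is_sv, drop = FALSE]
    if (any(!is.na(snp) & (snp < 0 | snp > 2))) {
      stop_svgp("SNP dosages must lie in [0, 2] (or NA)")
    }
  }
  invisible(TRUE)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  tab <- table(factor(x$markers$class, levels = MARKER_CLASSES))
  cat("genotype_matrix:", nrow(x$dosages), "accessions x",
      ncol(x$dosages), "markers\n")
  cat("  classes:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  cat("  missing:", sum(is.na(x$dosages)), "entries\n")
  invisible(x)
}

#' Subset a genotype matrix by accessions and/or markers
#'
#' @param G a `genotype_matrix`.
#' @param accessions accession ids or row indices (optional).
#' @param markers marker ids or column indices (optional).
#' @return A `genotype_matrix` restricted to the requested rows/columns.
#' @export
subset_genotypes <- function(G, accessions = NULL, markers = NULL) {
  stopifnot(inherits(G, "genotype_matrix"))
  ri <- seq_along(G$accession_ids)
  ci <- seq_len(ncol(G$dosages))
  if (!is.null(accessions)) {
    ri <- if (is.character(accessions)) match(accessions, G$accession_ids) else accessions
    if (anyNA(ri)) stop_svgp("unknown accession id(s)")
  }
  if (!is.null(markers)) {
    ci <- if (is.character(markers)) match(markers, G$markers$id) else markers
    if (anyNA(ci)) stop_svgp("unknown marker id(s)")
  }
  genotype_matrix(G$dosages[ri, ci, drop = FALSE],
                  G$markers[ci, , drop = FALSE],
                  G$accession_ids[ri])
}

#' Phenotype table
#'
#' Per-accession trait values with population-group labels. Binary traits are
#' stored on the \{1, 2\} class scale; quantitative traits are numeric.
#'
#' @param accession_ids character vector of unique ids.
#' @param group population-group label per accession.
#' @param traits data.frame of trait columns (one per trait).
#' @param kinds named character vector mapping trait name to
#'   `"quantitative"` or `"binary"`.
#' @return An object of class `phenotype_table`.
#' @export
phenotype_table <- function(accession_ids, group, traits, kinds) {
  accession_ids <- as.character(accession_ids)
  if (anyDuplicated(accession_ids)) stop_svgp("duplicate accession ids")
  traits <- as.data.frame(traits, stringsAsFactors = FALSE)
  if (nrow(traits) != length(accession_ids)) {
    stop_svgp("trait rows must match accession count")
  }
  if (!all(names(traits) %in% names(kinds))) {
    stop_svgp("every trait column needs an entry in `kinds`")
  }
  kinds <- kinds[names(traits)]
  if (!all(kinds %in% c("quantitative", "binary"))) {
    stop_svgp("trait kind must be quantitative or binary")
  }
  for (tr in names(traits)[kinds == "binary"]) {
    lev <- sort(unique(stats::na.omit(traits[[tr]])))
    if (length(lev) > 2L) {
      stop_svgp("binary trait '", tr, "' has more than two observed levels")
    }
  }
  structure(
    list(accession_ids = accession_ids, group = as.character(group),
         traits = traits, kinds = kinds),
    class = "phenotype_table"
  )
}

#' @export
print.phenotype_table <- function(x, ...) {
  cat("phenotype_table:", length(x$accession_ids), "accessions,",
      ncol(x$traits), "trait(s)\n")
  for (tr in names(x$traits)) {
    cat(sprintf("  %s (%s), %d missing\n", tr, x$kinds[[tr]],
                sum(is.na(x$traits[[tr]]))))
  }
  cat("  groups:", paste(names(table(x$group)), table(x$group),
                         sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Map a binary trait from the \{1,2\} class scale to \{0,1\}
#'
#' Class 2 is coded 1 (the "success" level for sigmoid heads and
#' cross-entropy); class 1 is coded 0. The mapping is recorded in loss
#' reports so downstream consumers can invert it.
#'
#' @param values vector on the \{1,2\} scale.
#' @return Numeric vector on \{0,1\}.
#' @export
binary_to_01 <- function(values) {
  lev <- sort(unique(stats::na.omit(values)))
  if (!all(lev %in% c(1, 2))) stop_svgp("binary trait must be coded {1,2}")
  as.numeric(values) - 1
}
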