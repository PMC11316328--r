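#' Folded minor-allele / presence frequency of one marker column
#'
#' SNPs: allele frequency from allele counts (mean dosage / 2), folded.
#' SVs: presence frequency, folded as min(f, 1 - f).
#'
#' @param x dosage vector (may contain `NA`).
#' @param class marker class.
#' @return Folded frequency in [0, 0.5].
#' @export
marker_maf <- function(x, class) {
  f <- if (class == "SNP") mean(x, na.rm = TRUE) / 2 else mean(x, na.rm = TRUE)
  if (is.nan(f)) return(NA_real_)
  min(f, 1 - f)
}

#' Filter markers on minor allele frequency and missing rate
#'
#' Removes markers with folded frequency at or below `maf_min` (strict:
#' MAF equal to the threshold is removed) or missing rate strictly above
#' `max_missing`. The removal log records one reason per removed marker
#' (missingness is checked first).
#'
#' @param G a [genotype_matrix()].
#' @param maf_min MAF threshold (default 0.01).
#' @param max_missing missing-rate threshold (default 0.01).
#' @return A list: `genotypes` (filtered [genotype_matrix()]) and `log`
#'   (data.frame `id`, `class`, `reason`, `value` for removed markers).
#' @export
filter_markers <- function(G, maf_min = 0.01, max_missing = 0.01) {
  stopifnot(inherits(G, "genotype_matrix"))
  m <- ncol(G$dosages)
  miss_rate <- colMeans(is.na(G$dosages))
  maf <- vapply(seq_len(m), function(j) {
    marker_maf(G$dosages[, j], G$markers$class[j])
  }, numeric(1))
  reason <- rep(NA_character_, m)
  reason[!is.na(maf) & maf <= maf_min] <- "MAF"
  reason[miss_rate > max_missing] <- "missing_rate"
  reason[is.na(maf)] <- "missing_rate"  # fully missing column
  drop <- which(!is.na(reason))
  if (length(drop) == m) stop_svgp("all markers removed: empty panel")
  log <- data.frame(id = G$markers$id[drop], class = G$markers$class[drop],
                    reason = reason[drop],
                    value = ifelse(reason[drop] == "MAF", maf[drop],
                                   miss_rate[drop]),
                    stringsAsFactors = FALSE)
  keep <- setdiff(seq_len(m), drop)
  list(genotypes = subset_genotypes(G, markers = keep), log = log)
}

#' Impute missing dosages by per-marker means
#'
#' A deliberately simple, leakage-safe stand-in for haplotype-based
#' imputation: SNP columns get their (real-valued) training mean, SV columns
#' the mean rounded half-up to \{0, 1\}. When `train_rows` is given, means
#' are computed on those rows only and applied everywhere (the cross-
#' validation discipline).
#'
#' @param G a [genotype_matrix()].
#' @param train_rows indices used to compute the means (default: all rows).
#' @return A [genotype_matrix()] with no missing entries.
#' @export
impute_missing <- function(G, train_rows = seq_along(G$accession_ids)) {
  stopifnot(inherits(G, "genotype_matrix"))
  X <- G$dosages
  for (j in which(colSums(is.na(X)) > 0)) {
    m <- mean(X[train_rows, j], na.rm = TRUE)
    if (is.nan(m)) {
      stop_svgp("marker ", G$markers$id[j],
                " is fully missing (should have been filtered)")
    }
    fill <- if (G$markers$class[j] == "SNP") m else floor(m + 0.5)
    X[is.na(X[, j]), j] <- fill
  }
  genotype_matrix(X, G$markers, G$accession_ids)
}

#' Transform phenotype columns (ordinal binning, log transform)
#'
#' Two rule kinds mirror common pre-analysis steps for plant trait panels:
#' `bin_ordinal` maps an ordinal score to two classes (value == 1 becomes
#' class 1, everything else class 2, balancing rare upper classes) and
#' `log` natural-log-transforms a positive quantitative trait (e.g. time to
#' flowering). Original columns are preserved; transformed columns get a
#' `_class` / `_log` suffix.
#'
#' @param P a [phenotype_table()].
#' @param rules list with optional character vectors `bin_ordinal` and
#'   `log`, plus optional `log_base` (default `exp(1)`).
#' @return A [phenotype_table()] with the added columns.
#' @export
transform_phenotypes <- function(P, rules = list()) {
  stopifnot(inherits(P, "phenotype_table"))
  traits <- P$traits
  kinds <- P$kinds
  base <- rules$log_base %||% exp(1)
  for (tr in rules$bin_ordinal %||% character()) {
    if (!tr %in% names(traits)) stop_svgp("unknown trait: ", tr)
    v <- traits[[tr]]
    nb <- paste0(tr, "_class")
    traits[[nb]] <- ifelse(is.na(v), NA, ifelse(v == 1, 1, 2))
    kinds[nb] <- "binary"
  }
  for (tr in rules$log %||% character()) {
    if (!tr %in% names(traits)) stop_svgp("unknown trait: ", tr)
    v <- traits[[tr]]
    bad <- which(!is.na(v) & v <= 0)
    if (length(bad)) {
      stop_svgp("nonpositive value under log rule for trait '", tr,
                "' at accession(s): ",
                paste(P$accession_ids[bad], collapse = ", "))
    }
    nb <- paste0(tr, "_log")
    traits[[nb]] <- log(v, base = base)
    kinds[nb] <- "quantitative"
  }
  phenotype_table(P$accession_ids, P$group, traits, kinds)
}
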