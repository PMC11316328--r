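#' Single-marker GWAS scan (fold-internal marker ranking)
#'
#' Per marker, fits the simple linear regression y = a + b x on the
#' supplied (training) rows and records the slope, t statistic and
#' two-sided p-value. Binary traits on the \{1,2\} class scale are mapped
#' to \{0,1\} and regressed with the same linear model (the conventional
#' linear-GWAS treatment of binary scores for ranking purposes, not
#' inference). Markers monomorphic in the fold get p = 1 and are flagged.
#'
#' @param G a [genotype_matrix()] restricted to training accessions (no
#'   missing dosages).
#' @param y trait values for those accessions.
#' @param kind `"quantitative"` or `"binary"` (binary is recoded 1/2 ->
#'   0/1 when needed).
#' @return An `association_scan`: data.frame with `id`, `class`, `slope`,
#'   `t`, `p`, `monomorphic`.
#' @export
gwas_scan <- function(G, y, kind = "quantitative") {
  stopifnot(inherits(G, "genotype_matrix"))
  X <- G$dosages
  if (anyNA(X)) stop_svgp("impute missing dosages before the GWAS scan")
  n <- nrow(X)
  if (n < 3L) stop_svgp("need at least 3 training accessions (residual df)")
  if (length(y) != n) stop_svgp("length(y) must match accessions")
  if (kind == "binary" && all(stats::na.omit(y) %in% c(1, 2))) {
    y <- binary_to_01(y)
  }
  y <- as.numeric(y)
  xm <- colMeans(X)
  Sxx <- colSums(X^2) - n * xm^2
  mono <- Sxx <= 0
  Sxy <- drop(crossprod(X, y)) - n * xm * mean(y)
  Syy <- sum((y - mean(y))^2)
  slope <- ifelse(mono, NA_real_, Sxy / Sxx)
  df <- n - 2L
  rss <- Syy - slope * Sxy
  rss <- pmax(rss, 0)
  se <- sqrt(rss / df / Sxx)
  t <- ifelse(se > 0, slope / se, ifelse(abs(slope) > 0, Inf, 0))
  p <- ifelse(mono, 1, 2 * stats::pt(-abs(t), df))
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  structure(
    data.frame(id = G$markers$id, class = G$markers$class,
               slope = slope, t = t, p = p, monomorphic = mono,
               stringsAsFactors = FALSE),
    class = c("association_scan", "data.frame")
  )
}

#' Select the k most associated markers from a scan
#'
#' Pooled ascending p-value ranking across the requested classes (all six
#' classes for the combined-variants strategy, SNPs only for the SNPs
#' strategy). Ties are broken by decreasing |t| then marker id, so the
#' selection is deterministic under column permutation. Markers flagged
#' monomorphic in the fold are excluded. Returns `min(k, available)` ids;
#' a warning is raised when k exceeds the available count.
#'
#' @param scan an `association_scan` from [gwas_scan()].
#' @param k how many markers to keep (study default 10,000).
#' @param classes marker classes eligible for selection (default: all).
#' @return Character vector of selected marker ids, best first.
#' @export
select_top_k <- function(scan, k = 10000, classes = MARKER_CLASSES) {
  stopifnot(inherits(scan, "association_scan"))
  if (!nrow(scan)) stop_svgp("empty association scan")
  cand <- scan[scan$class %in% classes & !scan$monomorphic, , drop = FALSE]
  if (!nrow(cand)) stop_svgp("no polymorphic markers in requested classes")
  ord <- order(cand$p, -abs(cand$t), cand$id)
  if (k > nrow(cand)) {
    warning("requested k = ", k, " but only ", nrow(cand),
            " markers available; returning all", call. = FALSE)
  }
  cand$id[ord][seq_len(min(k, nrow(cand)))]
}

#' Squared Pearson correlation between two dosage vectors (LD r2)
#'
#' The dosage-based linkage-disequilibrium measure used to decide whether
#' a SNP tags a structural variant. Undefined (returned as `NA` with a
#' warning) when either vector has zero variance.
#'
#' @param x,y equal-length dosage vectors (length >= 3).
#' @return r-squared in [0, 1], or `NA` if undefined.
#' @export
ld_r2 <- function(x, y) {
  if (length(x) != length(y)) stop_svgp("vectors must have equal length")
  if (length(x) < 3L) stop_svgp("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance: r2 undefined", call. = FALSE)
    return(NA_real_)
  }
  stats::cor(x, y)^2
}

#' Find SNPs linked to structural variants
#'
#' Computes dosage r-squared between every (SNP, SV) column pair —
#' optionally restricted to pairs on the same chromosome within `window`
#' base pairs — and returns the unique pairs reaching `threshold`
#' (study rule: r2 >= 0.8) together with the distinct tagging-SNP ids.
#'
#' @param G a [genotype_matrix()] restricted to training accessions, no
#'   missing dosages.
#' @param threshold minimum r-squared (default 0.8).
#' @param window optional basepair window restricting candidate pairs.
#' @return A list of class `linked_set`: `pairs` (data.frame `snp_id`,
#'   `sv_id`, `sv_class`, `chrom`, `pos`, `r2`), `snp_ids` (unique),
#'   `threshold`.
#' @export
linked_snps <- function(G, threshold = 0.8, window = NULL) {
  stopifnot(inherits(G, "genotype_matrix"))
  if (anyNA(G$dosages)) stop_svgp("impute missing dosages before LD scanning")
  snp_i <- which(G$markers$class == "SNP")
  sv_i <- which(G$markers$class %in% SV_CLASSES)
  empty <- data.frame(snp_id = character(), sv_id = character(),
                      sv_class = character(), chrom = character(),
                      pos = integer(), r2 = numeric(), stringsAsFactors = FALSE)
  if (!length(sv_i)) {
    warning("no structural variants present; empty linked set", call. = FALSE)
    return(structure(list(pairs = empty, snp_ids = character(),
                          threshold = threshold), class = "linked_set"))
  }
  if (!length(snp_i)) stop_svgp("no SNPs present")
  sds <- apply(G$dosages, 2, stats::sd)
  snp_i <- snp_i[sds[snp_i] > 0]
  sv_i <- sv_i[sds[sv_i] > 0]
  R2 <- stats::cor(G$dosages[, snp_i, drop = FALSE],
                   G$dosages[, sv_i, drop = FALSE])^2
  hits <- which(R2 >= threshold, arr.ind = TRUE)
  pairs <- empty
  if (nrow(hits)) {
    si <- snp_i[hits[, 1]]; vi <- sv_i[hits[, 2]]
    keep <- rep(TRUE, length(si))
    if (!is.null(window)) {
      keep <- G$markers$chrom[si] == G$markers$chrom[vi] &
        abs(G$markers$pos[si] - G$markers$pos[vi]) <= window
    }
    pairs <- data.frame(snp_id = G$markers$id[si][keep],
                        sv_id = G$markers$id[vi][keep],
                        sv_class = G$markers$class[vi][keep],
                        chrom = G$markers$chrom[si][keep],
                        pos = G$markers$pos[si][keep],
                        r2 = R2[hits][keep], stringsAsFactors = FALSE)
    pairs <- pairs[order(pairs$snp_id, pairs$sv_id), , drop = FALSE]
    rownames(pairs) <- NULL
  }
  structure(list(pairs = pairs, snp_ids = sort(unique(pairs$snp_id)),
                 threshold = threshold),
            class = "linked_set")
}

#' @export
print.linked_set <- function(x, ...) {
  cat("linked_set:", nrow(x$pairs), "SNP-SV pairs at r2 >=", x$threshold,
      "(", length(x$snp_ids), "distinct SNPs )\n")
  invisible(x)
}
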