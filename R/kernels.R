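#' Relationship kernel with provenance metadata
#'
#' @param values n x n symmetric matrix (accession ids as dimnames).
#' @param kind one of `"additive"`, `"dominance"`, `"epistatic"`.
#' @param source_classes marker classes the kernel was built from.
#' @param n_markers number of markers used.
#' @return An object of class `kernel_matrix`.
#' @export
kernel_matrix <- function(values, kind = c("additive", "dominance", "epistatic"),
                          source_classes = character(), n_markers = NA_integer_) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop_svgp("kernel must be square")
  if (max(abs(values - t(values))) > 1e-10 * max(1, max(abs(values)))) {
    stop_svgp("kernel must be symmetric")
  }
  values <- (values + t(values)) / 2
  structure(
    list(values = values, kind = kind, source_classes = source_classes,
         n_markers = n_markers),
    class = "kernel_matrix"
  )
}

#' @export
print.kernel_matrix <- function(x, ...) {
  cat(sprintf("kernel_matrix (%s): %d x %d, %s markers from [%s]\n",
              x$kind, nrow(x$values), ncol(x$values),
              ifelse(is.na(x$n_markers), "?", x$n_markers),
              paste(x$source_classes, collapse = ", ")))
  invisible(x)
}

#' Additive (VanRaden) genomic relationship matrix
#'
#' K = ZZ' / (2 * sum_j p_j (1 - p_j)) with Z = M - 2p, where M holds
#' diploid dosages and p the allele frequencies. SV presence/absence
#' columns enter the same formula as dosages on \{0, 1\} centered by 2p,
#' keeping a single denominator for all classes. Frequencies are estimated
#' on `train_rows` only and reused for the remaining rows, so test
#' accessions never influence the centering (no leakage).
#'
#' @param G a [genotype_matrix()] with no missing dosages.
#' @param classes marker classes to include (default `"SNP"`).
#' @param train_rows rows used to estimate allele frequencies.
#' @return A [kernel_matrix()] of kind `"additive"`.
#' @export
additive_grm <- function(G, classes = "SNP",
                         train_rows = seq_along(G$accession_ids)) {
  stopifnot(inherits(G, "genotype_matrix"))
  cols <- which(G$markers$class %in% classes)
  if (!length(cols)) stop_svgp("no markers of class ", paste(classes, collapse = ","))
  M <- G$dosages[, cols, drop = FALSE]
  if (anyNA(M)) stop_svgp("missing dosages: impute before building kernels")
  is_sv <- G$markers$class[cols] %in% SV_CLASSES
  # allele frequency: dosage mean / 2 for SNPs; presence frequency / 2-scaled
  # consistently so the 2p centering applies to both codings
  p <- colMeans(M[train_rows, , drop = FALSE]) / 2
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0) stop_svgp("zero VanRaden denominator: all markers monomorphic")
  if (!any(p > 0 & p < 1)) stop_svgp("no polymorphic markers")
  Z <- sweep(M, 2, 2 * p)
  K <- tcrossprod(Z) / denom
  dimnames(K) <- list(G$accession_ids, G$accession_ids)
  kernel_matrix(K, "additive", source_classes = unique(G$markers$class[cols]),
                n_markers = length(cols))
}

#' Dominance genomic relationship matrix (Vitezica coding)
#'
#' Per SNP with allele frequency p (q = 1 - p), the dominance covariate is
#' -2p^2 for genotype 0, 2pq for genotype 1 and -2q^2 for genotype 2;
#' D = HH' / sum_j (2 p_j q_j)^2. Only defined for diploid SNP dosages —
#' presence/absence SV classes are rejected.
#'
#' @param G a [genotype_matrix()] with no missing dosages.
#' @param train_rows rows used to estimate allele frequencies.
#' @param markers optional marker ids to restrict to (must be SNPs).
#' @return A [kernel_matrix()] of kind `"dominance"`.
#' @export
dominance_grm <- function(G, train_rows = seq_along(G$accession_ids),
                          markers = NULL) {
  stopifnot(inherits(G, "genotype_matrix"))
  cols <- if (is.null(markers)) seq_len(ncol(G$dosages)) else match(markers, G$markers$id)
  if (anyNA(cols)) stop_svgp("unknown marker id(s)")
  if (any(G$markers$class[cols] != "SNP")) {
    stop_svgp("dominance GRM is undefined for SV presence/absence markers")
  }
  M <- G$dosages[, cols, drop = FALSE]
  if (anyNA(M)) stop_svgp("missing dosages: impute before building kernels")
  p <- colMeans(M[train_rows, , drop = FALSE]) / 2
  q <- 1 - p
  denom <- sum((2 * p * q)^2)
  if (denom <= 0) stop_svgp("zero dominance denominator: all markers monomorphic")
  H <- matrix(0, nrow(M), ncol(M))
  # genotype may be fractional after mean imputation; round to nearest class
  Mr <- round(M)
  for (j in seq_len(ncol(M))) {
    H[, j] <- c(-2 * p[j]^2, 2 * p[j] * q[j], -2 * q[j]^2)[Mr[, j] + 1L]
  }
  D <- tcrossprod(H) / denom
  dimnames(D) <- list(G$accession_ids, G$accession_ids)
  kernel_matrix(D, "dominance", source_classes = "SNP", n_markers = ncol(M))
}

#' Additive-by-additive epistatic kernel (Hadamard square)
#'
#' E = A o A, the element-wise product of the additive kernel with itself
#' (PSD by the Schur product theorem). Left unnormalized by default; set
#' `normalize = TRUE` to divide by the mean diagonal.
#'
#' @param A a [kernel_matrix()] of kind `"additive"`.
#' @param normalize divide by the mean diagonal (default `FALSE`).
#' @return A [kernel_matrix()] of kind `"epistatic"`.
#' @export
epistatic_grm <- function(A, normalize = FALSE) {
  stopifnot(inherits(A, "kernel_matrix"))
  if (A$kind != "additive") stop_svgp("epistatic kernel requires an additive input")
  E <- A$values * A$values
  if (normalize) E <- E / mean(diag(E))
  kernel_matrix(E, "epistatic", source_classes = A$source_classes,
                n_markers = A$n_markers)
}

#' Principal-component features of a relationship kernel
#'
#' Eigendecomposes K and returns scores (eigenvectors scaled by the square
#' root of their eigenvalue, negatives clamped to 0) ordered by decreasing
#' eigenvalue. With all components kept, scores %*% t(scores) reconstructs
#' K up to the clamped noise. The default number of components is the
#' smallest set explaining at least `var_explained` of the trace.
#'
#' @param K a [kernel_matrix()].
#' @param n_components how many components to keep; `NULL` (default) picks
#'   by `var_explained`.
#' @param var_explained trace fraction threshold used when `n_components`
#'   is `NULL` (default 0.95).
#' @return A list of class `pc_features`: `scores` (n x c),
#'   `explained_variance` (eigenvalues), `source_kind`.
#' @export
grm_pcs <- function(K, n_components = NULL, var_explained = 0.95) {
  stopifnot(inherits(K, "kernel_matrix"))
  if (!is.null(n_components) && n_components <= 0) {
    stop_svgp("n_components must be positive")
  }
  eig <- eigen(K$values, symmetric = TRUE)
  ev <- pmax(eig$values, 0)
  rank <- sum(ev > 1e-10 * max(ev, 1e-300))
  if (is.null(n_components)) {
    cum <- cumsum(ev) / max(sum(ev), .Machine$double.eps)
    n_components <- max(1L, which(cum >= var_explained)[1])
    if (is.na(n_components)) n_components <- rank
  }
  c_keep <- min(n_components, max(rank, 1L))
  scores <- eig$vectors[, seq_len(c_keep), drop = FALSE] %*%
    diag(sqrt(ev[seq_len(c_keep)]), c_keep)
  rownames(scores) <- rownames(K$values)
  colnames(scores) <- paste0("PC", seq_len(c_keep))
  structure(list(scores = scores, explained_variance = ev[seq_len(c_keep)],
                 source_kind = K$kind),
            class = "pc_features")
}
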