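#' Plan a k-fold cross-validation
#'
#' Random partition into k folds of size floor(n/k) or ceiling(n/k); each
#' fold serves once as the test set, the remainder as training.
#' Deterministic given `seed`.
#'
#' @param n number of accessions.
#' @param k number of folds (study default 10).
#' @param seed integer seed.
#' @return List of `fold_plan` objects, each with `fold`, `train`,
#'   `validation` (empty; filled by [inner_split()] for network fits),
#'   `test`, `scheme`, `seed`.
#' @export
kfold_plan <- function(n, k = 10L, seed = 1L) {
  if (k <= 1L) stop_svgp("k must be > 1")
  if (n < k) stop_svgp("n must be >= k")
  with_seed(seed, {
    fold_of <- sample(rep(seq_len(k), length.out = n))
    lapply(seq_len(k), function(f) {
      structure(list(fold = f, train = which(fold_of != f),
                     validation = integer(0), test = which(fold_of == f),
                     scheme = "kfold", seed = seed),
                class = "fold_plan")
    })
  })
}

#' Plan an across-population holdout
#'
#' Test set: every accession whose group label is in `holdout`; training
#' set: all remaining accessions. Mirrors the independent-prediction design
#' where distant groups (aromatic and admixed accessions) are predicted
#' from the large training groups.
#'
#' @param groups group label per accession.
#' @param holdout labels forming the test set (default ARO and ADM).
#' @return A single `fold_plan` with `scheme = "across_population"`.
#' @export
across_population_plan <- function(groups, holdout = c("ARO", "ADM")) {
  present <- intersect(holdout, unique(groups))
  if (!length(present)) stop_svgp("no accession carries a holdout label")
  test <- which(groups %in% holdout)
  train <- which(!groups %in% holdout)
  if (!length(train)) stop_svgp("holdout covers every group: empty training set")
  structure(list(fold = 1L, train = train, validation = integer(0),
                 test = test, scheme = "across_population", seed = NA_integer_),
            class = "fold_plan")
}

#' Split a training set into inner train/validation subsets
#'
#' Used only for network fits: the validation share (floor(fraction * n))
#' steers hyperparameter selection and early stopping, while Bayesian
#' models train on the full set.
#'
#' @param train integer indices of the training set (length >= 5).
#' @param fraction validation share in (0, 1), default 0.2.
#' @param seed integer seed.
#' @return List with `train` and `validation` index vectors partitioning
#'   the input.
#' @export
inner_split <- function(train, fraction = 0.2, seed = 1L) {
  if (fraction <= 0 || fraction >= 1) stop_svgp("fraction must lie in (0, 1)")
  if (length(train) < 5L) stop_svgp("training set too small to split")
  with_seed(seed, {
    n_val <- floor(fraction * length(train))
    val <- sort(sample(train, n_val))
    list(train = setdiff(train, val), validation = val)
  })
}

#' Mean squared error
#' @param observed,predicted equal-length numeric vectors (no missing).
#' @return (1/N) sum (y - yhat)^2.
#' @export
mse <- function(observed, predicted) {
  if (length(observed) != length(predicted)) stop_svgp("length mismatch")
  if (!length(observed)) stop_svgp("empty vectors")
  if (anyNA(observed) || anyNA(predicted)) stop_svgp("missing values in loss")
  mean((observed - predicted)^2)
}

#' Binary cross-entropy
#'
#' -(1/N) sum [ y log p + (1 - y) log(1 - p) ] with natural logs;
#' probabilities are clipped to [1e-12, 1 - 1e-12] to avoid log(0).
#'
#' @param labels 0/1 vector.
#' @param probabilities predicted probabilities of the coded-1 class.
#' @return Scalar loss.
#' @export
binary_cross_entropy <- function(labels, probabilities) {
  if (length(labels) != length(probabilities)) stop_svgp("length mismatch")
  if (!length(labels)) stop_svgp("empty vectors")
  if (!all(labels %in% c(0, 1))) stop_svgp("labels must be 0/1")
  p <- pmin(pmax(probabilities, 1e-12), 1 - 1e-12)
  -mean(labels * log(p) + (1 - labels) * log(1 - p))
}
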