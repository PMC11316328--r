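# Internal helpers shared across modules.

MARKER_CLASSES <- c("SNP", "MITE-DTX", "RLX-RIX", "DEL", "DUP", "INV")
SV_CLASSES <- setdiff(MARKER_CLASSES, "SNP")

#' Derive a reproducible child seed from a master seed and a label
#'
#' One master seed fans out to the simulator, fold planner, samplers and
#' network initialisers through this function, so that a whole experiment is
#' reproducible from a single integer while its stages stay decoupled.
#'
#' @param master integer master seed.
#' @param label character tag naming the consumer (e.g. "folds", "rkhs").
#' @return An integer seed in [0, 2^31 - 1).
#' @export
derive_seed <- function(master, label) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(label))
  h <- sum(utf8ToInt(paste0(label, ":", master)) * seq_along(utf8ToInt(paste0(label, ":", master))))
  as.integer((abs(master) * 7919 + h * 104729) %% 2147483647)
}

# Run `expr` under a given seed, restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# scaled-inverse-chi-square draw: (df0*S0 + SS) / chisq(df0 + n)
rscaled_inv_chisq <- function(df, ssq) {
  ssq / stats::rchisq(1L, df = df)
}

# Truncated standard-location normal draw via inverse CDF; `lower`/`upper`
# are scalar bounds, mean/sd vectorised.
rtruncnorm <- function(n, mean, sd, lower, upper) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  u <- stats::runif(n, plo, phi)
  # guard against numerical collapse deep in a tail
  u <- pmin(pmax(u, 1e-12), 1 - 1e-12)
  stats::qnorm(u, mean, sd)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_svgp <- function(...) stop(..., call. = FALSE)
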