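#' MCMC run settings
#'
#' The study-scale defaults are 100,000 iterations with burn-in 500 and
#' thinning 5. [test_mcmc_settings()] provides a shorter chain (5,000
#' iterations) for unit tests and smoke runs; both are plain configuration
#' objects and interchangeable.
#'
#' @param n_iter total Gibbs sweeps.
#' @param burn_in sweeps discarded before recording.
#' @param thin keep every `thin`-th sweep after burn-in.
#' @param seed integer seed.
#' @return An object of class `mcmc_settings`.
#' @export
mcmc_settings <- function(n_iter = 100000L, burn_in = 500L, thin = 5L, seed = 1L) {
  if (burn_in >= n_iter) stop_svgp("burn_in must be smaller than n_iter")
  if (thin < 1L) stop_svgp("thin must be >= 1")
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), seed = as.integer(seed)),
            class = "mcmc_settings")
}

#' @rdname mcmc_settings
#' @export
test_mcmc_settings <- function(n_iter = 5000L, burn_in = 500L, thin = 5L,
                               seed = 1L) {
  mcmc_settings(n_iter, burn_in, thin, seed)
}

# Shared hyperprior helper: scaled-inv-chi2 scale whose mode equals `mode`.
sic_scale_for_mode <- function(mode, df) mode * (df + 2) / df

#' Multi-kernel RKHS regression by Gibbs sampling
#'
#' Fits y = mu + sum_k g_k + e with g_k ~ N(0, K_k sigma2_k) and
#' e ~ N(0, I sigma2_e), the Bayesian kernel ("RKHS") regression used to
#' partition genetic variance across marker classes and to predict masked
#' phenotypes. Each kernel is eigendecomposed once; kernel effects are
#' sampled in the eigenbasis (near-zero eigenvalues dropped), variance
#' components get scaled-inverse-chi-square conjugate updates (df 5; scale
#' set so the prior modes split 50% of the phenotypic variance equally
#' across terms, with 50% for the residual — the default heuristic of the
#' reference Bayesian regression software). Masked phenotypes are imputed
#' each sweep (Gaussian data augmentation); the binary response uses
#' probit latent-liability augmentation with threshold 0 and residual
#' variance fixed at 1.
#'
#' @param y numeric response of length n. Masked entries are `NA` (or give
#'   `mask`). For `response = "ordinal"` observed values must be 0/1.
#' @param kernels list of [kernel_matrix()] objects (or plain symmetric
#'   matrices), all over the same accessions in the same order; optionally
#'   named (names label the variance components).
#' @param settings an [mcmc_settings()].
#' @param response `"gaussian"` or `"ordinal"` (binary probit).
#' @param mask integer indices of accessions to hold out (merged with the
#'   `NA` entries of `y`).
#' @param fixed_variances optional named list freezing variance components
#'   for oracle checks: elements `kernel` (vector, one per kernel) and/or
#'   `residual`. Frozen components skip their Gibbs update.
#' @param df0 prior degrees of freedom for every variance term.
#' @param prior_r2 fraction of phenotypic variance the genetic prior modes
#'   sum to (default 0.5).
#' @param fit_intercept sample the general mean (default `TRUE`; set
#'   `FALSE` for pre-centered responses, e.g. closed-form cross-checks).
#' @return A `posterior_summary` with variance-component means and samples,
#'   posterior-mean genetic values, predictions for masked accessions (for
#'   ordinal: probabilities of the coded-1 class) and run metadata.
#' @export
fit_rkhs <- function(y, kernels, settings = mcmc_settings(),
                     response = c("gaussian", "ordinal"),
                     mask = integer(0), fixed_variances = NULL,
                     df0 = 5, prior_r2 = 0.5, fit_intercept = TRUE) {
  response <- match.arg(response)
  stopifnot(inherits(settings, "mcmc_settings"))
  if (inherits(kernels, "kernel_matrix")) kernels <- list(kernels)
  Ks <- lapply(kernels, function(k) if (inherits(k, "kernel_matrix")) k$values else as.matrix(k))
  nk <- length(Ks)
  if (nk < 1L) stop_svgp("need at least one kernel")
  n <- length(y)
  for (K in Ks) {
    if (!all(dim(K) == n)) stop_svgp("kernel dimensions must match length(y)")
  }
  knames <- names(kernels) %||% paste0("K", seq_len(nk))
  knames[knames == ""] <- paste0("K", which(knames == ""))

  mask <- sort(union(as.integer(mask), which(is.na(y))))
  obs <- setdiff(seq_len(n), mask)
  if (!length(obs)) stop_svgp("all phenotypes are masked")
  if (response == "ordinal" && !all(y[obs] %in% c(0, 1))) {
    stop_svgp("ordinal response requires observed y in {0, 1}")
  }

  eigs <- lapply(Ks, function(K) {
    e <- eigen((K + t(K)) / 2, symmetric = TRUE)
    if (min(e$values) < -1e-8 * max(abs(e$values))) {
      stop_svgp("kernel is not PSD within tolerance")
    }
    keep <- which(e$values > 1e-10 * max(e$values))
    list(U = e$vectors[, keep, drop = FALSE], lambda = e$values[keep])
  })

  vy <- stats::var(y[obs])
  if (!is.finite(vy) || vy == 0) vy <- 1
  mode_g <- prior_r2 * vy / nk
  S_g <- sic_scale_for_mode(mode_g, df0)
  S_e <- sic_scale_for_mode((1 - prior_r2) * vy, df0)

  fix_k <- fixed_variances$kernel
  fix_e <- fixed_variances$residual
  ordinal <- response == "ordinal"

  with_seed(settings$seed, {
    sig2 <- if (!is.null(fix_k)) rep_len(fix_k, nk) else rep(mode_g, nk)
    sige2 <- if (ordinal) 1 else if (!is.null(fix_e)) fix_e else (1 - prior_r2) * vy
    ystar <- y
    if (ordinal) {
      ystar <- ifelse(is.na(y) | seq_len(n) %in% mask, 0,
                      ifelse(y == 1, 0.5, -0.5))
    } else {
      ystar[mask] <- mean(y[obs])
    }
    mu <- if (fit_intercept) mean(ystar) else 0
    gk <- matrix(0, n, nk)
    g_tot <- rowSums(gk)

    keep_iters <- seq(settings$burn_in + 1L, settings$n_iter)
    keep_iters <- keep_iters[(seq_along(keep_iters) - 1L) %% settings$thin == 0]
    n_keep <- length(keep_iters)
    keep_flag <- logical(settings$n_iter)
    keep_flag[keep_iters] <- TRUE
    var_samp <- matrix(NA_real_, n_keep, nk + 1L,
                       dimnames = list(NULL, c(knames, "residual")))
    # realized genetic variance per kernel: sample variance of g_k each sweep
    gvar_samp <- matrix(NA_real_, n_keep, nk, dimnames = list(NULL, knames))
    mu_samp <- numeric(n_keep)
    g_sum <- numeric(n)
    eta_sum <- numeric(n)
    s <- 0L
    if (ordinal) {
      lo <- ifelse(!is.na(y) & y == 1, 0, -Inf)
      hi <- ifelse(!is.na(y) & y == 0, 0, Inf)
      lo[mask] <- -Inf; hi[mask] <- Inf
    }

    for (it in seq_len(settings$n_iter)) {
      eta <- mu + g_tot
      if (ordinal) {
        # latent liabilities: truncated at 0 by the observed class
        ystar <- rtruncnorm(n, eta, 1, lo, hi)
      } else if (length(mask)) {
        ystar[mask] <- eta[mask] + stats::rnorm(length(mask), 0, sqrt(sige2))
      }

      for (k in seq_len(nk)) {
        r <- ystar - mu - (g_tot - gk[, k])
        U <- eigs[[k]]$U; lam <- eigs[[k]]$lambda
        u <- drop(crossprod(U, r))
        v <- 1 / (1 / (lam * sig2[k]) + 1 / sige2)
        m <- u / sige2 * v
        alpha <- stats::rnorm(length(lam), m, sqrt(v))
        gnew <- drop(U %*% alpha)
        g_tot <- g_tot - gk[, k] + gnew
        gk[, k] <- gnew
        if (is.null(fix_k)) {
          ss <- sum(alpha^2 / lam)
          sig2[k] <- rscaled_inv_chisq(df0 + length(lam), ss + df0 * S_g)
        }
      }

      if (fit_intercept) {
        mu <- stats::rnorm(1, mean(ystar - g_tot), sqrt(sige2 / n))
      }
      if (!ordinal && is.null(fix_e)) {
        resid <- ystar - mu - g_tot
        sige2 <- rscaled_inv_chisq(df0 + n, sum(resid^2) + df0 * S_e)
      }

      if (keep_flag[it]) {
        s <- s + 1L
        var_samp[s, ] <- c(sig2, sige2)
        gvar_samp[s, ] <- apply(gk, 2, stats::var)
        mu_samp[s] <- mu
        g_sum <- g_sum + g_tot
        eta_sum <- eta_sum + mu + g_tot
      }
    }

    g_mean <- g_sum / n_keep
    eta_mean <- eta_sum / n_keep
    preds <- if (ordinal) stats::pnorm(eta_mean[mask]) else eta_mean[mask]
    names(preds) <- as.character(mask)
    structure(list(
      model = "rkhs", response = response,
      var_components = colMeans(var_samp),
      var_samples = var_samp,
      genetic_variances = colMeans(gvar_samp),
      genetic_variance_samples = gvar_samp,
      mu_mean = mean(mu_samp),
      g_mean = g_mean,
      eta_mean = eta_mean,
      predictions = preds,
      mask = mask,
      n_samples = n_keep,
      settings = settings,
      kernel_names = knames
    ), class = "posterior_summary")
  })
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat(sprintf("posterior_summary (%s, %s response): %d samples\n",
              x$model, x$response, x$n_samples))
  cat("  variance components:\n")
  vc <- x$var_components
  for (nm in names(vc)) cat(sprintf("    %-12s %.4f\n", nm, vc[[nm]]))
  cat("  masked accessions:", length(x$mask), "\n")
  invisible(x)
}

#' Predictions for masked accessions
#'
#' Quantitative response: posterior-mean predicted phenotype. Binary
#' (ordinal) response: probability of the coded-1 class via the normal CDF
#' of the posterior-mean latent liability. Requesting an accession that was
#' not masked during fitting is an error (it would be an in-sample value).
#'
#' @param object a `posterior_summary` from [fit_rkhs()] or [fit_bayesc()].
#' @param rows indices to predict (default: every masked accession).
#' @param ... unused.
#' @return Named numeric vector of predictions.
#' @export
predict.posterior_summary <- function(object, rows = object$mask, ...) {
  rows <- as.integer(rows)
  if (!length(rows)) return(stats::setNames(numeric(0), character(0)))
  bad <- setdiff(rows, object$mask)
  if (length(bad)) {
    stop_svgp("accession(s) not masked during fitting (in-sample): ",
              paste(bad, collapse = ", "))
  }
  object$predictions[as.character(rows)]
}
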