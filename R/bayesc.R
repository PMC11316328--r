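#' Standardize a design matrix on training rows
#'
#' Columns are centered and scaled to unit variance using statistics from
#' `train_rows` only; the same transform is applied to all rows. Constant
#' training columns cannot be standardized and raise an error.
#'
#' @param X numeric matrix (accessions x markers).
#' @param train_rows rows supplying the mean/sd.
#' @return Matrix of the same shape, with `center`/`scale` attributes.
#' @export
standardize_design <- function(X, train_rows = seq_len(nrow(X))) {
  X <- as.matrix(X)
  mu <- colMeans(X[train_rows, , drop = FALSE])
  sd <- apply(X[train_rows, , drop = FALSE], 2, stats::sd)
  if (any(sd == 0)) {
    stop_svgp("constant column(s) in design matrix: ",
              paste(utils::head(which(sd == 0), 5), collapse = ", "))
  }
  Z <- sweep(sweep(X, 2, mu), 2, sd, "/")
  attr(Z, "center") <- mu
  attr(Z, "scale") <- sd
  Z
}

#' BayesC spike-and-slab marker regression by Gibbs sampling
#'
#' Fits y = mu + X beta + e where each marker effect is zero with
#' probability 1 - pi and N(0, sigma2_b) with probability pi, with
#' pi ~ Beta parameterized by prior counts `p0` and prior mean `pi0`
#' (study defaults p0 = 5, pi0 = 0.01). The common effect variance and the
#' residual variance get scaled-inverse-chi-square updates (df 5; scales
#' chosen so the prior modes split the phenotypic variance 50/50 between
#' the genetic and residual terms). Masked rows are excluded from the
#' likelihood; their predictions are X E[beta] + E[mu]. The binary response
#' uses probit latent-liability augmentation (threshold 0, residual
#' variance 1).
#'
#' @param y response of length n (`NA` or `mask` marks holdouts; observed
#'   values must be 0/1 for `response = "ordinal"`).
#' @param X design matrix; standardized internally on the training rows.
#' @param settings an [mcmc_settings()].
#' @param response `"gaussian"` or `"ordinal"`.
#' @param mask indices of held-out accessions.
#' @param p0 prior counts of the Beta prior on pi.
#' @param pi0 prior mean inclusion probability.
#' @param fixed_pi freeze pi (e.g. 1 for the ridge oracle check).
#' @param fixed_variances optional list with elements `effect` and/or
#'   `residual` freezing sigma2_b / sigma2_e.
#' @param df0 prior degrees of freedom for the variance terms.
#' @param prior_r2 prior fraction of variance assigned to markers.
#' @return A `posterior_summary` with effect means, per-marker inclusion
#'   probabilities, pi samples and masked-row predictions.
#' @export
fit_bayesc <- function(y, X, settings = mcmc_settings(),
                       response = c("gaussian", "ordinal"),
                       mask = integer(0), p0 = 5, pi0 = 0.01,
                       fixed_pi = NULL, fixed_variances = NULL,
                       df0 = 5, prior_r2 = 0.5) {
  response <- match.arg(response)
  stopifnot(inherits(settings, "mcmc_settings"))
  X <- as.matrix(X)
  n <- length(y)
  if (nrow(X) != n) stop_svgp("nrow(X) must equal length(y)")
  if (pi0 <= 0 || pi0 >= 1) stop_svgp("pi0 must lie in (0, 1)")
  mask <- sort(union(as.integer(mask), which(is.na(y))))
  train <- setdiff(seq_len(n), mask)
  if (length(train) < 2L) stop_svgp("need at least two training phenotypes")
  ordinal <- response == "ordinal"
  if (ordinal && !all(y[train] %in% c(0, 1))) {
    stop_svgp("ordinal response requires observed y in {0, 1}")
  }

  Z <- standardize_design(X, train)
  Zt <- Z[train, , drop = FALSE]
  p <- ncol(Zt)
  x2 <- colSums(Zt^2)
  nt <- length(train)

  vy <- stats::var(y[train]); if (!is.finite(vy) || vy == 0) vy <- 1
  S_b <- sic_scale_for_mode(prior_r2 * vy / (p * pi0), df0)
  S_e <- sic_scale_for_mode((1 - prior_r2) * vy, df0)
  fix_b <- fixed_variances$effect
  fix_e <- fixed_variances$residual

  with_seed(settings$seed, {
    s2b <- fix_b %||% (prior_r2 * vy / (p * pi0))
    s2e <- if (ordinal) 1 else (fix_e %||% ((1 - prior_r2) * vy))
    pi_cur <- fixed_pi %||% pi0
    beta <- numeric(p)
    delta <- integer(p)
    ystar <- if (ordinal) ifelse(y[train] == 1, 0.5, -0.5) else y[train]
    mu <- mean(ystar)
    r <- ystar - mu

    keep_iters <- seq(settings$burn_in + 1L, settings$n_iter)
    keep_iters <- keep_iters[(seq_along(keep_iters) - 1L) %% settings$thin == 0]
    keep_flag <- logical(settings$n_iter)
    keep_flag[keep_iters] <- TRUE
    n_keep <- length(keep_iters)

    beta_sum <- numeric(p)
    incl_sum <- numeric(p)
    mu_sum <- 0
    pi_samp <- numeric(n_keep)
    var_samp <- matrix(NA_real_, n_keep, 2L,
                       dimnames = list(NULL, c("effect", "residual")))
    s <- 0L
    if (ordinal) {
      lo <- ifelse(y[train] == 1, 0, -Inf)
      hi <- ifelse(y[train] == 0, 0, Inf)
    }

    for (it in seq_len(settings$n_iter)) {
      if (ordinal) {
        eta <- ystar - r            # current linear predictor mu + Z beta
        liab <- rtruncnorm(nt, eta, 1, lo, hi)
        r <- r + (liab - ystar)
        ystar <- liab
      }
      sw <- bayesc_sweep(Zt, r, beta, delta, x2, s2b, s2e, pi_cur)
      r <- sw$r; beta <- sw$beta; delta <- sw$delta

      mu_new <- stats::rnorm(1, mu + mean(r), sqrt(s2e / nt))
      r <- r - (mu_new - mu)
      mu <- mu_new

      nin <- sum(delta)
      if (is.null(fix_b)) {
        s2b <- rscaled_inv_chisq(df0 + nin, sum(beta^2) + df0 * S_b)
      }
      if (!ordinal && is.null(fix_e)) {
        s2e <- rscaled_inv_chisq(df0 + nt, sum(r^2) + df0 * S_e)
      }
      if (is.null(fixed_pi)) {
        pi_cur <- stats::rbeta(1, p0 * pi0 + nin, p0 * (1 - pi0) + p - nin)
        pi_cur <- min(max(pi_cur, 1e-8), 1 - 1e-8)
      }

      if (keep_flag[it]) {
        s <- s + 1L
        beta_sum <- beta_sum + beta
        incl_sum <- incl_sum + delta
        mu_sum <- mu_sum + mu
        pi_samp[s] <- pi_cur
        var_samp[s, ] <- c(s2b, s2e)
      }
    }

    beta_mean <- beta_sum / n_keep
    incl <- incl_sum / n_keep
    mu_mean <- mu_sum / n_keep
    eta_all <- drop(Z %*% beta_mean) + mu_mean
    preds <- if (ordinal) stats::pnorm(eta_all[mask]) else eta_all[mask]
    names(preds) <- as.character(mask)
    structure(list(
      model = "bayesc", response = response,
      effect_means = stats::setNames(beta_mean, colnames(X)),
      inclusion_prob = stats::setNames(incl, colnames(X)),
      pi_samples = pi_samp,
      pi_mean = mean(pi_samp),
      var_components = colMeans(var_samp),
      var_samples = var_samp,
      mu_mean = mu_mean,
      eta_mean = eta_all,
      predictions = preds,
      mask = mask,
      n_samples = n_keep,
      settings = settings
    ), class = "posterior_summary")
  })
}
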