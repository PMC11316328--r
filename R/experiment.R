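# Experiment runner: crosses traits x folds x (model, input strategy),
# with strictly fold-internal preprocessing, and emits the per-fold loss
# table plus a per-trait minimum-loss summary.

# which (model, strategy) cells exist in the study design
experiment_cells <- function(models, strategies) {
  valid <- rbind(
    expand.grid(model = c("rkhs", "bayesc", "mlp", "cnn"),
                strategy = c("COMBINED_VARIANTS", "SNPS", "LINKED_SNPS"),
                stringsAsFactors = FALSE),
    data.frame(model = "mlp_pcs", strategy = "PCS", stringsAsFactors = FALSE),
    data.frame(model = c("multi_input", "rkhs"), strategy = "MULTIPLE_INPUTS",
               stringsAsFactors = FALSE)
  )
  valid[valid$model %in% models & valid$strategy %in% strategies, , drop = FALSE]
}

config_digest <- function(cfg) {
  s <- jsonlite::toJSON(cfg, auto_unbox = TRUE, force = TRUE)
  v <- utf8ToInt(as.character(s))
  sprintf("%08x", sum(v * seq_along(v)) %% 4294967291)
}

#' Run a genomic-prediction cross-validation experiment
#'
#' For each trait and fold: (1) fold-internal preprocessing — imputation
#' means, allele frequencies, standardization statistics and marker
#' selection all computed on training rows only; (2) input-strategy
#' materialization — `COMBINED_VARIANTS` (top-k markers pooled over all six
#' classes), `SNPS` (top-k SNPs), `LINKED_SNPS` (SNPs tagging SVs at
#' r2 >= threshold), `PCS` (single matrix of principal components of the
#' six class kernels), `MULTIPLE_INPUTS` (six PC blocks / six kernels);
#' (3) model fits — multi-kernel RKHS (additive + dominance + epistatic
#' kernels for SNP-only strategies, six additive kernels for multiple
#' inputs), BayesC, and MLP / CNN / PC-input MLP / multi-input networks
#' with successive-halving tuning on an inner 20% validation split
#' (Bayesian models use no inner split); (4) losses on the untouched test
#' set (MSE for quantitative, binary cross-entropy for binary traits with
#' classes \{1,2\} mapped to \{0,1\}).
#'
#' Failed cells are logged with `NA` loss and the error message, never
#' dropped.
#'
#' @param G a [genotype_matrix()] (filtered; missing dosages allowed, they
#'   are mean-imputed per fold from training rows).
#' @param P a [phenotype_table()] over the same accessions.
#' @param traits trait names to analyse (default: all).
#' @param scheme `"kfold"`, `"across_population"`, or both.
#' @param k folds for the k-fold scheme.
#' @param holdout group labels for the across-population scheme.
#' @param models,strategies cells to run (defaults: all).
#' @param top_k markers kept by the GWAS ranking (study value 10,000).
#' @param ld_threshold r2 threshold for linked SNPs (study value 0.8).
#' @param mcmc an [mcmc_settings()] for the Bayesian fits.
#' @param var_explained trace fraction for choosing the number of kernel
#'   PCs.
#' @param tuner list of successive-halving settings (`n_configs`,
#'   `first_epochs`, `max_epochs`, `patience`, `batch_size`).
#' @param seed master seed; fold, sampler and network seeds derive from it.
#' @return A list of class `loss_report`: `losses` (the per-fold table),
#'   `summary` (per trait x scheme minimum loss with its model/strategy),
#'   `meta` (resolved settings, including the binary class mapping).
#' @export
run_experiment <- function(G, P,
                           traits = names(P$traits),
                           scheme = "kfold",
                           k = 10L,
                           holdout = c("ARO", "ADM"),
                           models = c("rkhs", "bayesc", "mlp", "cnn",
                                      "mlp_pcs", "multi_input"),
                           strategies = c("COMBINED_VARIANTS", "SNPS",
                                          "LINKED_SNPS", "PCS",
                                          "MULTIPLE_INPUTS"),
                           top_k = 10000L,
                           ld_threshold = 0.8,
                           mcmc = test_mcmc_settings(),
                           var_explained = 0.95,
                           tuner = list(n_configs = 4L, first_epochs = 3L,
                                        max_epochs = 20L, patience = 5L,
                                        batch_size = 32L),
                           seed = 1L) {
  stopifnot(inherits(G, "genotype_matrix"), inherits(P, "phenotype_table"))
  if (!identical(G$accession_ids, P$accession_ids)) {
    stop_svgp("genotype and phenotype accessions differ")
  }
  cells <- experiment_cells(models, strategies)
  if (!nrow(cells)) stop_svgp("no valid (model, strategy) cells requested")

  plans <- list()
  if ("kfold" %in% scheme) {
    plans <- c(plans, kfold_plan(length(G$accession_ids), k,
                                 derive_seed(seed, "folds")))
  }
  if ("across_population" %in% scheme) {
    plans <- c(plans, list(across_population_plan(P$group, holdout)))
  }
  if (!length(plans)) stop_svgp("unknown scheme: ", paste(scheme, collapse = ","))

  rows <- list()
  for (trait in traits) {
    kind <- P$kinds[[trait]]
    y_raw <- P$traits[[trait]]
    y <- if (kind == "binary") binary_to_01(y_raw) else as.numeric(y_raw)
    metric <- if (kind == "binary") "binary_cross_entropy" else "MSE"
    for (plan in plans) {
      ctx <- fold_context(G, y, kind, plan, top_k, ld_threshold,
                          var_explained, strategies)
      for (ci in seq_len(nrow(cells))) {
        model <- cells$model[ci]; strategy <- cells$strategy[ci]
        cfg <- list(trait = trait, model = model, strategy = strategy,
                    scheme = plan$scheme, fold = plan$fold, top_k = top_k,
                    ld = ld_threshold, mcmc = unclass(mcmc), tuner = tuner,
                    seed = seed)
        loss <- NA_real_; err <- NA_character_
        res <- tryCatch(
          fit_cell(model, strategy, ctx, G, y, kind, plan, mcmc, tuner, seed),
          error = function(e) conditionMessage(e))
        if (is.character(res)) err <- res else loss <- res
        rows[[length(rows) + 1L]] <- data.frame(
          trait = trait, model = model, strategy = strategy,
          scheme = plan$scheme, fold = plan$fold, loss = loss,
          metric = metric, seed = seed, config = config_digest(cfg),
          error = err, stringsAsFactors = FALSE)
      }
    }
  }
  losses <- do.call(rbind, rows)
  structure(list(losses = losses,
                 summary = summarize_min_loss(losses),
                 meta = list(binary_mapping = "class {1,2} -> {0,1}",
                             top_k = top_k, ld_threshold = ld_threshold,
                             var_explained = var_explained,
                             mcmc = unclass(mcmc), tuner = tuner,
                             seed = seed)),
            class = "loss_report")
}

# per-fold preprocessing shared across cells; reads training phenotypes only
fold_context <- function(G, y, kind, plan, top_k, ld_threshold,
                         var_explained, strategies) {
  tr <- plan$train
  Gi <- impute_missing(G, train_rows = tr)
  Gtr <- subset_genotypes(Gi, accessions = tr)
  scan <- gwas_scan(Gtr, y[tr], kind)
  ctx <- list(Gi = Gi, scan = scan)
  if ("COMBINED_VARIANTS" %in% strategies) {
    ctx$combined_ids <- select_top_k(scan, top_k, MARKER_CLASSES)
  }
  if ("SNPS" %in% strategies) {
    ctx$snp_ids <- select_top_k(scan, top_k, "SNP")
  }
  if ("LINKED_SNPS" %in% strategies) {
    ls <- suppressWarnings(linked_snps(Gtr, ld_threshold))
    ctx$linked_ids <- ls$snp_ids
  }
  if (any(c("PCS", "MULTIPLE_INPUTS") %in% strategies)) {
    present <- intersect(MARKER_CLASSES, unique(Gi$markers$class))
    kerns <- lapply(present, function(cl) {
      tryCatch(additive_grm(Gi, classes = cl, train_rows = tr),
               error = function(e) NULL)
    })
    names(kerns) <- present
    kerns <- Filter(Negate(is.null), kerns)
    ctx$class_kernels <- kerns
    ctx$class_pcs <- lapply(kerns, function(K) {
      grm_pcs(K, var_explained = var_explained)$scores
    })
  }
  ctx
}

# dosage design matrix for a set of marker ids, train-constant columns
# dropped, standardized on training rows
design_for <- function(Gi, ids, tr) {
  X <- Gi$dosages[, match(ids, Gi$markers$id), drop = FALSE]
  sds <- apply(X[tr, , drop = FALSE], 2, stats::sd)
  X <- X[, sds > 0, drop = FALSE]
  if (!ncol(X)) stop_svgp("no polymorphic training markers in selection")
  standardize_design(X, tr)
}

strategy_ids <- function(strategy, ctx) {
  ids <- switch(strategy,
                COMBINED_VARIANTS = ctx$combined_ids,
                SNPS = ctx$snp_ids,
                LINKED_SNPS = ctx$linked_ids,
                stop_svgp("strategy has no marker-id set: ", strategy))
  if (!length(ids)) stop_svgp("empty marker selection for ", strategy)
  ids
}

fit_cell <- function(model, strategy, ctx, G, y, kind, plan, mcmc, tuner,
                     seed) {
  tr <- plan$train; te <- plan$test
  Gi <- ctx$Gi
  response <- if (kind == "binary") "ordinal" else "gaussian"
  y_masked <- y
  y_masked[te] <- NA
  cfg_seed <- derive_seed(seed, paste(model, strategy, plan$scheme, plan$fold))
  set <- mcmc_settings(mcmc$n_iter, mcmc$burn_in, mcmc$thin, cfg_seed)

  score <- function(pred) {
    if (kind == "binary") binary_cross_entropy(y[te], pred) else mse(y[te], pred)
  }

  if (model == "rkhs") {
    kernels <- if (strategy == "MULTIPLE_INPUTS") {
      ctx$class_kernels
    } else if (strategy == "COMBINED_VARIANTS") {
      ids <- strategy_ids(strategy, ctx)
      list(additive = additive_grm(subset_genotypes(Gi, markers = ids),
                                   classes = MARKER_CLASSES, train_rows = tr))
    } else {
      ids <- strategy_ids(strategy, ctx)
      Gsel <- subset_genotypes(Gi, markers = ids)
      A <- additive_grm(Gsel, classes = "SNP", train_rows = tr)
      list(additive = A,
           dominance = dominance_grm(Gsel, train_rows = tr),
           epistatic = epistatic_grm(A))
    }
    fit <- fit_rkhs(y_masked, kernels, set, response = response, mask = te)
    return(score(predict(fit, te)))
  }

  if (model == "bayesc") {
    ids <- strategy_ids(strategy, ctx)
    Z <- design_for(Gi, ids, tr)
    fit <- fit_bayesc(y_masked, Z, set, response = response, mask = te)
    return(score(predict(fit, te)))
  }

  # network models: inner validation split off the training set
  split <- inner_split(tr, 0.2, derive_seed(cfg_seed, "inner"))
  if (model %in% c("mlp", "cnn")) {
    ids <- strategy_ids(strategy, ctx)
    if (model == "cnn") {
      md <- Gi$markers[match(ids, Gi$markers$id), ]
      ids <- ids[order(md$chrom, md$pos)]
    }
    Z <- design_for(Gi, ids, tr)
    xs <- list(train = Z[split$train, , drop = FALSE],
               val = Z[split$validation, , drop = FALSE],
               test = Z[te, , drop = FALSE])
    arch <- model
  } else if (model == "mlp_pcs") {
    Z <- do.call(cbind, ctx$class_pcs)
    xs <- list(train = Z[split$train, , drop = FALSE],
               val = Z[split$validation, , drop = FALSE],
               test = Z[te, , drop = FALSE])
    arch <- "mlp"
  } else if (model == "multi_input") {
    blocks <- ctx$class_pcs
    if (length(blocks) != 6L) {
      stop_svgp("multi-input strategy needs all six marker classes (got ",
                length(blocks), ")")
    }
    xs <- list(train = lapply(blocks, function(B) B[split$train, , drop = FALSE]),
               val = lapply(blocks, function(B) B[split$validation, , drop = FALSE]),
               test = lapply(blocks, function(B) B[te, , drop = FALSE]))
    arch <- "multi_input"
  } else {
    stop_svgp("unknown model: ", model)
  }
  sr <- hyperband_search(arch, xs$train, y[split$train], xs$val,
                         y[split$validation], trait_kind = kind,
                         n_configs = tuner$n_configs %||% 4L,
                         halving_factor = tuner$halving_factor %||% 2L,
                         first_epochs = tuner$first_epochs %||% 3L,
                         max_epochs = tuner$max_epochs %||% 20L,
                         patience = tuner$patience %||% 5L,
                         batch_size = tuner$batch_size %||% 32L,
                         seed = cfg_seed)
  score(predict(sr$model, xs$test))
}

#' Minimum-loss summary per trait and validation scheme
#'
#' Reduces a loss table to one row per (trait, scheme): the (model,
#' strategy) pair with the smallest mean loss across folds — the shape of
#' the study's headline comparison table.
#'
#' @param losses the `losses` data.frame of a `loss_report` (or the report).
#' @return data.frame with `trait`, `scheme`, `loss`, `model`, `strategy`.
#' @export
summarize_min_loss <- function(losses) {
  if (inherits(losses, "loss_report")) losses <- losses$losses
  ok <- losses[!is.na(losses$loss), , drop = FALSE]
  if (!nrow(ok)) {
    return(data.frame(trait = character(), scheme = character(),
                      loss = numeric(), model = character(),
                      strategy = character(), stringsAsFactors = FALSE))
  }
  agg <- stats::aggregate(loss ~ trait + scheme + model + strategy, ok, mean)
  out <- do.call(rbind, lapply(split(agg, list(agg$trait, agg$scheme), drop = TRUE),
                               function(d) d[which.min(d$loss), ]))
  rownames(out) <- NULL
  out[, c("trait", "scheme", "loss", "model", "strategy")]
}

#' @export
print.loss_report <- function(x, ...) {
  cat("loss_report:", nrow(x$losses), "cells (",
      sum(is.na(x$losses$loss)), "failed )\n")
  cat("minimum loss per trait x scheme:\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Write a loss report to TSV (+ JSON metadata)
#'
#' @param report a `loss_report`.
#' @param path base path; writes `<path>.tsv`, `<path>_summary.tsv` and
#'   `<path>_meta.json`.
#' @return Invisibly, the base path.
#' @export
write_loss_report <- function(report, path) {
  stopifnot(inherits(report, "loss_report"))
  utils::write.table(report$losses, paste0(path, ".tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(report$summary, paste0(path, "_summary.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(report$meta, paste0(path, "_meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
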