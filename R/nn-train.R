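#' Loss of predictions under a trait kind
#'
#' MSE for quantitative traits, binary cross-entropy for binary traits
#' (labels on the 0/1 scale).
#' @param y observed values.
#' @param yhat predictions (probabilities for binary).
#' @param trait_kind `"quantitative"` or `"binary"`.
#' @return Scalar loss.
#' @export
prediction_loss <- function(y, yhat, trait_kind) {
  if (trait_kind == "binary") binary_cross_entropy(y, yhat) else mse(y, yhat)
}

#' Train a network by mini-batch gradient descent
#'
#' Minimizes MSE (quantitative) or binary cross-entropy (binary, labels
#' 0/1) plus the spec's L1/L2 penalties with the spec's optimizer.
#' Early-stops on the validation loss with the given patience and restores
#' the best-epoch parameters. Deterministic given `seed` (which drives
#' batch shuffling and dropout masks).
#'
#' @param model an `nn_model` from [build_mlp()], [build_cnn()] or
#'   [build_multi_input()].
#' @param x_train features (matrix, or list of 6 matrices for multi-input).
#' @param y_train response (0/1 for binary traits).
#' @param x_val,y_val validation split (optional; `NULL` disables early
#'   stopping).
#' @param epochs maximum epochs (0 returns the initialized model).
#' @param batch_size mini-batch size.
#' @param patience epochs without validation improvement before stopping.
#' @param seed RNG seed for shuffling/dropout.
#' @return A `trained_model`: the fitted `nn_model`, per-epoch `history`
#'   (train/validation loss), `best_val_loss`, `best_epoch`.
#' @export
train_network <- function(model, x_train, y_train, x_val = NULL, y_val = NULL,
                          epochs = 100L, batch_size = 32L, patience = 10L,
                          seed = 1L) {
  stopifnot(inherits(model, "nn_model"))
  n <- length(y_train)
  take_rows <- function(x, idx) {
    if (is.list(x)) lapply(x, function(b) b[idx, , drop = FALSE])
    else x[idx, , drop = FALSE]
  }
  has_val <- !is.null(x_val) && !is.null(y_val)
  eval_loss <- function(m, x, y) {
    prediction_loss(y, drop(model_forward(m, x, FALSE)$yhat), m$trait_kind)
  }
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())
  best <- list(params = model_params(model), val = Inf, epoch = 0L)
  if (epochs == 0L) {
    return(structure(list(model = model, history = history,
                          best_val_loss = NA_real_, best_epoch = 0L,
                          seed = seed, spec = model$spec),
                     class = "trained_model"))
  }
  with_seed(seed, {
    opt <- make_optimizer(model$spec$optimizer)
    wait <- 0L
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      for (start in seq(1L, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1L, n)]
        xb <- take_rows(x_train, idx)
        yb <- y_train[idx]
        fw <- model_forward(model, xb, training = TRUE)
        nb <- length(yb)
        # gradient wrt the pre-activation of the output unit:
        # linear head + MSE: 2(z - y)/n; sigmoid head + BCE: (p - y)/n
        dZ <- if (model$output_activation == "sigmoid") {
          matrix((fw$yhat - yb) / nb, nb, 1)
        } else {
          matrix(2 * (drop(fw$z) - yb) / nb, nb, 1)
        }
        if (any(!is.finite(dZ))) {
          stop_svgp("NaN/Inf loss gradient at epoch ", ep,
                    " (optimizer ", model$spec$optimizer,
                    ", l1 ", model$spec$l1, ", l2 ", model$spec$l2,
                    "): lower the learning rate or penalties")
        }
        grads <- flatten_grads(model, model_backward(model, fw$caches, dZ))
        step <- optimizer_step(opt, model_params(model), grads)
        opt <- step$opt
        model <- model_set_params(model, step$params)
      }
      tl <- eval_loss(model, x_train, y_train)
      vl <- if (has_val) eval_loss(model, x_val, y_val) else NA_real_
      if (!is.finite(tl)) {
        stop_svgp("training loss diverged (NaN) at epoch ", ep)
      }
      history <- rbind(history, data.frame(epoch = ep, train_loss = tl,
                                           val_loss = vl))
      track <- if (has_val) vl else tl
      if (track < best$val) {
        best <- list(params = model_params(model), val = track, epoch = ep)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (has_val && wait >= patience) break
      }
    }
  })
  model <- model_set_params(model, best$params)
  structure(list(model = model, history = history,
                 best_val_loss = best$val, best_epoch = best$epoch,
                 seed = seed, spec = model$spec),
            class = "trained_model")
}

#' @export
print.trained_model <- function(x, ...) {
  cat(sprintf("trained_model (%s): %d epochs run, best %s loss %.5f at epoch %d\n",
              x$model$arch, nrow(x$history),
              ifelse(all(is.na(x$history$val_loss)), "train", "validation"),
              x$best_val_loss, x$best_epoch))
  invisible(x)
}

#' @export
predict.trained_model <- function(object, x, ...) {
  predict(object$model, x)
}

#' Hyperparameter search by successive halving (Hyperband-style)
#'
#' Samples `n_configs` specifications from the study's grid, trains each
#' for a small epoch budget, keeps the top-performing half by validation
#' loss, multiplies the budget by the halving factor, and repeats until one
#' survivor remains. The survivor is retrained on the full training data
#' with the full epoch budget. The log records every (config, budget,
#' loss) evaluation.
#'
#' @param arch architecture to search over.
#' @param x_train,y_train,x_val,y_val data splits (validation drives the
#'   halving decisions).
#' @param trait_kind `"quantitative"` or `"binary"`.
#' @param n_configs initial number of sampled configurations.
#' @param halving_factor keep 1/factor of configs per round (>= 2).
#' @param first_epochs epoch budget of the first round.
#' @param max_epochs epoch cap for later rounds and the final retraining.
#' @param patience early-stopping patience for the final retraining.
#' @param batch_size mini-batch size.
#' @param seed master seed (fans out per config).
#' @param objective optional replacement evaluator
#'   `function(spec, budget_epochs, config_seed) -> loss`, used in tests to
#'   substitute a fixed loss table for real training.
#' @param retrain retrain the survivor (default `TRUE`; ignored when
#'   `objective` is supplied).
#' @return A list of class `search_result`: `best_spec`, `log` (data.frame
#'   `config`, `round`, `budget`, `loss`), and `model` (the retrained
#'   `trained_model`, or `NULL`).
#' @export
hyperband_search <- function(arch, x_train, y_train, x_val, y_val,
                             trait_kind = "quantitative",
                             n_configs = 8L, halving_factor = 2L,
                             first_epochs = 3L, max_epochs = 50L,
                             patience = 10L, batch_size = 32L, seed = 1L,
                             objective = NULL, retrain = TRUE) {
  if (halving_factor < 2L) stop_svgp("halving factor must be >= 2")
  if (first_epochs < 1L) stop_svgp("budget below one epoch per configuration")
  build <- function(spec, cfg_seed) {
    dim_of <- function(x) if (is.list(x)) vapply(x, ncol, 1L) else ncol(x)
    switch(arch,
           mlp = build_mlp(spec, ncol(x_train), trait_kind, cfg_seed),
           cnn = build_cnn(spec, ncol(x_train), trait_kind, cfg_seed),
           multi_input = build_multi_input(spec, dim_of(x_train), trait_kind,
                                           cfg_seed))
  }
  default_objective <- function(spec, budget, cfg_seed) {
    tm <- train_network(build(spec, cfg_seed), x_train, y_train, x_val, y_val,
                        epochs = budget, batch_size = batch_size,
                        patience = budget + 1L,  # no early exit inside brackets
                        seed = cfg_seed)
    tm$best_val_loss
  }
  obj <- objective %||% default_objective
  specs <- with_seed(derive_seed(seed, "halving-sample"), {
    lapply(seq_len(n_configs), function(i) sample_network_spec(arch))
  })
  alive <- seq_len(n_configs)
  budget <- first_epochs
  log <- data.frame(config = integer(), round = integer(), budget = integer(),
                    loss = numeric())
  round <- 0L
  while (TRUE) {
    round <- round + 1L
    losses <- vapply(alive, function(i) {
      obj(specs[[i]], budget, derive_seed(seed, paste0("cfg", i)))
    }, numeric(1))
    log <- rbind(log, data.frame(config = alive, round = round,
                                 budget = budget, loss = losses))
    if (length(alive) == 1L) break
    keep <- ceiling(length(alive) / halving_factor)
    alive <- alive[order(losses)][seq_len(keep)]
    budget <- min(budget * halving_factor, max_epochs)
  }
  best_spec <- specs[[alive]]
  model <- NULL
  if (retrain && is.null(objective)) {
    model <- train_network(build(best_spec, derive_seed(seed, "retrain")),
                           x_train, y_train, x_val, y_val,
                           epochs = max_epochs, batch_size = batch_size,
                           patience = patience,
                           seed = derive_seed(seed, "retrain"))
  }
  structure(list(best_spec = best_spec, best_config = alive, log = log,
                 model = model),
            class = "search_result")
}
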