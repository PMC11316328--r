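# Network specification and model builders (MLP, 1-D CNN, six-branch
# multi-input), constrained to the study's hyperparameter grids.

NETWORK_GRID <- list(
  first_units = c(16, 38, 64, 128),
  n_hidden_mlp = 0:3,
  n_hidden_cnn = 1:3,
  hidden_units = c(2, 4, 8, 16),
  activation = c("relu", "tanh", "linear"),
  optimizer = c("adam", "rmsprop", "sgd"),
  dropout = c(0, 0.05, 0.1, 0.15, 0.2, 0.25, 0.3),
  penalty = c(0, 0.001, 0.01, 0.1)  # 0 = regularizer absent
)

#' Network hyperparameter specification
#'
#' Validated against the study's search grids: first-layer units / CNN
#' filters in \{16, 38, 64, 128\}; hidden dense layers 0-3 (MLP) or 1-3
#' (CNN); hidden units in \{2, 4, 8, 16\}; activation relu/tanh/linear;
#' optimizer adam/rmsprop/sgd; dropout in \{0, 0.05, ..., 0.3\}; L1/L2
#' weight-decay in \{0.001, 0.01, 0.1\} (0 disables the regularizer). The
#' CNN kernel width / stride / pooling width are not part of the search
#' grid; their defaults (3 / 1 / 2) are recorded in the spec.
#'
#' @param arch `"mlp"`, `"cnn"` or `"multi_input"`.
#' @param first_units units of the first dense layer (MLP, branch layers of
#'   the multi-input net) or number of CNN filters.
#' @param n_hidden number of hidden dense layers.
#' @param hidden_units units per hidden dense layer.
#' @param activation,optimizer,dropout,l1,l2 grid-constrained choices.
#' @param kernel_width,stride,pool_width,pool_stride CNN geometry.
#' @return An object of class `network_spec`.
#' @export
network_spec <- function(arch = c("mlp", "cnn", "multi_input"),
                         first_units = 16, n_hidden = 1, hidden_units = 8,
                         activation = "relu", optimizer = "adam",
                         dropout = 0, l1 = 0, l2 = 0,
                         kernel_width = 3L, stride = 1L,
                         pool_width = 2L, pool_stride = pool_width) {
  arch <- match.arg(arch)
  g <- NETWORK_GRID
  chk <- function(v, grid, what) {
    if (!v %in% grid) {
      stop_svgp(what, " = ", v, " outside grid {", paste(grid, collapse = ","), "}")
    }
  }
  chk(first_units, g$first_units, "first_units")
  chk(n_hidden, if (arch == "cnn") g$n_hidden_cnn else g$n_hidden_mlp, "n_hidden")
  chk(hidden_units, g$hidden_units, "hidden_units")
  chk(activation, g$activation, "activation")
  chk(optimizer, g$optimizer, "optimizer")
  chk(dropout, g$dropout, "dropout")
  chk(l1, g$penalty, "l1")
  chk(l2, g$penalty, "l2")
  structure(list(arch = arch, first_units = first_units, n_hidden = n_hidden,
                 hidden_units = hidden_units, activation = activation,
                 optimizer = optimizer, dropout = dropout, l1 = l1, l2 = l2,
                 kernel_width = as.integer(kernel_width),
                 stride = as.integer(stride),
                 pool_width = as.integer(pool_width),
                 pool_stride = as.integer(pool_stride)),
            class = "network_spec")
}

#' Draw a random network specification from the search grid
#'
#' @param arch architecture to sample for.
#' @return A [network_spec()] drawn uniformly from the grids (uses the
#'   current RNG stream).
#' @export
sample_network_spec <- function(arch = c("mlp", "cnn", "multi_input")) {
  arch <- match.arg(arch)
  g <- NETWORK_GRID
  pick <- function(v) v[sample.int(length(v), 1L)]
  network_spec(arch,
               first_units = pick(g$first_units),
               n_hidden = pick(if (arch == "cnn") g$n_hidden_cnn else g$n_hidden_mlp),
               hidden_units = pick(g$hidden_units),
               activation = pick(g$activation),
               optimizer = pick(g$optimizer),
               dropout = pick(g$dropout),
               l1 = pick(g$penalty), l2 = pick(g$penalty))
}

output_for_kind <- function(trait_kind) {
  switch(trait_kind, quantitative = "linear", binary = "sigmoid",
         stop_svgp("unknown trait kind: ", trait_kind))
}

#' Build an untrained multilayer perceptron
#'
#' input -> first dense layer -> `n_hidden` hidden dense layers (L1+L2
#' penalties on all hidden layers) -> dropout -> 1-unit output (linear for
#' quantitative traits, sigmoid for binary).
#'
#' @param spec a [network_spec()] with `arch = "mlp"`.
#' @param input_dim number of input features.
#' @param trait_kind `"quantitative"` or `"binary"`.
#' @param seed seed for weight initialisation.
#' @return An object of class `nn_model`.
#' @export
build_mlp <- function(spec, input_dim, trait_kind = "quantitative", seed = 1L) {
  stopifnot(inherits(spec, "network_spec"))
  if (spec$arch != "mlp") stop_svgp("spec$arch must be 'mlp'")
  with_seed(seed, {
    layers <- list()
    d <- input_dim
    if (spec$n_hidden >= 0) {
      layers <- c(layers, list(layer_dense(d, spec$first_units, spec$activation,
                                           spec$l1, spec$l2)))
      d <- spec$first_units
    }
    for (i in seq_len(spec$n_hidden)) {
      layers <- c(layers, list(layer_dense(d, spec$hidden_units, spec$activation,
                                           spec$l1, spec$l2)))
      d <- spec$hidden_units
    }
    if (spec$dropout > 0) layers <- c(layers, list(layer_dropout(spec$dropout)))
    layers <- c(layers, list(layer_dense(d, 1L, "linear")))
    structure(list(arch = "mlp", spec = spec, layers = layers,
                   input_dim = input_dim,
                   output_activation = output_for_kind(trait_kind),
                   trait_kind = trait_kind, seed = seed),
              class = "nn_model")
  })
}

#' Build an untrained 1-D convolutional network
#'
#' Markers must be ordered by (chromosome, position) so convolution windows
#' have spatial meaning. Architecture: 1-D convolution (`first_units`
#' filters, shared weights) -> activation -> max-pooling -> flatten ->
#' `n_hidden` dense layers -> dropout -> 1-unit output.
#'
#' @inheritParams build_mlp
#' @param spec a [network_spec()] with `arch = "cnn"`.
#' @return An `nn_model`.
#' @export
build_cnn <- function(spec, input_dim, trait_kind = "quantitative", seed = 1L) {
  stopifnot(inherits(spec, "network_spec"))
  if (spec$arch != "cnn") stop_svgp("spec$arch must be 'cnn'")
  if (input_dim < spec$kernel_width) {
    stop_svgp("input length ", input_dim, " shorter than kernel width ",
              spec$kernel_width)
  }
  with_seed(seed, {
    Tn <- length(conv_windows(input_dim, spec$kernel_width, spec$stride))
    Tp <- if (Tn >= spec$pool_width) {
      length(conv_windows(Tn, spec$pool_width, spec$pool_stride))
    } else {
      stop_svgp("feature map shorter than pooling width")
    }
    layers <- list(
      layer_conv1d(spec$kernel_width, spec$first_units, spec$stride,
                   spec$activation),
      layer_maxpool(spec$pool_width, spec$pool_stride),
      layer_flatten()
    )
    d <- Tp * spec$first_units
    for (i in seq_len(spec$n_hidden)) {
      layers <- c(layers, list(layer_dense(d, spec$hidden_units, spec$activation,
                                           spec$l1, spec$l2)))
      d <- spec$hidden_units
    }
    if (spec$dropout > 0) layers <- c(layers, list(layer_dropout(spec$dropout)))
    layers <- c(layers, list(layer_dense(d, 1L, "linear")))
    structure(list(arch = "cnn", spec = spec, layers = layers,
                   input_dim = input_dim,
                   output_activation = output_for_kind(trait_kind),
                   trait_kind = trait_kind, seed = seed),
              class = "nn_model")
  })
}

#' Build an untrained six-branch multi-input network
#'
#' One input block per marker class (principal-component scores of each
#' class's relationship kernel). Each block feeds its own dense layer; the
#' branch outputs are concatenated and passed through shared hidden dense
#' layers, dropout and the 1-unit output.
#'
#' @inheritParams build_mlp
#' @param spec a [network_spec()] with `arch = "multi_input"`.
#' @param block_dims integer vector of the six block widths.
#' @return An `nn_model` with `branches` and `trunk` layer stacks.
#' @export
build_multi_input <- function(spec, block_dims, trait_kind = "quantitative",
                              seed = 1L) {
  stopifnot(inherits(spec, "network_spec"))
  if (spec$arch != "multi_input") stop_svgp("spec$arch must be 'multi_input'")
  if (length(block_dims) != 6L) {
    stop_svgp("multi-input network requires exactly 6 input blocks, got ",
              length(block_dims))
  }
  with_seed(seed, {
    branches <- lapply(block_dims, function(d) {
      list(layer_dense(d, spec$first_units, spec$activation, spec$l1, spec$l2))
    })
    d <- spec$first_units * 6L
    trunk <- list()
    for (i in seq_len(spec$n_hidden)) {
      trunk <- c(trunk, list(layer_dense(d, spec$hidden_units, spec$activation,
                                         spec$l1, spec$l2)))
      d <- spec$hidden_units
    }
    if (spec$dropout > 0) trunk <- c(trunk, list(layer_dropout(spec$dropout)))
    trunk <- c(trunk, list(layer_dense(d, 1L, "linear")))
    structure(list(arch = "multi_input", spec = spec, branches = branches,
                   trunk = trunk, block_dims = block_dims,
                   output_activation = output_for_kind(trait_kind),
                   trait_kind = trait_kind, seed = seed),
              class = "nn_model")
  })
}

# full forward pass; x is a matrix (or list of 6 matrices for multi_input).
# Returns list(out [pre-output-activation z and activated yhat], caches).
model_forward <- function(model, x, training = FALSE) {
  if (model$arch == "multi_input") {
    if (!is.list(x) || length(x) != 6L) stop_svgp("multi_input expects 6 blocks")
    bouts <- vector("list", 6L)
    bcaches <- vector("list", 6L)
    for (b in 1:6) {
      fw <- forward_stack(model$branches[[b]], as.matrix(x[[b]]), training)
      bouts[[b]] <- fw$out
      bcaches[[b]] <- fw$caches
    }
    concat <- do.call(cbind, bouts)
    tw <- forward_stack(model$trunk, concat, training)
    z <- tw$out
    list(z = z, yhat = act_fun(z, model$output_activation),
         caches = list(branches = bcaches, trunk = tw$caches,
                       widths = vapply(bouts, ncol, 1L)))
  } else {
    fw <- forward_stack(model$layers, as.matrix(x), training)
    list(z = fw$out, yhat = act_fun(fw$out, model$output_activation),
         caches = fw$caches)
  }
}

# backward pass from gradient wrt pre-output-activation z
model_backward <- function(model, caches, dZ) {
  if (model$arch == "multi_input") {
    bw <- backward_stack(model$trunk, caches$trunk, dZ)
    grads <- list(trunk = bw$grads, branches = vector("list", 6L))
    splits <- c(0, cumsum(caches$widths))
    for (b in 1:6) {
      dB <- bw$dIn[, (splits[b] + 1):splits[b + 1], drop = FALSE]
      bwb <- backward_stack(model$branches[[b]], caches$branches[[b]], dB)
      grads$branches[[b]] <- bwb$grads
    }
    grads
  } else {
    backward_stack(model$layers, caches, dZ)$grads
  }
}

# flat named parameter list <-> model
model_params <- function(model) {
  out <- list()
  grab <- function(layers, prefix) {
    for (i in seq_along(layers)) {
      ly <- layers[[i]]
      for (pn in intersect(c("W", "b", "K"), names(ly))) {
        out[[paste0(prefix, i, ".", pn)]] <<- ly[[pn]]
      }
    }
  }
  if (model$arch == "multi_input") {
    for (b in 1:6) grab(model$branches[[b]], paste0("br", b, ".L"))
    grab(model$trunk, "tr.L")
  } else {
    grab(model$layers, "L")
  }
  out
}

model_set_params <- function(model, params) {
  put <- function(layers, prefix) {
    for (i in seq_along(layers)) {
      for (pn in intersect(c("W", "b", "K"), names(layers[[i]]))) {
        layers[[i]][[pn]] <- params[[paste0(prefix, i, ".", pn)]]
      }
    }
    layers
  }
  if (model$arch == "multi_input") {
    for (b in 1:6) model$branches[[b]] <- put(model$branches[[b]], paste0("br", b, ".L"))
    model$trunk <- put(model$trunk, "tr.L")
  } else {
    model$layers <- put(model$layers, "L")
  }
  model
}

# grads (nested, parallel to layers) -> flat named list matching model_params
flatten_grads <- function(model, grads) {
  out <- list()
  grab <- function(glist, prefix) {
    for (i in seq_along(glist)) {
      g <- glist[[i]]
      if (is.null(g)) next
      for (pn in names(g)) out[[paste0(prefix, i, ".", pn)]] <<- g[[pn]]
    }
  }
  if (model$arch == "multi_input") {
    for (b in 1:6) grab(grads$branches[[b]], paste0("br", b, ".L"))
    grab(grads$trunk, "tr.L")
  } else {
    grab(grads, "L")
  }
  out
}

#' Evaluate a network on new inputs
#'
#' Dropout is disabled: repeated evaluation on the same input is
#' bit-identical.
#'
#' @param object an `nn_model` (possibly inside a `trained_model`).
#' @param x feature matrix, or list of 6 matrices for multi-input nets.
#' @param ... unused.
#' @return Numeric vector of predictions (probabilities for sigmoid heads).
#' @export
predict.nn_model <- function(object, x, ...) {
  drop(model_forward(object, x, training = FALSE)$yhat)
}
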