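# Minimal feed-forward network engine: dense, 1-D convolution, max-pooling,
# flatten and dropout layers with reverse-mode gradients, written for the
# small marker panels this package trains on. Batches are rows.

act_fun <- function(z, name) {
  switch(name,
         relu = pmax(z, 0),
         tanh = tanh(z),
         linear = z,
         sigmoid = 1 / (1 + exp(-z)),
         stop_svgp("unknown activation: ", name))
}

act_grad <- function(z, name) {
  switch(name,
         relu = (z > 0) * 1,
         tanh = 1 - tanh(z)^2,
         linear = z * 0 + 1,
         stop_svgp("no gradient for activation: ", name))
}

glorot_init <- function(fan_in, fan_out, dims = c(fan_in, fan_out)) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -lim, lim), dim = dims)
}

layer_dense <- function(d_in, units, activation = "linear", l1 = 0, l2 = 0) {
  list(type = "dense", W = glorot_init(d_in, units), b = numeric(units),
       activation = activation, l1 = l1, l2 = l2)
}

layer_conv1d <- function(width, filters, stride = 1L, activation = "linear") {
  list(type = "conv", K = glorot_init(width, filters), b = numeric(filters),
       width = width, filters = filters, stride = as.integer(stride),
       activation = activation)
}

layer_maxpool <- function(width = 2L, stride = width) {
  list(type = "pool", width = as.integer(width), stride = as.integer(stride))
}

layer_flatten <- function() list(type = "flatten")

layer_dropout <- function(rate) list(type = "dropout", rate = rate)

conv_windows <- function(L, width, stride) {
  if (L < width) stop_svgp("input length ", L, " shorter than kernel width ", width)
  starts <- seq(1L, L - width + 1L, by = stride)
  starts
}

# forward through one layer; returns list(out, cache)
layer_forward <- function(layer, A, training = FALSE) {
  switch(layer$type,
    dense = {
      Z <- sweep(A %*% layer$W, 2, layer$b, "+")
      list(out = act_fun(Z, layer$activation), cache = list(A = A, Z = Z))
    },
    conv = {
      starts <- conv_windows(ncol(A), layer$width, layer$stride)
      Tn <- length(starts); Fn <- layer$filters; B <- nrow(A)
      Z <- array(0, dim = c(B, Tn, Fn))
      Acols <- vector("list", layer$width)
      for (j in seq_len(layer$width)) {
        Acols[[j]] <- A[, starts + j - 1L, drop = FALSE]
      }
      for (f in seq_len(Fn)) {
        Zf <- matrix(layer$b[f], B, Tn)
        for (j in seq_len(layer$width)) Zf <- Zf + Acols[[j]] * layer$K[j, f]
        Z[, , f] <- Zf
      }
      list(out = act_fun(Z, layer$activation),
           cache = list(Acols = Acols, Z = Z, starts = starts, L = ncol(A)))
    },
    pool = {
      dimA <- dim(A)  # batch x T x F
      starts <- conv_windows(dimA[2], layer$width, layer$stride)
      Tn <- length(starts); B <- dimA[1]; Fn <- dimA[3]
      out <- array(-Inf, dim = c(B, Tn, Fn))
      amax <- array(0L, dim = c(B, Tn, Fn))
      for (j in seq_len(layer$width)) {
        slab <- A[, starts + j - 1L, , drop = FALSE]
        upd <- slab > out
        out[upd] <- slab[upd]
        amax[upd] <- j
      }
      list(out = out, cache = list(starts = starts, amax = amax, dimA = dimA))
    },
    flatten = {
      d <- dim(A)
      list(out = matrix(A, d[1], prod(d[-1])), cache = list(d = d))
    },
    dropout = {
      if (training && layer$rate > 0) {
        m <- array(stats::rbinom(length(A), 1, 1 - layer$rate) / (1 - layer$rate),
                   dim = dim(A) %||% c(length(A), 1))
        dim(m) <- dim(A)
        list(out = A * m, cache = list(mask = m))
      } else {
        list(out = A, cache = list(mask = NULL))
      }
    },
    stop_svgp("unknown layer type")
  )
}

# backward through one layer; dOut is gradient wrt layer output.
# returns list(dIn, grads) with grads named like the layer's parameters.
layer_backward <- function(layer, cache, dOut) {
  switch(layer$type,
    dense = {
      dZ <- dOut * act_grad(cache$Z, layer$activation)
      dW <- crossprod(cache$A, dZ)
      if (layer$l2 > 0) dW <- dW + 2 * layer$l2 * layer$W
      if (layer$l1 > 0) dW <- dW + layer$l1 * sign(layer$W)
      list(dIn = dZ %*% t(layer$W),
           grads = list(W = dW, b = colSums(dZ)))
    },
    conv = {
      dZ <- dOut * act_grad(cache$Z, layer$activation)
      Fn <- layer$filters
      dK <- matrix(0, layer$width, Fn)
      db <- numeric(Fn)
      B <- dim(dZ)[1]
      dIn <- matrix(0, B, cache$L)
      for (f in seq_len(Fn)) {
        dZf <- dZ[, , f, drop = FALSE]
        dim(dZf) <- dim(dZ)[1:2]
        db[f] <- sum(dZf)
        for (j in seq_len(layer$width)) {
          dK[j, f] <- sum(cache$Acols[[j]] * dZf)
        }
      }
      for (j in seq_len(layer$width)) {
        Cj <- matrix(0, B, length(cache$starts))
        for (f in seq_len(Fn)) {
          dZf <- dZ[, , f, drop = FALSE]
          dim(dZf) <- dim(dZ)[1:2]
          Cj <- Cj + dZf * layer$K[j, f]
        }
        cols <- cache$starts + j - 1L
        dIn[, cols] <- dIn[, cols] + Cj
      }
      list(dIn = dIn, grads = list(K = dK, b = db))
    },
    pool = {
      dIn <- array(0, dim = cache$dimA)
      B <- cache$dimA[1]; Fn <- cache$dimA[3]
      Tn <- length(cache$starts)
      for (j in seq_len(layer$width)) {
        sel <- cache$amax == j
        if (!any(sel)) next
        contrib <- array(0, dim = dim(sel))
        contrib[sel] <- dOut[sel]
        cols <- cache$starts + j - 1L
        dIn[, cols, ] <- dIn[, cols, ] + contrib
      }
      list(dIn = dIn, grads = NULL)
    },
    flatten = {
      dIn <- dOut
      dim(dIn) <- cache$d
      list(dIn = dIn, grads = NULL)
    },
    dropout = {
      if (is.null(cache$mask)) list(dIn = dOut, grads = NULL)
      else list(dIn = dOut * cache$mask, grads = NULL)
    }
  )
}

forward_stack <- function(layers, A, training = FALSE) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    fw <- layer_forward(layers[[i]], A, training)
    A <- fw$out
    caches[[i]] <- fw$cache
  }
  list(out = A, caches = caches)
}

backward_stack <- function(layers, caches, dOut) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    bw <- layer_backward(layers[[i]], caches[[i]], dOut)
    grads[[i]] <- bw$grads
    dOut <- bw$dIn
  }
  list(grads = grads, dIn = dOut)
}

# penalty contribution of a stack to the loss
stack_penalty <- function(layers) {
  s <- 0
  for (ly in layers) {
    if (ly$type == "dense" && (ly$l1 > 0 || ly$l2 > 0)) {
      s <- s + ly$l1 * sum(abs(ly$W)) + ly$l2 * sum(ly$W^2)
    }
  }
  s
}

# ---- optimizers ------------------------------------------------------------
# Keras-default learning rates: adam/rmsprop 0.001, sgd 0.01.

make_optimizer <- function(name, lr = NULL) {
  name <- match.arg(name, c("adam", "rmsprop", "sgd"))
  lr <- lr %||% switch(name, adam = 0.001, rmsprop = 0.001, sgd = 0.01)
  list(name = name, lr = lr, state = list(), t = 0L)
}

# one update over flat named lists of parameter arrays and their gradients;
# returns list(opt, params)
optimizer_step <- function(opt, params, grads) {
  opt$t <- opt$t + 1L
  for (key in names(params)) {
    g <- grads[[key]]
    if (is.null(g)) next
    p <- params[[key]]
    if (opt$name == "sgd") {
      p <- p - opt$lr * g
    } else if (opt$name == "rmsprop") {
      st <- opt$state[[key]] %||% list(v = p * 0)
      st$v <- 0.9 * st$v + 0.1 * g^2
      p <- p - opt$lr * g / (sqrt(st$v) + 1e-7)
      opt$state[[key]] <- st
    } else {
      st <- opt$state[[key]] %||% list(m = p * 0, v = p * 0)
      st$m <- 0.9 * st$m + 0.1 * g
      st$v <- 0.999 * st$v + 0.001 * g^2
      p <- p - opt$lr * (st$m / (1 - 0.9^opt$t)) /
        (sqrt(st$v / (1 - 0.999^opt$t)) + 1e-7)
      opt$state[[key]] <- st
    }
    params[[key]] <- p
  }
  list(opt = opt, params = params)
}
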