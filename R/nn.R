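# Minimal 1-D CNN engine: sequential conv/pool/dense chains over batches,
# reverse-mode gradients, Adam. Signals travel as arrays [channels x time x
# batch]; tabular/flattened activations as matrices [features x batch].
# All layer parameters live in a flat named list so the optimiser and
# serialisation stay trivial.

new_param <- function(params, name, dims, fan_in) {
  params[[paste0(name, "_W")]] <-
    matrix(rnorm(prod(dims), 0, sqrt(2 / fan_in)), dims[1], dims[2])
  params[[paste0(name, "_b")]] <- numeric(dims[1])
  params
}

conv_layer <- function(name, ic, oc, k, stride) {
  list(type = "conv", name = name, ic = ic, oc = oc, k = k, stride = stride)
}
dense_layer <- function(name, n_in, n_out) {
  list(type = "dense", name = name, n_in = n_in, n_out = n_out)
}
relu_layer <- function() list(type = "relu")
maxpool_layer <- function(width) list(type = "maxpool", width = width)
flatten_layer <- function() list(type = "flatten")

conv_out_len <- function(L, k, stride) (L - k) %/% stride + 1L

# Forward one chain; returns list(out, cache) where cache[[i]] stores what
# the backward pass needs for layer i.
chain_forward <- function(layers, params, x, keep_cache = TRUE) {
  cache <- if (keep_cache) vector("list", length(layers)) else NULL
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    if (ly$type == "conv") {
      if (keep_cache) cache[[i]] <- list(x = x)
      x <- .conv1d_fwd(x, params[[paste0(ly$name, "_W")]],
                       params[[paste0(ly$name, "_b")]], ly$stride, ly$k)
    } else if (ly$type == "relu") {
      if (keep_cache) cache[[i]] <- list(mask = x > 0)
      x <- pmax(x, 0)
    } else if (ly$type == "maxpool") {
      mp <- .maxpool1d_fwd(x, ly$width)
      if (keep_cache) cache[[i]] <- list(idx = mp$idx, in_len = dim(x)[2])
      x <- mp$y
    } else if (ly$type == "flatten") {
      d <- dim(x)
      if (keep_cache) cache[[i]] <- list(dims = d)
      x <- matrix(x, d[1] * d[2], d[3])
    } else if (ly$type == "dense") {
      if (keep_cache) cache[[i]] <- list(x = x)
      x <- params[[paste0(ly$name, "_W")]] %*% x + params[[paste0(ly$name, "_b")]]
    } else stop("unknown layer type ", ly$type)
  }
  list(out = x, cache = cache)
}

# Backward one chain; accumulates parameter gradients into `grads`
# (an environment used as a mutable accumulator) and returns d(input)
# when need_dx is TRUE.
chain_backward <- function(layers, params, cache, dy, grads, need_dx = FALSE) {
  for (i in rev(seq_along(layers))) {
    ly <- layers[[i]]
    last <- i == 1L
    if (ly$type == "conv") {
      bw <- .conv1d_bwd(cache[[i]]$x, params[[paste0(ly$name, "_W")]],
                        dy, ly$stride, ly$k, need_dx || !last)
      gW <- paste0(ly$name, "_W"); gb <- paste0(ly$name, "_b")
      grads[[gW]] <- if (is.null(grads[[gW]])) bw$dW else grads[[gW]] + bw$dW
      grads[[gb]] <- if (is.null(grads[[gb]])) bw$db else grads[[gb]] + bw$db
      dy <- bw$dx
      if (last && !need_dx) return(invisible(NULL))
    } else if (ly$type == "relu") {
      dy <- dy * cache[[i]]$mask
    } else if (ly$type == "maxpool") {
      dy <- .maxpool1d_bwd(dy, cache[[i]]$idx, cache[[i]]$in_len)
    } else if (ly$type == "flatten") {
      dy <- array(dy, cache[[i]]$dims)
    } else if (ly$type == "dense") {
      x <- cache[[i]]$x
      W <- params[[paste0(ly$name, "_W")]]
      gW <- paste0(ly$name, "_W"); gb <- paste0(ly$name, "_b")
      dW <- dy %*% t(x)
      grads[[gW]] <- if (is.null(grads[[gW]])) dW else grads[[gW]] + dW
      db <- rowSums(dy)
      grads[[gb]] <- if (is.null(grads[[gb]])) db else grads[[gb]] + db
      if (!last || need_dx) dy <- t(W) %*% dy else return(invisible(NULL))
    }
  }
  dy
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# Full network forward. x: [8 x L x B] array; tab: [p x B] matrix or NULL.
net_forward <- function(net, x, tab = NULL, keep_cache = FALSE) {
  tr <- chain_forward(net$trunk, net$params, x, keep_cache)
  emb <- tr$out
  tb <- NULL
  h <- emb
  if (!is.null(net$tab_layers)) {
    stopifnot(!is.null(tab))
    tb <- chain_forward(net$tab_layers, net$params, tab, keep_cache)
    h <- rbind(emb, tb$out)
  }
  hd <- chain_forward(net$head, net$params, h, keep_cache)
  list(logit = hd$out, embedding = emb,
       cache = if (keep_cache) list(trunk = tr$cache,
                                    tab = if (!is.null(tb)) tb$cache,
                                    head = hd$cache,
                                    emb_dim = nrow(emb)))
}

# Backward from d(logit); returns d(signal input) when need_dx.
net_backward <- function(net, cache, dlogit, grads, need_dx = FALSE) {
  dh <- chain_backward(net$head, net$params, cache$head, dlogit, grads,
                       need_dx = TRUE)
  if (!is.null(net$tab_layers)) {
    demb <- dh[seq_len(cache$emb_dim), , drop = FALSE]
    dtab <- dh[-seq_len(cache$emb_dim), , drop = FALSE]
    chain_backward(net$tab_layers, net$params, cache$tab, dtab, grads,
                   need_dx = FALSE)
  } else {
    demb <- dh
  }
  chain_backward(net$trunk, net$params, cache$trunk, demb, grads,
                 need_dx = need_dx)
}

n_params <- function(net) sum(vapply(net$params, length, numeric(1)))

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    upd <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    # gradients for bias vectors arrive as column matrices; keep the
    # parameter's original shape so repeated steps do not mutate it
    attributes(upd) <- attributes(params[[nm]])
    params[[nm]] <- upd
  }
  list(params = params, state = state)
}

# Stack a list of [8 x L] matrices into an [8 x L x B] array.
batch_cube <- function(signal_list, idx) {
  b <- signal_list[idx]
  array(unlist(b, use.names = FALSE),
        dim = c(nrow(b[[1]]), ncol(b[[1]]), length(b)))
}

# Weighted binary cross-entropy on logits; returns loss and d(logit).
bce_loss <- function(logit, y, w) {
  p <- sigmoid(logit)
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  loss <- -mean(w * (y * log(p) + (1 - y) * log(1 - p)))
  dlogit <- matrix(w * (p - y) / length(y), 1L)
  list(loss = loss, dlogit = dlogit)
}
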