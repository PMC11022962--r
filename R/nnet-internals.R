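# Batched network internals: forward with cache, exact backprop, parameter
# flattening. All segment tensors in a batch share the graph, so the
# B segments x n nodes are packed into (n*B)-row matrices with the channel
# index varying fastest; S and pooling then act blockwise via reshapes.

.sigmoid <- function(x) 1 / (1 + exp(-x))

# (n, t, d, B) array -> list over time of (n*B x d) step-input matrices
.step_inputs <- function(arr) {
  dm <- dim(arr)
  n <- dm[1]; tt <- dm[2]; d <- dm[3]; B <- dm[4]
  lapply(seq_len(tt), function(j) {
    sl <- arr[, j, , , drop = FALSE]
    dim(sl) <- c(n, d, B)
    m <- aperm(sl, c(1, 3, 2))
    dim(m) <- c(n * B, d)
    m
  })
}

# list of feature tensors (or one) -> (n, t, d, B) array
.stack_tensors <- function(tensors) {
  if (inherits(tensors, "feature_tensor") || is.array(tensors) &&
      !is.list(tensors)) tensors <- list(tensors)
  d1 <- dim(tensors[[1]])
  arr <- vapply(tensors, function(x) {
    if (anyNA(x) || any(!is.finite(x)))
      stop("feature tensor contains NaN/Inf; refuse to run the recurrence")
    array(as.numeric(x), dim = d1)
  }, array(0, dim = d1))
  dim(arr) <- c(d1, length(tensors))
  arr
}

# One LSTM direction over the step list; returns final hidden + cache.
.lstm_dir_forward <- function(xs, p) {
  N <- nrow(xs[[1]])
  h <- nrow(p$Wh)
  ii <- seq_len(h); ff <- h + ii; oo <- 2 * h + ii; gg <- 3 * h + ii
  hc <- matrix(0, N, h); cc <- matrix(0, N, h)
  cache <- vector("list", length(xs))
  for (j in seq_along(xs)) {
    z <- xs[[j]] %*% p$Wx + hc %*% p$Wh
    z <- z + rep(p$b, each = N)
    i <- .sigmoid(z[, ii, drop = FALSE])
    f <- .sigmoid(z[, ff, drop = FALSE])
    o <- .sigmoid(z[, oo, drop = FALSE])
    g <- tanh(z[, gg, drop = FALSE])
    cprev <- cc
    cc <- f * cprev + i * g
    tc <- tanh(cc)
    cache[[j]] <- list(x = xs[[j]], hprev = hc, cprev = cprev,
                       i = i, f = f, o = o, g = g, tc = tc)
    hc <- o * tc
  }
  list(h = hc, cache = cache)
}

# BPTT for one direction given the gradient on the final hidden state.
.lstm_dir_backward <- function(dh, cache, p) {
  dWx <- p$Wx * 0; dWh <- p$Wh * 0; db <- p$b * 0
  dc <- dh * 0
  for (j in rev(seq_along(cache))) {
    st <- cache[[j]]
    dc <- dc + dh * st$o * (1 - st$tc^2)
    do <- dh * st$tc
    di <- dc * st$g
    dg <- dc * st$i
    df <- dc * st$cprev
    dz <- cbind(di * st$i * (1 - st$i),
                df * st$f * (1 - st$f),
                do * st$o * (1 - st$o),
                dg * (1 - st$g^2))
    dWx <- dWx + crossprod(st$x, dz)
    dWh <- dWh + crossprod(st$hprev, dz)
    db <- db + colSums(dz)
    dh <- dz %*% t(p$Wh)
    dc <- dc * st$f
  }
  list(Wx = dWx, Wh = dWh, b = db)
}

# Apply S per segment: H is (n*B x d) with channel index fastest.
.seg_matmul <- function(S, H, n, B) {
  d <- ncol(H)
  m <- H
  dim(m) <- c(n, B * d)
  out <- S %*% m
  dim(out) <- c(n * B, d)
  out
}

# Blockwise pooling with cache for backprop; groups have 1 or 2 members.
.pool_forward <- function(H, asg, n, B, reducer) {
  d <- ncol(H)
  m <- max(asg)
  out <- matrix(0, m * B, d)
  groups <- split(seq_len(n), asg)
  masks <- vector("list", m)
  offs_in <- (seq_len(B) - 1L) * n
  offs_out <- (seq_len(B) - 1L) * m
  for (g in seq_len(m)) {
    mem <- groups[[g]]
    rows_out <- offs_out + g
    if (length(mem) == 1L) {
      out[rows_out, ] <- H[offs_in + mem, , drop = FALSE]
    } else {
      h1 <- H[offs_in + mem[1], , drop = FALSE]
      h2 <- H[offs_in + mem[2], , drop = FALSE]
      if (reducer == "max") {
        mask <- h1 >= h2
        out[rows_out, ] <- h1 * mask + h2 * !mask
        masks[[g]] <- mask
      } else {
        out[rows_out, ] <- (h1 + h2) / 2
      }
    }
  }
  list(out = out, m = m, groups = groups, masks = masks, reducer = reducer)
}

.pool_backward <- function(dOut, pc, n, B) {
  d <- ncol(dOut)
  dH <- matrix(0, n * B, d)
  offs_in <- (seq_len(B) - 1L) * n
  offs_out <- (seq_len(B) - 1L) * pc$m
  for (g in seq_len(pc$m)) {
    mem <- pc$groups[[g]]
    dg <- dOut[offs_out + g, , drop = FALSE]
    if (length(mem) == 1L) {
      dH[offs_in + mem, ] <- dg
    } else if (pc$reducer == "max") {
      dH[offs_in + mem[1], ] <- dg * pc$masks[[g]]
      dH[offs_in + mem[2], ] <- dg * !pc$masks[[g]]
    } else {
      dH[offs_in + mem[1], ] <- dg / 2
      dH[offs_in + mem[2], ] <- dg / 2
    }
  }
  dH
}

# (n*B x d) node features -> (B x n*d) flat per-segment rows (and inverse)
.flatten_nodes <- function(H, n, B) {
  d <- ncol(H)
  a <- H
  dim(a) <- c(n, B, d)
  a <- aperm(a, c(1, 3, 2))
  dim(a) <- c(n * d, B)
  t(a)
}

.unflatten_nodes <- function(F_, n, B) {
  d <- ncol(F_) / n
  a <- t(F_)
  dim(a) <- c(n, d, B)
  a <- aperm(a, c(1, 3, 2))
  dim(a) <- c(n * B, d)
  a
}

# Full forward pass with cache. `training` enables dropout via the R RNG.
.net_forward <- function(arr, params, gstack, config, training = FALSE) {
  dm <- dim(arr)
  n <- dm[1]; B <- dm[4]
  xs <- .step_inputs(arr)
  fwd <- .lstm_dir_forward(xs, params$lstm$fwd)
  bwd <- .lstm_dir_forward(rev(xs), params$lstm$bwd)
  H <- cbind(fwd$h, bwd$h)
  L <- length(params$gcn)
  gcache <- vector("list", L)
  pcache <- vector("list", L)
  ncur <- n
  for (l in seq_len(L)) {
    S <- gstack$S[[l]]
    SH <- .seg_matmul(S, H, ncur, B)
    Z <- SH %*% params$gcn[[l]]$W
    Z <- Z + rep(params$gcn[[l]]$b, each = nrow(Z))
    A <- brelu(Z, config$brelu_cap)
    gcache[[l]] <- list(SH = SH, Z = Z, S = S, n = ncur)
    pc <- .pool_forward(A, gstack$assignment[[l]], ncur, B,
                        config$pool_reducer)
    pcache[[l]] <- pc
    H <- pc$out
    ncur <- pc$m
  }
  F_ <- .flatten_nodes(H, ncur, B)
  if (training && config$dropout > 0) {
    keep <- 1 - config$dropout
    mask <- matrix(stats::runif(length(F_)) < keep, nrow(F_), ncol(F_)) / keep
    Fd <- F_ * mask
  } else {
    mask <- NULL
    Fd <- F_
  }
  logits <- Fd %*% params$dense$W
  logits <- logits + rep(params$dense$b, each = B)
  mx <- apply(logits, 1, max)
  e <- exp(logits - mx)
  probs <- e / rowSums(e)
  list(probs = probs,
       cache = list(fwd = fwd, bwd = bwd, gcache = gcache, pcache = pcache,
                    Fd = Fd, mask = mask, n = n, B = B, n_final = ncur,
                    h = ncol(fwd$h)))
}

# Exact gradient of (weighted) mean cross-entropy + lambda * sum(theta^2).
.net_backward <- function(fc, y_onehot, params, config, lambda,
                          sample_w = NULL) {
  cc <- fc$cache
  B <- cc$B
  dlogits <- (fc$probs - y_onehot) / B
  if (!is.null(sample_w)) dlogits <- dlogits * sample_w
  gd <- params   # same structure, overwritten below
  gd$dense$W <- crossprod(cc$Fd, dlogits)
  gd$dense$b <- colSums(dlogits)
  dFd <- tcrossprod(dlogits, params$dense$W)
  dF <- if (is.null(cc$mask)) dFd else dFd * cc$mask
  dH <- .unflatten_nodes(dF, cc$n_final, B)
  for (l in rev(seq_along(params$gcn))) {
    gl <- cc$gcache[[l]]
    dA <- .pool_backward(dH, cc$pcache[[l]], gl$n, B)
    dZ <- dA * (gl$Z > 0 & gl$Z < config$brelu_cap)
    gd$gcn[[l]]$W <- crossprod(gl$SH, dZ)
    gd$gcn[[l]]$b <- colSums(dZ)
    dSH <- tcrossprod(dZ, params$gcn[[l]]$W)
    dH <- .seg_matmul(t(gl$S), dSH, gl$n, B)
  }
  h <- cc$h
  gd$lstm$fwd <- .lstm_dir_backward(dH[, seq_len(h), drop = FALSE],
                                    cc$fwd$cache, params$lstm$fwd)
  gd$lstm$bwd <- .lstm_dir_backward(dH[, h + seq_len(h), drop = FALSE],
                                    cc$bwd$cache, params$lstm$bwd)
  if (lambda > 0) {
    flat <- .param_flatten(gd) + 2 * lambda * .param_flatten(params)
    gd <- .param_unflatten(flat, gd)
  }
  gd
}

# Loss + gradient for one minibatch (used by the optimiser and the
# finite-difference gradient check).
.net_loss_grad <- function(arr, labels, params, gstack, config, lambda,
                           training = FALSE, sample_w = NULL) {
  fc <- .net_forward(arr, params, gstack, config, training = training)
  y <- .one_hot(labels, ncol(fc$probs))
  ce <- -rowSums(y * log(pmax(fc$probs, 1e-12)))
  if (!is.null(sample_w)) ce <- ce * sample_w
  loss <- mean(ce) + lambda * sum(.param_flatten(params)^2)
  list(loss = loss,
       grad = .net_backward(fc, y, params, config, lambda, sample_w),
       probs = fc$probs)
}

# Depth-first parameter flattening (order matches unlist()).
.param_flatten <- function(p) unlist(p, use.names = FALSE)

.param_unflatten <- function(v, template) {
  pos <- 0L
  walk <- function(x) {
    if (is.list(x)) return(lapply(x, walk))
    len <- length(x)
    out <- v[pos + seq_len(len)]
    pos <<- pos + len
    attributes(out) <- attributes(x)
    out
  }
  out <- walk(template)
  class(out) <- class(template)
  out
}
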