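# Minimal neural-network engine: 1-D valid convolution over time with the
# channel dimension fully connected, ReLU, post-activation batch
# normalization, dense layers, inverted dropout, softmax cross-entropy and
# Adam. Everything is vectorized over the batch with BLAS matrix products;
# the convolution loops only over the H kernel offsets.
#
# Layer objects are plain lists:
#   conv:    kind, w (H x C x F), b (F), gamma/beta/run_mean/run_var (F), stride, H
#   dense:   kind, w (in x out), b (out), activation ("relu"/"linear")
#   dropout: kind, rate
# Batch inputs are arrays (B, L, C) for conv stacks or matrices (B, D) for
# dense heads.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.9

xavier_uniform <- function(dims, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -lim, lim), dim = dims)
}

new_conv_layer <- function(H, C, Fout, stride) {
  list(kind = "conv",
       w = xavier_uniform(c(H, C, Fout), fan_in = H * C, fan_out = H * Fout),
       b = numeric(Fout),
       gamma = rep(1, Fout), beta = numeric(Fout),
       run_mean = numeric(Fout), run_var = rep(1, Fout),
       stride = as.integer(stride), H = as.integer(H))
}

new_dense_layer <- function(n_in, n_out, activation = "relu") {
  list(kind = "dense",
       w = xavier_uniform(c(n_in, n_out), fan_in = n_in, fan_out = n_out),
       b = numeric(n_out), activation = activation)
}

new_dropout_layer <- function(rate) list(kind = "dropout", rate = rate)

conv1d_forward <- function(x, w, b, stride) {
  d <- dim(x); B <- d[1]; L <- d[2]; C <- d[3]
  H <- dim(w)[1]; Fout <- dim(w)[3]
  N <- (L - H) %/% stride + 1L
  pos0 <- seq.int(0L, by = stride, length.out = N)
  ymat <- matrix(b, nrow = B * N, ncol = Fout, byrow = TRUE)
  for (h in seq_len(H)) {
    xs <- x[, pos0 + h, , drop = FALSE]
    dim(xs) <- c(B * N, C)
    ymat <- ymat + xs %*% matrix(w[h, , ], nrow = C)
  }
  dim(ymat) <- c(B, N, Fout)
  ymat
}

conv1d_backward <- function(dy, x, w, stride) {
  d <- dim(x); B <- d[1]; C <- d[3]
  H <- dim(w)[1]; Fout <- dim(w)[3]
  N <- dim(dy)[2]
  pos0 <- seq.int(0L, by = stride, length.out = N)
  dym <- dy; dim(dym) <- c(B * N, Fout)
  dx <- array(0, dim = d)
  dw <- array(0, dim = dim(w))
  for (h in seq_len(H)) {
    idx <- pos0 + h
    xs <- x[, idx, , drop = FALSE]; dim(xs) <- c(B * N, C)
    dw[h, , ] <- crossprod(xs, dym)
    dxs <- tcrossprod(dym, matrix(w[h, , ], nrow = C))
    dim(dxs) <- c(B, N, C)
    dx[, idx, ] <- dx[, idx, , drop = FALSE] + dxs
  }
  list(dx = dx, dw = dw, db = colSums(dym))
}

# Forward pass through a layer list. In training mode batch-norm uses batch
# statistics (returned in the caches so the caller can update running
# averages) and dropout is active; in inference mode running statistics are
# used and dropout is the identity.
layers_forward <- function(layers, x, train) {
  caches <- vector("list", length(layers))
  for (li in seq_along(layers)) {
    ly <- layers[[li]]
    if (ly$kind == "conv") {
      z <- conv1d_forward(x, ly$w, ly$b, ly$stride)
      a <- z; a[a < 0] <- 0                      # ReLU, then batch norm
      d <- dim(a)
      amat <- a; dim(amat) <- c(d[1] * d[2], d[3])
      if (train) {
        mu <- colMeans(amat)
        xc <- sweep(amat, 2, mu)
        v <- colMeans(xc * xc)
        istd <- 1 / sqrt(v + BN_EPS)
        xhat <- sweep(xc, 2, istd, "*")
      } else {
        mu <- ly$run_mean; v <- ly$run_var
        istd <- 1 / sqrt(v + BN_EPS)
        xhat <- sweep(sweep(amat, 2, mu), 2, istd, "*")
      }
      out <- sweep(sweep(xhat, 2, ly$gamma, "*"), 2, ly$beta, "+")
      dim(out) <- d
      caches[[li]] <- list(x = x, z = z, xhat = xhat, istd = istd, dims = d,
                           batch_mu = mu, batch_var = v)
      x <- out
    } else if (ly$kind == "dense") {
      flat_dim <- NULL
      if (length(dim(x)) == 3) {                 # flatten conv features
        flat_dim <- dim(x)
        dim(x) <- c(flat_dim[1], flat_dim[2] * flat_dim[3])
      }
      z <- sweep(x %*% ly$w, 2, ly$b, "+")
      caches[[li]] <- list(x = x, z = z, flat_dim = flat_dim)
      x <- if (ly$activation == "relu") pmax(z, 0) else z
    } else if (ly$kind == "dropout") {
      if (train && ly$rate > 0) {
        mask <- (matrix(stats::runif(length(x)), nrow(x)) >= ly$rate) / (1 - ly$rate)
        caches[[li]] <- list(mask = mask)
        x <- x * mask
      }
    } else stop("unknown layer kind: ", ly$kind)
  }
  list(out = x, caches = caches)
}

layers_backward <- function(layers, caches, dout) {
  grads <- vector("list", length(layers))
  for (li in rev(seq_along(layers))) {
    ly <- layers[[li]]; cc <- caches[[li]]
    if (ly$kind == "dropout") {
      if (!is.null(cc$mask)) dout <- dout * cc$mask
    } else if (ly$kind == "dense") {
      dz <- if (ly$activation == "relu") dout * (cc$z > 0) else dout
      grads[[li]] <- list(w = crossprod(cc$x, dz), b = colSums(dz))
      dout <- tcrossprod(dz, ly$w)
      if (!is.null(cc$flat_dim)) dim(dout) <- cc$flat_dim
    } else if (ly$kind == "conv") {
      d <- cc$dims
      dy <- dout; dim(dy) <- c(d[1] * d[2], d[3])
      grads_gamma <- colSums(dy * cc$xhat)
      grads_beta <- colSums(dy)
      dxhat <- sweep(dy, 2, ly$gamma, "*")
      da <- sweep(dxhat, 2, colMeans(dxhat)) -
        sweep(cc$xhat, 2, colMeans(dxhat * cc$xhat), "*")
      da <- sweep(da, 2, cc$istd, "*")
      dim(da) <- d
      da <- da * (cc$z > 0)                      # back through ReLU
      cb <- conv1d_backward(da, cc$x, ly$w, ly$stride)
      grads[[li]] <- list(w = cb$dw, b = cb$db,
                          gamma = grads_gamma, beta = grads_beta)
      dout <- cb$dx
    }
  }
  grads
}

softmax_rows <- function(logits) {
  z <- logits - apply(logits, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Average categorical cross-entropy and gradient wrt logits.
softmax_ce <- function(logits, y1) {
  n <- nrow(logits)
  p <- softmax_rows(logits)
  loss <- -mean(log(pmax(p[cbind(seq_len(n), y1)], 1e-12)))
  dlogits <- p
  dlogits[cbind(seq_len(n), y1)] <- dlogits[cbind(seq_len(n), y1)] - 1
  list(loss = loss, dlogits = dlogits / n, prob = p)
}

adam_init <- function(layers) {
  lapply(layers, function(ly) {
    pn <- switch(ly$kind, conv = c("w", "b", "gamma", "beta"),
                 dense = c("w", "b"), NULL)
    if (is.null(pn)) return(NULL)
    st <- lapply(pn, function(p) list(m = array(0, dim = dim(ly[[p]]) %||% length(ly[[p]])),
                                      v = array(0, dim = dim(ly[[p]]) %||% length(ly[[p]]))))
    names(st) <- pn
    st
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_step <- function(layers, grads, opt, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (li in seq_along(layers)) {
    g <- grads[[li]]
    if (is.null(g)) next
    for (pn in names(g)) {
      m <- beta1 * opt[[li]][[pn]]$m + (1 - beta1) * g[[pn]]
      v <- beta2 * opt[[li]][[pn]]$v + (1 - beta2) * g[[pn]]^2
      opt[[li]][[pn]]$m <- m
      opt[[li]][[pn]]$v <- v
      mhat <- m / (1 - beta1^t)
      vhat <- v / (1 - beta2^t)
      layers[[li]][[pn]] <- layers[[li]][[pn]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(layers = layers, opt = opt)
}

slice_rows <- function(x, idx) {
  if (length(dim(x)) == 3) x[idx, , , drop = FALSE] else x[idx, , drop = FALSE]
}

# Mini-batch training loop shared by single-modal networks and fused heads.
# Assumes the RNG has already been seeded by the caller.
train_layers <- function(layers, x, y1, config) {
  n <- if (length(dim(x)) == 3) dim(x)[1] else nrow(x)
  abort_if(n == 0, "training set is empty")
  val_idx <- integer(0)
  if (config$validation_split > 0) {
    val_idx <- sample.int(n, max(1L, round(config$validation_split * n)))
  }
  tr_idx <- setdiff(seq_len(n), val_idx)
  opt <- adam_init(layers)
  step <- 0L
  history <- numeric(0)
  val_history <- numeric(0)
  best_val <- Inf; best_layers <- layers; since_best <- 0L
  for (epoch in seq_len(config$epochs)) {
    ord <- tr_idx[sample.int(length(tr_idx))]
    batch_losses <- numeric(0)
    for (b0 in seq(1, length(ord), by = config$batch_size)) {
      bidx <- ord[b0:min(b0 + config$batch_size - 1L, length(ord))]
      fw <- layers_forward(layers, slice_rows(x, bidx), train = TRUE)
      ce <- softmax_ce(fw$out, y1[bidx])
      batch_losses <- c(batch_losses, ce$loss)
      grads <- layers_backward(layers, fw$caches, ce$dlogits)
      step <- step + 1L
      upd <- adam_step(layers, grads, opt, lr = config$learning_rate, t = step)
      layers <- upd$layers; opt <- upd$opt
      for (li in seq_along(layers)) {           # running batch-norm stats
        if (layers[[li]]$kind == "conv") {
          cc <- fw$caches[[li]]
          layers[[li]]$run_mean <- BN_MOMENTUM * layers[[li]]$run_mean +
            (1 - BN_MOMENTUM) * cc$batch_mu
          layers[[li]]$run_var <- BN_MOMENTUM * layers[[li]]$run_var +
            (1 - BN_MOMENTUM) * cc$batch_var
        }
      }
    }
    history <- c(history, mean(batch_losses))
    if (length(val_idx) > 0) {
      fwv <- layers_forward(layers, slice_rows(x, val_idx), train = FALSE)
      vloss <- softmax_ce(fwv$out, y1[val_idx])$loss
      val_history <- c(val_history, vloss)
      if (!is.null(config$early_stopping_patience)) {
        if (vloss < best_val - 1e-6) {
          best_val <- vloss; best_layers <- layers; since_best <- 0L
        } else {
          since_best <- since_best + 1L
          if (since_best >= config$early_stopping_patience) {
            layers <- best_layers
            break
          }
        }
      }
    }
    if (isTRUE(config$verbose))
      message(sprintf("epoch %d: loss %.4f%s", epoch, mean(batch_losses),
                      if (length(val_history)) sprintf(" val %.4f", utils::tail(val_history, 1)) else ""))
  }
  list(layers = layers, history = history, val_history = val_history)
}
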