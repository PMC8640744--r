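# Minimal feed-forward network engine with reverse-mode gradients, written
# against base R matrix ops. Deep-learning frameworks are deliberately not a
# dependency here: the architectures needed are small and fixed (dense,
# 1-D valid convolution, order-independent graph convolution), gradients with
# respect to *inputs* are required for integrated gradients, and everything
# must be bit-reproducible from a seed on CPU.
#
# Conventions:
#   - batch input is either an array of dim c(n, L, F) or, after a flatten
#     layer, an n x features matrix;
#   - a network is a list of layers, each a list with a $kind tag and any
#     parameters; the final layer is a dense layer with one output unit;
#   - forward passes return per-layer caches so a single backward sweep
#     yields both parameter gradients and input gradients.

.init_mat <- function(nr, nc, fan_in) {
  s <- sqrt(1 / fan_in)
  matrix(stats::runif(nr * nc, -s, s), nr, nc)
}

layer_flatten <- function() list(kind = "flatten")
layer_dense <- function(n_in, n_out)
  list(kind = "dense", W = .init_mat(n_in, n_out, n_in), b = numeric(n_out))
layer_leaky_relu <- function(slope = 0.2)
  list(kind = "leaky_relu", slope = slope)
layer_dropout <- function(p = 0.2) list(kind = "dropout", p = p)
layer_seq_conv <- function(k, f_in, f_out)
  list(kind = "seq_conv", k = as.integer(k), f_in = f_in, f_out = f_out,
       W = .init_mat(k * f_in, f_out, k * f_in), b = numeric(f_out))
layer_graph_conv <- function(f_in, f_out, A) {
  stopifnot(is.matrix(A), nrow(A) == ncol(A))
  list(kind = "graph_conv", f_in = f_in, f_out = f_out, A = A,
       W_C = .init_mat(f_in, f_out, f_in),
       W_N = .init_mat(f_in, f_out, f_in),
       b = numeric(f_out))
}

.param_names <- function(layer) {
  switch(layer$kind,
         dense = c("W", "b"),
         seq_conv = c("W", "b"),
         graph_conv = c("W_C", "W_N", "b"),
         character(0))
}

# (L, n, F)-permuted matrix product used by graph convolution:
# applies M (L x L) to every sample's L x F feature block.
.apply_over_positions <- function(M, X) {
  d <- dim(X) # n, L, F
  P <- aperm(X, c(2L, 1L, 3L))
  dim(P) <- c(d[2], d[1] * d[3])
  Q <- M %*% P
  dim(Q) <- c(d[2], d[1], d[3])
  aperm(Q, c(2L, 1L, 3L))
}

# im2col for 1-D valid convolution: returns (n*L_out) x (k*F) matrix whose
# row (p-1)*n + s holds the window of sample s at output position p.
.im2col <- function(X, k) {
  d <- dim(X) # n, L, F
  L_out <- d[2] - k + 1L
  C <- array(0, dim = c(d[1], L_out, k * d[3]))
  for (j in seq_len(k))
    C[, , (seq_len(d[3]) - 1L) * k + j] <- X[, j:(j + L_out - 1L), , drop = FALSE]
  dim(C) <- c(d[1] * L_out, k * d[3])
  C
}

.col2im <- function(dC, n, L, Fin, k) {
  L_out <- L - k + 1L
  dim(dC) <- c(n, L_out, k * Fin)
  dX <- array(0, dim = c(n, L, Fin))
  for (j in seq_len(k))
    dX[, j:(j + L_out - 1L), ] <- dX[, j:(j + L_out - 1L), , drop = FALSE] +
      dC[, , (seq_len(Fin) - 1L) * k + j, drop = FALSE]
  dX
}

.layer_forward <- function(layer, X, train) {
  switch(layer$kind,
    flatten = {
      if (is.matrix(X)) list(out = X, cache = list(dims = dim(X)))
      else {
        d <- dim(X)
        list(out = matrix(X, nrow = d[1]), cache = list(dims = d))
      }
    },
    dense = {
      Y <- X %*% layer$W
      Y <- sweep(Y, 2L, layer$b, "+")
      list(out = Y, cache = list(X = X))
    },
    leaky_relu = {
      neg <- X < 0
      Y <- X
      Y[neg] <- layer$slope * Y[neg]
      list(out = Y, cache = list(neg = neg))
    },
    dropout = {
      if (!train) return(list(out = X, cache = list(mask = NULL)))
      keep <- 1 - layer$p
      mask <- (stats::runif(length(X)) < keep) / keep
      if (!is.null(dim(X))) dim(mask) <- dim(X)
      list(out = X * mask, cache = list(mask = mask))
    },
    seq_conv = {
      d <- dim(X)
      if (d[2] < layer$k)
        stop("sequence length ", d[2], " shorter than kernel ", layer$k)
      M <- .im2col(X, layer$k)
      Y <- M %*% layer$W
      Y <- sweep(Y, 2L, layer$b, "+")
      L_out <- d[2] - layer$k + 1L
      dim(Y) <- c(d[1], L_out, layer$f_out)
      list(out = Y, cache = list(M = M, dims = d))
    },
    graph_conv = {
      d <- dim(X)
      if (d[2] != nrow(layer$A))
        stop("graph has ", nrow(layer$A), " nodes but input has ",
             d[2], " positions")
      Xn <- .apply_over_positions(layer$A, X)
      Mc <- X; dim(Mc) <- c(d[1] * d[2], d[3])
      Mn <- Xn; dim(Mn) <- c(d[1] * d[2], d[3])
      Y <- Mc %*% layer$W_C + Mn %*% layer$W_N
      Y <- sweep(Y, 2L, layer$b, "+")
      dim(Y) <- c(d[1], d[2], layer$f_out)
      list(out = Y, cache = list(Mc = Mc, Mn = Mn, dims = d))
    },
    stop("unknown layer kind: ", layer$kind))
}

.layer_backward <- function(layer, cache, dY) {
  switch(layer$kind,
    flatten = {
      dX <- dY
      if (length(cache$dims) == 3L) dim(dX) <- cache$dims
      list(dX = dX, grads = NULL)
    },
    dense = {
      list(dX = dY %*% t(layer$W),
           grads = list(W = crossprod(cache$X, dY), b = colSums(dY)))
    },
    leaky_relu = {
      dX <- dY
      dX[cache$neg] <- layer$slope * dX[cache$neg]
      list(dX = dX, grads = NULL)
    },
    dropout = {
      if (is.null(cache$mask)) list(dX = dY, grads = NULL)
      else list(dX = dY * cache$mask, grads = NULL)
    },
    seq_conv = {
      d <- cache$dims
      L_out <- d[2] - layer$k + 1L
      dYm <- dY; dim(dYm) <- c(d[1] * L_out, layer$f_out)
      dW <- crossprod(cache$M, dYm)
      db <- colSums(dYm)
      dM <- dYm %*% t(layer$W)
      list(dX = .col2im(dM, d[1], d[2], d[3], layer$k),
           grads = list(W = dW, b = db))
    },
    graph_conv = {
      d <- cache$dims
      dYm <- dY; dim(dYm) <- c(d[1] * d[2], layer$f_out)
      dW_C <- crossprod(cache$Mc, dYm)
      dW_N <- crossprod(cache$Mn, dYm)
      db <- colSums(dYm)
      dXc <- dYm %*% t(layer$W_C); dim(dXc) <- d
      dXn <- dYm %*% t(layer$W_N); dim(dXn) <- d
      dX <- dXc + .apply_over_positions(t(layer$A), dXn)
      list(dX = dX, grads = list(W_C = dW_C, W_N = dW_N, b = db))
    },
    stop("unknown layer kind: ", layer$kind))
}

# Full forward pass. Returns predictions (numeric vector), per-layer caches
# and per-layer outputs (for latent extraction).
nn_forward <- function(layers, X, train = FALSE, keep_outputs = FALSE) {
  caches <- vector("list", length(layers))
  outputs <- if (keep_outputs) vector("list", length(layers)) else NULL
  cur <- X
  for (i in seq_along(layers)) {
    fw <- .layer_forward(layers[[i]], cur, train)
    caches[[i]] <- fw$cache
    cur <- fw$out
    if (keep_outputs) outputs[[i]] <- cur
  }
  list(pred = as.numeric(cur), caches = caches, outputs = outputs)
}

# Backward sweep from per-sample output gradients dout (n-vector).
# Returns input gradients and the list of per-layer parameter gradients.
nn_backward <- function(layers, caches, dout) {
  dY <- matrix(dout, ncol = 1L)
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    bw <- .layer_backward(layers[[i]], caches[[i]], dY)
    grads[i] <- list(bw$grads) # may be NULL; keep list alignment
    dY <- bw$dX
  }
  list(dX = dY, grads = grads)
}

.adam_init <- function(layers) {
  lapply(layers, function(layer) {
    nm <- .param_names(layer)
    if (length(nm) == 0L) return(NULL)
    st <- lapply(nm, function(p) list(m = layer[[p]] * 0, v = layer[[p]] * 0))
    names(st) <- nm
    st
  })
}

.adam_step <- function(layers, grads, state, lr, t,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (i in seq_along(layers)) {
    nm <- .param_names(layers[[i]])
    for (p in nm) {
      g <- grads[[i]][[p]]
      st <- state[[i]][[p]]
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g * g
      mhat <- st$m / (1 - beta1^t)
      vhat <- st$v / (1 - beta2^t)
      layers[[i]][[p]] <- layers[[i]][[p]] - lr * mhat / (sqrt(vhat) + eps)
      state[[i]][[p]] <- st
    }
  }
  list(layers = layers, state = state)
}

.slice_batch <- function(X, idx) {
  if (is.matrix(X)) X[idx, , drop = FALSE]
  else X[idx, , , drop = FALSE]
}

.mse <- function(pred, y) mean((pred - y)^2)

# Core training loop: Adam on minibatch MSE, epoch-level early stopping on
# the unweighted mean tuning loss, restoring the best-epoch parameters.
nn_fit <- function(layers, X, y, X_tune, y_tune,
                   lr = 0.001, batch_size = 128L, max_epochs = 300L,
                   patience = 15L, min_delta = 1e-5, seed = 1L,
                   verbose = FALSE) {
  n <- if (is.matrix(X)) nrow(X) else dim(X)[1]
  stopifnot(length(y) == n, patience < max_epochs)
  state <- .adam_init(layers)
  best <- list(loss = Inf, layers = layers, epoch = 0L)
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     tune_loss = numeric(0))
  t_global <- 0L
  wait <- 0L
  withr::with_seed(seed, {
    for (epoch in seq_len(max_epochs)) {
      ord <- sample.int(n)
      batch_losses <- numeric(0)
      for (start in seq(1L, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1L, n)]
        Xb <- .slice_batch(X, idx)
        yb <- y[idx]
        fw <- nn_forward(layers, Xb, train = TRUE)
        if (any(!is.finite(fw$pred)))
          stop("non-finite predictions at epoch ", epoch,
               "; reduce the learning rate")
        loss <- .mse(fw$pred, yb)
        batch_losses <- c(batch_losses, loss)
        dout <- 2 * (fw$pred - yb) / length(yb)
        bw <- nn_backward(layers, fw$caches, dout)
        t_global <- t_global + 1L
        upd <- .adam_step(layers, bw$grads, state, lr, t_global)
        layers <- upd$layers
        state <- upd$state
      }
      tune_loss <- .mse(nn_forward(layers, X_tune)$pred, y_tune)
      if (!is.finite(tune_loss))
        stop("non-finite tuning loss at epoch ", epoch)
      hist <- rbind(hist, data.frame(epoch = epoch,
                                     train_loss = mean(batch_losses),
                                     tune_loss = tune_loss))
      if (verbose)
        message(sprintf("epoch %3d train %.5f tune %.5f", epoch,
                        mean(batch_losses), tune_loss))
      if (tune_loss < best$loss - min_delta) {
        best <- list(loss = tune_loss, layers = layers, epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= patience) break
      }
    }
  })
  list(layers = best$layers, history = hist, best_epoch = best$epoch,
       best_tune_loss = best$loss)
}
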