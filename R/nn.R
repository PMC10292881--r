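# Tabular-transformer internals: parameter initialization, forward pass
# with cache, analytic backpropagation, and the AdamW update. Parameters
# live in a flat named list of matrices/vectors so the optimizer and the
# checkpoint format stay trivial. Shapes:
#   emb_<j>        V_j x d        token embedding table, categorical col j
#   blk<b>_Wq/Wk/Wv/Wo  d x d     per-block attention weights (multi-head)
#   blk<b>_W1, blk<b>_b1          position-wise feedforward (ReLU, residual)
#   head<l>_W, head<l>_b          dense head (ELU), final layer linear

elu <- function(z) ifelse(z > 0, z, exp(pmin(z, 0)) - 1)
elu_grad <- function(z) ifelse(z > 0, 1, exp(pmin(z, 0)))
relu <- function(z) pmax(z, 0)

glorot <- function(nin, nout) {
  s <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -s, s), nin, nout)
}

init_params <- function(config, n_continuous, vocab_sizes, out_dim = 1) {
  d <- config$d_embed
  if (d < 1) stop("d_embed must be positive")
  if (d %% config$n_heads != 0)
    stop("d_embed must be a multiple of n_heads")
  local_seed(config$seed, {
    p <- list()
    for (j in seq_along(vocab_sizes))
      p[[paste0("emb_", j)]] <- matrix(stats::rnorm(vocab_sizes[j] * d, 0, 0.1),
                                       vocab_sizes[j], d)
    for (b in seq_len(config$n_blocks)) {
      p[[paste0("blk", b, "_Wq")]] <- glorot(d, d)
      p[[paste0("blk", b, "_Wk")]] <- glorot(d, d)
      p[[paste0("blk", b, "_Wv")]] <- glorot(d, d)
      p[[paste0("blk", b, "_Wo")]] <- glorot(d, d)
      p[[paste0("blk", b, "_W1")]] <- glorot(d, d)
      p[[paste0("blk", b, "_b1")]] <- numeric(d)
    }
    widths <- c(length(vocab_sizes) * d + n_continuous,
                config$head_hidden, out_dim)
    for (l in seq_len(length(widths) - 1)) {
      last <- l == length(widths) - 1
      p[[paste0("head", l, "_W")]] <-
        if (last) matrix(stats::rnorm(widths[l] * widths[l + 1], 0, 0.01),
                         widths[l], widths[l + 1])
        else glorot(widths[l], widths[l + 1])
      p[[paste0("head", l, "_b")]] <- numeric(widths[l + 1])
    }
    p
  })
}

attn_scale_value <- function(config) {
  dh <- config$d_embed / config$n_heads
  if (identical(config$attn_scale, "linear")) dh else sqrt(dh)
}

# Forward pass. X: n x D scaled continuous; Z: n x M integer token indices.
# Returns list(out, hidden = last pre-output activation, cache).
nn_forward <- function(params, X, Z, config, keep_cache = FALSE) {
  n <- nrow(X); M <- ncol(Z); d <- config$d_embed
  H <- config$n_heads; dh <- d / H
  scale <- attn_scale_value(config)
  A <- lapply(seq_len(M), function(j) params[[paste0("emb_", j)]][Z[, j], , drop = FALSE])
  cache <- list(A0 = A, blocks = list())
  for (b in seq_len(config$n_blocks)) {
    Wq <- params[[paste0("blk", b, "_Wq")]]; Wk <- params[[paste0("blk", b, "_Wk")]]
    Wv <- params[[paste0("blk", b, "_Wv")]]; Wo <- params[[paste0("blk", b, "_Wo")]]
    W1 <- params[[paste0("blk", b, "_W1")]]; b1 <- params[[paste0("blk", b, "_b1")]]
    Q <- lapply(A, function(a) a %*% Wq)
    K <- lapply(A, function(a) a %*% Wk)
    V <- lapply(A, function(a) a %*% Wv)
    attn <- vector("list", H)          # attn[[h]][[t1]]: n x M softmax rows
    O <- lapply(seq_len(M), function(t) matrix(0, n, d))
    for (h in seq_len(H)) {
      hd <- ((h - 1) * dh + 1):(h * dh)
      attn[[h]] <- vector("list", M)
      for (t1 in seq_len(M)) {
        S <- vapply(seq_len(M), function(t2)
          rowSums(Q[[t1]][, hd, drop = FALSE] * K[[t2]][, hd, drop = FALSE]),
          numeric(n)) / scale
        S <- matrix(S, n, M)
        S <- S - apply(S, 1, max)
        E <- exp(S); P <- E / rowSums(E)
        attn[[h]][[t1]] <- P
        acc <- matrix(0, n, dh)
        for (t2 in seq_len(M))
          acc <- acc + P[, t2] * V[[t2]][, hd, drop = FALSE]
        O[[t1]][, hd] <- acc
      }
    }
    Pj <- lapply(O, function(o) o %*% Wo)
    R1 <- mapply(function(a, pj) a + pj, A, Pj, SIMPLIFY = FALSE)
    Z1 <- lapply(R1, function(r) sweep(r %*% W1, 2, b1, "+"))
    Fo <- lapply(Z1, relu)
    Aout <- mapply(function(r, f) r + f, R1, Fo, SIMPLIFY = FALSE)
    if (keep_cache)
      cache$blocks[[b]] <- list(A = A, Q = Q, K = K, V = V, attn = attn,
                                O = O, R1 = R1, Z1 = Z1)
    A <- Aout
  }
  Hin <- cbind(do.call(cbind, A), X)
  acts <- list(Hin)
  zs <- list()
  L <- sum(grepl("^head\\d+_W$", names(params)))
  h <- Hin
  for (l in seq_len(L)) {
    z <- sweep(h %*% params[[paste0("head", l, "_W")]], 2,
               params[[paste0("head", l, "_b")]], "+")
    zs[[l]] <- z
    h <- if (l < L) elu(z) else z
    acts[[l + 1]] <- h
  }
  if (keep_cache) { cache$acts <- acts; cache$zs <- zs; cache$X <- X; cache$Z <- Z }
  list(out = h, hidden = if (L >= 2) acts[[L]] else Hin, cache = cache)
}

# Backward pass: dOut is n x K gradient of the loss wrt the network output.
# Returns a flat gradient list matching params.
nn_backward <- function(params, dOut, config, cache) {
  n <- nrow(dOut); d <- config$d_embed
  H <- config$n_heads; dh <- d / H
  scale <- attn_scale_value(config)
  g <- lapply(params, function(p) array(0, dim = if (is.matrix(p)) dim(p) else length(p)))
  for (nm in names(params)) if (!is.matrix(params[[nm]])) g[[nm]] <- numeric(length(params[[nm]]))
  L <- sum(grepl("^head\\d+_W$", names(params)))
  dh_up <- dOut
  for (l in rev(seq_len(L))) {
    z <- cache$zs[[l]]
    dz <- if (l < L) dh_up * elu_grad(z) else dh_up
    g[[paste0("head", l, "_W")]] <- crossprod(cache$acts[[l]], dz)
    g[[paste0("head", l, "_b")]] <- colSums(dz)
    dh_up <- dz %*% t(params[[paste0("head", l, "_W")]])
  }
  M <- ncol(cache$Z)
  dA <- lapply(seq_len(M), function(t) dh_up[, ((t - 1) * d + 1):(t * d), drop = FALSE])
  for (b in rev(seq_len(config$n_blocks))) {
    cb <- cache$blocks[[b]]
    Wq <- params[[paste0("blk", b, "_Wq")]]; Wk <- params[[paste0("blk", b, "_Wk")]]
    Wv <- params[[paste0("blk", b, "_Wv")]]; Wo <- params[[paste0("blk", b, "_Wo")]]
    W1 <- params[[paste0("blk", b, "_W1")]]
    # feedforward + residual
    dR1 <- dA
    dW1 <- matrix(0, d, d); db1 <- numeric(d)
    for (t in seq_len(M)) {
      dzf <- dA[[t]] * (cb$Z1[[t]] > 0)
      dW1 <- dW1 + crossprod(cb$R1[[t]], dzf)
      db1 <- db1 + colSums(dzf)
      dR1[[t]] <- dR1[[t]] + dzf %*% t(W1)
    }
    g[[paste0("blk", b, "_W1")]] <- dW1
    g[[paste0("blk", b, "_b1")]] <- db1
    # attention output projection + residual
    dAin <- dR1                                  # residual path
    dO <- vector("list", M)
    dWo <- matrix(0, d, d)
    for (t in seq_len(M)) {
      dWo <- dWo + crossprod(cb$O[[t]], dR1[[t]])
      dO[[t]] <- dR1[[t]] %*% t(Wo)
    }
    g[[paste0("blk", b, "_Wo")]] <- dWo
    dQ <- lapply(seq_len(M), function(t) matrix(0, n, d))
    dK <- lapply(seq_len(M), function(t) matrix(0, n, d))
    dV <- lapply(seq_len(M), function(t) matrix(0, n, d))
    for (h in seq_len(H)) {
      hd <- ((h - 1) * dh + 1):(h * dh)
      for (t1 in seq_len(M)) {
        P <- cb$attn[[h]][[t1]]
        dOh <- dO[[t1]][, hd, drop = FALSE]
        da <- vapply(seq_len(M), function(t2)
          rowSums(dOh * cb$V[[t2]][, hd, drop = FALSE]), numeric(n))
        da <- matrix(da, n, M)
        for (t2 in seq_len(M))
          dV[[t2]][, hd] <- dV[[t2]][, hd] + P[, t2] * dOh
        dS <- P * (da - rowSums(da * P))          # softmax jacobian, rowwise
        for (t2 in seq_len(M)) {
          dQ[[t1]][, hd] <- dQ[[t1]][, hd] +
            dS[, t2] * cb$K[[t2]][, hd, drop = FALSE] / scale
          dK[[t2]][, hd] <- dK[[t2]][, hd] +
            dS[, t2] * cb$Q[[t1]][, hd, drop = FALSE] / scale
        }
      }
    }
    dWq <- matrix(0, d, d); dWk <- matrix(0, d, d); dWv <- matrix(0, d, d)
    for (t in seq_len(M)) {
      dWq <- dWq + crossprod(cb$A[[t]], dQ[[t]])
      dWk <- dWk + crossprod(cb$A[[t]], dK[[t]])
      dWv <- dWv + crossprod(cb$A[[t]], dV[[t]])
      dAin[[t]] <- dAin[[t]] + dQ[[t]] %*% t(Wq) + dK[[t]] %*% t(Wk) +
        dV[[t]] %*% t(Wv)
    }
    g[[paste0("blk", b, "_Wq")]] <- dWq
    g[[paste0("blk", b, "_Wk")]] <- dWk
    g[[paste0("blk", b, "_Wv")]] <- dWv
    dA <- dAin
  }
  for (j in seq_len(M)) {
    nm <- paste0("emb_", j)
    acc <- rowsum(dA[[j]], group = cache$Z[, j])
    gm <- matrix(0, nrow(params[[nm]]), d)
    gm[as.integer(rownames(acc)), ] <- acc
    g[[nm]] <- gm
  }
  g
}

adamw_state <- function(params)
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0)

adamw_step <- function(params, grads, state, lr, weight_decay = 0,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                       trainable = names(params)) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t; bc2 <- 1 - beta2^state$t
  for (nm in trainable) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    upd <- (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
    params[[nm]] <- params[[nm]] - lr * upd - lr * weight_decay * params[[nm]]
  }
  list(params = params, state = state)
}

# Loss gradients. y: numeric vector (mse) or integer class 1/2 (ce).
loss_grad <- function(out, y, loss, class_weights = NULL) {
  n <- nrow(out)
  if (loss == "mse") {
    e <- out[, 1] - y
    list(loss = mean(e^2), dOut = matrix(2 * e / n, n, 1))
  } else {
    Sm <- out - apply(out, 1, max)
    E <- exp(Sm); P <- E / rowSums(E)
    w <- if (is.null(class_weights)) rep(1, n) else class_weights[y]
    pick <- cbind(seq_len(n), y)
    l <- -sum(w * log(pmax(P[pick], 1e-12))) / sum(w)
    onehot <- matrix(0, n, ncol(out)); onehot[pick] <- 1
    list(loss = l, dOut = w * (P - onehot) / sum(w), prob = P)
  }
}

# Mini-batch AdamW training with early stopping on a validation criterion
# (MAE for regression, weighted cross-entropy for classification). Fully
# deterministic given config$seed. Returns best-validation parameters and
# the per-epoch log.
train_network <- function(params, X, Z, y, Xval, Zval, yval, config,
                          loss = "mse", class_weights = NULL,
                          trainable = names(params), quiet = TRUE) {
  if (nrow(Xval) == 0) stop("empty validation set")
  state <- adamw_state(params)
  best <- list(crit = Inf, params = params, epoch = 0)
  log <- data.frame(epoch = integer(0), train_loss = numeric(0),
                    val_crit = numeric(0))
  n <- nrow(X)
  bs <- min(config$batch_size, n)
  local_seed(config$seed + 1000L, {
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; nb <- 0
      for (start in seq(1, n, by = bs)) {
        ix <- ord[start:min(start + bs - 1, n)]
        fw <- nn_forward(params, X[ix, , drop = FALSE], Z[ix, , drop = FALSE],
                         config, keep_cache = TRUE)
        lg <- loss_grad(fw$out, y[ix], loss, class_weights)
        if (!is.finite(lg$loss))
          stop("non-finite training loss at epoch ", epoch,
               " (batch starting ", start, "); check inputs/learning rate")
        gr <- nn_backward(params, lg$dOut, config, fw$cache)
        st <- adamw_step(params, gr, state, config$learning_rate,
                         config$weight_decay, trainable = trainable)
        params <- st$params; state <- st$state
        ep_loss <- ep_loss + lg$loss; nb <- nb + 1
      }
      vo <- nn_forward(params, Xval, Zval, config)$out
      crit <- if (loss == "mse") mean(abs(vo[, 1] - yval))
              else loss_grad(vo, yval, loss, class_weights)$loss
      log <- rbind(log, data.frame(epoch = epoch, train_loss = ep_loss / nb,
                                   val_crit = crit))
      if (crit < best$crit - 1e-10) {
        best$crit <- crit; best$params <- params; best$epoch <- epoch
      } else if (epoch - best$epoch >= config$patience) break
      if (!quiet && epoch %% 25 == 0)
        message(sprintf("epoch %d train %.4f val %.4f", epoch,
                        ep_loss / nb, crit))
    }
  })
  list(params = best$params, log = log, best_epoch = best$epoch,
       best_crit = best$crit)
}

# Central-difference gradient check on a random subset of parameter
# entries; returns the worst relative deviation. Used by the test suite.
nn_grad_check <- function(config, n = 4, n_continuous = 3, vocab_sizes = c(2, 2),
                          entries_per_param = 3, eps = 1e-5, seed = 42) {
  local_seed(seed, {
    params <- init_params(config, n_continuous, vocab_sizes)
    X <- matrix(stats::rnorm(n * n_continuous), n)
    Z <- cbind(sample.int(vocab_sizes[1], n, TRUE),
               sample.int(vocab_sizes[2], n, TRUE))
    y <- stats::rnorm(n)
    fw <- nn_forward(params, X, Z, config, keep_cache = TRUE)
    lg <- loss_grad(fw$out, y, "mse")
    gr <- nn_backward(params, lg$dOut, config, fw$cache)
    worst <- 0
    for (nm in names(params)) {
      k <- min(entries_per_param, length(params[[nm]]))
      for (i in sample.int(length(params[[nm]]), k)) {
        pp <- params; pp[[nm]][i] <- pp[[nm]][i] + eps
        lp <- loss_grad(nn_forward(pp, X, Z, config)$out, y, "mse")$loss
        pm <- params; pm[[nm]][i] <- pm[[nm]][i] - eps
        lm <- loss_grad(nn_forward(pm, X, Z, config)$out, y, "mse")$loss
        num <- (lp - lm) / (2 * eps)
        ana <- gr[[nm]][i]
        rel <- abs(num - ana) / max(abs(num), abs(ana), 1e-6)
        worst <- max(worst, rel)
      }
    }
    worst
  })
}
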