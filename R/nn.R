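# Minimal neural-network engine: dense and convolutional layers with
# manual backpropagation, used by the supervised embedding models.  All
# randomness (initialization, batching, dropout) is seeded by the caller.

.nn_init_dense <- function(n_in, n_out) {
  # He-style initialization
  list(W = matrix(rnorm(n_in * n_out, 0, sqrt(2 / n_in)), n_in, n_out),
       b = rep(0, n_out))
}

.opt_new <- function(params, kind, lr) {
  state <- lapply(params, function(p)
    list(m = lapply(p, function(x) x * 0), v = lapply(p, function(x) x * 0)))
  list(kind = kind, lr = lr, t = 0, state = state)
}

.opt_step <- function(opt, params, grads) {
  opt$t <- opt$t + 1
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; mom <- 0.9
  for (l in seq_along(params)) {
    for (nm in names(params[[l]])) {
      g <- grads[[l]][[nm]]
      st <- opt$state[[l]]
      if (opt$kind == "adam") {
        st$m[[nm]] <- b1 * st$m[[nm]] + (1 - b1) * g
        st$v[[nm]] <- b2 * st$v[[nm]] + (1 - b2) * g^2
        mhat <- st$m[[nm]] / (1 - b1^opt$t)
        vhat <- st$v[[nm]] / (1 - b2^opt$t)
        params[[l]][[nm]] <- params[[l]][[nm]] - opt$lr * mhat / (sqrt(vhat) + eps)
      } else if (opt$kind == "rmsprop") {
        st$v[[nm]] <- 0.99 * st$v[[nm]] + 0.01 * g^2
        params[[l]][[nm]] <- params[[l]][[nm]] - opt$lr * g / (sqrt(st$v[[nm]]) + eps)
      } else {  # sgd with momentum
        st$m[[nm]] <- mom * st$m[[nm]] + g
        params[[l]][[nm]] <- params[[l]][[nm]] - opt$lr * st$m[[nm]]
      }
      opt$state[[l]] <- st
    }
  }
  list(opt = opt, params = params)
}

# ---- MLP with a 2-d linear bottleneck ----------------------------------
# Architecture: input -> [hidden ReLU (+dropout)] x L -> bottleneck (2,
# linear) -> output (1, linear).

mlp_new <- function(n_in, hidden, bottleneck = 2L) {
  dims <- c(n_in, hidden, bottleneck, 1L)
  params <- lapply(seq_len(length(dims) - 1L), function(i)
    .nn_init_dense(dims[i], dims[i + 1]))
  list(params = params, hidden = hidden, n_in = n_in,
       bottleneck_layer = length(hidden) + 1L)
}

mlp_forward <- function(net, X, dropout = 0, train = FALSE) {
  acts <- list(X); masks <- list()
  A <- X
  L <- length(net$params)
  for (l in seq_len(L)) {
    Z <- sweep(A %*% net$params[[l]]$W, 2, net$params[[l]]$b, `+`)
    if (l <= length(net$hidden)) {
      A <- pmax(Z, 0)
      if (train && dropout > 0) {
        m <- matrix(runif(length(A)) >= dropout, nrow(A), ncol(A)) / (1 - dropout)
        A <- A * m; masks[[l]] <- m
      }
    } else A <- Z  # bottleneck and output are linear
    acts[[l + 1]] <- A
  }
  list(acts = acts, masks = masks, out = A[, 1],
       embedding = acts[[net$bottleneck_layer + 1L]])
}

mlp_backward <- function(net, fwd, y, dropout = 0) {
  L <- length(net$params)
  nb <- length(y)
  grads <- vector("list", L)
  delta <- matrix(2 * (fwd$out - y) / nb, ncol = 1)
  for (l in rev(seq_len(L))) {
    A_prev <- fwd$acts[[l]]
    grads[[l]] <- list(W = crossprod(A_prev, delta), b = colSums(delta))
    if (l > 1) {
      delta <- delta %*% t(net$params[[l]]$W)
      if (l - 1 <= length(net$hidden)) {
        if (dropout > 0 && length(fwd$masks) >= l - 1 &&
            !is.null(fwd$masks[[l - 1]]))
          delta <- delta * fwd$masks[[l - 1]]
        delta <- delta * (fwd$acts[[l]] > 0)
      }
    }
  }
  grads
}

# Generic minibatch training loop with early stopping on validation MSE.
# fit_data/val_data: list(X=..., y=...).  Returns net with best weights,
# per-epoch losses and the stopping epoch.
mlp_train <- function(net, train_data, val_data, lr = 1e-3,
                      optimizer = "adam", batch_size = 16L, dropout = 0,
                      max_epochs = 200L, patience = 20L) {
  opt <- .opt_new(net$params, optimizer, lr)
  n <- nrow(train_data$X)
  best <- list(loss = Inf, params = net$params, epoch = 0L)
  log <- data.frame(epoch = integer(0), train = numeric(0), val = numeric(0))
  wait <- 0L
  for (ep in seq_len(max_epochs)) {
    ord <- sample.int(n)
    for (start in seq(1L, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, n)]
      fwd <- mlp_forward(net, train_data$X[idx, , drop = FALSE],
                         dropout = dropout, train = TRUE)
      grads <- mlp_backward(net, fwd, train_data$y[idx], dropout = dropout)
      st <- .opt_step(opt, net$params, grads)
      opt <- st$opt; net$params <- st$params
    }
    tr_loss <- mean((mlp_forward(net, train_data$X)$out - train_data$y)^2)
    va_loss <- if (is.null(val_data)) tr_loss else
      mean((mlp_forward(net, val_data$X)$out - val_data$y)^2)
    log <- rbind(log, data.frame(epoch = ep, train = tr_loss, val = va_loss))
    if (is.finite(va_loss) && va_loss < best$loss - 1e-12) {
      best <- list(loss = va_loss, params = net$params, epoch = ep)
      wait <- 0L
    } else wait <- wait + 1L
    if (wait >= patience) break
  }
  net$params <- best$params
  list(net = net, best_epoch = best$epoch, best_val = best$loss, log = log)
}

# ---- Tiny CNN ----------------------------------------------------------
# Fixed preprocessing: channel-wise average pooling of the rendered image
# down to a small grid; then conv(3x3) + ReLU + avgpool(2) blocks, global
# average pooling, dense bottleneck (2, linear), dense output (1).

avg_pool_image <- function(pixels, factor) {
  d <- dim(pixels)
  H <- d[1] %/% factor; W <- d[2] %/% factor
  out <- array(0, c(H, W, d[3]))
  for (ch in seq_len(d[3])) {
    m <- pixels[seq_len(H * factor), seq_len(W * factor), ch]
    m <- matrix(colMeans(matrix(m, factor)), H)       # pool rows
    m <- t(matrix(colMeans(matrix(t(m), factor)), W)) # pool cols
    out[, , ch] <- m
  }
  out
}

.im2col <- function(img, k) {
  # img: H x W x C; returns (H-k+1)*(W-k+1) x k*k*C matrix
  H <- dim(img)[1]; W <- dim(img)[2]; C <- dim(img)[3]
  Ho <- H - k + 1L; Wo <- W - k + 1L
  cols <- matrix(0, Ho * Wo, k * k * C)
  cidx <- 1L
  for (ch in seq_len(C)) for (dx in seq_len(k)) for (dy in seq_len(k)) {
    cols[, cidx] <- as.vector(img[dy:(dy + Ho - 1L), dx:(dx + Wo - 1L), ch])
    cidx <- cidx + 1L
  }
  cols
}

.col2im <- function(cols, H, W, C, k) {
  img <- array(0, c(H, W, C))
  Ho <- H - k + 1L; Wo <- W - k + 1L
  cidx <- 1L
  for (ch in seq_len(C)) for (dx in seq_len(k)) for (dy in seq_len(k)) {
    img[dy:(dy + Ho - 1L), dx:(dx + Wo - 1L), ch] <-
      img[dy:(dy + Ho - 1L), dx:(dx + Wo - 1L), ch] + matrix(cols[, cidx], Ho, Wo)
    cidx <- cidx + 1L
  }
  img
}

.pool2 <- function(img) {
  H <- dim(img)[1] %/% 2L * 2L; W <- dim(img)[2] %/% 2L * 2L
  C <- dim(img)[3]
  out <- array(0, c(H / 2, W / 2, C))
  for (ch in seq_len(C))
    out[, , ch] <- 0.25 * (img[seq(1, H, 2), seq(1, W, 2), ch] +
                           img[seq(2, H, 2), seq(1, W, 2), ch] +
                           img[seq(1, H, 2), seq(2, W, 2), ch] +
                           img[seq(2, H, 2), seq(2, W, 2), ch])
  out
}

.unpool2 <- function(d_out, H, W) {
  C <- dim(d_out)[3]
  img <- array(0, c(H, W, C))
  Hp <- dim(d_out)[1]; Wp <- dim(d_out)[2]
  for (ch in seq_len(C)) {
    e <- d_out[, , ch] * 0.25
    img[seq(1, 2 * Hp, 2), seq(1, 2 * Wp, 2), ch] <- e
    img[seq(2, 2 * Hp, 2), seq(1, 2 * Wp, 2), ch] <- e
    img[seq(1, 2 * Hp, 2), seq(2, 2 * Wp, 2), ch] <- e
    img[seq(2, 2 * Hp, 2), seq(2, 2 * Wp, 2), ch] <- e
  }
  img
}

cnn_new <- function(in_shape, channels = c(8L, 16L), k = 3L,
                    bottleneck = 2L) {
  C_in <- in_shape[3]
  conv <- list(); shapes <- list(in_shape)
  H <- in_shape[1]; W <- in_shape[2]; Cprev <- C_in
  for (i in seq_along(channels)) {
    conv[[i]] <- .nn_init_dense(k * k * Cprev, channels[i])
    H <- (H - k + 1L) %/% 2L; W <- (W - k + 1L) %/% 2L
    Cprev <- channels[i]
    shapes[[i + 1]] <- c(H, W, Cprev)
  }
  head <- list(.nn_init_dense(Cprev, bottleneck),
               .nn_init_dense(bottleneck, 1L))
  list(conv = conv, head = head, k = k, channels = channels,
       in_shape = in_shape, shapes = shapes, n_feat = Cprev)
}

cnn_forward_one <- function(net, img, keep = FALSE) {
  k <- net$k
  acts <- list(img)
  cols_list <- list(); pre_list <- list()
  A <- img
  for (i in seq_along(net$conv)) {
    H <- dim(A)[1]; W <- dim(A)[2]
    cols <- .im2col(A, k)
    Z <- sweep(cols %*% net$conv[[i]]$W, 2, net$conv[[i]]$b, `+`)
    Ho <- H - k + 1L; Wo <- W - k + 1L
    Zarr <- array(Z, c(Ho, Wo, net$channels[i]))
    R <- pmax(Zarr, 0)
    P <- .pool2(R)
    if (keep) { cols_list[[i]] <- cols; pre_list[[i]] <- Zarr }
    acts[[i + 1]] <- P
    A <- P
  }
  feat <- apply(A, 3, mean)  # global average pooling
  emb <- as.vector(feat %*% net$head[[1]]$W + net$head[[1]]$b)
  out <- as.vector(emb %*% net$head[[2]]$W + net$head[[2]]$b)
  list(out = out, embedding = emb, feat = feat, acts = acts,
       cols = cols_list, pre = pre_list)
}

cnn_backward_one <- function(net, fwd, dy, mask = NULL) {
  k <- net$k
  g_head <- list(
    list(W = NULL, b = NULL), list(W = NULL, b = NULL))
  emb_eff <- if (is.null(mask)) fwd$embedding else fwd$embedding * mask
  demb <- dy * as.vector(net$head[[2]]$W)
  if (!is.null(mask)) demb <- demb * mask
  g_head[[2]] <- list(W = matrix(emb_eff, ncol = 1) * dy,
                      b = dy)
  g_head[[1]] <- list(W = outer(fwd$feat, demb),
                      b = demb)
  dfeat <- as.vector(net$head[[1]]$W %*% demb)
  # gradient through GAP
  L <- length(net$conv)
  top <- fwd$acts[[L + 1]]
  Hp <- dim(top)[1]; Wp <- dim(top)[2]
  dA <- array(0, dim(top))
  for (ch in seq_len(dim(top)[3])) dA[, , ch] <- dfeat[ch] / (Hp * Wp)
  g_conv <- vector("list", L)
  for (i in rev(seq_len(L))) {
    pre <- fwd$pre[[i]]
    Ho <- dim(pre)[1]; Wo <- dim(pre)[2]
    dR <- .unpool2(dA, Ho %/% 2L * 2L, Wo %/% 2L * 2L)
    if (dim(dR)[1] < Ho || dim(dR)[2] < Wo) {
      tmp <- array(0, dim(pre))
      tmp[seq_len(dim(dR)[1]), seq_len(dim(dR)[2]), ] <- dR
      dR <- tmp
    }
    dZ <- dR * (pre > 0)
    dZm <- matrix(dZ, Ho * Wo, net$channels[i])
    g_conv[[i]] <- list(W = crossprod(fwd$cols[[i]], dZm), b = colSums(dZm))
    if (i > 1) {
      dcols <- dZm %*% t(net$conv[[i]]$W)
      Hin <- dim(fwd$acts[[i]])[1]; Win <- dim(fwd$acts[[i]])[2]
      dA <- .col2im(dcols, Hin, Win, dim(fwd$acts[[i]])[3], k)
    }
  }
  c(g_conv, g_head)
}

cnn_predict <- function(net, imgs) {
  t(vapply(imgs, function(im) {
    f <- cnn_forward_one(net, im)
    c(f$out, f$embedding)
  }, numeric(3)))
}

cnn_train <- function(net, train_imgs, train_y, val_imgs, val_y,
                      lr = 1e-3, optimizer = "adam", batch_size = 16L,
                      dropout = 0, max_epochs = 30L, patience = 8L) {
  params <- c(net$conv, net$head)
  opt <- .opt_new(params, optimizer, lr)
  n <- length(train_imgs)
  best <- list(loss = Inf, params = params, epoch = 0L)
  wait <- 0L
  log <- data.frame(epoch = integer(0), train = numeric(0), val = numeric(0))
  sync <- function(net, params) {
    net$conv <- params[seq_along(net$conv)]
    net$head <- params[length(net$conv) + 1:2]
    net
  }
  for (ep in seq_len(max_epochs)) {
    ord <- sample.int(n)
    for (start in seq(1L, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, n)]
      acc <- NULL
      for (i in idx) {
        fwd <- cnn_forward_one(net, train_imgs[[i]], keep = TRUE)
        m <- NULL
        if (dropout > 0) {
          # dropout on the bottleneck during training
          m <- (runif(length(fwd$embedding)) >= dropout) / (1 - dropout)
          pred <- sum(fwd$embedding * m * as.vector(net$head[[2]]$W)) +
            net$head[[2]]$b
        } else pred <- fwd$out
        dy <- 2 * (pred - train_y[i]) / length(idx)
        g <- cnn_backward_one(net, fwd, dy, mask = m)
        if (is.null(acc)) acc <- g else
          for (l in seq_along(g)) for (nm in names(g[[l]]))
            acc[[l]][[nm]] <- acc[[l]][[nm]] + g[[l]][[nm]]
      }
      st <- .opt_step(opt, params, acc)
      opt <- st$opt; params <- st$params
      net <- sync(net, params)
    }
    tr <- mean((cnn_predict(net, train_imgs)[, 1] - train_y)^2)
    va <- if (is.null(val_imgs)) tr else
      mean((cnn_predict(net, val_imgs)[, 1] - val_y)^2)
    log <- rbind(log, data.frame(epoch = ep, train = tr, val = va))
    if (is.finite(va) && va < best$loss - 1e-12) {
      best <- list(loss = va, params = params, epoch = ep); wait <- 0L
    } else wait <- wait + 1L
    if (wait >= patience) break
  }
  net <- sync(net, best$params)
  list(net = net, best_epoch = best$epoch, best_val = best$loss, log = log)
}
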