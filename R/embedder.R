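#' Budget and search space for embedder hyperparameter optimization
#'
#' Default search ranges: learning rate 1e-4..1e-2 (MLP) or 1e-5..1e-2
#' (CNN) on a log scale, dropout 0..0.5, batch sizes \{8, 16, 32, 64\},
#' optimizers Adam/RMSprop (MLP) plus SGD (CNN), 1-3 hidden layers of
#' 32-256 units for the MLP.  `max_epochs` caps training length; early
#' stopping on validation loss decides the effective number of epochs.
#'
#' @param n_trials number of random-search trials (1 = train the single
#'   sampled configuration without search).
#' @param patience early-stopping patience in epochs.
#' @param max_epochs cap on training epochs per trial.
#' @param pool_factor CNN-only: factor of the fixed average-pooling
#'   front end applied to rendered images (224 / 8 = 28 pixel grid).
#' @param channels CNN-only: channels per conv block.
#' @param seed integer seed for sampling and training.
#' @return object of class `hpo_budget`.
#' @export
hpo_budget <- function(n_trials = 100L, patience = 20L, max_epochs = 200L,
                       pool_factor = 8L, channels = c(8L, 16L), seed = 1L) {
  stopifnot(n_trials >= 1, patience >= 1, max_epochs >= 1)
  structure(list(n_trials = as.integer(n_trials),
                 patience = as.integer(patience),
                 max_epochs = as.integer(max_epochs),
                 pool_factor = as.integer(pool_factor),
                 channels = as.integer(channels),
                 seed = as.integer(seed)),
            class = "hpo_budget")
}

.sample_embed_config <- function(kind) {
  if (kind == "mlp") {
    list(lr = 10^runif(1, -4, -2), dropout = runif(1, 0, 0.5),
         batch_size = sample(c(8L, 16L, 32L, 64L), 1L),
         optimizer = sample(c("adam", "rmsprop"), 1L),
         n_layers = sample(1:3, 1L),
         units = as.integer(round(2^runif(1, 5, 8))))
  } else {
    list(lr = 10^runif(1, -5, -2), dropout = runif(1, 0, 0.5),
         batch_size = sample(c(8L, 16L, 32L, 64L), 1L),
         optimizer = sample(c("adam", "sgd", "rmsprop"), 1L))
  }
}

.fit_embed_net <- function(kind, config, X_fit, y_fit, X_mon, y_mon,
                           budget, seed) {
  with_seed(seed, {
    if (kind == "mlp") {
      net <- mlp_new(ncol(X_fit), rep(config$units, config$n_layers))
      mlp_train(net, list(X = X_fit, y = y_fit),
                if (is.null(X_mon)) NULL else list(X = X_mon, y = y_mon),
                lr = config$lr, optimizer = config$optimizer,
                batch_size = config$batch_size, dropout = config$dropout,
                max_epochs = budget$max_epochs, patience = budget$patience)
    } else {
      net <- cnn_new(dim(X_fit[[1]]), channels = budget$channels)
      cnn_train(net, X_fit, y_fit, X_mon, y_mon,
                lr = config$lr, optimizer = config$optimizer,
                batch_size = config$batch_size, dropout = config$dropout,
                max_epochs = budget$max_epochs, patience = budget$patience)
    }
  })
}

#' Train a supervised 2-d embedding model
#'
#' Three-step protocol.  Step 1: random-search hyperparameter optimization,
#' each candidate trained on the training rows with early stopping and
#' scored by validation loss.  Step 2: final training on the combined
#' train+validation rows with the selected configuration, early stopping
#' selecting the best weights (monitored on the validation rows; the test
#' partition is never touched).  Step 3 is performed separately by
#' [extract_embeddings()].  Rows with a missing target are dropped from
#' fitting.
#'
#' @param kind `"mlp"` (descriptor vectors) or `"cnn"` (rendered images).
#' @param target `"CL"` or `"VD"`; only used to label the embedding.
#' @param X for `"mlp"` a numeric matrix (rows = compounds); for `"cnn"` a
#'   list of pixel arrays from [render_molecule_image()].
#' @param y numeric target on the transformed scale (NA = missing).
#' @param train_idx,val_idx disjoint row indices.
#' @param budget an [hpo_budget()].
#' @return object of class `embedding_model`.
#' @export
train_embedder <- function(kind = c("mlp", "cnn"), target = c("CL", "VD"),
                           X, y, train_idx, val_idx, budget = hpo_budget()) {
  kind <- match.arg(kind); target <- match.arg(target)
  stopifnot(length(intersect(train_idx, val_idx)) == 0)
  if (!length(val_idx)) stop("empty validation partition")
  train_idx <- train_idx[!is.na(y[train_idx])]
  val_idx <- val_idx[!is.na(y[val_idx])]
  if (!length(train_idx)) stop("no training rows with observed target")
  if (!length(val_idx)) stop("no validation rows with observed target")

  if (kind == "mlp") {
    mu <- colMeans(X[train_idx, , drop = FALSE])
    sg <- apply(X[train_idx, , drop = FALSE], 2, sd)
    sg[!is.finite(sg) | sg == 0] <- 1
    prep <- list(kind = "standardize", mu = mu, sd = sg)
    Xp <- sweep(sweep(X, 2, mu), 2, sg, `/`)
    sel <- function(idx) Xp[idx, , drop = FALSE]
  } else {
    prep <- list(kind = "avgpool", factor = budget$pool_factor)
    Xp <- lapply(X, function(im)
      avg_pool_image(if (is.list(im)) im$pixels else im, budget$pool_factor))
    sel <- function(idx) Xp[idx]
  }

  trials <- vector("list", budget$n_trials)
  with_seed(budget$seed, {
    configs <- lapply(seq_len(budget$n_trials),
                      function(i) .sample_embed_config(kind))
  })
  for (i in seq_len(budget$n_trials)) {
    fit <- .fit_embed_net(kind, configs[[i]], sel(train_idx), y[train_idx],
                          sel(val_idx), y[val_idx], budget,
                          seed = budget$seed + 1000L * i)
    trials[[i]] <- list(config = configs[[i]], val_loss = fit$best_val,
                        best_epoch = fit$best_epoch)
  }
  losses <- vapply(trials, `[[`, numeric(1), "val_loss")
  best_i <- which.min(losses)
  chosen <- configs[[best_i]]

  fit_idx <- c(train_idx, val_idx)
  final <- .fit_embed_net(kind, chosen, sel(fit_idx), y[fit_idx],
                          sel(val_idx), y[val_idx], budget,
                          seed = budget$seed + 77L)
  structure(list(kind = kind, target = target, config = chosen,
                 net = final$net, prep = prep,
                 hpo_record = list(trials = trials, chosen = best_i,
                                   seed = budget$seed),
                 final_val = final$best_val, best_epoch = final$best_epoch,
                 trained = TRUE),
            class = "embedding_model")
}

#' Extract 2-d embeddings from a trained model
#'
#' Pure inference: dropout off, no weight updates.  Output columns follow
#' the `<kind>_vec{1,2}_<target>` naming convention.
#'
#' @param model an `embedding_model`.
#' @param X same format as the `X` used at training time.
#' @return numeric matrix with 2 named columns, one row per input row.
#' @export
extract_embeddings <- function(model, X) {
  if (!inherits(model, "embedding_model") || !isTRUE(model$trained))
    stop("model is not a trained embedding_model")
  if (model$kind == "mlp") {
    Xp <- sweep(sweep(X, 2, model$prep$mu), 2, model$prep$sd, `/`)
    emb <- mlp_forward(model$net, Xp)$embedding
  } else {
    Xp <- lapply(X, function(im)
      avg_pool_image(if (is.list(im)) im$pixels else im, model$prep$factor))
    emb <- cnn_predict(model$net, Xp)[, 2:3, drop = FALSE]
  }
  colnames(emb) <- paste0(model$kind, "_vec", 1:2, "_", model$target)
  emb
}

#' @export
print.embedding_model <- function(x, ...) {
  cat(sprintf("<embedding_model> %s / %s (val loss %.4g, %d HPO trials)\n",
              x$kind, x$target, x$final_val,
              length(x$hpo_record$trials)))
  invisible(x)
}
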