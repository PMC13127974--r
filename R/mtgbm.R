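#' Configuration for the multi-task boosting engine
#'
#' Defaults are the estimated multi-task settings used throughout:
#' learning rate 0.014, 44 leaves, depth cap 13, L1/L2 regularization
#' 0.71/2.89, up to 15,000 boosting rounds with early-stopping patience
#' 150 monitoring validation MSE summed across tasks.
#'
#' @param learning_rate shrinkage per round (> 0).
#' @param num_leaves maximum leaves per tree (>= 2).
#' @param max_depth depth cap per tree.
#' @param lambda_l1,lambda_l2 L1/L2 leaf regularization (>= 0).
#' @param min_child_samples minimum rows per leaf.
#' @param max_rounds cap on boosting rounds.
#' @param patience early-stopping rounds without validation improvement.
#' @param n_tasks 1 (single-task baseline) or 2 (shared trees).
#' @param seed integer seed (engine is deterministic; kept for the record).
#' @return object of class `boost_config`.
#' @export
boost_config <- function(learning_rate = 0.014, num_leaves = 44L,
                         max_depth = 13L, lambda_l1 = 0.71,
                         lambda_l2 = 2.89, min_child_samples = 20L,
                         max_rounds = 15000L, patience = 150L,
                         n_tasks = 2L, seed = 1L) {
  stopifnot(learning_rate > 0, num_leaves >= 2, max_depth >= 1,
            lambda_l1 >= 0, lambda_l2 >= 0, min_child_samples >= 1,
            max_rounds >= 1, patience >= 1, n_tasks %in% c(1L, 2L))
  structure(list(learning_rate = learning_rate,
                 num_leaves = as.integer(num_leaves),
                 max_depth = as.integer(max_depth),
                 lambda_l1 = lambda_l1, lambda_l2 = lambda_l2,
                 min_child_samples = as.integer(min_child_samples),
                 max_rounds = as.integer(max_rounds),
                 patience = as.integer(patience),
                 n_tasks = as.integer(n_tasks),
                 seed = as.integer(seed)),
            class = "boost_config")
}

.as_task_matrix <- function(y, n_tasks) {
  if (is.matrix(y)) y else matrix(y, ncol = n_tasks)
}

#' Per-task gradients and Hessians for the squared-error objective
#'
#' Loss per task is `0.5 * (pred - y)^2` on the transformed scale, so
#' `g = pred - y` and `h = 1` on unmasked entries; masked entries carry
#' `g = h = 0` and contribute nothing to any leaf.
#'
#' @param pred,y n x T matrices (or vectors for one task).
#' @param masks logical n x T matrix; defaults to `!is.na(y)`.
#' @return object of class `task_gradients` with `g`, `h`, `masks`.
#' @export
compute_task_gradients <- function(pred, y, masks = NULL) {
  pred <- as.matrix(pred); y <- as.matrix(y)
  stopifnot(all(dim(pred) == dim(y)))
  if (is.null(masks)) masks <- !is.na(y)
  masks <- as.matrix(masks)
  stopifnot(all(dim(masks) == dim(y)))
  if (any(masks & (is.na(y) | is.nan(y))))
    stop("NaN/NA target in unmasked entry")
  g <- (pred - ifelse(masks, y, 0)) * masks
  h <- masks * 1
  structure(list(g = g, h = h, masks = masks), class = "task_gradients")
}

#' Best shared split for one node
#'
#' Exhaustive scan over features and midpoint thresholds of sorted unique
#' values; gain is the second-order gain summed over tasks; ties break to
#' the lowest feature index, then the lowest threshold.
#'
#' @param X feature matrix for the node's samples.
#' @param grads a [compute_task_gradients()] result aligned with `X`.
#' @param cfg a [boost_config()].
#' @return list `(feature, threshold, gain)` or `NULL` when no
#'   positive-gain split exists.
#' @export
find_best_split <- function(X, grads, cfg) {
  s <- cpp_best_split(as.matrix(X), grads$g, grads$h, cfg$lambda_l2,
                      cfg$min_child_samples)
  if (!s$found) return(NULL)
  list(feature = s$feature, threshold = s$threshold, gain = s$gain)
}

#' Grow one shared-structure tree
#'
#' Best-first (leaf-wise) growth to the leaf cap under the depth cap.
#' Each leaf stores one value per task:
#' `w_t = -soft_threshold(G_t, lambda1) / (H_t + lambda2)`; a leaf whose
#' samples are all masked for a task gets 0 for that task.
#'
#' @inheritParams find_best_split
#' @return object of class `mtgbm_tree`.
#' @export
grow_shared_tree <- function(X, grads, cfg) {
  tr <- cpp_grow_tree(as.matrix(X), grads$g, grads$h, cfg$lambda_l1,
                      cfg$lambda_l2, cfg$num_leaves, cfg$max_depth,
                      cfg$min_child_samples)
  structure(tr, class = "mtgbm_tree")
}

#' Fit a (multi-task) gradient boosting ensemble with shared trees
#'
#' Base score per task is the mean of the unmasked training targets.  Each
#' round computes per-task gradients, grows one shared tree, and updates
#' both tasks' predictions by `learning_rate` times the per-task leaf
#' values.  With validation data, training stops once the summed-across-
#' tasks validation MSE has not improved for `patience` rounds;
#' `best_iteration` is the argmin of the validation loss.  Without
#' validation data the ensemble runs for exactly `max_rounds` rounds.
#'
#' @param X numeric feature matrix (rows = samples).
#' @param y targets: vector (1 task) or n x 2 matrix, NA = missing.
#' @param X_val,y_val optional validation partition.
#' @param cfg a [boost_config()].
#' @return object of class `mtgbm_model`.
#' @export
mtgbm_fit <- function(X, y, X_val = NULL, y_val = NULL, cfg = boost_config()) {
  X <- as.matrix(X)
  Y <- .as_task_matrix(y, cfg$n_tasks)
  stopifnot(ncol(Y) == cfg$n_tasks, nrow(Y) == nrow(X))
  masks <- !is.na(Y)
  if (any(colSums(masks) == 0))
    stop("a task has no unmasked training target")
  base <- vapply(seq_len(cfg$n_tasks),
                 function(t) mean(Y[masks[, t], t]), numeric(1))
  pred <- matrix(rep(base, each = nrow(X)), ncol = cfg$n_tasks)
  has_val <- !is.null(X_val)
  if (has_val) {
    X_val <- as.matrix(X_val)
    Yv <- .as_task_matrix(y_val, cfg$n_tasks)
    masks_v <- !is.na(Yv)
    pred_v <- matrix(rep(base, each = nrow(X_val)), ncol = cfg$n_tasks)
  }
  task_mse <- function(p, yy, mm)
    vapply(seq_len(ncol(p)), function(t)
      if (any(mm[, t])) mean((p[mm[, t], t] - yy[mm[, t], t])^2) else NA_real_,
      numeric(1))
  trees <- vector("list", cfg$max_rounds)
  log_train <- numeric(0); log_val <- numeric(0)
  best_iter <- 0L
  best_loss <- if (has_val) sum(task_mse(pred_v, Yv, masks_v), na.rm = TRUE)
               else Inf
  wait <- 0L
  n_rounds <- 0L
  for (round in seq_len(cfg$max_rounds)) {
    gr <- compute_task_gradients(pred, Y, masks)
    tr <- cpp_grow_tree(X, gr$g, gr$h, cfg$lambda_l1, cfg$lambda_l2,
                        cfg$num_leaves, cfg$max_depth, cfg$min_child_samples)
    pred <- pred + cfg$learning_rate *
      tr$leaf_values[tr$row_node, , drop = FALSE]
    trees[[round]] <- tr[c("feature", "threshold", "left", "right",
                           "leaf_values")]
    n_rounds <- round
    log_train <- c(log_train, sum(task_mse(pred, Y, masks), na.rm = TRUE))
    if (has_val) {
      nodes_v <- cpp_route(tr$feature, tr$threshold, tr$left, tr$right, X_val)
      pred_v <- pred_v + cfg$learning_rate *
        tr$leaf_values[nodes_v, , drop = FALSE]
      vl <- sum(task_mse(pred_v, Yv, masks_v), na.rm = TRUE)
      log_val <- c(log_val, vl)
      if (vl < best_loss - 1e-12) {
        best_loss <- vl; best_iter <- round; wait <- 0L
      } else wait <- wait + 1L
      if (wait >= cfg$patience) break
    }
  }
  if (!has_val) best_iter <- n_rounds
  if (best_iter == 0L) best_iter <- n_rounds  # validation never improved
  structure(list(trees = trees[seq_len(n_rounds)], base_scores = base,
                 config = cfg, best_iteration = best_iter,
                 feature_names = colnames(X),
                 log = list(train = log_train,
                            val = if (has_val) log_val else NULL)),
            class = "mtgbm_model")
}

#' Predict from a fitted ensemble
#'
#' `base_score + sum over the first `best_iteration` trees of
#' `learning_rate * leaf value` for the requested task, on the transformed
#' target scale.
#'
#' @param model an `mtgbm_model`.
#' @param X feature matrix with the training columns in order.
#' @param task task index (1-based).
#' @param n_trees number of trees to use (default `best_iteration`).
#' @return numeric vector of predictions.
#' @export
mtgbm_predict <- function(model, X, task = 1L, n_trees = NULL) {
  stopifnot(inherits(model, "mtgbm_model"), task >= 1,
            task <= model$config$n_tasks)
  X <- as.matrix(X)
  if (!is.null(model$feature_names) && !is.null(colnames(X))) {
    if (!identical(colnames(X), model$feature_names)) {
      missing_cols <- setdiff(model$feature_names, colnames(X))
      if (length(missing_cols))
        stop("feature columns missing or out of order: ",
             paste(missing_cols, collapse = ", "))
      X <- X[, model$feature_names, drop = FALSE]
    }
  }
  n_trees <- n_trees %||% model$best_iteration
  stopifnot(n_trees <= length(model$trees))
  if (n_trees == 0)
    return(rep(model$base_scores[task], nrow(X)))
  cpp_predict_ensemble(model$trees, X, as.integer(task),
                       as.integer(n_trees), model$config$learning_rate,
                       model$base_scores[task])
}

#' @export
print.mtgbm_model <- function(x, ...) {
  cat(sprintf(
    "<mtgbm_model> %d task(s), %d trees (best iteration %d), lr %.4g\n",
    x$config$n_tasks, length(x$trees), x$best_iteration,
    x$config$learning_rate))
  invisible(x)
}

#' Serialize a fitted ensemble to JSON
#'
#' Writes the tree lists (feature indices, thresholds, children, per-task
#' leaf values), base scores, configuration and best iteration; the file
#' round-trips through [mtgbm_from_json()].
#'
#' @param model an `mtgbm_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
mtgbm_to_json <- function(model, path) {
  stopifnot(inherits(model, "mtgbm_model"))
  payload <- list(
    base_scores = model$base_scores,
    config = unclass(model$config),
    best_iteration = model$best_iteration,
    feature_names = model$feature_names,
    trees = lapply(model$trees, function(tr)
      list(feature = tr$feature, threshold = tr$threshold,
           left = tr$left, right = tr$right,
           leaf_values = tr$leaf_values)))
  jsonlite::write_json(payload, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Restore a fitted ensemble from JSON
#' @param path file written by [mtgbm_to_json()].
#' @return an `mtgbm_model`.
#' @export
mtgbm_from_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(boost_config, as.list(p$config))
  trees <- lapply(seq_len(nrow(p$trees)), function(i) {
    list(feature = p$trees$feature[[i]],
         threshold = p$trees$threshold[[i]],
         left = p$trees$left[[i]], right = p$trees$right[[i]],
         leaf_values = matrix(p$trees$leaf_values[[i]],
                              ncol = cfg$n_tasks))
  })
  structure(list(trees = trees, base_scores = p$base_scores, config = cfg,
                 best_iteration = as.integer(p$best_iteration),
                 feature_names = p$feature_names, log = NULL),
            class = "mtgbm_model")
}

#' Random-search hyperparameter optimization for the single-task baseline
#'
#' Samples configurations from the stated spaces (learning rate 0.005-0.05
#' log-uniform, 8-64 leaves, depth 6-15, `min_child_samples` 10-50, L1/L2
#' regularization 0.01-10 log-uniform), fits each with early stopping, and
#' returns the configuration minimizing validation GMFE computed on the
#' original scale via `inverse_fn`.
#'
#' @param X_train,y_train training features/target (transformed scale).
#' @param X_val,y_val validation features/target (transformed scale).
#' @param y_val_orig validation target on the original scale.
#' @param inverse_fn maps transformed predictions back to the original
#'   scale.
#' @param n_trials number of sampled configurations (>= 1).
#' @param seed integer seed.
#' @param max_rounds,patience boosting schedule per trial.
#' @param space optional list overriding any sampling range, fields
#'   `lr`, `num_leaves`, `max_depth`, `min_child_samples`, `lambda` each a
#'   length-2 numeric range.
#' @return list: `config` (best [boost_config()]), `record` (all trials).
#' @export
hpo_single_task <- function(X_train, y_train, X_val, y_val, y_val_orig,
                            inverse_fn, n_trials = 100L, seed = 1L,
                            max_rounds = 2000L, patience = 150L,
                            space = NULL) {
  stopifnot(n_trials >= 1)
  sp <- list(lr = c(0.005, 0.05), num_leaves = c(8, 64),
             max_depth = c(6, 15), min_child_samples = c(10, 50),
             lambda = c(0.01, 10))
  for (nm in names(space %||% list())) sp[[nm]] <- space[[nm]]
  ok <- !is.na(y_val)
  pick <- function(range) {
    x <- seq(range[1], range[2])
    x[sample.int(length(x), 1L)]
  }
  record <- with_seed(seed, lapply(seq_len(n_trials), function(i) {
    cfg <- boost_config(
      learning_rate = exp(runif(1, log(sp$lr[1]), log(sp$lr[2]))),
      num_leaves = pick(sp$num_leaves),
      max_depth = pick(sp$max_depth),
      min_child_samples = pick(sp$min_child_samples),
      lambda_l1 = exp(runif(1, log(sp$lambda[1]), log(sp$lambda[2]))),
      lambda_l2 = exp(runif(1, log(sp$lambda[1]), log(sp$lambda[2]))),
      max_rounds = max_rounds, patience = patience, n_tasks = 1L,
      seed = seed)
    fit <- mtgbm_fit(X_train, y_train, X_val, y_val, cfg)
    pv <- mtgbm_predict(fit, X_val, task = 1L)
    score <- gmfe(inverse_fn(pv[ok]), y_val_orig[ok])
    list(config = cfg, val_gmfe = score)
  }))
  scores <- vapply(record, `[[`, numeric(1), "val_gmfe")
  list(config = record[[which.min(scores)]]$config,
       record = record, val_gmfe = min(scores))
}
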