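#' Configuration for shadow-feature selection
#'
#' Defaults follow the reference configuration: 5,000 iterations, 80th
#' percentile of shadow importances as the per-iteration hit threshold,
#' a depth-5 gradient-boosted learner, and acceptance alpha 0.05 on a
#' two-sided binomial test of the hit count.  A percentile of 100
#' recovers the max-shadow rule.
#'
#' @param n_iterations number of shadow-permutation iterations.
#' @param shadow_percentile threshold percentile in (0, 100].
#' @param max_depth depth cap of the learner.
#' @param alpha acceptance significance level; with `mc_adjust` it is
#'   Bonferroni-divided by the number of candidate features, as in the
#'   reference Boruta implementations.
#' @param mc_adjust apply the Bonferroni multiplicity adjustment
#'   (default TRUE).
#' @param n_rounds,learning_rate,num_leaves learner schedule per
#'   iteration.  The learner is deliberately compact: shadow comparison
#'   needs a ranking of features against their permuted copies, not a
#'   well-fit model, and a small learner avoids chasing chance structure
#'   in the fixed training table.
#' @param subsample_frac fraction of rows drawn (without replacement) for
#'   each iteration's refit.  The resampling decorrelates iterations (the
#'   binomial hit test assumes non-degenerate iteration-to-iteration
#'   variability) and deliberately dilutes chance associations a fixed
#'   training table always contains, which would otherwise be
#'   indistinguishable from weak real signal.
#' @param n_explain,n_background rows explained / background rows used by
#'   the Shapley importance estimator.
#' @param seed integer seed.
#' @return object of class `selection_config`.
#' @export
selection_config <- function(n_iterations = 5000L, shadow_percentile = 80,
                             max_depth = 5L, alpha = 0.05,
                             n_rounds = 10L, learning_rate = 0.1,
                             num_leaves = 3L, subsample_frac = 1/3,
                             mc_adjust = TRUE, n_explain = 8L,
                             n_background = 8L, seed = 1L) {
  stopifnot(n_iterations >= 1, shadow_percentile > 0,
            shadow_percentile <= 100, alpha > 0, alpha < 1,
            subsample_frac > 0, subsample_frac <= 1)
  if (n_iterations < 5)
    warning("fewer than 5 iterations: binomial test underpowered")
  structure(list(n_iterations = as.integer(n_iterations),
                 shadow_percentile = shadow_percentile,
                 max_depth = as.integer(max_depth), alpha = alpha,
                 n_rounds = as.integer(n_rounds),
                 learning_rate = learning_rate,
                 num_leaves = as.integer(num_leaves),
                 subsample_frac = subsample_frac,
                 mc_adjust = isTRUE(mc_adjust),
                 n_explain = as.integer(n_explain),
                 n_background = as.integer(n_background),
                 seed = as.integer(seed)),
            class = "selection_config")
}

#' Append shadow features to a feature table
#'
#' Each original column gets an independently row-permuted copy named
#' `shadow_<name>`, doubling the width; shadows break any association
#' with the target while preserving each column's marginal distribution.
#'
#' @param X numeric matrix or data.frame with >= 1 column and >= 2 rows.
#' @param seed integer seed.
#' @return numeric matrix with original then shadow columns.
#' @export
shadow_augment <- function(X, seed) {
  X <- as.matrix(X)
  stopifnot(ncol(X) >= 1, nrow(X) >= 2)
  with_seed(seed, {
    Sh <- apply(X, 2, function(col) col[sample.int(length(col))])
    colnames(Sh) <- paste0("shadow_", colnames(X))
    cbind(X, Sh)
  })
}

#' Shapley-based feature importance of a fitted learner
#'
#' Mean absolute Shapley attribution per column: exact enumeration when
#' the table has at most 10 columns, the sampling estimator otherwise.
#' A subset of rows is explained against a background drawn from `X`
#' (both seeded) to bound cost.
#'
#' @param model a fitted `mtgbm_model` (single task).
#' @param X the feature matrix the model was fit on.
#' @param n_explain,n_background subsample sizes.
#' @param seed integer seed.
#' @return named nonnegative numeric vector, one score per column.
#' @export
importance_scores <- function(model, X, n_explain = 16L, n_background = 10L,
                              seed = 1L) {
  if (!inherits(model, "mtgbm_model")) stop("model must be a fitted mtgbm_model")
  X <- as.matrix(X)
  M <- ncol(X)
  fn <- function(mat) {
    colnames(mat) <- colnames(X)
    mtgbm_predict(model, mat, task = 1L)
  }
  idx <- with_seed(seed, list(
    rows = sample.int(nrow(X), min(n_explain, nrow(X))),
    bg = sample.int(nrow(X), min(n_background, nrow(X)))))
  bg <- X[idx$bg, , drop = FALSE]
  if (M <= 10) {
    phis <- t(vapply(idx$rows, function(i)
      exact_shapley(fn, X[i, ], bg)$phi[1, ], numeric(M)))
    imp <- colMeans(abs(phis))
  } else {
    budget <- max(2 * M + 2, min(2^M - 2, 8 * M))
    attr <- kernel_shapley(fn, X[idx$rows, , drop = FALSE], bg,
                           budget = budget, seed = seed)
    imp <- colMeans(abs(attr$phi))
  }
  stats::setNames(pmax(imp, 0), colnames(X))
}

#' Boruta-style feature selection with Shapley importance
#'
#' Per iteration: a row subsample is drawn, shadows are re-permuted, a
#' depth-capped gradient-boosted learner is refit on the augmented table,
#' and each original feature scores a "hit" when its Shapley importance
#' exceeds the `shadow_percentile`-th percentile of the shadow importances
#' of that iteration.  After all iterations a feature is accepted when the
#' two-sided binomial test of its hit count (null probability 0.5) is
#' significant with more hits than expected, rejected when significant
#' with fewer, and tentative otherwise.
#'
#' @param X feature matrix (no missing values).
#' @param y numeric target, no NA.
#' @param cfg a [selection_config()].
#' @return object of class `feature_decision`: data.frame `decisions`
#'   (feature, status, hits, trials, p_value) and `accepted` (ordered
#'   names).
#' @export
boruta_shap_select <- function(X, y, cfg = selection_config()) {
  X <- as.matrix(X)
  if (anyNA(X)) stop("X must not contain missing values")
  if (anyNA(y)) stop("y must not contain missing values")
  p <- ncol(X)
  feats <- colnames(X) %||% paste0("x", seq_len(p))
  colnames(X) <- feats
  hits <- integer(p)
  n <- nrow(X)
  n_sub <- max(2L, round(cfg$subsample_frac * n))
  learner_cfg <- boost_config(
    learning_rate = cfg$learning_rate, num_leaves = cfg$num_leaves,
    max_depth = cfg$max_depth, lambda_l1 = 0, lambda_l2 = 5,
    min_child_samples = max(5L, min(25L, n_sub %/% 10L)),
    max_rounds = cfg$n_rounds, patience = cfg$n_rounds, n_tasks = 1L)
  for (it in seq_len(cfg$n_iterations)) {
    it_seed <- cfg$seed + it
    sub <- with_seed(it_seed, sample.int(n, n_sub))
    Xa <- shadow_augment(X[sub, , drop = FALSE], seed = it_seed + 7L)
    fit <- mtgbm_fit(Xa, y[sub], cfg = learner_cfg)
    imp <- importance_scores(fit, Xa, n_explain = cfg$n_explain,
                             n_background = cfg$n_background,
                             seed = it_seed)
    thr <- quantile(imp[(p + 1):(2 * p)], cfg$shadow_percentile / 100,
                    names = FALSE)
    hits <- hits + as.integer(imp[1:p] > thr)
  }
  pvals <- vapply(hits, function(hh)
    binom.test(hh, cfg$n_iterations, 0.5)$p.value, numeric(1))
  alpha_eff <- if (cfg$mc_adjust) cfg$alpha / p else cfg$alpha
  status <- ifelse(pvals < alpha_eff & hits > cfg$n_iterations / 2,
                   "accepted",
                   ifelse(pvals < alpha_eff & hits < cfg$n_iterations / 2,
                          "rejected", "tentative"))
  decisions <- data.frame(feature = feats, status = status, hits = hits,
                          trials = cfg$n_iterations, p_value = pvals,
                          stringsAsFactors = FALSE)
  structure(list(decisions = decisions,
                 accepted = feats[status == "accepted"],
                 config = cfg),
            class = "feature_decision")
}

#' @export
print.feature_decision <- function(x, ...) {
  cat(sprintf("<feature_decision> %d accepted / %d rejected / %d tentative (of %d)\n",
              sum(x$decisions$status == "accepted"),
              sum(x$decisions$status == "rejected"),
              sum(x$decisions$status == "tentative"),
              nrow(x$decisions)))
  invisible(x)
}

#' Union of accepted features across the two targets
#'
#' Ordered by first appearance: the CL list followed by VD-only
#' additions.  Tentative features are excluded.
#'
#' @param dec_cl,dec_vd `feature_decision` objects (or plain character
#'   vectors of accepted names) computed on the same candidate set.
#' @return character vector.
#' @export
union_features <- function(dec_cl, dec_vd) {
  a <- if (inherits(dec_cl, "feature_decision")) dec_cl$accepted else dec_cl
  b <- if (inherits(dec_vd, "feature_decision")) dec_vd$accepted else dec_vd
  c(a, setdiff(b, a))
}
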