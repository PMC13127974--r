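# Model-agnostic Shapley attribution with the interventional
# (background-replacement) value function: v(S) is the mean model output
# over background rows with the features in S fixed to the explained
# row's values.

.coalition_values <- function(model_fn, row, background, Z) {
  # Z: n_coalitions x M 0/1 matrix; returns v(z) for each coalition
  M <- ncol(Z); B <- nrow(background)
  n_z <- nrow(Z)
  big <- background[rep(seq_len(B), times = n_z), , drop = FALSE]
  zrep <- Z[rep(seq_len(n_z), each = B), , drop = FALSE]
  rowm <- matrix(row, nrow(big), M, byrow = TRUE)
  big[zrep == 1] <- rowm[zrep == 1]
  preds <- model_fn(big)
  colMeans(matrix(preds, B, n_z))
}

#' Exact Shapley values by coalition enumeration
#'
#' Enumerates all `2^M` coalitions (M <= 12) under the interventional
#' value function and applies the exact Shapley weighting.  Serves as the
#' oracle for the sampling estimator.
#'
#' @param model_fn function taking a numeric matrix (rows = inputs) and
#'   returning numeric predictions.
#' @param row numeric vector: the input to explain.
#' @param background numeric matrix of reference rows (training rows).
#' @return object of class `shap_attribution` with a single explained row.
#' @export
exact_shapley <- function(model_fn, row, background) {
  background <- as.matrix(background)
  M <- length(row)
  if (M > 12)
    stop("exact enumeration limited to 12 features; use kernel_shapley()")
  n_z <- 2^M
  Z <- matrix(0L, n_z, M)
  for (j in seq_len(M))
    Z[, j] <- rep(rep(c(0L, 1L), each = 2^(j - 1)), length.out = n_z)
  v <- .coalition_values(model_fn, row, background, Z)
  sizes <- rowSums(Z)
  fact <- factorial(0:M)
  phi <- numeric(M)
  for (j in seq_len(M)) {
    without <- Z[, j] == 0
    idx_without <- which(without)
    idx_with <- idx_without + 2^(j - 1)  # same coalition plus feature j
    s <- sizes[idx_without]
    w <- fact[s + 1] * fact[M - s] / fact[M + 1]
    phi[j] <- sum(w * (v[idx_with] - v[idx_without]))
  }
  base <- v[1]
  structure(list(phi = matrix(phi, 1, M,
                              dimnames = list(NULL, names(row))),
                 base = base, pred = v[n_z],
                 features = names(row) %||% paste0("x", seq_len(M)),
                 method = "exact"),
            class = "shap_attribution")
}

.shapley_kernel_weight <- function(M, s) {
  (M - 1) / (choose(M, s) * s * (M - s))
}

.kernel_one_row <- function(model_fn, row, background, Z, w, fx, base) {
  M <- ncol(Z)
  v <- .coalition_values(model_fn, row, background, Z)
  A <- Z[, -M, drop = FALSE] - Z[, M]
  yv <- v - base - Z[, M] * (fx - base)
  AtW <- t(A * w)
  lhs <- AtW %*% A
  rhs <- AtW %*% yv
  phi_head <- tryCatch(solve(lhs, rhs), error = function(e) {
    warning("singular kernel design; ridge fallback applied")
    solve(lhs + diag(1e-8, ncol(lhs)), rhs)
  })
  c(as.vector(phi_head), fx - base - sum(phi_head))
}

#' Sampling-based (kernel) Shapley estimator
#'
#' Weighted least squares over coalitions with Shapley kernel weights,
#' constrained so attributions plus base reproduce each row's prediction
#' (local accuracy).  When the budget covers all `2^M - 2` proper
#' coalitions the full enumeration is used and the estimate equals the
#' exact Shapley values; otherwise coalitions are sampled by kernel
#' weight, deterministically given `seed`.
#'
#' @param model_fn vectorized prediction function over a numeric matrix.
#' @param rows numeric matrix of inputs to explain (<= 200 by convention).
#' @param background numeric matrix of reference rows (<= 30 by
#'   convention, drawn from training data).
#' @param budget number of coalitions to evaluate (>= 2M + 2).
#' @param seed integer seed.
#' @return `shap_attribution` with one attribution row per explained row.
#' @export
kernel_shapley <- function(model_fn, rows, background, budget = 200L,
                           seed = 1L) {
  rows <- as.matrix(rows); background <- as.matrix(background)
  M <- ncol(rows)
  if (budget < 2 * M + 2) stop("budget must be at least 2M + 2")
  full <- 2^M - 2
  if (budget >= full) {
    Z <- matrix(0L, full, M)
    k <- 0L
    for (i in seq_len(2^M - 2)) {
      bits <- as.integer(intToBits(i)[1:M])
      Z[i, ] <- bits
    }
    sizes <- rowSums(Z)
    w <- .shapley_kernel_weight(M, sizes)
  } else {
    Z <- with_seed(seed, {
      sizes_all <- 1:(M - 1)
      size_w <- vapply(sizes_all, function(s)
        choose(M, s) * .shapley_kernel_weight(M, s), numeric(1))
      smp <- sample(sizes_all, budget, replace = TRUE,
                    prob = size_w / sum(size_w))
      t(vapply(smp, function(s) {
        z <- integer(M); z[sample.int(M, s)] <- 1L; z
      }, integer(M)))
    })
    w <- rep(1, nrow(Z))  # kernel weight absorbed into sampling frequency
  }
  base <- mean(model_fn(background))
  fx <- model_fn(rows)
  phi <- t(vapply(seq_len(nrow(rows)), function(i)
    .kernel_one_row(model_fn, rows[i, ], background, Z, w, fx[i], base),
    numeric(M)))
  colnames(phi) <- colnames(rows) %||% paste0("x", seq_len(M))
  structure(list(phi = phi, base = base, pred = fx,
                 features = colnames(phi), method = "kernel"),
            class = "shap_attribution")
}

#' @export
print.shap_attribution <- function(x, ...) {
  cat(sprintf("<shap_attribution> %d row(s) x %d features (%s), base %.4g\n",
              nrow(x$phi), ncol(x$phi), x$method, x$base))
  invisible(x)
}

#' Rank attributions and compute modality shares
#'
#' Per-feature mean absolute Shapley value, the top-k ranking, and the
#' share of the top-k importance mass carried by each modality
#' (preclinical PK, physicochemical, CNN embedding, MLP embedding).
#' Shares sum to 1.
#'
#' @param attr a `shap_attribution`.
#' @param feature_modalities named character vector mapping every feature
#'   to a modality label.
#' @param top_k size of the ranking (default 10).
#' @return list with `importance` (named, sorted), `top` (data.frame) and
#'   `modality_shares` (named numeric).
#' @export
summarize_attributions <- function(attr, feature_modalities, top_k = 10L) {
  stopifnot(inherits(attr, "shap_attribution"))
  feats <- attr$features
  unmapped <- setdiff(feats, names(feature_modalities))
  if (length(unmapped))
    stop("unmapped features: ", paste(unmapped, collapse = ", "))
  imp <- colMeans(abs(attr$phi))
  names(imp) <- feats
  imp <- sort(imp, decreasing = TRUE)
  top <- head(imp, top_k)
  top_df <- data.frame(feature = names(top), mean_abs_shap = unname(top),
                       modality = unname(feature_modalities[names(top)]))
  tot <- sum(top)
  sums <- tapply(top_df$mean_abs_shap, top_df$modality, sum)
  shares <- stats::setNames(as.numeric(sums), names(sums))
  shares <- if (tot > 0) shares / tot else shares * 0
  list(importance = imp, top = top_df,
       modality_shares = shares[order(-shares)])
}
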