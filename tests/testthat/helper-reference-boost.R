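# Independent brute-force second-order boosting reference, used as the
# oracle for the tree engine.  Deliberately written in a different style:
# recursive-free, data.frame node bookkeeping, plain loops everywhere.

ref_best_split <- function(X, g, h, rows, lambda2, min_child) {
  best <- list(gain = 0, feature = NA, threshold = NA)
  Gp <- sum(g[rows]); Hp <- sum(h[rows])
  parent <- if (Hp + lambda2 > 0) Gp^2 / (Hp + lambda2) else 0
  for (f in seq_len(ncol(X))) {
    xs <- sort(unique(X[rows, f]))
    if (length(xs) < 2) next
    for (ti in seq_len(length(xs) - 1)) {
      thr <- (xs[ti] + xs[ti + 1]) / 2
      lef <- rows[X[rows, f] <= thr]
      rig <- rows[X[rows, f] > thr]
      if (length(lef) < min_child || length(rig) < min_child) next
      GL <- sum(g[lef]); HL <- sum(h[lef])
      GR <- sum(g[rig]); HR <- sum(h[rig])
      gain <- -parent
      if (HL + lambda2 > 0) gain <- gain + GL^2 / (HL + lambda2)
      if (HR + lambda2 > 0) gain <- gain + GR^2 / (HR + lambda2)
      if (gain > best$gain) best <- list(gain = gain, feature = f,
                                         threshold = thr)
    }
  }
  if (is.na(best$feature)) NULL else best
}

# Best-first growth; returns per-row leaf value vector for the round.
ref_tree_values <- function(X, g, h, num_leaves, max_depth, lambda2,
                            min_child) {
  leaves <- list(list(rows = seq_len(nrow(X)), depth = 0))
  n_leaves <- 1
  while (n_leaves < num_leaves) {
    gains <- rep(-Inf, length(leaves))
    cands <- vector("list", length(leaves))
    for (k in seq_along(leaves)) {
      if (leaves[[k]]$depth >= max_depth) next
      s <- ref_best_split(X, g, h, leaves[[k]]$rows, lambda2, min_child)
      if (!is.null(s)) { gains[k] <- s$gain; cands[[k]] <- s }
    }
    if (all(!is.finite(gains))) break
    k <- which.max(gains)          # first max = lowest node id
    s <- cands[[k]]
    rows <- leaves[[k]]$rows
    lef <- rows[X[rows, s$feature] <= s$threshold]
    rig <- rows[X[rows, s$feature] > s$threshold]
    d <- leaves[[k]]$depth + 1
    leaves[[k]] <- list(rows = lef, depth = d)
    leaves[[length(leaves) + 1]] <- list(rows = rig, depth = d)
    n_leaves <- n_leaves + 1
  }
  vals <- numeric(nrow(X))
  for (lf in leaves) {
    G <- sum(g[lf$rows]); H <- sum(h[lf$rows])
    vals[lf$rows] <- if (H + lambda2 > 0) -G / (H + lambda2) else 0
  }
  vals
}

# Per-round predictions of plain single-task second-order boosting
# (lambda1 = 0, squared-error loss).
ref_boost_predictions <- function(X, y, lr, num_leaves, max_depth,
                                  lambda2, min_child, n_rounds) {
  pred <- rep(mean(y), nrow(X))
  out <- matrix(NA_real_, nrow(X), n_rounds)
  for (r in seq_len(n_rounds)) {
    g <- pred - y
    h <- rep(1, length(y))
    pred <- pred + lr * ref_tree_values(X, g, h, num_leaves, max_depth,
                                        lambda2, min_child)
    out[, r] <- pred
  }
  out
}
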