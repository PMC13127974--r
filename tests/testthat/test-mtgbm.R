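test_that("task gradients implement the squared-error objective with masks", {
  y <- cbind(c(1, 2, 3), c(4, NA, 6))
  pred <- cbind(c(1, 2, 3), c(0, 0, 0))
  gr <- compute_task_gradients(pred, y)
  expect_equal(gr$g[, 1], c(0, 0, 0))
  expect_equal(gr$g[, 2], c(-4, 0, -6))
  expect_equal(gr$h[, 2], c(1, 0, 1))

  gr2 <- compute_task_gradients(matrix(0), matrix(3))
  expect_equal(gr2$g[1, 1], -3)
  expect_equal(gr2$h[1, 1], 1)

  expect_error(compute_task_gradients(matrix(0), matrix(NaN),
                                      masks = matrix(TRUE)), "NaN")
})

test_that("best split matches the hand-computed second-order gain", {
  X <- matrix(c(0, 1, 2, 3), ncol = 1)
  gr <- compute_task_gradients(matrix(c(-1, -1, 1, 1)),
                               matrix(rep(0, 4)))  # g = (-1,-1,1,1), h = 1
  cfg <- boost_config(n_tasks = 1, lambda_l2 = 0, min_child_samples = 1)
  s <- find_best_split(X, gr, cfg)
  expect_equal(s$feature, 1)
  expect_equal(s$threshold, 1.5)
  expect_equal(s$gain, 4)  # (-2)^2/2 + 2^2/2 - 0

  # duplicated task: same argmax, gain exactly doubled
  gr2 <- structure(list(g = cbind(gr$g, gr$g), h = cbind(gr$h, gr$h),
                        masks = cbind(gr$masks, gr$masks)),
                   class = "task_gradients")
  cfg2 <- boost_config(n_tasks = 2, lambda_l2 = 0, min_child_samples = 1)
  s2 <- find_best_split(X, gr2, cfg2)
  expect_equal(s2$feature, s$feature)
  expect_equal(s2$threshold, s$threshold)
  expect_equal(s2$gain, 2 * s$gain)

  # constant feature matrix: no split
  grc <- compute_task_gradients(matrix(rnorm(4)), matrix(rep(0, 4)))
  expect_null(find_best_split(matrix(1, 4, 1), grc, cfg))
})

test_that("leaf values apply the soft-thresholded Newton step", {
  X <- matrix(1, 2, 1)  # single leaf (no split possible)
  mk_grads <- function() compute_task_gradients(matrix(c(0, 0)),
                                                matrix(c(1, 3)))
  leafval <- function(l1, l2) {
    cfg <- boost_config(n_tasks = 1, lambda_l1 = l1, lambda_l2 = l2,
                        min_child_samples = 1)
    tr <- grow_shared_tree(X, mk_grads(), cfg)
    tr$leaf_values[tr$row_node[1], 1]
  }
  expect_equal(leafval(0, 0), 2)      # mean residual
  expect_equal(leafval(0, 2), 1)      # -(-4)/(2+2)
  expect_equal(leafval(5, 0), 0)      # |G| = 4 < lambda1
})

test_that("engine matches the brute-force reference per round", {
  set.seed(42)
  for (trial in 1:3) {
    n <- sample(20:50, 1)
    p <- sample(2:5, 1)
    X <- matrix(rnorm(n * p), n, p)
    y <- X[, 1] + rnorm(n)
    lr <- 0.3; nl <- 6L; md <- 3L; l2 <- runif(1, 0, 2); mc <- 2L; R <- 10L
    ref <- ref_boost_predictions(X, y, lr, nl, md, l2, mc, R)
    cfg <- boost_config(learning_rate = lr, num_leaves = nl, max_depth = md,
                        lambda_l1 = 0, lambda_l2 = l2,
                        min_child_samples = mc, max_rounds = R,
                        patience = R, n_tasks = 1)
    m <- mtgbm_fit(X, y, cfg = cfg)
    ours <- vapply(seq_len(R),
                   function(r) mtgbm_predict(m, X, 1, n_trees = r),
                   numeric(n))
    expect_lt(max(abs(ours - ref)), 1e-9)
  }
})

test_that("duplicating one target as two tasks reduces to the single-task fit", {
  set.seed(7)
  n <- 80
  X <- matrix(rnorm(n * 4), n, 4)
  y <- X[, 1] + 0.5 * X[, 2]^2 + rnorm(n, 0, 0.2)
  Xv <- matrix(rnorm(30 * 4), 30, 4)
  yv <- Xv[, 1] + 0.5 * Xv[, 2]^2 + rnorm(30, 0, 0.2)
  mk <- function(k) boost_config(learning_rate = 0.1, num_leaves = 8,
                                 max_depth = 4, lambda_l1 = 0.1,
                                 lambda_l2 = 1, min_child_samples = 5,
                                 max_rounds = 100, patience = 20,
                                 n_tasks = k)
  m1 <- mtgbm_fit(X, y, Xv, yv, mk(1))
  m2 <- mtgbm_fit(X, cbind(y, y), Xv, cbind(yv, yv), mk(2))
  p1 <- mtgbm_predict(m1, Xv, 1)
  expect_lt(max(abs(mtgbm_predict(m2, Xv, 1) - mtgbm_predict(m2, Xv, 2))),
            1e-12)
  expect_lt(max(abs(mtgbm_predict(m2, Xv, 1) - p1)), 1e-12)
})

test_that("training loss is non-increasing without L1", {
  set.seed(3)
  X <- matrix(rnorm(200), 50, 4)
  y <- X[, 1] + rnorm(50)
  m <- mtgbm_fit(X, y, cfg = boost_config(
    learning_rate = 0.2, num_leaves = 8, max_depth = 4, lambda_l1 = 0,
    lambda_l2 = 1, min_child_samples = 5, max_rounds = 40, patience = 40,
    n_tasks = 1))
  expect_true(all(diff(m$log$train) <= 1e-12))
})

test_that("rows masked for a task contribute nothing to its leaf values", {
  set.seed(5)
  X <- matrix(rnorm(40), 20, 2)
  y1 <- X[, 1] + rnorm(20, 0, 0.1)
  y2 <- X[, 2] + rnorm(20, 0, 0.1)
  y2[1:8] <- NA
  gr <- compute_task_gradients(matrix(0, 20, 2), cbind(y1, y2))
  cfg <- boost_config(n_tasks = 2, lambda_l1 = 0, lambda_l2 = 0.5,
                      num_leaves = 4, max_depth = 3, min_child_samples = 2)
  tr <- grow_shared_tree(X, gr, cfg)
  for (leaf in unique(tr$row_node)) {
    rows <- which(tr$row_node == leaf)
    unmasked <- rows[!is.na(y2[rows])]
    G2 <- sum(-y2[unmasked]); H2 <- length(unmasked)
    expected <- if (H2 + 0.5 > 0) -G2 / (H2 + 0.5) else 0
    expect_equal(tr$leaf_values[leaf, 2], expected, tolerance = 1e-12)
  }
})

test_that("prediction reproduces base scores and the training log", {
  set.seed(11)
  X <- matrix(rnorm(60), 30, 2)
  y <- X[, 1] + rnorm(30, 0, 0.3)
  cfg0 <- boost_config(n_tasks = 1, max_rounds = 1, patience = 1,
                       learning_rate = 0.1, num_leaves = 2,
                       min_child_samples = 30)  # no split possible -> base
  m0 <- mtgbm_fit(X, y, cfg = cfg0)
  expect_equal(mtgbm_predict(m0, X, 1, n_trees = 0), rep(mean(y), 30))

  cfg <- boost_config(n_tasks = 1, learning_rate = 0.1, num_leaves = 6,
                      max_depth = 3, lambda_l1 = 0, lambda_l2 = 1,
                      min_child_samples = 3, max_rounds = 15, patience = 15)
  m <- mtgbm_fit(X, y, cfg = cfg)
  pred <- mtgbm_predict(m, X, 1, n_trees = length(m$trees))
  expect_equal(mean((pred - y)^2), m$log$train[length(m$trees)],
               tolerance = 1e-12)

  # column mismatch names the missing columns
  colnames(X) <- c("a", "b")
  mnamed <- mtgbm_fit(X, y, cfg = cfg)
  bad <- X[, 1, drop = FALSE]
  expect_error(mtgbm_predict(mnamed, bad, 1), "b")
})

test_that("fit validates inputs and echoes the documented defaults", {
  cfg <- boost_config()
  expect_equal(cfg$learning_rate, 0.014)
  expect_equal(cfg$num_leaves, 44L)
  expect_equal(cfg$max_depth, 13L)
  expect_equal(cfg$lambda_l1, 0.71)
  expect_equal(cfg$lambda_l2, 2.89)
  expect_equal(cfg$max_rounds, 15000L)
  expect_equal(cfg$n_tasks, 2L)

  X <- matrix(rnorm(20), 10, 2)
  expect_error(mtgbm_fit(X, cbind(rnorm(10), rep(NA_real_, 10)),
                         cfg = boost_config(max_rounds = 5)),
               "no unmasked")
})

test_that("JSON serialization round-trips predictions exactly", {
  set.seed(4)
  X <- matrix(rnorm(200), 50, 4)
  colnames(X) <- paste0("f", 1:4)
  Y <- cbind(X[, 1] + rnorm(50, 0, 0.2), X[, 2] + rnorm(50, 0, 0.2))
  m <- mtgbm_fit(X, Y, cfg = boost_config(
    learning_rate = 0.1, num_leaves = 6, max_depth = 3,
    min_child_samples = 3, max_rounds = 20, patience = 20))
  path <- tempfile(fileext = ".json")
  mtgbm_to_json(m, path)
  m2 <- mtgbm_from_json(path)
  for (t in 1:2)
    expect_equal(mtgbm_predict(m2, X, t), mtgbm_predict(m, X, t),
                 tolerance = 1e-12)
  expect_identical(m2$best_iteration, m$best_iteration)
  expect_identical(m2$feature_names, m$feature_names)
})

test_that("single-task HPO is seeded and honors collapsed search spaces", {
  set.seed(2)
  X <- matrix(rnorm(240), 60, 4); y <- X[, 1] + rnorm(60, 0, 0.5)
  Xv <- matrix(rnorm(80), 20, 4); yv <- Xv[, 1] + rnorm(20, 0, 0.5)
  inv <- function(v) exp(v)  # positive original scale
  h1 <- hpo_single_task(X, y, Xv, yv, exp(yv), inv, n_trials = 1,
                        seed = 9, max_rounds = 30, patience = 10)
  expect_s3_class(h1$config, "boost_config")
  expect_length(h1$record, 1)
  h1b <- hpo_single_task(X, y, Xv, yv, exp(yv), inv, n_trials = 3,
                         seed = 9, max_rounds = 30, patience = 10)
  h1c <- hpo_single_task(X, y, Xv, yv, exp(yv), inv, n_trials = 3,
                         seed = 9, max_rounds = 30, patience = 10)
  expect_identical(unclass(h1b$config), unclass(h1c$config))

  point <- list(lr = c(0.02, 0.02), num_leaves = c(10, 10),
                max_depth = c(7, 7), min_child_samples = c(12, 12),
                lambda = c(1, 1))
  hp <- hpo_single_task(X, y, Xv, yv, exp(yv), inv, n_trials = 2,
                        seed = 4, max_rounds = 30, patience = 10,
                        space = point)
  expect_equal(hp$config$learning_rate, 0.02)
  expect_equal(hp$config$num_leaves, 10L)
  expect_equal(hp$config$max_depth, 7L)
  expect_equal(hp$config$min_child_samples, 12L)
})
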