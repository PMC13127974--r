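test_that("exact Shapley recovers additive coefficients and axioms", {
  fn <- function(X) 2 * X[, 1] + 3 * X[, 2]
  bg <- matrix(0, 5, 2)
  a <- exact_shapley(fn, c(x1 = 1, x2 = 1), bg)
  expect_equal(as.vector(a$phi), c(2, 3))
  expect_equal(a$base, 0)
  expect_equal(a$pred, 5)

  const <- exact_shapley(function(X) rep(7, nrow(X)), c(1, 2),
                         matrix(rnorm(6), 3, 2))
  expect_equal(as.vector(const$phi), c(0, 0))
  expect_equal(const$base, 7)

  # symmetry: duplicated feature contributing through the sum
  sym <- exact_shapley(function(X) X[, 1] + X[, 2], c(2, 2),
                       matrix(0, 4, 2))
  expect_equal(sym$phi[1], sym$phi[2])

  # dummy: an irrelevant feature gets exactly zero
  dum <- exact_shapley(function(X) X[, 1], c(1, 5),
                       matrix(rnorm(8), 4, 2))
  expect_equal(dum$phi[1, 2], 0)

  expect_error(exact_shapley(fn, rnorm(13), matrix(0, 2, 13)),
               "12 features")
})

test_that("kernel estimator agrees with enumeration and is locally accurate", {
  set.seed(3)
  n <- 60
  X <- matrix(rnorm(n * 6), n, 6)
  colnames(X) <- paste0("f", 1:6)
  y <- 2 * X[, 1] + X[, 3] + rnorm(n, 0, 0.1)
  m <- mtgbm_fit(X, y, cfg = boost_config(
    learning_rate = 0.2, num_leaves = 8, max_depth = 3, lambda_l1 = 0,
    lambda_l2 = 1, min_child_samples = 5, max_rounds = 40, patience = 40,
    n_tasks = 1))
  fn <- function(M) { colnames(M) <- colnames(X); mtgbm_predict(m, M, 1) }
  bg <- X[1:10, ]
  rows <- X[11:15, ]
  ke <- kernel_shapley(fn, rows, bg, budget = 2^6, seed = 5)
  ex <- t(vapply(11:15, function(i) exact_shapley(fn, X[i, ], bg)$phi[1, ],
                 numeric(6)))
  expect_lt(max(abs(ke$phi - ex)), 1e-6)
  expect_lt(max(abs(ke$base + rowSums(ke$phi) - ke$pred)), 1e-6)
  # determinism at a sampled budget
  k1 <- kernel_shapley(fn, rows, bg, budget = 20, seed = 7)
  k2 <- kernel_shapley(fn, rows, bg, budget = 20, seed = 7)
  expect_identical(k1$phi, k2$phi)
  expect_lt(max(abs(k1$base + rowSums(k1$phi) - k1$pred)), 1e-6)
  expect_error(kernel_shapley(fn, rows, bg, budget = 5), "2M")
})

test_that("sampling error shrinks toward enumeration as budget grows", {
  fn <- function(X) X[, 1] * 2 + X[, 2] * X[, 3]
  set.seed(9)
  X8 <- matrix(rnorm(40 * 8), 40, 8)
  exv <- exact_shapley(fn, X8[1, ], X8[2:11, ])$phi[1, ]
  errs <- vapply(c(40, 120, 2^8 - 2), function(b)
    max(abs(kernel_shapley(fn, X8[1, , drop = FALSE], X8[2:11, ],
                           budget = b, seed = 3)$phi[1, ] - exv)),
    numeric(1))
  expect_lt(errs[3], 1e-6)
  expect_lt(errs[3], errs[1])
})

test_that("attribution summaries rank features and split modality mass", {
  phi <- rbind(c(2, 0, 0), c(-4, 0, 0))
  attr <- structure(list(phi = phi, base = 0, pred = c(2, -4),
                         features = c("a", "b", "c"), method = "exact"),
                    class = "shap_attribution")
  mods <- c(a = "preclinical_pk", b = "physicochemical",
            c = "embedding_mlp")
  s <- summarize_attributions(attr, mods)
  expect_equal(unname(s$modality_shares["preclinical_pk"]), 1)
  expect_equal(sum(s$modality_shares), 1)

  phi2 <- rbind(c(1, 1), c(-1, 1))
  attr2 <- structure(list(phi = phi2, base = 0, pred = c(0, 0),
                          features = c("a", "b"), method = "exact"),
                     class = "shap_attribution")
  s2 <- summarize_attributions(attr2, mods[c("a", "b")])
  expect_equal(unname(s2$modality_shares), c(0.5, 0.5))

  phi3 <- rbind(c(3, 2, 1))
  attr3 <- structure(list(phi = phi3, base = 0, pred = 6,
                          features = c("a", "b", "c"), method = "exact"),
                     class = "shap_attribution")
  s3 <- summarize_attributions(attr3, mods, top_k = 2)
  expect_equal(s3$top$feature, c("a", "b"))
  expect_equal(unname(s3$modality_shares["preclinical_pk"]), 3 / 5)

  expect_error(summarize_attributions(attr, mods[1:2]), "unmapped")
})
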