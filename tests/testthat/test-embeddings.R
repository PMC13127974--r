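test_that("descriptor vectors have the documented layout", {
  v <- assemble_descriptor_vector("CCO")
  expect_length(v, 561)
  expect_equal(unname(v["HBD"]), 1)  # ethanol: one donor
  expect_equal(unname(v["HBA"]), 1)  # one acceptor
  fp <- v[grep("^fp_", names(v))]
  expect_length(fp, 256)
  expect_true(all(fp %in% c(0, 1)))
  expect_length(grep("^sub_", names(v)), 300)
  expect_identical(v, assemble_descriptor_vector("CCO"))
  expect_error(descriptor_matrix("][junk"), "SMILES")
})

test_that("structurally different molecules get different fingerprints", {
  d <- descriptor_matrix(c("CCO", "CCN", "C1CCCCC1", "CCO"))
  fp <- d[, grep("^fp_", colnames(d))]
  expect_false(identical(fp[1, ], fp[2, ]))
  expect_false(identical(fp[1, ], fp[3, ]))
  expect_identical(fp[1, ], fp[4, ])
})

test_that("molecule images are fixed-shape, bounded and deterministic", {
  im <- render_molecule_image("CCO")
  expect_equal(dim(im$pixels), c(224, 224, 3))
  expect_true(all(im$pixels >= 0 & im$pixels <= 1))
  expect_lt(min(im$pixels), 1)  # something was drawn
  expect_identical(im$pixels, render_molecule_image("CCO")$pixels)
  expect_false(identical(im$pixels, render_molecule_image("CCCCC")$pixels))
  expect_error(render_molecule_image("not_a_smiles"), "SMILES")
})

test_that("MLP embedder learns, is seeded, and never mutates at inference", {
  set.seed(1)
  n <- 100
  X <- matrix(rnorm(n * 8), n, 8)
  y <- as.vector(X %*% c(2, -1, rep(0, 6)))  # noiseless linear target
  tr <- 1:60; va <- 61:100
  budget <- hpo_budget(n_trials = 1, patience = 10, max_epochs = 60,
                       seed = 5)
  m <- train_embedder("mlp", "CL", X, y, tr, va, budget)
  expect_s3_class(m, "embedding_model")
  # learnability: residual loss far below target variance
  expect_lt(m$final_val, var(y[va]) / 10)
  # determinism of the whole three-step protocol
  m2 <- train_embedder("mlp", "CL", X, y, tr, va, budget)
  expect_identical(m$net$params, m2$net$params)
  expect_identical(m$config, m2$config)

  e1 <- extract_embeddings(m, X)
  expect_equal(dim(e1), c(n, 2))
  expect_identical(colnames(e1), c("mlp_vec1_CL", "mlp_vec2_CL"))
  params_before <- m$net$params
  e2 <- extract_embeddings(m, X)
  expect_identical(m$net$params, params_before)
  expect_identical(e1, e2)
  # embedding informativeness on held-out rows: the bottleneck is 2-d and
  # which dimension carries the signal is arbitrary, so check the best
  expect_gt(max(abs(cor(e1[va, ], y[va], method = "spearman"))), 0.3)
})

test_that("embedder training ignores rows outside train/val", {
  set.seed(2)
  n <- 60
  X <- matrix(rnorm(n * 5), n, 5)
  y <- as.vector(X %*% c(1.5, rep(0, 4))) + rnorm(n, 0, 0.1)
  tr <- 1:30; va <- 31:45  # rows 46:60 are test
  budget <- hpo_budget(n_trials = 1, patience = 6, max_epochs = 30, seed = 3)
  m1 <- train_embedder("mlp", "VD", X, y, tr, va, budget)
  y_corrupt <- y
  y_corrupt[46:60] <- 1e6
  m2 <- train_embedder("mlp", "VD", X, y_corrupt, tr, va, budget)
  expect_identical(m1$net$params, m2$net$params)
  expect_identical(extract_embeddings(m1, X), extract_embeddings(m2, X))
})

test_that("embedder contracts: empty validation errors, budget of one trains", {
  X <- matrix(rnorm(40), 20, 2); y <- rnorm(20)
  expect_error(train_embedder("mlp", "CL", X, y, 1:10, integer(0)),
               "validation")
  expect_error(extract_embeddings(structure(list(trained = FALSE),
                                            class = "embedding_model"), X),
               "trained")
})

test_that("CNN embedder trains on rendered molecules and extracts 2-d codes", {
  smiles <- generate_molecules(24, seed = 9, max_heavy_atoms = 16)
  imgs <- lapply(smiles, render_molecule_image)
  counts <- vapply(mol_graphs(smiles), `[[`, numeric(1), "n_atoms")
  y <- as.vector(scale(counts))
  tr <- 1:16; va <- 17:24
  budget <- hpo_budget(n_trials = 1, patience = 2, max_epochs = 3,
                       pool_factor = 16L, channels = c(3L, 6L), seed = 7)
  m <- train_embedder("cnn", "VD", imgs, y, tr, va, budget)
  e <- extract_embeddings(m, imgs)
  expect_equal(dim(e), c(24, 2))
  expect_identical(colnames(e), c("cnn_vec1_VD", "cnn_vec2_VD"))
  expect_identical(e, extract_embeddings(m, imgs))
  m2 <- train_embedder("cnn", "VD", imgs, y, tr, va, budget)
  expect_identical(extract_embeddings(m2, imgs), e)
})
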