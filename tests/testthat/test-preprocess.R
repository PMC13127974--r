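test_that("merge keys on whitespace-stripped name and SMILES", {
  cl <- data.frame(name = "drug A", smiles = "CCO",
                   human_CL_mL_min_kg = 5, stringsAsFactors = FALSE)
  vd <- data.frame(name = "drugA ", smiles = "CCO",
                   human_VDss_L_kg = 1.2, stringsAsFactors = FALSE)
  m <- merge_cl_vd(cl, vd)
  expect_equal(nrow(m), 1)
  expect_equal(m$human_CL_mL_min_kg, 5)
  expect_equal(m$human_VDss_L_kg, 1.2)

  # CL-only compound kept with missing VD
  m2 <- merge_cl_vd(cl, vd[0, , drop = FALSE])
  expect_equal(nrow(m2), 1)
  expect_true(is.na(m2$human_VDss_L_kg))

  # compounds with neither target are dropped
  cl3 <- data.frame(name = c("a", "b"), smiles = c("C", "CC"),
                    human_CL_mL_min_kg = c(NA, 2), stringsAsFactors = FALSE)
  m3 <- merge_cl_vd(cl3, vd[0, , drop = FALSE])
  expect_equal(m3$name, "b")

  # strict both-targets mode
  m4 <- merge_cl_vd(cl3, vd, require_both = FALSE)
  expect_equal(nrow(m4), 2)  # "b" (CL) and "drugA" (VD)
})

test_that("duplicate keys within one table raise an error naming the key", {
  cl <- data.frame(name = c("x", "x "), smiles = c("CCO", "C CO"),
                   human_CL_mL_min_kg = c(1, 2), stringsAsFactors = FALSE)
  expect_error(merge_cl_vd(cl, cl[0, , drop = FALSE]),
               "duplicate.*x")
})

test_that("physiological filter removes out-of-range compounds inclusively", {
  rec <- data.frame(
    name = letters[1:5],
    human_CL_mL_min_kg = c(25, 19.9, 20.0, NA, 5),
    human_VDss_L_kg = c(1, 4.9, 1, 5.0, NA))
  out <- filter_physiological(rec)
  expect_setequal(out$records$name, c("b", "e"))
  expect_equal(out$removed_count, 3)
  # idempotence
  again <- filter_physiological(out$records)
  expect_identical(again$records, out$records)
  expect_equal(again$removed_count, 0)
})

test_that("winsorization matches the sorted-percentile rule", {
  x <- as.numeric(1:100)
  w <- winsorize(x)
  q <- quantile(x, c(0.01, 0.99), type = 7, names = FALSE)
  expect_equal(min(w), q[1])
  expect_equal(max(w), q[2])
  expect_equal(w[3:98], x[3:98])  # interior unchanged

  expect_equal(winsorize(rep(7, 10)), rep(7, 10))
  expect_equal(winsorize(c(3, NA)), c(3, NA))
  expect_warning(winsorize(c(NA_real_, NA_real_)), "missing")
})

test_that("fitted transforms follow column roles and invert exactly", {
  set.seed(1)
  train <- data.frame(
    human_CL_mL_min_kg = rlnorm(50),
    rat_CL_mL_min_kg = rlnorm(50),
    pKa_Acid = rnorm(50, 5),
    Caco_2_flux = rnorm(50))
  roles <- c(human_CL_mL_min_kg = "target", rat_CL_mL_min_kg = "animal_pk",
             pKa_Acid = "physicochemical", Caco_2_flux = "physicochemical")
  sc <- fit_transforms(train, roles)
  expect_equal(sc$params$Caco_2_flux$kind, "excluded")
  expect_equal(sc$params$human_CL_mL_min_kg$kind, "log1p_standardize")
  expect_equal(sc$params$pKa_Acid$kind, "standardize_only")

  tr <- apply_transforms(sc, train)
  expect_equal(mean(tr$human_CL_mL_min_kg), 0, tolerance = 1e-12)
  expect_identical(tr$Caco_2_flux, train$Caco_2_flux)

  for (col in c("human_CL_mL_min_kg", "rat_CL_mL_min_kg", "pKa_Acid")) {
    x <- if (grepl("Ka", col)) rnorm(200) else rlnorm(200, 1, 2)
    z <- apply_transforms(sc, stats::setNames(data.frame(x), col))[[1]]
    expect_lt(max(abs(invert_transform(sc, col, z) - x)), 1e-10)
  }
})

test_that("zero-variance columns get a unit-sd guard", {
  train <- data.frame(human_CL_mL_min_kg = rep(exp(1) - 1, 10))
  expect_warning(
    sc <- fit_transforms(train, c(human_CL_mL_min_kg = "target")),
    "zero-variance")
  z <- apply_transforms(sc, train)[[1]]
  expect_equal(z, rep(0, 10))
})

test_that("optimized splits respect ratios and improve on a single draw", {
  cfg <- synth_config(n_compounds = 100, seed = 21)
  rec <- generate_pk_dataset(cfg)$records
  plan1 <- optimize_split(rec, n_candidates = 1, seed = 5)
  plan50 <- optimize_split(rec, n_candidates = 50, seed = 5)
  expect_equal(length(plan50$train_idx), 60)
  expect_equal(length(plan50$val_idx), 20)
  expect_equal(length(plan50$test_idx), 20)
  # same seed: candidate 1 is in both streams, so argmin can only improve
  expect_lte(plan50$criterion, plan1$criterion)
  idx <- c(plan50$train_idx, plan50$val_idx, plan50$test_idx)
  expect_setequal(idx, seq_len(nrow(rec)))
  expect_equal(anyDuplicated(idx), 0)
  # determinism
  expect_identical(unclass(plan50),
                   unclass(optimize_split(rec, n_candidates = 50, seed = 5)))
})

test_that("repeated splits are seeded, disjoint and exhaustive", {
  cfg <- synth_config(n_compounds = 73, seed = 4)
  rec <- generate_pk_dataset(cfg)$records
  plans <- repeated_splits(rec, k = 10, base_seed = 100)
  expect_length(plans, 10)
  expect_equal(vapply(plans, `[[`, numeric(1), "seed"), 100:109)
  for (p in plans) {
    idx <- c(p$train_idx, p$val_idx, p$test_idx)
    expect_setequal(idx, seq_len(nrow(rec)))
    expect_equal(anyDuplicated(idx), 0)
  }
  plans2 <- repeated_splits(rec, k = 10, base_seed = 100)
  expect_identical(plans, plans2)
  expect_false(identical(plans[[1]]$train_idx, plans[[2]]$train_idx))
})
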