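#' Configuration for the end-to-end modeling pipeline
#'
#' Two presets are provided.  `"paper"` mirrors the full study protocol:
#' 10,000 split candidates scored by distribution similarity, 100
#' hyperparameter-search trials per embedder, 5,000 selection iterations,
#' single-task hyperparameter search, and up to 15,000 boosting rounds.
#' `"tiny"` scales every budget down (single embedding trials, a reduced
#' CNN, 200 selection iterations, 200 boosting rounds, random split) so a
#' complete run finishes on one CPU in about a minute per stage; it is the
#' preset used by the package's own tests.
#'
#' @param profile `"tiny"` or `"paper"`.
#' @param seed global seed; per-stage seeds are derived from it.
#' @param out_dir artifact directory.
#' @param synth a [synth_config()] for synthetic data, or NULL with
#'   `data_csv` pointing at a compound table.
#' @param data_csv optional path to a compound CSV in the canonical
#'   column layout (used when `synth` is NULL).
#' @param ... named overrides of any top-level field of the returned list.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(profile = c("tiny", "paper"), seed = 42L,
                            out_dir = tempfile("pkrun"), synth = NULL,
                            data_csv = NULL, ...) {
  profile <- match.arg(profile)
  tiny <- profile == "tiny"
  cfg <- list(
    profile = profile,
    seed = as.integer(seed),
    out_dir = out_dir,
    synth = synth %||% (if (is.null(data_csv))
      synth_config(n_compounds = if (tiny) 200L else 700L,
                   seed = stage_seed(seed, "simulate"))),
    data_csv = data_csv,
    split = list(method = if (tiny) "random" else "optimized",
                 n_candidates = if (tiny) 50L else 10000L,
                 ratios = c(0.6, 0.2, 0.2)),
    embeddings = list(
      kinds = c("mlp", "cnn"),
      mlp_budget = hpo_budget(n_trials = if (tiny) 1L else 100L,
                              patience = if (tiny) 8L else 20L,
                              max_epochs = if (tiny) 40L else 300L),
      cnn_budget = hpo_budget(n_trials = if (tiny) 1L else 100L,
                              patience = if (tiny) 3L else 10L,
                              max_epochs = if (tiny) 8L else 60L,
                              pool_factor = if (tiny) 16L else 8L,
                              channels = if (tiny) c(4L, 8L) else c(8L, 16L))),
    selection = list(enabled = TRUE,
                     config = selection_config(
                       n_iterations = if (tiny) 200L else 5000L,
                       n_explain = if (tiny) 8L else 16L)),
    st = list(hpo = !tiny, n_trials = if (tiny) 1L else 100L,
              config = boost_config(
                learning_rate = 0.03, num_leaves = 16L, max_depth = 6L,
                lambda_l1 = 0.71, lambda_l2 = 2.89,
                max_rounds = if (tiny) 200L else 15000L,
                patience = if (tiny) 50L else 150L, n_tasks = 1L)),
    mt = list(config = boost_config(
      max_rounds = if (tiny) 200L else 15000L,
      patience = if (tiny) 50L else 150L, n_tasks = 2L)),
    explain = list(enabled = TRUE,
                   n_test = if (tiny) 30L else 200L,
                   n_background = if (tiny) 10L else 30L))
  dots <- list(...)
  for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]
  structure(cfg, class = "pipeline_config")
}

# Target access guard: fitting stages read targets through this wrapper,
# which records every (stage, partition) access so leakage is auditable.
new_target_guard <- function(Y, test_idx) {
  env <- new.env(parent = emptyenv())
  env$log <- list()
  env$Y <- Y
  env$test_idx <- test_idx
  env
}

guard_read <- function(guard, idx, stage) {
  touches_test <- length(intersect(idx, guard$test_idx)) > 0
  guard$log[[length(guard$log) + 1L]] <-
    list(stage = stage, n = length(idx), touches_test = touches_test)
  if (touches_test && stage != "evaluate")
    stop("stage '", stage, "' attempted to read test-partition targets")
  guard$Y[idx, , drop = FALSE]
}

.numeric_feature_cols <- function(records) {
  setdiff(names(records)[vapply(records, is.numeric, logical(1))],
          c("human_CL_mL_min_kg", "human_VDss_L_kg"))
}

.column_roles <- function(records) {
  cols <- .numeric_feature_cols(records)
  roles <- c(human_CL_mL_min_kg = "target", human_VDss_L_kg = "target")
  for (col in cols) {
    roles[[col]] <- if (grepl("_(CL_mL_min_kg|VDss_L_kg)$", col))
      "animal_pk" else "physicochemical"
  }
  roles
}

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  path
}

#' Run the full modeling pipeline
#'
#' Simulate (or ingest) compound data, apply the physiological filter and
#' feature winsorization, split, fit the invertible scalers on the
#' training partition, train supervised embeddings, select features per
#' target, train the single-task baselines and the shared-tree multi-task
#' model, evaluate on the held-out test partition, and attribute the
#' multi-task predictions.  Every artifact is written under
#' `cfg$out_dir` and hashed into a manifest; the test partition's targets
#' are blanked before any fitting stage and all target reads pass through
#' a recording access guard.
#'
#' @param cfg a [pipeline_config()].
#' @param split optional pre-computed `split_plan` (overrides the split
#'   stage; used for paired runs on identical partitions).
#' @return object of class `pipeline_result`: metrics, models, artifact
#'   paths and the manifest.
#' @export
run_pipeline <- function(cfg, split = NULL) {
  stopifnot(inherits(cfg, "pipeline_config"))
  out <- cfg$out_dir
  for (d in c("data", "splits", "embeddings", "selection", "models",
              "metrics", "explanations", "logs"))
    dir.create(file.path(out, d), recursive = TRUE, showWarnings = FALSE)

  # -- data ---------------------------------------------------------------
  if (!is.null(cfg$synth)) {
    ds <- generate_pk_dataset(cfg$synth)
    records <- ds$records
  } else {
    records <- read.csv(cfg$data_csv, stringsAsFactors = FALSE)
  }
  flt <- filter_physiological(records)
  records <- flt$records
  feat_cols <- .numeric_feature_cols(records)
  for (col in feat_cols) records[[col]] <- winsorize(records[[col]])
  write_pk_csv(records, file.path(out, "data", "preprocessed.csv"))

  # -- split --------------------------------------------------------------
  if (is.null(split)) {
    split <- if (cfg$split$method == "optimized")
      optimize_split(records, cfg$split$n_candidates, cfg$split$ratios,
                     seed = stage_seed(cfg$seed, "split"))
    else
      repeated_splits(records, k = 1L, ratios = cfg$split$ratios,
                      base_seed = stage_seed(cfg$seed, "split"))[[1]]
  }
  write_split_json(split, file.path(out, "splits", "split.json"))
  tr <- split$train_idx; va <- split$val_idx; te <- split$test_idx

  # -- transforms (training partition only) -------------------------------
  roles <- .column_roles(records)
  scaler <- fit_transforms(records[tr, , drop = FALSE], roles)
  .write_json(lapply(scaler$params, unclass),
              file.path(out, "data", "scaler.json"))
  trans <- apply_transforms(scaler, records)

  # targets on the transformed scale; test rows blanked before fitting
  Y_full <- cbind(cl = trans$human_CL_mL_min_kg,
                  vd = trans$human_VDss_L_kg)
  guard <- new_target_guard(Y_full, te)
  Y_model <- Y_full
  Y_model[te, ] <- NA_real_

  # -- embeddings ---------------------------------------------------------
  emb_list <- list()
  emb_models <- list()
  if (length(cfg$embeddings$kinds)) {
    desc <- descriptor_matrix(records$smiles)
    imgs <- if ("cnn" %in% cfg$embeddings$kinds)
      lapply(records$smiles, render_molecule_image)
    for (kind in cfg$embeddings$kinds) {
      for (tgt in c("CL", "VD")) {
        tcol <- if (tgt == "CL") 1L else 2L
        yg <- rep(NA_real_, nrow(records))
        yg[c(tr, va)] <- guard_read(guard, c(tr, va),
                                    paste0("embed_", kind, "_", tgt))[, tcol]
        budget <- if (kind == "mlp") cfg$embeddings$mlp_budget else
          cfg$embeddings$cnn_budget
        budget$seed <- stage_seed(cfg$seed,
                                  paste0("embed_", kind, "_", tolower(tgt)))
        Xk <- if (kind == "mlp") desc else imgs
        model <- train_embedder(kind, tgt, Xk, yg, tr, va, budget)
        emb <- extract_embeddings(model, Xk)
        emb_list[[paste(kind, tgt, sep = "_")]] <- emb
        emb_models[[paste(kind, tgt, sep = "_")]] <- model
      }
    }
    emb_mat <- do.call(cbind, emb_list)
    write.csv(data.frame(row = seq_len(nrow(emb_mat)), emb_mat),
              file.path(out, "embeddings", "embeddings.csv"),
              row.names = FALSE)
  } else emb_mat <- NULL

  # -- feature table ------------------------------------------------------
  base_feats <- as.matrix(trans[, .numeric_feature_cols(records),
                                drop = FALSE])
  X_all <- if (is.null(emb_mat)) base_feats else cbind(base_feats, emb_mat)
  modality <- ifelse(grepl("_(CL_mL_min_kg|VDss_L_kg)$", colnames(X_all)),
                     "preclinical_pk",
              ifelse(grepl("^cnn_", colnames(X_all)), "embedding_cnn",
              ifelse(grepl("^mlp_", colnames(X_all)), "embedding_mlp",
                     "physicochemical")))
  names(modality) <- colnames(X_all)

  # -- selection ----------------------------------------------------------
  if (isTRUE(cfg$selection$enabled)) {
    sel_feats <- list()
    decisions <- list()
    for (tgt in c("CL", "VD")) {
      tcol <- if (tgt == "CL") 1L else 2L
      yg <- guard_read(guard, tr, paste0("select_", tgt))[, tcol]
      keep <- !is.na(yg)
      scfg <- cfg$selection$config
      scfg$seed <- stage_seed(cfg$seed, paste0("select_",
                                               tolower(tgt)))
      dec <- boruta_shap_select(X_all[tr[keep], , drop = FALSE],
                                yg[keep], scfg)
      decisions[[tgt]] <- dec
      sel_feats[[tgt]] <- dec$accepted
      write.csv(dec$decisions,
                file.path(out, "selection",
                          paste0("decisions_", tgt, ".csv")),
                row.names = FALSE)
    }
    features <- union_features(sel_feats$CL, sel_feats$VD)
    if (length(features) < 2) features <- colnames(X_all)  # degenerate guard
  } else {
    features <- colnames(X_all)
    decisions <- NULL
  }
  .write_json(list(features = features),
              file.path(out, "selection", "union.json"))
  X <- X_all[, features, drop = FALSE]

  # -- model training -----------------------------------------------------
  inv_cl <- function(v) invert_transform(scaler, "human_CL_mL_min_kg", v)
  inv_vd <- function(v) invert_transform(scaler, "human_VDss_L_kg", v)
  st_models <- list()
  for (tgt in c("CL", "VD")) {
    tcol <- if (tgt == "CL") 1L else 2L
    y_tr <- guard_read(guard, tr, paste0("train_st_", tgt))[, tcol]
    y_va <- guard_read(guard, va, paste0("train_st_", tgt))[, tcol]
    ktr <- !is.na(y_tr); kva <- !is.na(y_va)
    st_cfg <- cfg$st$config
    if (isTRUE(cfg$st$hpo)) {
      inv <- if (tgt == "CL") inv_cl else inv_vd
      orig <- records[[if (tgt == "CL") "human_CL_mL_min_kg" else
        "human_VDss_L_kg"]][va]
      hpo <- hpo_single_task(X[tr[ktr], , drop = FALSE], y_tr[ktr],
                             X[va[kva], , drop = FALSE], y_va[kva],
                             orig[kva], inv, n_trials = cfg$st$n_trials,
                             seed = stage_seed(cfg$seed, "hpo"),
                             max_rounds = st_cfg$max_rounds,
                             patience = st_cfg$patience)
      st_cfg <- hpo$config
    }
    st_models[[tgt]] <- mtgbm_fit(X[tr[ktr], , drop = FALSE], y_tr[ktr],
                                  X[va[kva], , drop = FALSE], y_va[kva],
                                  st_cfg)
  }
  y_tr_mt <- guard_read(guard, tr, "train_mt")
  y_va_mt <- guard_read(guard, va, "train_mt")
  mt_model <- mtgbm_fit(X[tr, , drop = FALSE], y_tr_mt,
                        X[va, , drop = FALSE], y_va_mt, cfg$mt$config)
  .write_json(list(st_cl_best_iter = st_models$CL$best_iteration,
                   st_vd_best_iter = st_models$VD$best_iteration,
                   mt_best_iter = mt_model$best_iteration,
                   features = features),
              file.path(out, "models", "models_summary.json"))
  mtgbm_to_json(mt_model, file.path(out, "models", "mt_model.json"))
  mtgbm_to_json(st_models$CL, file.path(out, "models", "st_model_CL.json"))
  mtgbm_to_json(st_models$VD, file.path(out, "models", "st_model_VD.json"))

  # -- evaluation (the only stage reading test targets) -------------------
  obs_cl <- records$human_CL_mL_min_kg[te]
  obs_vd <- records$human_VDss_L_kg[te]
  pred <- list(
    st_cl = inv_cl(mtgbm_predict(st_models$CL, X[te, , drop = FALSE], 1L)),
    st_vd = inv_vd(mtgbm_predict(st_models$VD, X[te, , drop = FALSE], 1L)),
    mt_cl = inv_cl(mtgbm_predict(mt_model, X[te, , drop = FALSE], 1L)),
    mt_vd = inv_vd(mtgbm_predict(mt_model, X[te, , drop = FALSE], 2L)))
  ok_cl <- !is.na(obs_cl); ok_vd <- !is.na(obs_vd)
  metrics <- list(
    st = list(CL = metrics_report(pred$st_cl, obs_cl),
              VD = metrics_report(pred$st_vd, obs_vd)),
    mt = list(CL = metrics_report(pred$mt_cl, obs_cl),
              VD = metrics_report(pred$mt_vd, obs_vd)))
  dm <- list(
    CL = dm_test(log1p(pmax(pred$mt_cl[ok_cl], 1e-6)) - log1p(obs_cl[ok_cl]),
                 log1p(pmax(pred$st_cl[ok_cl], 1e-6)) - log1p(obs_cl[ok_cl])),
    VD = dm_test(log1p(pmax(pred$mt_vd[ok_vd], 1e-6)) - log1p(obs_vd[ok_vd]),
                 log1p(pmax(pred$st_vd[ok_vd], 1e-6)) - log1p(obs_vd[ok_vd])))
  strat <- stratified_gmfe(pred$mt_vd, pred$st_vd, obs_vd)
  .write_json(list(metrics = metrics,
                   dm = lapply(dm, unclass),
                   stratified_vd = list(bins = strat$bins,
                                        n_missing = strat$n_missing)),
              file.path(out, "metrics", "metrics.json"))

  # -- attribution --------------------------------------------------------
  explanations <- NULL
  if (isTRUE(cfg$explain$enabled)) {
    ex_seed <- stage_seed(cfg$seed, "explain")
    n_test <- min(cfg$explain$n_test, length(te))
    bg_idx <- with_seed(ex_seed,
                        sample(tr, min(cfg$explain$n_background, length(tr))))
    rows_idx <- with_seed(ex_seed + 1L, sample(te, n_test))
    M <- ncol(X)
    budget <- max(2 * M + 2, min(2^M - 2, 16 * M))
    explanations <- lapply(c(CL = 1L, VD = 2L), function(task) {
      fn <- function(mat) {
        colnames(mat) <- colnames(X)
        mtgbm_predict(mt_model, mat, task)
      }
      attr <- kernel_shapley(fn, X[rows_idx, , drop = FALSE],
                             X[bg_idx, , drop = FALSE],
                             budget = budget, seed = ex_seed + task)
      write.csv(data.frame(row = rows_idx, attr$phi, check.names = FALSE),
                file.path(out, "explanations",
                          paste0("attributions_",
                                 if (task == 1L) "CL" else "VD", ".csv")),
                row.names = FALSE)
      summarize_attributions(attr, modality[features])
    })
    .write_json(lapply(explanations, function(s)
      list(top = s$top, modality_shares = as.list(s$modality_shares))),
      file.path(out, "explanations", "shap_summary.json"))
  }

  # -- manifest -----------------------------------------------------------
  .write_json(lapply(guard$log, unclass),
              file.path(out, "logs", "access_log.json"))
  files <- sort(list.files(out, recursive = TRUE, full.names = FALSE))
  files <- setdiff(files, "manifest.json")
  hashes <- tools::md5sum(file.path(out, files))
  manifest <- data.frame(file = files, md5 = unname(hashes),
                         stringsAsFactors = FALSE)
  .write_json(manifest, file.path(out, "manifest.json"))

  structure(list(metrics = metrics, dm = dm, stratified_vd = strat,
                 predictions = pred, split = split, features = features,
                 models = list(st = st_models, mt = mt_model),
                 embedding_models = emb_models,
                 explanations = explanations, guard_log = guard$log,
                 manifest = manifest, out_dir = out),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  for (m in c("st", "mt")) for (t in c("CL", "VD"))
    cat(sprintf("  %s %s: MSE(log1p) %.4f, GMFE %.3f, R2 %.3f (n=%d)\n",
                toupper(m), t, x$metrics[[m]][[t]]$mse_log,
                x$metrics[[m]][[t]]$gmfe, x$metrics[[m]][[t]]$r2,
                x$metrics[[m]][[t]]$n))
  invisible(x)
}

#' Repeated-split stability protocol
#'
#' Runs the modeling stages on `k` independent random 60/20/20 splits of
#' one dataset (seeds `base + 0 ... base + k - 1`), refitting transforms,
#' embeddings and models per split, and aggregates per-target test MSE of
#' the single-task baseline versus the multi-task model into win rates and
#' mean/sd summaries.  Compound data and descriptor/image features are
#' computed once and shared across runs (they depend only on structure).
#'
#' @param cfg a [pipeline_config()].
#' @param k number of repeated splits (>= 2).
#' @return object of class `repeated_runs`: per-run data.frame and
#'   per-target [summarize_repeats()] summaries; both are also written
#'   under `cfg$out_dir/repeats/`.
#' @export
run_repeated <- function(cfg, k = 10L) {
  stopifnot(inherits(cfg, "pipeline_config"), k >= 2)
  if (!is.null(cfg$synth)) {
    ds <- generate_pk_dataset(cfg$synth)
    records <- ds$records
  } else {
    records <- read.csv(cfg$data_csv, stringsAsFactors = FALSE)
  }
  flt <- filter_physiological(records)
  records <- flt$records
  feat_cols <- .numeric_feature_cols(records)
  for (col in feat_cols) records[[col]] <- winsorize(records[[col]])
  desc <- if ("mlp" %in% cfg$embeddings$kinds)
    descriptor_matrix(records$smiles)
  imgs <- if ("cnn" %in% cfg$embeddings$kinds)
    lapply(records$smiles, render_molecule_image)
  splits <- repeated_splits(records, k = k, ratios = cfg$split$ratios,
                            base_seed = stage_seed(cfg$seed, "split"))
  run_one <- function(i) {
    split <- splits[[i]]
    tr <- split$train_idx; va <- split$val_idx; te <- split$test_idx
    roles <- .column_roles(records)
    scaler <- fit_transforms(records[tr, , drop = FALSE], roles)
    trans <- apply_transforms(scaler, records)
    Y <- cbind(cl = trans$human_CL_mL_min_kg, vd = trans$human_VDss_L_kg)
    Y[te, ] <- NA_real_
    emb_list <- list()
    for (kind in cfg$embeddings$kinds) {
      for (tgt in c("CL", "VD")) {
        tcol <- if (tgt == "CL") 1L else 2L
        budget <- if (kind == "mlp") cfg$embeddings$mlp_budget else
          cfg$embeddings$cnn_budget
        budget$seed <- stage_seed(cfg$seed,
                                  paste0("embed_", kind, "_",
                                         tolower(tgt))) + i
        Xk <- if (kind == "mlp") desc else imgs
        model <- train_embedder(kind, tgt, Xk, Y[, tcol], tr, va, budget)
        emb_list[[paste(kind, tgt, sep = "_")]] <-
          extract_embeddings(model, Xk)
      }
    }
    base_feats <- as.matrix(trans[, feat_cols, drop = FALSE])
    X_all <- if (length(emb_list))
      cbind(base_feats, do.call(cbind, emb_list)) else base_feats
    features <- colnames(X_all)
    if (isTRUE(cfg$selection$enabled)) {
      sel <- lapply(c(CL = 1L, VD = 2L), function(tcol) {
        yv <- Y[tr, tcol]; keep <- !is.na(yv)
        scfg <- cfg$selection$config
        scfg$seed <- stage_seed(cfg$seed, paste0(
          "select_", if (tcol == 1) "cl" else "vd")) + i
        boruta_shap_select(X_all[tr[keep], , drop = FALSE], yv[keep],
                           scfg)$accepted
      })
      features <- union_features(sel$CL, sel$VD)
      if (length(features) < 2) features <- colnames(X_all)
    }
    X <- X_all[, features, drop = FALSE]
    fit_st <- function(tcol) {
      ytr <- Y[tr, tcol]; yva <- Y[va, tcol]
      ktr <- !is.na(ytr); kva <- !is.na(yva)
      mtgbm_fit(X[tr[ktr], , drop = FALSE], ytr[ktr],
                X[va[kva], , drop = FALSE], yva[kva], cfg$st$config)
    }
    st_cl <- fit_st(1L); st_vd <- fit_st(2L)
    mt <- mtgbm_fit(X[tr, , drop = FALSE], Y[tr, , drop = FALSE],
                    X[va, , drop = FALSE], Y[va, , drop = FALSE],
                    cfg$mt$config)
    inv <- function(col, v) invert_transform(scaler, col, v)
    obs_cl <- records$human_CL_mL_min_kg[te]
    obs_vd <- records$human_VDss_L_kg[te]
    okc <- !is.na(obs_cl); okv <- !is.na(obs_vd)
    p <- list(
      st_cl = inv("human_CL_mL_min_kg", mtgbm_predict(st_cl, X[te, , drop = FALSE], 1L)),
      st_vd = inv("human_VDss_L_kg", mtgbm_predict(st_vd, X[te, , drop = FALSE], 1L)),
      mt_cl = inv("human_CL_mL_min_kg", mtgbm_predict(mt, X[te, , drop = FALSE], 1L)),
      mt_vd = inv("human_VDss_L_kg", mtgbm_predict(mt, X[te, , drop = FALSE], 2L)))
    data.frame(run = i, seed = split$seed,
               mse_st_cl = mse_log(pmax(p$st_cl[okc], 1e-6), obs_cl[okc]),
               mse_mt_cl = mse_log(pmax(p$mt_cl[okc], 1e-6), obs_cl[okc]),
               mse_st_vd = mse_log(pmax(p$st_vd[okv], 1e-6), obs_vd[okv]),
               mse_mt_vd = mse_log(pmax(p$mt_vd[okv], 1e-6), obs_vd[okv]),
               n_test_cl = sum(okc), n_test_vd = sum(okv),
               n_features = length(features))
  }
  runs <- vector("list", k)
  failures <- character(0)
  for (i in seq_len(k)) {
    runs[[i]] <- tryCatch(run_one(i), error = function(e) {
      failures <<- c(failures, sprintf("run %d: %s", i,
                                       conditionMessage(e)))
      NULL
    })
  }
  per_run <- do.call(rbind, runs)
  if (is.null(per_run) || nrow(per_run) < 1)
    stop("all repeated runs failed: ", paste(failures, collapse = "; "))
  summary <- list(
    CL = summarize_repeats(per_run$mse_mt_cl, per_run$mse_st_cl),
    VD = summarize_repeats(per_run$mse_mt_vd, per_run$mse_st_vd))
  rep_dir <- file.path(cfg$out_dir, "repeats")
  dir.create(rep_dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(per_run, file.path(rep_dir, "per_run.csv"), row.names = FALSE)
  delta <- data.frame(run = per_run$run,
                      delta_cl = per_run$mse_mt_cl - per_run$mse_st_cl,
                      delta_vd = per_run$mse_mt_vd - per_run$mse_st_vd)
  write.csv(delta, file.path(rep_dir, "per_run_deltas.csv"),
            row.names = FALSE)
  .write_json(summary, file.path(rep_dir, "summary.json"))
  structure(list(per_run = per_run, summary = summary,
                 failures = failures, k_completed = nrow(per_run)),
            class = "repeated_runs")
}

#' @export
print.repeated_runs <- function(x, ...) {
  cat(sprintf("<repeated_runs> %d completed run(s)\n", x$k_completed))
  for (t in c("CL", "VD")) {
    s <- x$summary[[t]]
    cat(sprintf(
      "  %s: MT %.3f +/- %.3f vs ST %.3f +/- %.3f | wins %d/%d (%.0f%%)\n",
      t, s$mean_a, s$sd_a, s$mean_b, s$sd_b, s$win_count, s$k,
      100 * s$win_rate))
  }
  invisible(x)
}
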