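#' Merge CL and VDss tables into one compound table
#'
#' Rows are keyed by (name, SMILES) after deleting all whitespace from both
#' fields, so cosmetic spacing differences between the two source tables do
#' not prevent a match.  A compound present in only one table keeps its
#' single target; rows carrying neither target are dropped.
#'
#' @param cl_rows,vd_rows data.frames with at least `name` and `smiles`
#'   columns; `cl_rows` carries `human_CL_mL_min_kg`, `vd_rows` carries
#'   `human_VDss_L_kg`.  Shared covariate columns are taken from the CL
#'   table when present in both.
#' @param require_both drop compounds that lack either target (the strict
#'   reading of a both-measurements design); default keeps single-target
#'   compounds with a missing-value mask.
#' @return merged data.frame, one row per key.
#' @export
merge_cl_vd <- function(cl_rows, vd_rows, require_both = FALSE) {
  strip <- function(x) gsub("[[:space:]]+", "", x)
  key_of <- function(df) paste(strip(df$name), strip(df$smiles), sep = "\r")
  for (nm in c("cl_rows", "vd_rows")) {
    df <- get(nm)
    if (nrow(df) == 0) next
    if (!all(c("name", "smiles") %in% names(df)))
      stop(nm, " must contain 'name' and 'smiles' columns")
    k <- key_of(df)
    if (anyDuplicated(k)) {
      dup <- k[duplicated(k)][1]
      stop("duplicate compound key in ", nm, ": ",
           gsub("\r", " / ", dup, fixed = TRUE))
    }
  }
  empty <- data.frame(name = character(0), smiles = character(0))
  if (nrow(cl_rows) == 0) cl_rows <- cbind(empty, human_CL_mL_min_kg = numeric(0))
  if (nrow(vd_rows) == 0) vd_rows <- cbind(empty, human_VDss_L_kg = numeric(0))
  cl_rows$.key <- key_of(cl_rows); vd_rows$.key <- key_of(vd_rows)
  vd_extra <- setdiff(names(vd_rows), setdiff(names(cl_rows), ".key"))
  merged <- merge(cl_rows, vd_rows[, vd_extra, drop = FALSE],
                  by = ".key", all = TRUE)
  # fill identity columns for VD-only rows
  vd_only <- is.na(merged$name)
  if (any(vd_only)) {
    idx <- match(merged$.key[vd_only], vd_rows$.key)
    for (col in intersect(c("name", "smiles"), names(vd_rows)))
      merged[[col]][vd_only] <- vd_rows[[col]][idx]
  }
  merged$name <- strip(merged$name); merged$smiles <- strip(merged$smiles)
  merged$.key <- NULL
  if (!"human_CL_mL_min_kg" %in% names(merged)) merged$human_CL_mL_min_kg <- NA_real_
  if (!"human_VDss_L_kg" %in% names(merged)) merged$human_VDss_L_kg <- NA_real_
  keep <- if (require_both)
    !is.na(merged$human_CL_mL_min_kg) & !is.na(merged$human_VDss_L_kg)
  else
    !is.na(merged$human_CL_mL_min_kg) | !is.na(merged$human_VDss_L_kg)
  merged <- merged[keep, , drop = FALSE]
  rownames(merged) <- NULL
  front <- c("name", "smiles", "human_CL_mL_min_kg", "human_VDss_L_kg")
  merged[, c(front, setdiff(names(merged), front)), drop = FALSE]
}

#' Remove compounds outside physiological ranges
#'
#' A compound is removed when its human VDss is >= 5 L/kg or its human CL
#' is >= 20 mL/min/kg (inclusive thresholds); values beyond these limits
#' are treated as biologically implausible.  Missing targets never trigger
#' removal.
#'
#' @param records compound data.frame with `human_CL_mL_min_kg` and
#'   `human_VDss_L_kg` columns.
#' @return list with `records` (kept rows), `removed_count`, and `removed`
#'   (names of removed compounds).
#' @export
filter_physiological <- function(records, cl_max = 20, vd_max = 5) {
  cl <- records$human_CL_mL_min_kg; vd <- records$human_VDss_L_kg
  drop <- (!is.na(vd) & vd >= vd_max) | (!is.na(cl) & cl >= cl_max)
  out <- records[!drop, , drop = FALSE]
  rownames(out) <- NULL
  list(records = out, removed_count = sum(drop),
       removed = records$name[drop])
}

#' Winsorize a numeric column at empirical quantiles
#'
#' Values below the lower quantile are raised to it and values above the
#' upper quantile lowered to it; quantiles use linear interpolation between
#' order statistics (type 7).  Missing entries are ignored when computing
#' the quantiles and preserved in the output.
#'
#' @param values numeric vector.
#' @param lower_q,upper_q clip probabilities (defaults 0.01 / 0.99).
#' @return winsorized vector of the same length.
#' @export
winsorize <- function(values, lower_q = 0.01, upper_q = 0.99) {
  ok <- !is.na(values)
  if (!any(ok)) {
    warning("winsorize: all values missing; column returned unchanged")
    return(values)
  }
  q <- quantile(values[ok], c(lower_q, upper_q), type = 7, names = FALSE)
  out <- values
  out[ok & values < q[1]] <- q[1]
  out[ok & values > q[2]] <- q[2]
  out
}

#' Fit invertible per-column scaling transforms
#'
#' Target and animal-PK columns get `log1p` followed by standardization
#' (mean/sd of the log1p values over the rows supplied, normally the
#' training partition); physicochemical columns are standardized only;
#' columns whose name starts with `Caco_2` or `water_solubility`, and any
#' column whose role is `excluded`, are passed through untouched.  A
#' zero-variance column gets sd 1 with a warning so no division by zero
#' can occur.
#'
#' @param train_records data.frame of training rows.
#' @param column_roles named character vector mapping column name to one of
#'   `"target"`, `"animal_pk"`, `"physicochemical"`, `"excluded"`.
#' @return object of class `scaler_params`.
#' @export
fit_transforms <- function(train_records, column_roles) {
  stopifnot(all(column_roles %in%
                  c("target", "animal_pk", "physicochemical", "excluded")))
  params <- lapply(names(column_roles), function(col) {
    role <- column_roles[[col]]
    if (role == "excluded" || grepl("^(Caco_2|water_solubility)", col))
      return(list(kind = "excluded", mean = 0, sd = 1))
    x <- train_records[[col]]
    if (is.null(x)) stop("column not present in training data: ", col)
    kind <- if (role %in% c("target", "animal_pk"))
      "log1p_standardize" else "standardize_only"
    x <- x[!is.na(x)]
    if (kind == "log1p_standardize") x <- log1p(x)
    m <- if (length(x)) mean(x) else 0
    s <- if (length(x) > 1) sd(x) else 0
    if (!is.finite(s) || s == 0) {
      warning("zero-variance column '", col, "': sd set to 1")
      s <- 1
    }
    list(kind = kind, mean = m, sd = s)
  })
  names(params) <- names(column_roles)
  structure(list(params = params), class = "scaler_params")
}

#' Apply fitted transforms to a data.frame
#' @param scaler a [fit_transforms()] result.
#' @param records data.frame containing the fitted columns.
#' @return data.frame with transformed columns.
#' @export
apply_transforms <- function(scaler, records) {
  stopifnot(inherits(scaler, "scaler_params"))
  for (col in names(scaler$params)) {
    p <- scaler$params[[col]]
    if (p$kind == "excluded" || is.null(records[[col]])) next
    x <- records[[col]]
    if (p$kind == "log1p_standardize") x <- log1p(x)
    records[[col]] <- (x - p$mean) / p$sd
  }
  records
}

#' Invert fitted transforms for one column
#' @param scaler a [fit_transforms()] result.
#' @param column column name.
#' @param values transformed values.
#' @return values on the original scale.
#' @export
invert_transform <- function(scaler, column, values) {
  p <- scaler$params[[column]]
  if (is.null(p)) stop("no transform fitted for column: ", column)
  if (p$kind == "excluded") return(values)
  x <- values * p$sd + p$mean
  if (p$kind == "log1p_standardize") x <- expm1(x)
  x
}

.split_sizes <- function(n, ratios) {
  n_train <- round(ratios[1] * n); n_val <- round(ratios[2] * n)
  c(n_train, n_val, n - n_train - n_val)
}

.random_partition <- function(n, ratios) {
  sz <- .split_sizes(n, ratios)
  idx <- sample.int(n)
  list(train_idx = sort(idx[seq_len(sz[1])]),
       val_idx = sort(idx[sz[1] + seq_len(sz[2])]),
       test_idx = sort(idx[sz[1] + sz[2] + seq_len(sz[3])]))
}

# Distribution-similarity criterion for a candidate partition: mean over
# targets of the mean pairwise two-sample KS statistic among the three
# partitions, on the log1p target scale; missing targets are ignored.
.split_criterion <- function(part, targets) {
  per_target <- vapply(targets, function(y) {
    a <- log1p(y[part$train_idx]); b <- log1p(y[part$val_idx])
    c3 <- log1p(y[part$test_idx])
    mean(c(ks_statistic(a, b), ks_statistic(a, c3), ks_statistic(b, c3)),
         na.rm = TRUE)
  }, numeric(1))
  mean(per_target, na.rm = TRUE)
}

#' Choose a train/validation/test split by distribution similarity
#'
#' Draws `n_candidates` random 60/20/20 partitions and keeps the one whose
#' target distributions are most alike across the three partitions, scored
#' as the mean (over the CL and VDss targets, log1p scale) of the mean
#' pairwise two-sample Kolmogorov-Smirnov statistic.
#'
#' @param records compound data.frame.
#' @param n_candidates number of random partitions to score.
#' @param ratios train/val/test fractions, summing to 1.
#' @param seed integer seed.
#' @return object of class `split_plan` with `train_idx`, `val_idx`,
#'   `test_idx`, `ratios`, `seed`, `criterion`.
#' @export
optimize_split <- function(records, n_candidates = 10000L,
                           ratios = c(0.6, 0.2, 0.2), seed = 1L) {
  n <- nrow(records)
  stopifnot(n >= 10, n_candidates >= 1, abs(sum(ratios) - 1) < 1e-8)
  targets <- list(cl = records$human_CL_mL_min_kg,
                  vd = records$human_VDss_L_kg)
  targets <- Filter(Negate(is.null), targets)
  with_seed(seed, {
    best <- NULL; best_crit <- Inf
    for (i in seq_len(n_candidates)) {
      part <- .random_partition(n, ratios)
      if (!length(part$train_idx) || !length(part$val_idx) ||
          !length(part$test_idx)) next
      crit <- .split_criterion(part, targets)
      if (is.finite(crit) && crit < best_crit) {
        best <- part; best_crit <- crit
      }
    }
    if (is.null(best)) stop("no valid candidate partition found")
    structure(c(best, list(ratios = ratios, seed = as.integer(seed),
                           criterion = best_crit)),
              class = "split_plan")
  })
}

#' Independent repeated random splits
#'
#' `k` single random partitions (no similarity optimization) from seeds
#' `base_seed + 0 ... base_seed + k - 1`, for stability analysis.
#'
#' @param records compound data.frame.
#' @param k number of repeats.
#' @param ratios train/val/test fractions.
#' @param base_seed first seed.
#' @return list of `split_plan` objects.
#' @export
repeated_splits <- function(records, k = 10L, ratios = c(0.6, 0.2, 0.2),
                            base_seed = 1L) {
  stopifnot(k >= 1)
  n <- nrow(records)
  lapply(seq_len(k) - 1L, function(i) {
    sd_i <- as.integer(base_seed) + i
    with_seed(sd_i, {
      part <- .random_partition(n, ratios)
      structure(c(part, list(ratios = ratios, seed = sd_i,
                             criterion = NA_real_)),
                class = "split_plan")
    })
  })
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("<split_plan> train %d / val %d / test %d (seed %d, criterion %s)\n",
              length(x$train_idx), length(x$val_idx), length(x$test_idx),
              x$seed, format(x$criterion, digits = 4)))
  invisible(x)
}

#' Serialize a split plan to JSON (0-based indices)
#' @param plan a `split_plan`.
#' @param path output path.
#' @export
write_split_json <- function(plan, path) {
  jsonlite::write_json(list(train = plan$train_idx - 1L,
                            val = plan$val_idx - 1L,
                            test = plan$test_idx - 1L,
                            ratios = plan$ratios, seed = plan$seed,
                            criterion = plan$criterion),
                       path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}
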