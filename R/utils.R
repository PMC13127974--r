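#' @keywords internal
"_PACKAGE"

#' @useDynLib pkboost, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif quantile sd var cor predict plogis qnorm
#'   pnorm binom.test complete.cases
#' @importFrom utils write.csv read.csv head
NULL

# Run code under a temporary RNG state; global .Random.seed is restored.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Deterministic fan-out of one global seed into per-stage seeds.  Stage
# seeds stay well below 2^31 so they remain valid R integers.
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  offs <- c(simulate = 1L, split = 2L, embed_cnn_cl = 3L, embed_cnn_vd = 4L,
            embed_mlp_cl = 5L, embed_mlp_vd = 6L, select_cl = 7L,
            select_vd = 8L, train_st = 9L, train_mt = 10L, explain = 11L,
            hpo = 12L)
  if (!stage %in% names(offs)) stop("unknown stage: ", stage)
  (as.integer(seed) %% 1000000L) * 1000L + offs[[stage]]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Two-sample Kolmogorov-Smirnov statistic (no p-value, ties allowed).
ks_statistic <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (!length(a) || !length(b)) return(NA_real_)
  pooled <- sort(unique(c(a, b)))
  Fa <- vapply(pooled, function(t) mean(a <= t), numeric(1))
  Fb <- vapply(pooled, function(t) mean(b <= t), numeric(1))
  max(abs(Fa - Fb))
}
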