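# Compact pipeline configurations for tests: small synthetic cohorts and
# reduced budgets so a full run takes tens of seconds.

mini_pipeline_cfg <- function(seed = 7, out_dir = tempfile("pktest"),
                              n = 120L, cnn = FALSE, selection = TRUE,
                              sel_iters = 30L, rounds = 120L,
                              synth = NULL) {
  cfg <- pipeline_config("tiny", seed = seed, out_dir = out_dir,
                         synth = synth %||%
                           synth_config(n_compounds = n,
                                        seed = seed + 1000L))
  cfg$embeddings$kinds <- if (cnn) c("mlp", "cnn") else "mlp"
  cfg$embeddings$mlp_budget <- hpo_budget(n_trials = 1L, patience = 6L,
                                          max_epochs = 25L)
  cfg$embeddings$cnn_budget <- hpo_budget(n_trials = 1L, patience = 2L,
                                          max_epochs = 4L,
                                          pool_factor = 16L,
                                          channels = c(3L, 6L))
  cfg$selection$enabled <- selection
  cfg$selection$config <- selection_config(n_iterations = sel_iters,
                                           n_explain = 8L,
                                           n_background = 8L)
  cfg$st$hpo <- FALSE
  cfg$st$config$max_rounds <- rounds
  cfg$st$config$patience <- 40L
  cfg$mt$config$max_rounds <- rounds
  cfg$mt$config$patience <- 40L
  cfg$explain$n_test <- 12L
  cfg$explain$n_background <- 8L
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

manifest_subset <- function(res, dirs) {
  m <- res$manifest
  m[grepl(paste0("^(", paste(dirs, collapse = "|"), ")/"), m$file), ]
}
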