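#' Default run configuration
#'
#' Pipeline-level defaults: correlation threshold `rho = 0.75`,
#' `K = 50` permutation rounds, selection-frequency threshold
#' `tau = 0.5`, and the default base-learner set (information gain,
#' SVM-RFE, Vita-style permutation importance, Boruta-style shadow
#' screening).
#'
#' @return Named list of defaults.
#' @export
default_config <- function() {
  list(rho = 0.75, K = 50L, tau = 0.5,
       base_learners = c("info_gain", "svm_rfe", "vita", "boruta"),
       seed = 1L)
}

#' Load a run configuration from YAML or JSON
#'
#' Missing keys take the defaults of [default_config()]; unknown keys
#' are an error (they usually indicate a typo); explicit `overrides`
#' (e.g. parsed command-line flags) take precedence over the file.
#'
#' @param path Path to a YAML or JSON file, or `NULL` for defaults only.
#' @param overrides Named list overriding file values.
#' @return Validated configuration list.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  cfg <- default_config()
  if (!is.null(path)) {
    file_cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
      jsonlite::read_json(path, simplifyVector = TRUE)
    else yaml::read_yaml(path)
    if (is.null(file_cfg)) file_cfg <- list()
    unknown <- setdiff(names(file_cfg), names(cfg))
    if (length(unknown))
      stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    cfg[names(file_cfg)] <- file_cfg
  }
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg[names(overrides)] <- overrides
  cfg$K <- as.integer(cfg$K); cfg$seed <- as.integer(cfg$seed)
  if (!is.numeric(cfg$rho) || cfg$rho <= 0 || cfg$rho >= 1)
    stop("rho must lie in (0, 1)", call. = FALSE)
  if (cfg$K < 1L) stop("K must be >= 1", call. = FALSE)
  if (!is.numeric(cfg$tau) || cfg$tau <= 0 || cfg$tau > 1)
    stop("tau must lie in (0, 1]", call. = FALSE)
  bad <- setdiff(cfg$base_learners,
                 c("info_gain", "cfs", "svm_rfe", "boruta", "vita", "lasso"))
  if (length(bad))
    stop("unknown base learner(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  cfg
}

#' Write toy fixtures for the pipeline
#'
#' Writes (a) a 6-sample AIRR rearrangement TSV set with hand-countable
#' VJ tallies, (b) a 50 x 100 feature matrix plus labels from a
#' miniature correlated-group scenario (three causal groups of size 5),
#' and (c) a JSON file with the five worked-example fold selections for
#' the weighted relative frequency.
#'
#' @param dir Output directory (created if needed).
#' @param seed Seed for the feature-matrix draw.
#' @return Invisibly, the vector of file paths written.
#' @export
make_fixtures <- function(dir, seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()

  ## (a) toy AIRR set: 2 groups x 3 samples, small fixed repertoires
  vgenes <- c("TRBV19", "TRBV5-1", "TRBV12-3")
  jgenes <- c("TRBJ2-1", "TRBJ1-2")
  set.seed(as.integer(seed))
  for (i in 1:6) {
    n_rows <- 4L + (i %% 3L)
    df <- data.frame(
      sequence_id = sprintf("s%d_r%d", i, seq_len(n_rows)),
      v_call = paste0(vgenes[1 + (seq_len(n_rows) + i) %% 3], "*01"),
      j_call = paste0(jgenes[1 + (seq_len(n_rows)) %% 2], "*01"),
      duplicate_count = ((seq_len(n_rows) + i) %% 4L) + 1L)
    p <- file.path(dir, sprintf("sample%d.tsv", i))
    utils::write.table(df, p, sep = "\t", row.names = FALSE, quote = FALSE)
    paths <- c(paths, p)
  }

  ## (b) miniature scenario: n = 50, G = 100, groups of 5
  sc <- simulation_scenario("toy_n50_G100", n = 50L, G = 100L, eta = 0.5,
                            beta = c(0, -9, 6, 3),
                            group_sizes = rep(5L, 6L))
  sim <- simulate_dataset(sc, seed)
  xp <- file.path(dir, "toy_features.csv")
  utils::write.csv(data.frame(sim$X, check.names = FALSE), xp,
                   row.names = FALSE)
  yp <- file.path(dir, "toy_labels.csv")
  utils::write.csv(data.frame(y = sim$y), yp, row.names = FALSE)
  mp <- file.path(dir, "toy_manifest.json")
  jsonlite::write_json(list(scenario = sc$label, seed = seed,
                            causal = which(sim$causal)),
                       mp, auto_unbox = TRUE)
  paths <- c(paths, xp, yp, mp)

  ## (c) the WRF worked example: five fold selections
  wp <- file.path(dir, "wrf_example.json")
  jsonlite::write_json(list(folds = list(c("X1", "X2"),
                                         c("X2", "X4", "X5"),
                                         c("X1", "X5"),
                                         c("X1"),
                                         c("X2", "X5", "X7"))),
                       wp)
  paths <- c(paths, wp)
  invisible(paths)
}
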