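#' Benchmark feature selectors on simulated scenarios
#'
#' For each scenario and replicate pair, every requested selector runs
#' on both replicates: selection-quality metrics (FDR, sensitivity, F1)
#' are computed on the first replicate against the known causal
#' features, stability is the Jaccard index between the selections on
#' the two replicates, and each requested classifier is trained on the
#' first replicate (restricted to its selection) and evaluated on the
#' second.  Empirical power per causal variable is tallied across
#' replicates.
#'
#' Selector failures are recorded as missing cells rather than aborting
#' the run.
#'
#' @param scenarios Character vector of scenario labels from
#'   [scenario_registry()], or a list of `repsel_scenario` objects.
#' @param selectors Character vector among `"info_gain"`, `"cfs"`,
#'   `"svm_rfe"`, `"boruta"`, `"vita"`, `"lasso"`, `"ensemble"`.
#' @param classifiers Character vector among `classifier_names()` (may
#'   be empty to skip prediction).
#' @param n_pairs Number of replicate pairs per scenario.
#' @param seed Master seed.
#' @param cfg A [selector_config()].
#' @param ensemble_args List of extra arguments for [ensemble_select()]
#'   (e.g. `rho`, `K`, `tau`, `methods`).
#' @return List with `metrics` (long data frame: scenario, selector,
#'   pair, metric, value), `power` (scenario, selector, variable,
#'   power) and `selections` (nested list of per-pair selections).
#' @export
run_benchmark <- function(scenarios, selectors = c("ensemble", "lasso"),
                          classifiers = character(), n_pairs = 5L,
                          seed = 1L, cfg = selector_config(),
                          ensemble_args = list()) {
  if (is.character(scenarios))
    scenarios <- scenario_registry()[scenarios]
  stopifnot(length(scenarios) >= 1L,
            all(vapply(scenarios, inherits, logical(1), "repsel_scenario")))
  rows <- list(); power_rows <- list(); all_sel <- list()
  sc_seeds <- derive_seeds(seed, length(scenarios))
  for (si in seq_along(scenarios)) {
    sc <- scenarios[[si]]
    pairs <- make_replicate_pairs(sc, n_pairs, sc_seeds[si])
    causal <- which(pairs[[1]]$train$causal)
    pair_seeds <- derive_seeds(sc_seeds[si] + 1L, n_pairs)
    for (sel in selectors) {
      train_sets <- vector("list", n_pairs)
      for (k in seq_len(n_pairs)) {
        tr <- pairs[[k]]$train; te <- pairs[[k]]$test
        s_tr <- try(select_features(sel, tr$X, tr$y, cfg, pair_seeds[k],
                                    ensemble_args), silent = TRUE)
        s_te <- try(select_features(sel, te$X, te$y, cfg, pair_seeds[k] + 1L,
                                    ensemble_args), silent = TRUE)
        if (inherits(s_tr, "try-error") || inherits(s_te, "try-error")) {
          rows[[length(rows) + 1L]] <- data.frame(
            scenario = sc$label, selector = sel, pair = k,
            metric = "failed", value = 1, stringsAsFactors = FALSE)
          next
        }
        train_sets[[k]] <- s_tr
        m <- selection_metrics(s_tr, causal, sc$G)
        stab <- jaccard_stability(list(list(s_tr, s_te)))$mean
        vals <- c(fdr = m$fdr, sensitivity = m$sensitivity, f1 = m$f1,
                  n_selected = m$n_selected, stability = stab)
        for (nm in names(vals))
          rows[[length(rows) + 1L]] <- data.frame(
            scenario = sc$label, selector = sel, pair = k,
            metric = nm, value = unname(vals[nm]), stringsAsFactors = FALSE)
        for (cl in classifiers) {
          res <- classify(tr$X, tr$y, te$X, te$y, s_tr, method = cl,
                          seed = pair_seeds[k])
          for (nm in c("accuracy", "auc"))
            rows[[length(rows) + 1L]] <- data.frame(
              scenario = sc$label, selector = sel, pair = k,
              metric = paste(cl, nm, sep = "_"), value = res[[nm]],
              stringsAsFactors = FALSE)
        }
      }
      ok <- !vapply(train_sets, is.null, logical(1))
      if (any(ok)) {
        pw <- empirical_power(train_sets[ok], causal)
        power_rows[[length(power_rows) + 1L]] <- data.frame(
          scenario = sc$label, selector = sel,
          variable = as.integer(names(pw)), power = unname(pw),
          stringsAsFactors = FALSE)
      }
      all_sel[[sc$label]][[sel]] <- train_sets
    }
  }
  list(metrics = do.call(rbind, rows),
       power = if (length(power_rows)) do.call(rbind, power_rows) else NULL,
       selections = all_sel)
}

## dispatch a selector by name, returning integer feature indices
select_features <- function(name, X, y, cfg, seed, ensemble_args = list()) {
  if (name == "ensemble") {
    args <- c(list(X = X, y = y, seed = seed, cfg = cfg), ensemble_args)
    return(do.call(ensemble_select, args)$selected)
  }
  run_base_selectors(X, y, methods = name, cfg = cfg, seed = seed)[[1]]$selected
}
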