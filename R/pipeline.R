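# End-to-end pipeline: simulate (or accept) labelled sessions, cut windows,
# extract the 90-feature catalog, rank by mutual information, select the top
# 30, rebalance to 300/300/300, 75/25 split, train the RBF SVM and evaluate
# on the in-sample test split and on the discarded real-sample pool.

#' Run the full tremor-classification pipeline
#'
#' @param n_sessions Number of synthetic sessions to simulate (one limb
#'   each); ignored when `windows` is supplied.
#' @param config A [session_config()] whose `seed` field is re-derived per
#'   session from `seed`.
#' @param windows Optional pre-extracted list of `labelled_window` objects;
#'   when given, simulation is skipped.
#' @param top_k Number of features kept after MI ranking (default 30).
#' @param target Per-class sample count after rebalancing (default 300).
#' @param train_frac Training fraction of the balanced set (default 0.75).
#' @param C,gamma SVM hyperparameters (see [train_svm()]).
#' @param seed Master seed; all stage seeds derive from it.
#' @return List with `features` (the full `feature_matrix`), `ranking`,
#'   `selected` (feature names), `resampled` (the `resampled_dataset`),
#'   `split`, `model`, `report_test`, `report_discarded` (or `NULL` when the
#'   pool is empty), `pca` (embedding of the resampled set in initial-data
#'   coordinates), and bookkeeping counts.
#' @export
run_pipeline <- function(n_sessions = 24, config = session_config(),
                         windows = NULL, top_k = 30, target = 300,
                         train_frac = 0.75, C = 1, gamma = NULL, seed = 1L) {
  seed <- as.integer(seed)
  if (is.null(windows)) {
    windows <- list()
    skipped <- c(nodata = 0L, short = 0L)
    for (s in seq_len(n_sessions)) {
      cfg <- config
      cfg$seed <- (seed * 1000L + s) %% .Machine$integer.max
      sim <- simulate_session(cfg, subject_id = sprintf("S%02d", s),
                              limb = LIMBS[(s - 1) %% 4 + 1])
      w <- extract_windows(sim$recording, sim$events)
      skipped <- skipped + c(attr(w, "n_skipped_nodata"), attr(w, "n_skipped_short"))
      windows <- c(windows, w)
    }
  } else {
    skipped <- c(nodata = NA_integer_, short = NA_integer_)
  }
  if (!length(windows)) stop("no usable windows")

  fm <- extract_features(windows)
  ranking <- mutual_information_ranking(fm, seed = seed + 1L)
  selected <- select_top_k(ranking, k = top_k)
  X_sel <- fm$features[, selected, drop = FALSE]

  class_counts <- table(factor(fm$labels, levels = 0:2))
  ds <- rebalance_dataset(X_sel, fm$labels, target = target, seed = seed + 2L)
  split <- train_test_split(ds, train_frac = train_frac, seed = seed + 3L)

  model <- train_svm(ds$matrix[split$train, , drop = FALSE],
                     ds$labels[split$train], C = C, gamma = gamma)
  report_test <- evaluate(model, ds$matrix[split$test, , drop = FALSE],
                          ds$labels[split$test], "in_sample_test")
  report_discarded <- if (nrow(ds$discarded)) evaluate_discarded(model, ds) else NULL
  pca <- pca_embedding(X_sel, ds$matrix, synthetic = ds$synthetic)

  list(features = fm, ranking = ranking, selected = selected,
       resampled = ds, split = split, model = model,
       report_test = report_test, report_discarded = report_discarded,
       pca = pca,
       counts = list(n_windows = length(windows), skipped = skipped,
                     class_counts = class_counts,
                     n_synthetic = sum(ds$synthetic),
                     n_discarded = nrow(ds$discarded)))
}
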