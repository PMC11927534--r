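#' Run the full identification workflow on synthetic data
#'
#' Simulate a multimodal seed dataset, smooth and normalize, select
#' morphological and spectral features, fuse, evaluate the candidate
#' pool, rank by the diversity/performance comprehensive score, fit
#' the top-K stacking ensemble (optionally DE-tuned), evaluate on the
#' held-out split, and explain the ensemble with weighted SHAP.
#'
#' @param sim a [sim_config()] describing the synthetic study.
#' @param out_dir optional directory for artifacts (JSON report, CSV
#'   diversity matrices, config snapshot).
#' @param morph_method,morph_k morphological selector and size.
#' @param spectral_method `"SPA"`, `"CARS"` or `"BOSS"` (or `"none"`
#'   to keep all bands).
#' @param learners candidate pool.
#' @param K ensemble size (top-K by comprehensive score).
#' @param optimize tune the final stack with [hde_optimize()].
#' @param control an [hde_control()] for the optimizer.
#' @param sg_window,sg_polyorder Savitzky-Golay settings.
#' @param train_frac train proportion of the stratified split.
#' @param n_folds CV folds for candidate evaluation and meta-features.
#' @param shap_samples how many test samples to explain (0 skips).
#' @param sweep_k also run the ensemble-size sweep.
#' @param seed master seed for split/folds/fits.
#' @return A list of class `hde_pipeline` with the fitted `stack`,
#'   the diversity `report`, `selection` results, test `metrics`,
#'   per-base `base_metrics`, optional `sweep` and `shap`, and the
#'   configuration.
#' @export
run_pipeline <- function(sim = sim_config(), out_dir = NULL,
                         morph_method = "RFE", morph_k = 15,
                         spectral_method = "SPA",
                         learners = c("LR", "DT", "SVM", "KNN", "GP",
                                      "MLP"),
                         K = 3, optimize = FALSE,
                         control = hde_control(),
                         sg_window = 11, sg_polyorder = 2,
                         train_frac = 0.7, n_folds = 5,
                         shap_samples = 0, sweep_k = FALSE,
                         seed = 1) {
  data <- sim_seed_dataset(sim)
  sm <- sg_smooth(data$spectra, sg_window, sg_polyorder)
  ft_s <- spectra_to_features(sm, data$y)
  ft_m <- data$morph
  sp <- split_stratified(ft_m, train_frac, seed)
  tr_id <- sp$train$sample_id
  te_id <- sp$test$sample_id
  rows <- match(tr_id, ft_s$sample_id)
  rows_te <- match(te_id, ft_s$sample_id)
  m_tr <- minmax_normalize(sp$train)
  m_te <- minmax_normalize(ft_subset_rows(ft_m, rows_te),
                           ranges = attr(m_tr, "ranges"))
  s_tr <- minmax_normalize(ft_subset_rows(ft_s, rows))
  s_te <- minmax_normalize(ft_subset_rows(ft_s, rows_te),
                           ranges = attr(s_tr, "ranges"))
  sel_m <- morph_select(m_tr, morph_method, k = morph_k, seed = seed)
  sel_s <- if (spectral_method == "none") NULL else
    switch(spectral_method,
           SPA = spa_select(s_tr$x, s_tr$y, n_max = 30, seed = seed),
           CARS = cars_select(s_tr$x, s_tr$y, n_mc = 30, seed = seed),
           BOSS = boss_select(s_tr$x, s_tr$y, n_boot = 20,
                              seed = seed),
           stop("unknown spectral_method"))
  take <- function(ft, idx) feature_table(ft$x[, idx, drop = FALSE],
                                          ft$y, ft$modality[idx],
                                          ft$sample_id)
  s_idx <- if (is.null(sel_s)) seq_len(ncol(s_tr$x)) else
    sort(sel_s$indices)
  train <- fuse_features(take(m_tr, sel_m$indices), take(s_tr, s_idx))
  test <- fuse_features(take(m_te, sel_m$indices), take(s_te, s_idx))
  preds <- evaluate_candidates(train, learners, n_folds = n_folds,
                               seed = seed)
  report <- diversity_report(preds, train$y)
  sel <- select_base_learners(report, K)
  stack <- hde_stack(train, learners = sel, n_folds = n_folds,
                     seed = seed, optimize = optimize,
                     control = control)
  pr_te <- predict(stack, test$x)
  metrics <- performance_metrics(pr_te, test$y)
  pool <- candidate_pool(sel)
  base_metrics <- t(vapply(sel, function(b) {
    params <- .merge_params(pool[[b]], NULL)
    set.seed(seed + 7L)
    m <- pool[[b]]$fit(train$x, train$y, params)
    p <- pool[[b]]$prob(m, test$x, levels(train$y))
    performance_metrics(levels(train$y)[max.col(p, "first")], test$y)
  }, numeric(4)))
  sweep <- if (sweep_k)
    ensemble_size_sweep(report, train, test, n_folds = n_folds,
                        seed = seed) else NULL
  shap <- if (shap_samples > 0) {
    idx <- seq_len(min(shap_samples, nrow(test$x)))
    stack_shap(stack, test$x[idx, , drop = FALSE], train$x,
               n_perm = 10, seed = seed)
  } else NULL
  out <- structure(list(stack = stack, report = report,
                        selection = list(morph = sel_m,
                                         spectral = sel_s),
                        metrics = metrics,
                        base_metrics = base_metrics, sweep = sweep,
                        shap = shap, train = train, test = test,
                        config = list(sim = unclass(sim),
                                      morph_method = morph_method,
                                      morph_k = morph_k,
                                      spectral_method = spectral_method,
                                      learners = learners, K = K,
                                      optimize = optimize,
                                      sg_window = sg_window,
                                      sg_polyorder = sg_polyorder,
                                      train_frac = train_frac,
                                      n_folds = n_folds, seed = seed)),
                   class = "hde_pipeline")
  if (!is.null(out_dir)) write_pipeline_artifacts(out, out_dir)
  out
}

#' @export
print.hde_pipeline <- function(x, ...) {
  cat("<hde_pipeline>\n  selected:",
      paste(x$stack$learners, collapse = " + "), "\n")
  cat(sprintf("  test accuracy %.2f%%, macro F1 %.2f%%\n",
              x$metrics["accuracy"], x$metrics["f1"]))
  invisible(x)
}

write_pipeline_artifacts <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(res$config,
                       file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(metrics = as.list(res$metrics),
         base_weights = as.list(res$stack$base_weights),
         ranking = res$report$ranking,
         base_metrics = as.data.frame(res$base_metrics)),
    file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  for (m in names(res$report$metrics))
    utils::write.csv(res$report$metrics[[m]],
                     file.path(out_dir, paste0("diversity_", m, ".csv")))
  if (!is.null(res$sweep))
    utils::write.csv(res$sweep, file.path(out_dir, "sweep_k.csv"),
                     row.names = FALSE)
  if (!is.null(res$shap)) {
    s <- shap_summary(res$shap)
    utils::write.csv(s$ranking, file.path(out_dir, "shap_ranking.csv"),
                     row.names = FALSE)
  }
  invisible(out_dir)
}

#' Collate a run directory into a human-readable report
#'
#' @param run_dir directory written by [run_pipeline()].
#' @return Character vector of markdown lines (invisibly printed).
#' @export
pipeline_report <- function(run_dir) {
  lines <- c("# Identification run report", "")
  f <- file.path(run_dir, "report.json")
  if (!file.exists(f)) {
    warning("incomplete run: report.json missing")
    return(invisible(c(lines, "*No results found.*")))
  }
  rep <- jsonlite::read_json(f, simplifyVector = TRUE)
  lines <- c(lines, "## Test metrics (%)",
             paste(sprintf("- %s: %.2f", names(rep$metrics),
                           unlist(rep$metrics)), collapse = "\n"),
             "", "## Candidate ranking",
             paste(utils::capture.output(print(rep$ranking)),
                   collapse = "\n"),
             "", "## Base-learner weights",
             paste(sprintf("- %s: %.3f", names(rep$base_weights),
                           unlist(rep$base_weights)), collapse = "\n"))
  writeLines(lines)
  invisible(lines)
}
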