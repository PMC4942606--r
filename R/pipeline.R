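confusion_matrix <- function(truth, predicted, classes = sort(unique(truth))) {
  table(
    truth = factor(truth, levels = classes),
    predicted = factor(predicted, levels = classes)
  )
}

#' Run the SNOM image-analysis arm end to end
#'
#' read images -> spectrum-like signals -> normalization and replicate
#' averaging -> biomarker area / delta-area table -> per-biomarker PCA (with
#' Hotelling T2 / Q diagnostics) on the stacked class-average signals.
#'
#' @param dataset either the list returned by [generate_snom_dataset()] /
#'   [read_snom_dataset()], or a manifest file path.
#' @param intervals optional named list of per-class integration intervals
#'   (micrometres); defaults to the automatic half-maximum interval.
#' @param order replicate combination order, see [build_area_table()].
#' @param n_components components for the per-biomarker PCA (default 2, the
#'   two plotted score dimensions).
#' @param out_dir optional directory; when given, the area table, per-
#'   biomarker score/diagnostic tables and a JSON run summary are written.
#' @param normal_class reference class label.
#' @return A list of class `snom_report`: `area_table`, `signals`
#'   (replicate-averaged normalized signals), `pca` (per biomarker: model +
#'   diagnostics + score table), `config`.
#' @export
run_snom_pipeline <- function(dataset, intervals = NULL,
                              order = "normalize_then_average",
                              n_components = 2L,
                              out_dir = NULL,
                              normal_class = "normal") {
  if (is.character(dataset)) dataset <- read_snom_dataset(dataset)
  images <- dataset$images
  if (length(images) == 0L) stop_validation("[read] empty image dataset")
  signals <- lapply(images, image_to_signal)
  area_table <- tryCatch(
    build_area_table(signals, intervals = intervals, order = order,
                     normal_class = normal_class),
    error = function(e) stop_validation("[areas] ", conditionMessage(e))
  )
  # per-biomarker class-average normalized signals -> PCA score plots
  bms <- intersect(snom_biomarkers(),
                   unique(vapply(signals, function(s) s$biomarker, character(1))))
  classes <- unique(vapply(signals, function(s) s$class_label, character(1)))
  pca_reports <- list()
  for (bm in bms) {
    rows <- lapply(classes, function(cl) {
      grp <- Filter(function(s) s$class_label == cl && s$biomarker == bm, signals)
      average_replicates(lapply(grp, normalize_signal))$values
    })
    X <- do.call(rbind, rows)
    A <- min(n_components, nrow(X) - 1L, ncol(X))
    model <- fit_pca(X, A)
    diag <- if (nrow(X) > A) pca_diagnostics(model, X) else NULL
    if (nrow(X) <= A + 1L) {
      message("[pca] ", bm, ": only ", nrow(X),
              " samples; 95% limits are poorly determined at this size")
    }
    scores <- data.frame(class_label = classes, model$scores)
    names(scores)[-1] <- paste0("PC", seq_len(A))
    pca_reports[[bm]] <- list(model = model, diagnostics = diag,
                              scores = scores)
  }
  report <- structure(
    list(
      area_table = area_table,
      pca = pca_reports,
      config = list(intervals = intervals, order = order,
                    n_components = n_components,
                    normal_class = normal_class)
    ),
    class = "snom_report"
  )
  if (!is.null(out_dir)) write_snom_report(report, out_dir)
  report
}

write_snom_report <- function(report, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  utils::write.csv(report$area_table, file.path(out_dir, "area_table.csv"),
                   row.names = FALSE)
  for (bm in names(report$pca)) {
    utils::write.csv(report$pca[[bm]]$scores,
                     file.path(out_dir, sprintf("pca_scores_%s.csv", bm)),
                     row.names = FALSE)
    d <- report$pca[[bm]]$diagnostics
    if (!is.null(d)) {
      utils::write.csv(
        data.frame(t2 = d$t2_values, q = d$q_values,
                   t2_limit_95 = d$t2_limit_95, q_limit_95 = d$q_limit_95,
                   outlier = d$outlier),
        file.path(out_dir, sprintf("pca_diagnostics_%s.csv", bm)),
        row.names = FALSE
      )
    }
  }
  summary <- list(
    arm = "snom",
    config = report$config,
    n_area_rows = nrow(report$area_table),
    biomarkers = names(report$pca),
    explained_variance_pct = lapply(report$pca, function(p)
      p$model$explained_variance_pct)
  )
  jsonlite::write_json(summary, file.path(out_dir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Run the ATR spectral-classification arm end to end
#'
#' Kennard-Stone 70/15/15 split -> PCA-LDA with validation-chosen component
#' count -> SPA-LDA with validation-chosen variable subset -> prediction-set
#' confusion matrices and accuracies. Deterministic for a fixed input table.
#'
#' @param dataset a [spectral_dataset()] or a spectra-table file path.
#' @param fractions Kennard-Stone fractions (default `c(0.70, 0.15, 0.15)`).
#' @param max_A candidate PCA-LDA component counts `1..max_A`.
#' @param max_len maximum SPA chain length.
#' @param out_dir optional directory for CSV/JSON outputs.
#' @return A list of class `atr_report`: `split`, `pca_lda`, `spa`,
#'   `pca_lda_confusion`, `spa_lda_confusion`, `pca_lda_accuracy`,
#'   `spa_lda_accuracy`, `selected_wavenumbers`, `config`.
#' @export
run_atr_pipeline <- function(dataset, fractions = c(0.70, 0.15, 0.15),
                             max_A = 10L, max_len = 10L, out_dir = NULL) {
  if (is.character(dataset)) dataset <- read_spectra_table(dataset)
  stopifnot(inherits(dataset, "spectral_dataset"))
  if (length(unique(dataset$class_labels)) < 2L) {
    stop_validation("[split] at least 2 classes are required")
  }
  split <- kennard_stone_split(dataset$intensities, fractions)
  pl <- tryCatch(pca_lda_train(dataset, split, max_A = max_A),
                 error = function(e) stop_validation("[pca_lda] ",
                                                     conditionMessage(e)))
  spa <- tryCatch(spa_lda_select(dataset, split, max_len = max_len),
                  error = function(e) stop_validation("[spa_lda] ",
                                                      conditionMessage(e)))
  Xpred <- dataset$intensities[split$prediction_idx, , drop = FALSE]
  ypred <- dataset$class_labels[split$prediction_idx]
  classes <- sort(unique(dataset$class_labels))
  pl_hat <- predict(pl, Xpred)
  spa_hat <- predict(spa, Xpred)
  report <- structure(
    list(
      split = split,
      pca_lda = pl,
      spa = spa,
      pca_lda_confusion = confusion_matrix(ypred, pl_hat, classes),
      spa_lda_confusion = confusion_matrix(ypred, spa_hat, classes),
      pca_lda_accuracy = mean(pl_hat == ypred),
      spa_lda_accuracy = mean(spa_hat == ypred),
      selected_wavenumbers = spa$selected_wavenumbers,
      config = list(fractions = fractions, max_A = max_A, max_len = max_len)
    ),
    class = "atr_report"
  )
  if (!is.null(out_dir)) write_atr_report(report, dataset, out_dir)
  report
}

write_atr_report <- function(report, dataset, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  n <- nrow(dataset$intensities)
  set_of <- rep("prediction", n)
  set_of[report$split$train_idx] <- "train"
  set_of[report$split$validation_idx] <- "validation"
  utils::write.csv(
    data.frame(sample_id = dataset$sample_ids,
               class_label = dataset$class_labels, set = set_of),
    file.path(out_dir, "split_assignment.csv"), row.names = FALSE
  )
  utils::write.csv(
    data.frame(wavenumber = report$selected_wavenumbers,
               variable_index = report$spa$selected_variables),
    file.path(out_dir, "spa_selected_wavenumbers.csv"), row.names = FALSE
  )
  utils::write.csv(as.data.frame(report$pca_lda_confusion),
                   file.path(out_dir, "pca_lda_confusion.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(report$spa_lda_confusion),
                   file.path(out_dir, "spa_lda_confusion.csv"),
                   row.names = FALSE)
  summary <- list(
    arm = "atr",
    config = report$config,
    chosen_A = report$pca_lda$chosen_A,
    n_selected_variables = length(report$spa$selected_variables),
    selected_wavenumbers = report$selected_wavenumbers,
    pca_lda_accuracy = report$pca_lda_accuracy,
    spa_lda_accuracy = report$spa_lda_accuracy
  )
  jsonlite::write_json(summary, file.path(out_dir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
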