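# Half-up rounding to the report precision of 4 decimals (round() rounds
# half to even, which would disagree with the printed tables).
round_half_up <- function(x, digits = 4) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Plan a stratified random k-fold split
#'
#' Setting 1: the image sets of each class are divided equally and randomly
#' across k folds, so per-class fold sizes differ by at most one. Image
#' sets from the same subject may land in different folds — subject leakage
#' is deliberate in this protocol.
#'
#' @param image_sets Image-set tibble with a `label` column.
#' @param k Number of folds (default 10).
#' @param rng_seed Seed for the random assignment.
#' @return A list of class `split_plan` with `mode = "random_kfold"` and a
#'   `fold` assignment (integer vector, one entry per row of `image_sets`).
#' @export
plan_random_kfold <- function(image_sets, k = 10, rng_seed = 1) {
  labs <- image_sets$label
  tab <- table(labs)
  small <- names(tab)[tab < k]
  if (length(small)) {
    abort(paste0("class(es) with fewer image sets than folds: ",
                 paste(small, collapse = ", ")),
          class = "ecgmi_error_validation")
  }
  set.seed(rng_seed)
  fold <- integer(length(labs))
  for (cls in names(tab)) {
    idx <- which(labs == cls)
    n <- length(idx)
    sizes <- rep(n %/% k, k) + (seq_len(k) <= n %% k)
    fold[sample(idx)] <- rep(seq_len(k), times = sizes)
  }
  structure(list(mode = "random_kfold", k = as.integer(k),
                 fold = fold, rng_seed = as.integer(rng_seed)),
            class = "split_plan")
}

#' Plan a subject-held-out split
#'
#' Setting 2: leave-one-subject-out. Each fold's test partition is exactly
#' one subject's image sets; the train partition is everyone else. Classes
#' with fewer subjects than `min_subjects` (default: single-subject
#' classes) are excluded from both partitions, since a held-out subject of
#' such a class could never appear in training.
#'
#' @param image_sets Image-set tibble with `label` and `subject_id`.
#' @param eligible_classes Classes to keep; defaults to those with >= 2
#'   subjects in `image_sets`.
#' @return A list of class `split_plan` with `mode = "subject_held_out"`,
#'   the retained row indices (`rows`), per-row fold assignment (`fold`,
#'   one fold per held-out subject) and the subject order (`subjects`).
#' @export
plan_subject_held_out <- function(image_sets, eligible_classes = NULL) {
  if (is.null(image_sets$subject_id) || anyNA(image_sets$subject_id)) {
    abort("subject-held-out planning requires subject_id on every image set",
          class = "ecgmi_error_validation")
  }
  census <- dplyr::distinct(image_sets, .data$subject_id, .data$label) |>
    dplyr::count(.data$label, name = "n_subjects") |>
    dplyr::rename(name = "label")
  dup <- dplyr::distinct(image_sets, .data$subject_id, .data$label) |>
    dplyr::count(.data$subject_id) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup)) {
    abort(paste0("subject(s) with more than one class label: ",
                 paste(dup$subject_id, collapse = ", ")),
          class = "ecgmi_error_validation")
  }
  if (is.null(eligible_classes)) {
    eligible_classes <- eligible_classes(census)
  }
  rows <- which(image_sets$label %in% eligible_classes)
  subjects <- unique(image_sets$subject_id[rows])
  fold <- match(image_sets$subject_id[rows], subjects)
  structure(list(mode = "subject_held_out", k = length(subjects),
                 rows = rows, fold = fold, subjects = subjects,
                 eligible_classes = eligible_classes),
            class = "split_plan")
}

#' Aggregate predictions into a confusion matrix
#'
#' @param truth,estimate Character vectors of true and predicted labels.
#' @param class_order Row/column ordering.
#' @return A K x K integer matrix of class `confusion_matrix` (rows = true
#'   class, columns = predicted class).
#' @export
aggregate_confusion <- function(truth, estimate, class_order) {
  bad <- setdiff(unique(c(truth, estimate)), class_order)
  if (length(bad)) {
    abort(paste0("labels outside class_order: ", paste(bad, collapse = ", ")),
          class = "ecgmi_error_validation")
  }
  stopifnot(length(truth) == length(estimate))
  cm <- table(factor(truth, levels = class_order),
              factor(estimate, levels = class_order))
  cm <- unclass(as.matrix(cm))
  storage.mode(cm) <- "integer"
  names(dimnames(cm)) <- c("true", "predicted")
  class(cm) <- c("confusion_matrix", class(cm))
  cm
}

#' Build a confusion matrix from printed counts
#'
#' @param counts K x K matrix (rows = true, columns = predicted).
#' @param class_order Class labels in matrix order.
#' @return A `confusion_matrix`.
#' @export
confusion_from_counts <- function(counts, class_order) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == ncol(counts),
            length(class_order) == nrow(counts), all(counts >= 0))
  dimnames(counts) <- list(true = class_order, predicted = class_order)
  storage.mode(counts) <- "integer"
  class(counts) <- c("confusion_matrix", class(counts))
  counts
}

#' Binary sensitivity, specificity and accuracy
#'
#' Sensitivity = TP / (TP + FN), specificity = TN / (TN + FP), accuracy =
#' (TP + TN) / (TP + FP + TN + FN), with the stated positive class.
#' Reported values are additionally given half-up rounded to 4 decimals in
#' the `rounded` column. A zero denominator yields `NA` with a warning,
#' not 0.
#'
#' @param cm A 2 x 2 `confusion_matrix`.
#' @param positive_class The positive class label (default `"MI"`).
#' @return A tibble with columns `metric`, `value`, `rounded`.
#' @export
binary_metrics <- function(cm, positive_class = "MI") {
  stopifnot(inherits(cm, "confusion_matrix"), nrow(cm) == 2)
  classes <- rownames(cm)
  if (!positive_class %in% classes) {
    abort("positive_class not present in the confusion matrix",
          class = "ecgmi_error_validation")
  }
  pos <- positive_class
  neg <- setdiff(classes, pos)
  tp <- cm[pos, pos]; fn <- cm[pos, neg]
  tn <- cm[neg, neg]; fp <- cm[neg, pos]
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warn(paste0(what, " undefined: zero denominator"))
      return(NA_real_)
    }
    num / den
  }
  vals <- c(
    sensitivity = safe_div(tp, tp + fn, "sensitivity"),
    specificity = safe_div(tn, tn + fp, "specificity"),
    accuracy = safe_div(tp + tn, tp + fp + tn + fn, "accuracy")
  )
  # identity check: accuracy is the prevalence-weighted mean of sens/spec
  if (!anyNA(vals)) {
    p <- tp + fn; n <- tn + fp
    stopifnot(abs(vals["accuracy"] -
                  (vals["sensitivity"] * p + vals["specificity"] * n) /
                  (p + n)) < 1e-12)
  }
  tibble::tibble(metric = names(vals), value = unname(vals),
                 rounded = round_half_up(unname(vals)))
}

#' Multiclass accuracy report
#'
#' Per-class accuracy is the diagonal count over the row total (the
#' fraction of each true class predicted correctly); overall accuracy is
#' the trace over the grand total. One-vs-rest sensitivity and specificity
#' are macro-averaged over `macro_scope` ("all" classes, or "mi" for the
#' infarction classes only; the choice only affects the macro summary).
#' Classes with an empty row get `NA` accuracy and are excluded from the
#' macro averages with a warning.
#'
#' @param cm A K x K `confusion_matrix`.
#' @param macro_scope `"all"` or `"mi"`.
#' @return A list of class `multiclass_report`: `per_class` tibble
#'   (`class`, `n`, `correct`, `accuracy`, `rounded`), `overall_accuracy`,
#'   `macro_sensitivity`, `macro_specificity`.
#' @export
multiclass_report <- function(cm, macro_scope = c("all", "mi")) {
  stopifnot(inherits(cm, "confusion_matrix"), nrow(cm) >= 2)
  macro_scope <- match.arg(macro_scope)
  classes <- rownames(cm)
  row_tot <- rowSums(cm)
  if (any(row_tot == 0)) {
    warn(paste0("class(es) with no evaluated items excluded from macro averages: ",
                paste(classes[row_tot == 0], collapse = ", ")))
  }
  per_acc <- unname(ifelse(row_tot > 0, diag(cm) / row_tot, NA_real_))
  total <- sum(cm)
  overall <- sum(diag(cm)) / total
  ovr <- lapply(seq_along(classes), function(i) {
    tp <- unname(cm[i, i]); fn <- unname(row_tot[i]) - tp
    fp <- sum(cm[, i]) - tp; tn <- total - tp - fn - fp
    c(sens = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
      spec = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
  })
  ovr <- do.call(rbind, ovr)
  scope <- if (macro_scope == "mi") classes != "N" else rep(TRUE, length(classes))
  scope <- scope & row_tot > 0
  structure(list(
    per_class = tibble::tibble(
      class = classes, n = as.integer(row_tot),
      correct = as.integer(diag(cm)),
      accuracy = per_acc, rounded = round_half_up(per_acc)
    ),
    overall_accuracy = overall,
    overall_rounded = round_half_up(overall),
    macro_sensitivity = mean(ovr[scope, "sens"], na.rm = TRUE),
    macro_specificity = mean(ovr[scope, "spec"], na.rm = TRUE),
    macro_scope = macro_scope
  ), class = "multiclass_report")
}

#' @export
print.multiclass_report <- function(x, ...) {
  print(x$per_class)
  cat(sprintf("overall accuracy: %.4f (macro sens %.4f / spec %.4f over %s classes)\n",
              x$overall_accuracy, x$macro_sensitivity, x$macro_specificity,
              x$macro_scope))
  invisible(x)
}

#' @rdname multiclass_report
#' @param x A `multiclass_report`.
#' @param ... Unused.
#' @export
tidy.multiclass_report <- function(x, ...) x$per_class

#' @rdname multiclass_report
#' @export
glance.multiclass_report <- function(x, ...) {
  tibble::tibble(overall_accuracy = x$overall_accuracy,
                 macro_sensitivity = x$macro_sensitivity,
                 macro_specificity = x$macro_specificity)
}

# collapse the 10 infarction-site labels onto "MI" for the detection task
binarize_labels <- function(labels) ifelse(labels == "N", "N", "MI")

#' Cross-validated detection or localization experiment
#'
#' Runs the full evaluation protocol on an image-set corpus: builds the
#' split plan (random stratified k-fold for setting 1, leave-one-subject-out
#' for setting 2), trains a fresh model per fold, predicts the held-out
#' partition, and aggregates one confusion matrix over all folds. The
#' detection task maps every infarction class onto a single positive "MI"
#' label before training (binary head); localization keeps the class
#' labels. For setting 2, single-subject classes are excluded (for
#' detection too, so both tasks see the same corpus).
#'
#' @param image_sets Image-set tibble with `label` (and `subject_id` for
#'   setting 2).
#' @param task `"detection"` or `"localization"`.
#' @param setting 1 (random k-fold) or 2 (subject-held-out).
#' @param arch Architecture template; its `n_classes` is replaced by the
#'   task's class count.
#' @param config A [train_config()].
#' @param k Folds for setting 1.
#' @param rng_seed Seed for fold assignment and per-fold model
#'   initialization.
#' @param keep_models Keep the per-fold fits (memory-heavy)?
#' @return A list of class `ecg_cv_result`: `confusion`, `metrics`
#'   (binary-metrics tibble or `multiclass_report`), `predictions` tibble,
#'   `plan`, `task`, `setting`.
#' @export
run_cross_validation <- function(image_sets,
                                 task = c("detection", "localization"),
                                 setting = 1,
                                 arch = ecg_cnn_architecture(),
                                 config = train_config(),
                                 k = 10, rng_seed = 1,
                                 keep_models = FALSE) {
  task <- match.arg(task)
  stopifnot(setting %in% c(1, 2))
  data <- image_sets
  if (setting == 2) {
    plan <- plan_subject_held_out(data)
    data <- data[plan$rows, , drop = FALSE]
    fold <- plan$fold
    n_folds <- plan$k
  } else {
    plan <- plan_random_kfold(data, k = k, rng_seed = rng_seed)
    fold <- plan$fold
    n_folds <- plan$k
  }
  work_label <- if (task == "detection") binarize_labels(data$label) else data$label
  taxonomy <- c(mi_classes()$name, "MI")
  levels <- taxonomy[taxonomy %in% unique(work_label)]
  arch_task <- arch
  arch_task$n_classes <- length(levels)
  attr(arch_task, "concat_features") <- NULL

  preds <- vector("list", n_folds)
  fits <- if (keep_models) vector("list", n_folds) else NULL
  for (f in seq_len(n_folds)) {
    test_idx <- which(fold == f)
    train_idx <- which(fold != f)
    train_data <- data[train_idx, , drop = FALSE]
    train_data$label <- work_label[train_idx]
    if (setting == 2) {
      leaked <- intersect(unique(data$subject_id[train_idx]),
                          unique(data$subject_id[test_idx]))
      stopifnot(length(leaked) == 0)  # no-leakage scan, every run
    }
    model <- build_ecg_cnn(arch_task, rng_seed = stable_seed(rng_seed, f))
    cfg <- config
    cfg$rng_seed <- stable_seed(rng_seed, 1000 + f)
    fit <- train_ecg_cnn(model, train_data, cfg, class_levels = levels)
    test_data <- data[test_idx, , drop = FALSE]
    p <- predict(fit, test_data)
    preds[[f]] <- tibble::tibble(
      fold = f,
      subject_id = test_data$subject_id,
      record_id = test_data$record_id,
      window_index = test_data$window_index,
      truth = work_label[test_idx],
      estimate = p$.pred_class
    )
    if (keep_models) fits[[f]] <- fit
  }
  predictions <- dplyr::bind_rows(preds)
  cm <- aggregate_confusion(predictions$truth, predictions$estimate, levels)
  stopifnot(sum(cm) == nrow(data))  # conservation, every run
  metrics <- if (task == "detection") binary_metrics(cm, "MI")
             else multiclass_report(cm)
  structure(list(confusion = cm, metrics = metrics,
                 predictions = predictions, plan = plan, task = task,
                 setting = setting, class_levels = levels, fits = fits),
            class = "ecg_cv_result")
}

#' @export
print.ecg_cv_result <- function(x, ...) {
  cat(sprintf("<ecg_cv_result> %s, setting %d, %d image sets\n",
              x$task, x$setting, sum(x$confusion)))
  print(x$confusion)
  if (x$task == "detection") print(x$metrics) else print(x$metrics$per_class)
  invisible(x)
}

#' @rdname run_cross_validation
#' @param x An `ecg_cv_result`.
#' @param ... Unused.
#' @export
tidy.ecg_cv_result <- function(x, ...) {
  if (x$task == "detection") x$metrics else x$metrics$per_class
}

#' @rdname run_cross_validation
#' @export
glance.ecg_cv_result <- function(x, ...) {
  if (x$task == "detection") {
    tidyr::pivot_wider(x$metrics[, c("metric", "value")],
                       names_from = "metric", values_from = "value")
  } else {
    glance(x$metrics)
  }
}

#' Write a cross-validation report to disk
#'
#' Emits the labeled confusion matrix as CSV, the metrics as JSON (both
#' exact values and 4-decimal strings) and the per-item predictions as CSV.
#'
#' @param result An `ecg_cv_result`.
#' @param dir Output directory.
#' @return The directory, invisibly.
#' @export
write_cv_report <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cm <- result$confusion
  cm_df <- tibble::as_tibble(as.data.frame.matrix(unclass(cm)))
  cm_df <- dplyr::bind_cols(tibble::tibble(true = rownames(cm)), cm_df)
  readr::write_csv(cm_df, file.path(dir, "confusion.csv"))
  met <- if (result$task == "detection") {
    m <- setNames(as.list(result$metrics$value), result$metrics$metric)
    m$formatted <- setNames(as.list(sprintf("%.4f", result$metrics$rounded)),
                            result$metrics$metric)
    m
  } else {
    list(per_class_accuracy = setNames(as.list(result$metrics$per_class$accuracy),
                                       result$metrics$per_class$class),
         overall_accuracy = result$metrics$overall_accuracy,
         macro_sensitivity = result$metrics$macro_sensitivity,
         macro_specificity = result$metrics$macro_specificity,
         formatted = list(overall_accuracy =
                            sprintf("%.4f", result$metrics$overall_rounded)))
  }
  jsonlite::write_json(met, file.path(dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  readr::write_csv(result$predictions, file.path(dir, "predictions.csv"))
  invisible(dir)
}
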