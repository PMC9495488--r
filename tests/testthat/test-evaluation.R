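test_that("stratified k-fold split divides each class equally and randomly", {
  sets <- tibble::tibble(
    subject_id = paste0("s", 1:200), record_id = paste0("r", 1:200),
    label = rep(c("N", "I"), each = 100), window_index = 0L)
  plan <- plan_random_kfold(sets, k = 10, rng_seed = 3)
  tab <- table(plan$fold, sets$label)
  expect_true(all(tab == 10))
  plan2 <- plan_random_kfold(sets, k = 10, rng_seed = 3)
  expect_identical(plan$fold, plan2$fold)
  expect_false(identical(plan$fold,
                         plan_random_kfold(sets, k = 10, rng_seed = 4)$fold))
  # 25 items over 10 folds: balanced-remainder sizes 3,3,3,3,3,2,...
  sets25 <- sets[1:25, ]
  sizes <- sort(as.vector(table(plan_random_kfold(sets25, 10, 1)$fold)),
                decreasing = TRUE)
  expect_equal(sizes, c(3, 3, 3, 3, 3, 2, 2, 2, 2, 2))
  expect_error(plan_random_kfold(sets[1:5, ], k = 10), "N",
               class = "ecgmi_error_validation")
})

test_that("subject-held-out plan partitions subjects without leakage", {
  # 20 subjects, 2 classes, several image sets each
  sets <- tibble::tibble(
    subject_id = rep(paste0("s", 1:20), each = 5),
    record_id = rep(paste0("r", 1:20), each = 5),
    label = rep(rep(c("N", "I"), each = 10), each = 5),
    window_index = rep(0:4, 20))
  plan <- plan_subject_held_out(sets)
  expect_equal(plan$k, 20)
  # union of test partitions covers every image set exactly once
  expect_equal(sort(unlist(lapply(seq_len(plan$k),
                                  function(f) plan$rows[plan$fold == f]))),
               seq_len(nrow(sets)))
  # exhaustive leakage scan
  for (f in seq_len(plan$k)) {
    te <- sets$subject_id[plan$rows[plan$fold == f]]
    tr <- sets$subject_id[plan$rows[plan$fold != f]]
    expect_length(intersect(unique(te), unique(tr)), 0)
    expect_length(unique(te), 1)
  }
  expect_error(
    plan_subject_held_out(dplyr::mutate(sets, subject_id = NA)),
    class = "ecgmi_error_validation")
})

test_that("single-subject classes are excluded from subject-held-out plans", {
  sets <- tibble::tibble(
    subject_id = c(rep(c("a1", "a2"), each = 4), rep("b1", 4)),
    record_id = "r", label = c(rep("N", 8), rep("L", 4)),
    window_index = 0L)
  plan <- plan_subject_held_out(sets)
  expect_equal(plan$eligible_classes, "N")
  expect_false(any(sets$label[plan$rows] == "L"))
  expect_equal(plan$k, 2)
})

test_that("confusion aggregation counts and conserves", {
  cm <- aggregate_confusion(c("N", "N", "MI"), c("N", "N", "MI"),
                            c("N", "MI"))
  expect_equal(unclass(cm),
               matrix(c(2L, 0L, 0L, 1L), 2, 2,
                      dimnames = list(true = c("N", "MI"),
                                      predicted = c("N", "MI"))))
  # reconstruct the published binary table from a synthetic prediction list
  truth <- c(rep("N", 4837), rep("MI", 20471))
  est <- c(rep("N", 4822), rep("MI", 15), rep("N", 31), rep("MI", 20440))
  cm <- aggregate_confusion(truth, est, c("N", "MI"))
  expect_equal(as.vector(unclass(cm)), c(4822L, 31L, 15L, 20440L))
  # conservation under random label lists
  set.seed(8)
  for (i in 1:20) {
    n <- sample(10:200, 1)
    k <- sample(2:5, 1)
    cls <- LETTERS[1:k]
    cm <- aggregate_confusion(sample(cls, n, TRUE), sample(cls, n, TRUE), cls)
    expect_equal(sum(cm), n)
  }
  expect_error(aggregate_confusion("X", "N", c("N", "MI")),
               class = "ecgmi_error_validation")
})

test_that("binary metrics implement the three indices with MI positive", {
  cm <- confusion_from_counts(matrix(c(4822, 15, 31, 20440), 2, 2,
                                     byrow = TRUE), c("N", "MI"))
  m <- binary_metrics(cm, "MI")
  expect_equal(m$rounded[m$metric == "sensitivity"], 0.9985)
  expect_equal(m$rounded[m$metric == "specificity"], 0.9969)
  expect_equal(m$rounded[m$metric == "accuracy"], 0.9982)
  # all-correct matrix
  m1 <- binary_metrics(confusion_from_counts(diag(c(5, 7)), c("N", "MI")))
  expect_equal(m1$value, c(1, 1, 1))
  # zero denominator reports NA with a warning, not 0
  cm0 <- confusion_from_counts(matrix(c(0, 0, 2, 8), 2, 2, byrow = TRUE),
                               c("N", "MI"))
  expect_warning(m0 <- binary_metrics(cm0, "MI"), "specificity")
  expect_true(is.na(m0$value[m0$metric == "specificity"]))
  expect_false(is.na(m0$value[m0$metric == "sensitivity"]))
})

test_that("multiclass report: per-class accuracy, overall, macro averages", {
  cm <- confusion_from_counts(diag(c(3, 4, 5)), c("A", "B", "C"))
  r <- multiclass_report(cm)
  expect_equal(r$per_class$accuracy, c(1, 1, 1))
  expect_equal(r$overall_accuracy, 1)
  expect_equal(r$macro_sensitivity, 1)
  expect_equal(r$macro_specificity, 1)
  # an empty row is excluded from macros with a warning
  cm2 <- confusion_from_counts(matrix(c(5, 1, 0, 0, 0, 0, 2, 0, 7), 3, 3,
                                      byrow = TRUE), c("A", "B", "C"))
  expect_warning(r2 <- multiclass_report(cm2), "B")
  expect_true(is.na(r2$per_class$accuracy[2]))
  expect_equal(r2$overall_accuracy, 12 / 15)
  # macro scope "mi" drops the normal class from the average
  cmN <- confusion_from_counts(matrix(c(8, 2, 1, 9), 2, 2, byrow = TRUE),
                               c("N", "I"))
  r_all <- multiclass_report(cmN, macro_scope = "all")
  r_mi <- multiclass_report(cmN, macro_scope = "mi")
  expect_equal(r_mi$macro_sensitivity, 0.9)
  expect_equal(r_all$macro_sensitivity, mean(c(0.8, 0.9)))
})

test_that("cross-validation drives training and conserves counts", {
  sets <- small_corpus(c("N", "I"), n_subjects = 3, duration_ms = 4000)
  arch <- tiny_arch(2)
  cfg <- train_config(epochs = 2, batch_size = 12, learning_rate = 3e-3,
                      rng_seed = 2)
  res <- run_cross_validation(sets, "detection", setting = 1, arch = arch,
                              config = cfg, k = 3, rng_seed = 5)
  expect_equal(sum(res$confusion), nrow(sets))
  expect_setequal(res$metrics$metric,
                  c("sensitivity", "specificity", "accuracy"))
  expect_equal(res$class_levels, c("N", "MI"))
  # binary metric identity: accuracy = (sens*P + spec*N) / (P + N)
  v <- setNames(res$metrics$value, res$metrics$metric)
  P <- sum(res$confusion["MI", ]); N <- sum(res$confusion["N", ])
  expect_equal(v[["accuracy"]],
               (v[["sensitivity"]] * P + v[["specificity"]] * N) / (P + N))
  # rerun is deterministic
  res2 <- run_cross_validation(sets, "detection", setting = 1, arch = arch,
                               config = cfg, k = 3, rng_seed = 5)
  expect_identical(res$predictions, res2$predictions)
})

test_that("setting-2 cross-validation excludes single-subject classes", {
  sets <- dplyr::bind_rows(
    small_corpus(c("N", "I"), n_subjects = 3, duration_ms = 4000),
    small_corpus("L", n_subjects = 1, duration_ms = 4000))
  arch <- tiny_arch(2)
  cfg <- train_config(epochs = 2, batch_size = 12, learning_rate = 3e-3,
                      rng_seed = 2)
  res <- run_cross_validation(sets, "localization", setting = 2, arch = arch,
                              config = cfg, rng_seed = 5)
  expect_false("L" %in% rownames(res$confusion))
  expect_equal(sum(res$confusion), sum(sets$label != "L"))
  expect_equal(res$plan$k, 6)
  # localization tidy/glance surfaces
  expect_true(all(c("class", "accuracy") %in% names(tidy(res))))
  expect_true("overall_accuracy" %in% names(glance(res)))
})

test_that("cross-validation reports round-trip to disk", {
  sets <- small_corpus(c("N", "I"), n_subjects = 3, duration_ms = 4000)
  cfg <- train_config(epochs = 1, batch_size = 12, rng_seed = 2)
  res <- run_cross_validation(sets, "detection", setting = 1,
                              arch = tiny_arch(2), config = cfg, k = 3,
                              rng_seed = 5)
  dir <- withr::local_tempdir()
  write_cv_report(res, dir)
  expect_true(all(file.exists(file.path(
    dir, c("confusion.csv", "metrics.json", "predictions.csv")))))
  met <- jsonlite::read_json(file.path(dir, "metrics.json"))
  expect_setequal(setdiff(names(met), "formatted"),
                  c("sensitivity", "specificity", "accuracy"))
  cmcsv <- readr::read_csv(file.path(dir, "confusion.csv"),
                           show_col_types = FALSE)
  expect_equal(sum(cmcsv[, -1]), sum(res$confusion))
})
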