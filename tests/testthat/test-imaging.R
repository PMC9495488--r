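test_that("window extraction matches brute-force enumeration", {
  # brute-force oracle: slide a start pointer and count complete windows
  brute_count <- function(n_samples, n_win, n_shift) {
    count <- 0; start <- 1
    while (start + n_win - 1 <= n_samples) {
      count <- count + 1
      start <- start + n_shift
    }
    count
  }
  subj <- noiseless_subject("N", 2)
  for (dur in c(1000, 1999, 2000, 4500, 10000, 32500)) {
    rec <- synthesize_record(subj, duration_ms = dur)
    win <- extract_windows(rec, window_spec(1000))
    expect_equal(nrow(win), brute_count(dur, 1000, 1000),
                 info = paste("duration", dur))
    expect_equal(nrow(win), floor(dur / 1000))
    expect_equal(win$window_index, seq_len(nrow(win)) - 1L)
    # window k covers [1000k, 1000(k+1)) ms
    expect_equal(win$start_ms, 1000 * (seq_len(nrow(win)) - 1))
    expect_true(all(vapply(win$signals, nrow, 1L) == 1000L))
  }
  # non-default shift
  rec <- synthesize_record(subj, duration_ms = 5000)
  expect_equal(nrow(extract_windows(rec, window_spec(2000, 1000))),
               brute_count(5000, 2000, 1000))
  expect_error(extract_windows(
    synthesize_record(subj, duration_ms = 1000)[1:500, ] |>
      as.data.frame() |> ecg_record(1000),
    window_spec(1000)), "shorter", class = "ecgmi_error_validation")
})

test_that("rasterization contracts: shape, range, flat line, margins", {
  rs <- raster_spec()
  img <- rasterize_window(sin(seq(0, 6 * pi, length.out = 1000)), rs)
  expect_equal(dim(img), c(64L, 64L))
  expect_type(img, "integer")
  expect_true(all(img >= 0 & img <= 255))
  # every column in the drawable span carries trace
  covered <- which(apply(img, 2, max) > 0)
  expect_true(all((rs$margin_px + 1):(64 - rs$margin_px) %in% covered))
  # flat window: one centered horizontal line
  flat <- rasterize_window(rep(2.5, 500), rs)
  nz_rows <- which(apply(flat, 1, max) > 0)
  expect_equal(nz_rows, 33L)  # row index 32 (0-based) of 0..63
  expect_true(all(flat[33, 3:62] == 255L))
  expect_error(rasterize_window(c(1, NA, 2)), class = "ecgmi_error_validation")
  expect_error(rasterize_window(3), class = "ecgmi_error_validation")
})

test_that("amplitude affine invariance and determinism", {
  set.seed(31)
  for (i in 1:20) {
    v <- cumsum(rnorm(200))
    a <- runif(1, 0.1, 10)
    b <- runif(1, -5, 5)
    expect_identical(rasterize_window(v), rasterize_window(a * v + b))
  }
  v <- rnorm(300)
  expect_identical(rasterize_window(v), rasterize_window(v + 3.7))
  expect_identical(rasterize_window(v), rasterize_window(v))
})

test_that("linear ramp rasterizes as a monotone band near the 1x oracle", {
  rs <- raster_spec()
  v <- seq(0, 1, length.out = 1000)
  img <- rasterize_window(v, rs)
  # brute-force oracle: nearest-pixel positions at 1x resolution
  side <- rs$side_px; m <- rs$margin_px
  x <- round(m + (seq_along(v) - 1) * (side - 1 - 2 * m) / (length(v) - 1))
  y <- round((side - 1 - m) - (v - min(v)) / diff(range(v)) *
               (side - 1 - 2 * m))
  oracle_row <- tapply(y, x, function(r) mean(range(r)))
  # intensity-weighted trace row per column
  trace_row <- apply(img, 2, function(col) {
    stats::weighted.mean(seq_along(col) - 1, w = col)
  })
  got <- trace_row[as.integer(names(oracle_row)) + 1]
  expect_true(all(abs(got - oracle_row) <= 1))
  # monotone: trace row decreases with column (positive slope drawn upward)
  expect_true(all(diff(got) <= 0))
})

test_that("record_to_image_sets composes windows and inherits metadata", {
  subj <- make_subject("AS", 13)
  rec <- synthesize_record(subj, duration_ms = 5000,
                           record_id = "AS_demo")
  sets <- record_to_image_sets(rec)
  expect_equal(nrow(sets), 5)
  expect_equal(sets$label, rep("AS", 5))
  expect_equal(sets$record_id, rep("AS_demo", 5))
  expect_true(all(vapply(sets$images, function(a)
    identical(dim(a), c(12L, 64L, 64L)), TRUE)))
  expect_true(all(vapply(sets$images, function(a)
    all(a >= 0 & a <= 255), TRUE)))
  # global rescale of the record leaves every image unchanged
  rec2 <- ecg_record(as.data.frame(rec) * 2.0, 1000,
                     subject_id = attr(rec, "subject_id"),
                     record_id = "AS_demo", label = "AS")
  sets2 <- record_to_image_sets(rec2)
  expect_identical(sets$images, sets2$images)
})

test_that("column-coverage invariant holds over random synthetic windows", {
  subj <- make_subject("IL", 17)
  rec <- synthesize_record(subj, duration_ms = 9000)
  sets <- record_to_image_sets(rec)
  rs <- raster_spec()
  min_cov <- 64 - 2 * rs$margin_px
  for (i in seq_len(nrow(sets))) {
    for (l in seq_len(12)) {
      nonbg <- sum(sets$images[[i]][l, , ] > 0)
      expect_gte(nonbg, min_cov)
    }
  }
})

test_that("PNG corpus round-trips through the manifest", {
  subj <- make_subject("P", 23)
  rec <- synthesize_record(subj, duration_ms = 3000, record_id = "P_r1")
  sets <- record_to_image_sets(rec)
  dir <- withr::local_tempdir()
  manifest <- write_image_corpus(sets, dir)
  files <- list.files(dir, pattern = "\\.png$")
  expect_equal(length(files), 3 * 12)
  expect_true(all(sprintf("P_r1_%d_%s.png", 0, canonical_leads()) %in% files))
  back <- read_image_corpus(manifest)
  expect_equal(nrow(back), 3)
  expect_identical(back$images, sets$images)
  expect_equal(back$label, sets$label)
})
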