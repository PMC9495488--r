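#' Windowing and rasterization parameters
#'
#' `window_spec()` controls the non-overlapping window shifting that cuts a
#' record into fixed-width segments: a width of W milliseconds and a shift
#' equal to W by default, so that consecutive windows tile the record with
#' no overlap and a trailing partial window is discarded. The default
#' W = 1000 ms corresponds to the average resting heart rate of about one
#' beat per second, so a window typically contains one beat.
#'
#' `raster_spec()` controls how one window of one lead becomes a grayscale
#' image: a 64 x 64 canvas with 256 gray levels in the faithful
#' configuration, drawn as a supersampled polyline and box-downsampled so
#' oblique segments render smoothly (antialiasing).
#'
#' @param width_ms Window width W in milliseconds.
#' @param shift_ms Window shift in milliseconds; defaults to `width_ms`
#'   (non-overlapping).
#' @return A list of class `window_spec` / `raster_spec`.
#' @export
window_spec <- function(width_ms = 1000, shift_ms = width_ms) {
  if (width_ms <= 0 || shift_ms <= 0) {
    abort("window width and shift must be positive",
          class = "ecgmi_error_validation")
  }
  structure(list(width_ms = width_ms, shift_ms = shift_ms),
            class = "window_spec")
}

#' @rdname window_spec
#' @param side_px Image side length in pixels.
#' @param gray_levels Number of gray levels (pixel values span
#'   `0 .. gray_levels - 1`).
#' @param supersample Integer supersampling factor for antialiasing.
#' @param margin_px Border margin (pixels) the trace stays clear of, so the
#'   antialiasing halo is not clipped.
#' @param trace_value,background_value Gray levels used for the trace and
#'   the background.
#' @export
raster_spec <- function(side_px = 64, gray_levels = 256, supersample = 4,
                        margin_px = 2, trace_value = gray_levels - 1,
                        background_value = 0) {
  stopifnot(side_px >= 8, gray_levels >= 2, supersample >= 1,
            margin_px >= 0, 2 * margin_px < side_px - 1)
  if (trace_value == background_value ||
      any(c(trace_value, background_value) < 0) ||
      any(c(trace_value, background_value) > gray_levels - 1)) {
    abort("trace and background values must be distinct gray levels",
          class = "ecgmi_error_validation")
  }
  structure(list(side_px = as.integer(side_px),
                 gray_levels = as.integer(gray_levels),
                 supersample = as.integer(supersample),
                 margin_px = as.integer(margin_px),
                 trace_value = as.integer(trace_value),
                 background_value = as.integer(background_value)),
            class = "raster_spec")
}

#' Cut a record into complete, non-overlapping windows
#'
#' Windows of `width_ms` are taken starting at the beginning of the record,
#' advancing by `shift_ms`; only complete windows are kept (a trailing
#' partial window is discarded). With the default shift = width this yields
#' `floor(duration_ms / width_ms)` windows.
#'
#' @param record An [ecg_record()].
#' @param wspec A [window_spec()].
#' @return A tibble with columns `window_index` (0-based), `start_ms`, and
#'   `signals` (list-column of per-window lead tibbles).
#' @export
extract_windows <- function(record, wspec = window_spec()) {
  stopifnot(inherits(record, "ecg_record"))
  fs <- attr(record, "sampling_rate")
  n <- nrow(record)
  n_win <- round(wspec$width_ms * fs / 1000)
  n_shift <- round(wspec$shift_ms * fs / 1000)
  if (n_win < 2) abort("window too short for this sampling rate",
                       class = "ecgmi_error_validation")
  if (n < n_win) {
    abort(sprintf(
      "record of %d samples (%.0f ms) is shorter than one %.0f ms window; no windows can be extracted",
      n, record_duration_ms(record), wspec$width_ms),
      class = "ecgmi_error_validation")
  }
  starts <- seq(1L, n - n_win + 1L, by = n_shift)
  df <- as.data.frame(record)
  tibble::tibble(
    window_index = seq_along(starts) - 1L,
    start_ms = (starts - 1L) * 1000 / fs,
    signals = lapply(starts, function(s) {
      tibble::as_tibble(df[s:(s + n_win - 1L), , drop = FALSE])
    })
  )
}

#' Rasterize one lead's window into a grayscale image
#'
#' Time maps linearly onto the horizontal axis and per-window min-max
#' normalized amplitude onto the vertical axis (larger voltage toward the
#' top, row 1). Consecutive samples are joined into a polyline drawn at
#' `supersample`x resolution and box-downsampled, giving antialiased gray
#' values between background and trace. A flat (constant) window renders a
#' single centered horizontal line. Because of the per-window min-max
#' normalization the image is invariant to affine amplitude changes
#' `a * v + b` (a > 0).
#'
#' @param voltage Numeric vector (>= 2 samples) of one lead over one window.
#' @param rspec A [raster_spec()].
#' @return An integer `side_px` x `side_px` matrix of gray levels.
#' @export
rasterize_window <- function(voltage, rspec = raster_spec()) {
  if (length(voltage) < 2) {
    abort("window must contain at least 2 samples",
          class = "ecgmi_error_validation")
  }
  if (!all(is.finite(voltage))) {
    abort("window contains non-finite voltages",
          class = "ecgmi_error_validation")
  }
  side <- rspec$side_px
  m <- rspec$margin_px
  lo <- min(voltage); hi <- max(voltage)
  if (hi > lo) {
    u <- (voltage - lo) / (hi - lo)
    # quantize the normalized amplitude so that affine-equivalent inputs
    # cannot straddle a pixel rounding boundary through float noise
    u <- round(u * 2^20) / 2^20
    y <- (side - 1 - m) - u * (side - 1 - 2 * m)
  } else {
    y <- rep(floor(side / 2), length(voltage))  # centered horizontal line
  }
  x <- m + (seq_along(voltage) - 1) * (side - 1 - 2 * m) / (length(voltage) - 1)
  cov <- rasterize_polyline_cpp(x, y, side, rspec$supersample)
  img <- rspec$background_value +
    round(cov * (rspec$trace_value - rspec$background_value))
  storage.mode(img) <- "integer"
  img
}

#' Convert a record into ECG image sets
#'
#' Applies [extract_windows()] and rasterizes each of the 12 leads of every
#' window, producing one "ECG image set" (twelve grayscale images sharing a
#' window index) per complete window.
#'
#' @param record An [ecg_record()].
#' @param wspec A [window_spec()].
#' @param rspec A [raster_spec()].
#' @return A tibble with one row per window: `subject_id`, `record_id`,
#'   `label`, `window_index`, and `images`, a list-column of arrays of
#'   dimension `12 x side_px x side_px` (lead, row, column) in canonical
#'   lead order.
#' @export
record_to_image_sets <- function(record, wspec = window_spec(),
                                 rspec = raster_spec()) {
  win <- extract_windows(record, wspec)
  leads <- canonical_leads()
  side <- rspec$side_px
  images <- lapply(win$signals, function(sig) {
    arr <- array(0L, dim = c(12L, side, side),
                 dimnames = list(leads, NULL, NULL))
    for (i in seq_along(leads)) {
      arr[i, , ] <- rasterize_window(sig[[leads[i]]], rspec)
    }
    arr
  })
  tibble::tibble(
    subject_id = attr(record, "subject_id"),
    record_id = attr(record, "record_id"),
    label = attr(record, "label"),
    window_index = win$window_index,
    images = images
  )
}

#' Persist an image-set corpus as PNG files plus a manifest
#'
#' Writes one 8-bit grayscale PNG per lead per window, named
#' `{record_id}_{window_index}_{lead}.png`, and a manifest CSV listing the
#' metadata and the 12 file paths of every image set.
#'
#' @param image_sets A tibble as returned by [record_to_image_sets()]
#'   (possibly row-bound over records).
#' @param dir Output directory (created if needed).
#' @param gray_levels Gray-level count used when the images were rasterized.
#' @return The manifest path, invisibly.
#' @export
write_image_corpus <- function(image_sets, dir, gray_levels = 256) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  leads <- canonical_leads()
  rows <- purrr::pmap(image_sets[, c("record_id", "window_index", "images")],
    function(record_id, window_index, images) {
      paths <- character(12)
      for (i in seq_along(leads)) {
        fn <- sprintf("%s_%d_%s.png", record_id, window_index, leads[i])
        png::writePNG(images[i, , ] / (gray_levels - 1), file.path(dir, fn))
        paths[i] <- fn
      }
      setNames(as.list(paths), paste0("file_", leads))
    })
  manifest <- dplyr::bind_cols(
    image_sets[, c("subject_id", "record_id", "window_index", "label")],
    dplyr::bind_rows(rows)
  )
  mp <- file.path(dir, "manifest.csv")
  readr::write_csv(manifest, mp)
  invisible(mp)
}

#' Read an image-set corpus back from a manifest
#'
#' @param manifest_path Path to a `manifest.csv` written by
#'   [write_image_corpus()].
#' @return A tibble in the same shape as [record_to_image_sets()] output.
#' @export
read_image_corpus <- function(manifest_path) {
  man <- readr::read_csv(manifest_path, show_col_types = FALSE)
  dir <- dirname(manifest_path)
  leads <- canonical_leads()
  images <- purrr::pmap(man[, paste0("file_", leads)], function(...) {
    files <- c(...)
    imgs <- lapply(files, function(f) {
      m <- png::readPNG(file.path(dir, f))
      if (length(dim(m)) == 3) m <- m[, , 1]
      round(m * 255)
    })
    side <- nrow(imgs[[1]])
    arr <- array(0L, dim = c(12L, side, side),
                 dimnames = list(leads, NULL, NULL))
    for (i in seq_along(imgs)) arr[i, , ] <- as.integer(imgs[[i]])
    arr
  })
  tibble::tibble(
    subject_id = as.character(man$subject_id),
    record_id = as.character(man$record_id),
    label = as.character(man$label),
    window_index = man$window_index,
    images = images
  )
}
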