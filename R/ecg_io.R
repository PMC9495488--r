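#' Construct a 12-lead ECG record
#'
#' An `ecg_record` is a tibble with one row per sample and one column per
#' lead (millivolts), in canonical lead order, carrying the subject id,
#' record id, class label and sampling rate as attributes. Lead columns may
#' be supplied in any order and with PTB-style lowercase names; they are
#' canonicalized.
#'
#' @param signals Data frame or matrix with exactly the 12 standard lead
#'   columns (any order, case-insensitive names).
#' @param sampling_rate Sampling rate in Hz (> 0).
#' @param subject_id,record_id Opaque identifiers.
#' @param label Class abbreviation, one of [class_levels()].
#' @return A tibble of class `ecg_record`.
#' @export
ecg_record <- function(signals, sampling_rate, subject_id = "s1",
                       record_id = subject_id, label = "N") {
  assert_class_label(label)
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1 ||
      !is.finite(sampling_rate) || sampling_rate <= 0) {
    abort("`sampling_rate` must be a single positive number (Hz)",
          class = "ecgmi_error_validation")
  }
  signals <- as.data.frame(signals)
  canon <- normalize_lead_names(names(signals))
  if (anyNA(canon) || anyDuplicated(canon) ||
      length(canon) != 12 || !setequal(canon, canonical_leads())) {
    missing <- setdiff(canonical_leads(),
                       canon[!is.na(canon)])
    abort(paste0(
      "signals must contain exactly the 12 standard leads; ",
      if (length(missing)) paste0("missing: ", paste(missing, collapse = ", "))
      else "unrecognized or duplicated lead columns present"
    ), class = "ecgmi_error_format")
  }
  names(signals) <- unname(canon)
  signals <- signals[, canonical_leads(), drop = FALSE]
  if (nrow(signals) < 1) {
    abort("record must contain at least one sample",
          class = "ecgmi_error_format")
  }
  if (!all(vapply(signals, is.numeric, logical(1)))) {
    abort("all lead series must be numeric", class = "ecgmi_error_format")
  }
  if (!all(vapply(signals, function(v) all(is.finite(v)), logical(1)))) {
    abort("all voltages must be finite", class = "ecgmi_error_validation")
  }
  out <- tibble::as_tibble(signals)
  attr(out, "subject_id") <- as.character(subject_id)
  attr(out, "record_id") <- as.character(record_id)
  attr(out, "label") <- label
  attr(out, "sampling_rate") <- as.numeric(sampling_rate)
  class(out) <- c("ecg_record", class(out))
  out
}

#' @rdname ecg_record
#' @param record An `ecg_record`.
#' @export
record_meta <- function(record) {
  tibble::tibble(
    subject_id = attr(record, "subject_id"),
    record_id = attr(record, "record_id"),
    label = attr(record, "label"),
    sampling_rate = attr(record, "sampling_rate"),
    n_samples = nrow(record),
    duration_ms = record_duration_ms(record)
  )
}

#' @rdname ecg_record
#' @export
record_duration_ms <- function(record) {
  nrow(record) * 1000 / attr(record, "sampling_rate")
}

#' Read and write ECG records as CSV
#'
#' The CSV dialect is a header row of lead names followed by one sample per
#' row, values in millivolts. `write_csv_record()` and `read_csv_record()`
#' round-trip voltages to within 1e-6 mV.
#'
#' @param csv_path File path.
#' @param sampling_rate Sampling rate in Hz of the stored signal.
#' @param subject_id,record_id,label Metadata; see [ecg_record()].
#' @return `read_csv_record()` returns an `ecg_record`;
#'   `write_csv_record()` invisibly returns `csv_path`.
#' @export
read_csv_record <- function(csv_path, sampling_rate, subject_id = "s1",
                            record_id = subject_id, label = "N") {
  if (!file.exists(csv_path)) {
    abort(paste0("file not found: ", csv_path), class = "ecgmi_error_io")
  }
  df <- utils::read.csv(csv_path, check.names = FALSE)
  bad <- which(!vapply(df, is.numeric, logical(1)))
  if (length(bad)) {
    col <- names(df)[bad[1]]
    row <- which(is.na(suppressWarnings(as.numeric(df[[bad[1]]]))))[1]
    abort(paste0("non-numeric cell in column '", col, "' near data row ",
                 row %||% NA), class = "ecgmi_error_parse")
  }
  ecg_record(df, sampling_rate = sampling_rate, subject_id = subject_id,
             record_id = record_id, label = label)
}

#' @rdname read_csv_record
#' @param record An `ecg_record`.
#' @export
write_csv_record <- function(record, csv_path) {
  stopifnot(inherits(record, "ecg_record"))
  df <- as.data.frame(record)[, canonical_leads(), drop = FALSE]
  ok <- tryCatch({
    utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                     csv_path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) {
    abort(paste0("could not write ", csv_path, ": ",
                 conditionMessage(ok)), class = "ecgmi_error_io")
  }
  invisible(csv_path)
}

# ---- WFDB (header/signal pair, format 16) -----------------------------------

parse_wfdb_gain <- function(tok) {
  # "gain", "gain(baseline)", "gain/units", "gain(baseline)/units"
  m <- regmatches(tok, regexec(
    "^([-+0-9.eE]+)(\\(([-+0-9]+)\\))?(/(.*))?$", tok))[[1]]
  if (length(m) == 0) abort(paste0("unparseable gain field: ", tok),
                            class = "ecgmi_error_format")
  list(gain = as.numeric(m[2]),
       baseline = if (nzchar(m[4])) as.numeric(m[4]) else 0,
       units = if (nzchar(m[6])) m[6] else "mV")
}

#' Read a WFDB record
#'
#' Reads a WFDB header/signal pair (format 16: interleaved little-endian
#' 16-bit integers) and returns the 12 standard leads in canonical order,
#' converted to millivolts via each channel's gain and baseline. Extra
#' channels (e.g. the three Frank leads vx/vy/vz carried by PTB records)
#' are dropped.
#'
#' @param header_path Path to the `.hea` file.
#' @param label Class abbreviation for this record (labels are supplied
#'   externally; they are not stored in PTB headers in machine-readable
#'   form).
#' @param subject_id Subject identifier; defaults to the record name.
#' @return An `ecg_record`.
#' @export
read_wfdb_record <- function(header_path, label, subject_id = NULL) {
  assert_class_label(label)
  if (!file.exists(header_path)) {
    abort(paste0("header not found: ", header_path), class = "ecgmi_error_io")
  }
  lines <- readLines(header_path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  head_tok <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  rec_name <- head_tok[1]
  nsig <- as.integer(head_tok[2])
  fs <- if (length(head_tok) >= 3) as.numeric(head_tok[3]) else 250
  nsamp <- if (length(head_tok) >= 4) as.integer(head_tok[4]) else NA_integer_
  sig_lines <- lines[seq(2, 1 + nsig)]
  sig <- lapply(sig_lines, function(l) {
    tok <- strsplit(trimws(l), "\\s+")[[1]]
    g <- parse_wfdb_gain(tok[3])
    list(file = tok[1], fmt = tok[2], gain = g$gain, baseline = g$baseline,
         desc = tok[length(tok)])
  })
  fmts <- unique(vapply(sig, `[[`, "", "fmt"))
  if (!identical(fmts, "16")) {
    abort(paste0("only WFDB format 16 is supported, got: ",
                 paste(fmts, collapse = ", ")), class = "ecgmi_error_format")
  }
  dat_files <- unique(vapply(sig, `[[`, "", "file"))
  if (length(dat_files) != 1) {
    abort("multi-file WFDB records are not supported",
          class = "ecgmi_error_format")
  }
  dat_path <- file.path(dirname(header_path), dat_files)
  if (!file.exists(dat_path)) {
    abort(paste0("signal file not found: ", dat_path),
          class = "ecgmi_error_io")
  }
  raw_n <- file.info(dat_path)$size %/% 2L
  vals <- readBin(dat_path, "integer", n = raw_n, size = 2L,
                  signed = TRUE, endian = "little")
  n_frames <- length(vals) %/% nsig
  if (!is.na(nsamp) && nsamp > 0) n_frames <- min(n_frames, nsamp)
  mat <- matrix(vals[seq_len(n_frames * nsig)], nrow = nsig)
  desc <- vapply(sig, `[[`, "", "desc")
  canon <- normalize_lead_names(desc)
  found <- !is.na(canon)
  missing <- setdiff(canonical_leads(), canon[found])
  if (length(missing)) {
    abort(paste0("record is missing standard lead(s): ",
                 paste(missing, collapse = ", ")),
          class = "ecgmi_error_format")
  }
  cols <- lapply(canonical_leads(), function(ld) {
    i <- which(canon == ld)[1]
    (mat[i, ] - sig[[i]]$baseline) / sig[[i]]$gain
  })
  names(cols) <- canonical_leads()
  ecg_record(as.data.frame(cols, check.names = FALSE), sampling_rate = fs,
             subject_id = subject_id %||% rec_name,
             record_id = rec_name, label = label)
}

#' Write a WFDB record
#'
#' Writes an `ecg_record` as a WFDB header/signal pair in format 16 with a
#' fixed gain of 2000 ADC units per mV (the PTB convention). Optionally
#' appends three zero-filled Frank leads (vx, vy, vz) to mimic 15-channel
#' PTB records; [read_wfdb_record()] drops them again.
#'
#' @param record An `ecg_record`.
#' @param dir Output directory.
#' @param frank_leads Append vx/vy/vz channels? Default `FALSE`.
#' @return The header path, invisibly.
#' @export
write_wfdb_record <- function(record, dir, frank_leads = FALSE) {
  stopifnot(inherits(record, "ecg_record"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rec_name <- attr(record, "record_id")
  gain <- 2000
  mat <- t(as.matrix(as.data.frame(record)[, canonical_leads()]))
  desc <- tolower(canonical_leads())
  if (frank_leads) {
    mat <- rbind(mat, matrix(0, 3, ncol(mat)))
    desc <- c(desc, "vx", "vy", "vz")
  }
  adc <- round(mat * gain)
  adc[adc > 32767] <- 32767
  adc[adc < -32768] <- -32768
  nsig <- nrow(adc)
  hea <- file.path(dir, paste0(rec_name, ".hea"))
  datf <- paste0(rec_name, ".dat")
  cksum <- apply(adc, 1, function(v) {
    s <- sum(v) %% 65536
    if (s >= 32768) s - 65536 else s
  })
  header <- c(
    paste(rec_name, nsig, attr(record, "sampling_rate"), ncol(adc)),
    sprintf("%s 16 %d(0)/mV 16 0 %d %d 0 %s",
            datf, gain, adc[, 1], cksum, desc)
  )
  writeLines(header, hea)
  writeBin(as.integer(adc), file.path(dir, datf), size = 2L,
           endian = "little")
  invisible(hea)
}
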