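# Shared fixtures, all generated in code.

# subject with every stochastic record-level component disabled
noiseless_subject <- function(label, seed = 7) {
  make_subject(label, seed, noise_sd = 0, wander_amp = 0,
               timing_jitter_sd = 0)
}

# a small architecture that keeps CNN tests fast
tiny_arch <- function(n_classes = 2) {
  ecg_cnn_architecture(n_classes = n_classes,
                       conv_channels = c(2, 2, 4, 4, 4, 4),
                       dense_units = c(32, 16))
}

# toy image sets: a bright blob whose vertical position encodes the class
toy_blob_sets <- function(n_per_class = 20, classes = c("N", "I"),
                          col_offset = 0, seed = 1) {
  set.seed(seed)
  rows_for <- function(cls) 10 + 30 * (match(cls, classes) - 1) + 0:9
  labs <- rep(classes, each = n_per_class)
  n <- length(labs)
  tibble::tibble(
    subject_id = paste0("s", seq_len(n)),
    record_id = paste0("r", seq_len(n)),
    label = labs,
    window_index = 0L,
    images = lapply(labs, function(cl) {
      arr <- array(0L, dim = c(12L, 64L, 64L))
      cols <- 21:30 + col_offset
      for (l in 1:12) {
        arr[l, rows_for(cl), cols] <- 255L
        noise <- matrix(as.integer(stats::rbinom(64 * 64, 1, 0.01) * 80L),
                        64, 64)
        arr[l, , ] <- pmin(255L, arr[l, , ] + noise)
      }
      arr
    })
  )
}

# small labeled synthetic corpus, cached across tests within a run
.corpus_cache <- new.env(parent = emptyenv())
small_corpus <- function(classes = c("N", "I"), n_subjects = 3,
                         duration_ms = 4000, master_seed = 11) {
  key <- paste(c(classes, n_subjects, duration_ms, master_seed),
               collapse = "_")
  if (is.null(.corpus_cache[[key]])) {
    plan <- setNames(rep(n_subjects, length(classes)), classes)
    ds <- generate_dataset(plan, records_per_subject = 1,
                           duration_ms = duration_ms,
                           master_seed = master_seed)
    .corpus_cache[[key]] <- dataset_to_image_sets(ds)
  }
  .corpus_cache[[key]]
}
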