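# Deterministic seed derivation: a small polynomial hash folded into
# [0, 2^31 - 2] so every subject/record gets an independent, reproducible
# R RNG seed regardless of generation order.
stable_seed <- function(...) {
  M <- 2147483647
  h <- 104729
  for (x in c(...)) h <- (h * 48271 + (abs(as.numeric(x)) %% M)) %% M
  as.integer(h)
}

#' Normal beat template
#'
#' A stylized PQRST beat modeled as a sum of Gaussian wavelets: each wave
#' has a center offset within the beat (ms), a width (ms) and an amplitude
#' (mV), with wave centers strictly ordered P < Q < R < S < T. Per-lead
#' amplitude multipliers shape the 12-lead projection; the R wave is
#' upright in I, II and V4-V6 and inverted in aVR, as in a normal ECG.
#'
#' @return A list with elements `waves` (tibble: wave, center_ms, width_ms,
#'   amp_mV) and `lead_mult` (named numeric vector over the 12 leads).
#' @export
normal_beat_template <- function() {
  list(
    waves = tibble::tibble(
      wave = c("P", "Q", "R", "S", "T"),
      center_ms = c(150, 330, 350, 372, 600),
      width_ms = c(25, 9, 13, 10, 60),
      amp_mV = c(0.15, -0.10, 1.20, -0.25, 0.35)
    ),
    lead_mult = c(
      I = 0.7, II = 1.0, III = 0.45, aVR = -0.85, aVL = 0.35, aVF = 0.75,
      V1 = -0.5, V2 = -0.2, V3 = 0.35, V4 = 1.1, V5 = 1.0, V6 = 0.8
    )
  )
}

#' Infarct-site to lead-group map
#'
#' Standard clinical correspondence between the infarcted wall and the
#' leads whose waveforms change. `direction = 1` marks leads showing the
#' primary signs (ST elevation, deepened Q, T inversion); `direction = -1`
#' marks leads showing reciprocal ST depression (posterior involvement seen
#' from V1-V3). Class N maps to no leads. The map is configuration: pass a
#' modified copy to [make_subject()] to explore alternatives.
#'
#' @return A tibble with columns `name` (class), `lead`, `direction`.
#' @export
mi_lead_map <- function() {
  g <- list(
    A = list(pos = c("V3", "V4")),
    AS = list(pos = c("V1", "V2", "V3")),
    AL = list(pos = c("I", "aVL", "V3", "V4", "V5", "V6")),
    I = list(pos = c("II", "III", "aVF")),
    IL = list(pos = c("I", "aVL", "II", "III", "aVF", "V5", "V6")),
    IP = list(pos = c("II", "III", "aVF"), neg = c("V1", "V2", "V3")),
    IPL = list(pos = c("I", "aVL", "II", "III", "aVF", "V5", "V6"),
               neg = c("V1", "V2", "V3")),
    L = list(pos = c("I", "aVL", "V5", "V6")),
    P = list(neg = c("V1", "V2", "V3")),
    PL = list(pos = c("I", "aVL", "V5", "V6"), neg = c("V1", "V2", "V3"))
  )
  purrr::imap_dfr(g, function(grp, cls) {
    tibble::tibble(
      name = cls,
      lead = c(grp$pos, grp$neg),
      direction = c(rep(1, length(grp$pos)), rep(-1, length(grp$neg)))
    )
  })
}

#' Draw a synthetic subject
#'
#' A subject is a deterministic function of `(label, rng_seed)`: the normal
#' beat template is jittered by subject-level random effects (per-wave
#' amplitude multipliers in 0.8-1.2, a global timing scale in 0.9-1.1 that
#' preserves wave order, a heart rate in 55-90 bpm), and the label's
#' infarction perturbation is drawn at subject-specific magnitude (ST shift
#' 0.15-0.30 mV, Q deepening 0.10-0.20 mV, T inversion factor 0.3-0.7).
#' Template effects are drawn from a label-independent stream, so subjects
#' of different classes with the same seed share the same underlying beat.
#'
#' @param label Class abbreviation.
#' @param rng_seed Integer seed.
#' @param noise_sd White-noise standard deviation in mV (default 0.03).
#' @param wander_amp,wander_freq Sinusoidal baseline-wander amplitude (mV)
#'   and frequency (Hz); defaults 0.1 mV at 0.3 Hz.
#' @param timing_jitter_sd Per-beat onset jitter SD in ms (default 8).
#' @param lead_map Infarct-site map; see [mi_lead_map()].
#' @return A list of class `ecg_subject`.
#' @export
make_subject <- function(label, rng_seed, noise_sd = 0.03,
                         wander_amp = 0.1, wander_freq = 0.3,
                         timing_jitter_sd = 8, lead_map = mi_lead_map()) {
  assert_class_label(label)
  stopifnot(noise_sd >= 0, wander_amp >= 0, timing_jitter_sd >= 0)
  tmpl <- normal_beat_template()

  # label-independent subject effects
  set.seed(stable_seed(rng_seed, 1))
  amp_jit <- runif(5, 0.8, 1.2)
  time_scale <- runif(1, 0.9, 1.1)
  width_jit <- runif(5, 0.9, 1.1)
  heart_rate <- runif(1, 55, 90)
  lead_jit <- runif(12, 0.9, 1.1)

  tmpl$waves$amp_mV <- tmpl$waves$amp_mV * amp_jit
  tmpl$waves$center_ms <- tmpl$waves$center_ms * time_scale
  tmpl$waves$width_ms <- tmpl$waves$width_ms * width_jit
  tmpl$lead_mult <- tmpl$lead_mult * lead_jit

  # label-specific perturbation magnitudes (separate stream); ranges
  # calibrated so the corpus carries learnable class signal while
  # magnitudes still vary substantially between subjects
  set.seed(stable_seed(rng_seed, 2))
  mags <- list(st_shift = runif(1, 0.25, 0.50),
               q_deepening = runif(1, 0.15, 0.35),
               t_inversion_factor = runif(1, 0.5, 0.9))
  perturb <- lead_map[lead_map$name == label, c("lead", "direction")]

  structure(list(
    subject_id = sprintf("%s_seed%d", label, rng_seed),
    label = label,
    heart_rate = heart_rate,
    template = tmpl,
    perturb = perturb,
    st_shift = mags$st_shift,
    q_deepening = mags$q_deepening,
    t_inversion_factor = mags$t_inversion_factor,
    noise_sd = noise_sd,
    wander_amp = wander_amp,
    wander_freq = wander_freq,
    timing_jitter_sd = timing_jitter_sd,
    rng_seed = as.integer(rng_seed)
  ), class = "ecg_subject")
}

# smooth ST-segment plateau between the end of S and the onset of T
st_plateau <- function(t_in_beat, s_end, t_onset, tau = 8) {
  stats::plogis((t_in_beat - s_end) / tau) *
    stats::plogis((t_onset - t_in_beat) / tau)
}

#' Synthesize one record for a subject
#'
#' Sums Gaussian wavelets per beat per lead (template amplitudes times lead
#' multipliers), realizes the class's ST-segment offset as a smooth plateau
#' between the S and T waves of affected leads (sign per lead direction),
#' deepens the Q wave and attenuates/inverts the T wave on primary leads,
#' then adds white Gaussian noise and sinusoidal baseline wander. Beats
#' start at intervals of `60000 / heart_rate` ms with per-beat timing
#' jitter. Fully deterministic given `record_seed`.
#'
#' @param subject An `ecg_subject` from [make_subject()].
#' @param duration_ms Record duration in ms (>= 1000).
#' @param sampling_rate Sampling rate in Hz (>= 250); default 1000.
#' @param record_seed Integer seed for record-level noise; defaults to the
#'   subject's seed.
#' @param record_id Identifier; defaults to `<subject_id>_r0`.
#' @return An [ecg_record()].
#' @export
synthesize_record <- function(subject, duration_ms = 10000,
                              sampling_rate = 1000,
                              record_seed = subject$rng_seed,
                              record_id = paste0(subject$subject_id, "_r0")) {
  stopifnot(inherits(subject, "ecg_subject"))
  if (duration_ms < 1000) abort("duration_ms must be >= 1000 ms",
                                class = "ecgmi_error_validation")
  if (sampling_rate < 250) abort("sampling_rate must be >= 250 Hz",
                                 class = "ecgmi_error_validation")
  n <- round(duration_ms * sampling_rate / 1000)
  t_ms <- (seq_len(n) - 1) * 1000 / sampling_rate
  period <- 60000 / subject$heart_rate
  set.seed(stable_seed(record_seed, 3))
  onsets <- seq(0, duration_ms + period, by = period)
  onsets <- onsets + rnorm(length(onsets), 0, subject$timing_jitter_sd)

  w <- subject$template$waves
  mult <- subject$template$lead_mult
  s_end <- w$center_ms[w$wave == "S"] + 12
  t_onset <- w$center_ms[w$wave == "T"] - 25
  leads <- canonical_leads()
  sig <- matrix(0, n, 12, dimnames = list(NULL, leads))

  for (li in seq_along(leads)) {
    lead <- leads[li]
    prow <- subject$perturb[subject$perturb$lead == lead, ]
    dirn <- if (nrow(prow)) prow$direction[1] else 0
    amps <- w$amp_mV * mult[lead]
    if (dirn == 1) {
      # primary infarction signs: deep Q, attenuated/inverted T
      amps[w$wave == "Q"] <- amps[w$wave == "Q"] -
        subject$q_deepening * abs(mult[lead])
      amps[w$wave == "T"] <- amps[w$wave == "T"] *
        (1 - 2 * subject$t_inversion_factor)
    }
    v <- numeric(n)
    for (o in onsets) {
      tb <- t_ms - o
      live <- tb > -100 & tb < period + 100
      if (!any(live)) next
      tbl <- tb[live]
      acc <- numeric(length(tbl))
      for (k in seq_len(nrow(w))) {
        acc <- acc + amps[k] *
          exp(-((tbl - w$center_ms[k])^2) / (2 * w$width_ms[k]^2))
      }
      if (dirn != 0) {
        acc <- acc + dirn * subject$st_shift * abs(mult[lead]) *
          st_plateau(tbl, s_end, t_onset)
      }
      v[live] <- v[live] + acc
    }
    sig[, li] <- v
  }

  # record-level noise: same draw order for every class, so matched seeds
  # differ only through the perturbation terms above
  for (li in seq_along(leads)) {
    phase <- runif(1, 0, 2 * pi)
    sig[, li] <- sig[, li] +
      subject$wander_amp * sin(2 * pi * subject$wander_freq * t_ms / 1000 + phase) +
      rnorm(n, 0, subject$noise_sd)
  }

  ecg_record(as.data.frame(sig), sampling_rate = sampling_rate,
             subject_id = subject$subject_id, record_id = record_id,
             label = subject$label)
}

#' Generate a labeled synthetic corpus
#'
#' Draws `class_plan[[cls]]` subjects per class with seeds derived from a
#' single master seed by stable hashing (reproducible regardless of
#' generation order), and synthesizes `records_per_subject` records per
#' subject with independent record-level noise.
#'
#' @param class_plan Named integer vector or list: class abbreviation ->
#'   subject count.
#' @param records_per_subject Records per subject (default 1).
#' @param duration_ms,sampling_rate Passed to [synthesize_record()].
#' @param master_seed Integer master seed.
#' @param ... Passed to [make_subject()] (noise settings, lead map).
#' @return A tibble with columns `subject_id`, `record_id`, `label`,
#'   `seed`, and `record` (list-column of [ecg_record()]s).
#' @export
generate_dataset <- function(class_plan, records_per_subject = 1,
                             duration_ms = 10000, sampling_rate = 1000,
                             master_seed = 1, ...) {
  stopifnot(length(class_plan) > 0, all(unlist(class_plan) >= 0))
  classes <- names(class_plan)
  lapply(classes, assert_class_label)
  rows <- list()
  for (ci in seq_along(classes)) {
    cls <- classes[ci]
    for (si in seq_len(class_plan[[ci]])) {
      sseed <- stable_seed(master_seed, ci * 1000 + si)
      subj <- make_subject(cls, sseed, ...)
      subj$subject_id <- sprintf("%s_s%02d", cls, si)
      for (ri in seq_len(records_per_subject)) {
        rec_id <- sprintf("%s_r%02d", subj$subject_id, ri)
        rec <- synthesize_record(
          subj, duration_ms = duration_ms, sampling_rate = sampling_rate,
          record_seed = stable_seed(sseed, 100 + ri), record_id = rec_id)
        rows[[length(rows) + 1]] <- tibble::tibble(
          subject_id = subj$subject_id, record_id = rec_id, label = cls,
          seed = sseed, record = list(rec))
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Rasterize a whole synthetic corpus
#'
#' Convenience wrapper: applies [record_to_image_sets()] to every record of
#' a [generate_dataset()] tibble and row-binds the image sets.
#'
#' @param dataset Output of [generate_dataset()].
#' @param wspec,rspec See [record_to_image_sets()].
#' @return An image-set tibble.
#' @export
dataset_to_image_sets <- function(dataset, wspec = window_spec(),
                                  rspec = raster_spec()) {
  dplyr::bind_rows(lapply(dataset$record, record_to_image_sets,
                          wspec = wspec, rspec = rspec))
}
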