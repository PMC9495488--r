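#' Canonical 12-lead order
#'
#' The standard clinical ordering of the 12 ECG leads: limb leads, augmented
#' limb leads, then precordial leads. All records, image sets and model
#' inputs in this package follow this order.
#'
#' @return Character vector of the 12 lead names.
#' @export
#' @examples
#' canonical_leads()
canonical_leads <- function() {
  c("I", "II", "III", "aVR", "aVL", "aVF",
    "V1", "V2", "V3", "V4", "V5", "V6")
}

# PTB-style lowercase spellings map onto the same canonical names.
normalize_lead_names <- function(x) {
  leads <- canonical_leads()
  idx <- match(tolower(x), tolower(leads))
  out <- leads[idx]
  names(out) <- x
  out
}

#' Diagnostic class taxonomy
#'
#' The eleven diagnostic classes: normal (N) plus ten myocardial-infarction
#' localizations named by the infarcted wall.
#'
#' @return A tibble with columns `name` (abbreviation) and `long_name`.
#' @export
#' @examples
#' mi_classes()
mi_classes <- function() {
  tibble::tibble(
    name = c("N", "A", "AL", "AS", "I", "IL", "IP", "IPL", "L", "P", "PL"),
    long_name = c(
      "Normal", "Anterior", "Anterior-Lateral", "Anterior-Septal",
      "Inferior", "Inferior-Lateral", "Inferior-Posterior",
      "Inferior-Posterior-Lateral", "Lateral", "Posterior",
      "Posterior-Lateral"
    )
  )
}

#' @rdname mi_classes
#' @export
class_levels <- function() mi_classes()$name

assert_class_label <- function(label) {
  if (length(label) != 1 || !label %in% class_levels()) {
    abort(paste0(
      "`label` must be one of: ", paste(class_levels(), collapse = ", ")
    ), class = "ecgmi_error_label")
  }
  label
}

#' Classes eligible for subject-held-out evaluation
#'
#' Subject-held-out cross-validation requires at least two subjects per
#' class (one held out, at least one left to train on). Given a census of
#' subjects per class, returns the eligible classes in taxonomy order.
#'
#' @param census A data frame with columns `name` (class abbreviation) and
#'   `n_subjects`, e.g. [ptb_census()].
#' @param min_subjects Minimum subjects a class needs; default 2.
#' @return Character vector of eligible class abbreviations.
#' @export
#' @examples
#' eligible_classes(ptb_census())
eligible_classes <- function(census, min_subjects = 2) {
  stopifnot(is.data.frame(census),
            all(c("name", "n_subjects") %in% names(census)))
  keep <- census$name[census$n_subjects >= min_subjects]
  class_levels()[class_levels() %in% keep]
}

#' Published PTB subject/record census
#'
#' The per-class counts of subjects, records and 1-second image sets of the
#' PTB-derived corpus this pipeline was designed around. Used to drive
#' proportionally scaled synthetic corpora and the subject-eligibility rule.
#'
#' @return A tibble with columns `name`, `n_subjects`, `n_records`,
#'   `n_image_sets`.
#' @export
ptb_census <- function() {
  tibble::tibble(
    name = class_levels(),
    n_subjects = c(51L, 17L, 14L, 27L, 30L, 23L, 1L, 8L, 1L, 1L, 2L),
    n_records = c(74L, 47L, 39L, 77L, 87L, 55L, 1L, 19L, 3L, 4L, 5L),
    n_image_sets = c(4837L, 2812L, 2580L, 4620L, 5268L, 3315L, 38L,
                     1118L, 180L, 240L, 300L)
  )
}
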