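#' Recognized cognitive domains
#'
#' The six neuropsychological domains the battery covers, in canonical order.
#' @return Character vector of domain keys.
#' @export
cognitive_domains <- function() {
  c(
    "attention_working_memory", "verbal_language", "motor",
    "abstract_executive", "learning_recall", "processing_speed"
  )
}

#' Composite cognitive-domain T-scores
#'
#' A domain assessed by several tests gets a composite T-score equal to the
#' arithmetic mean of the demographically adjusted T-scores of all tests in
#' that domain. Inputs are already-normed T-scores (mean 50, SD 10 in the
#' reference population); norming raw scores is upstream of this package.
#'
#' @param test_scores Data frame in long format with columns `domain`,
#'   `tscore`, and optionally `subject_id` (plus any test identifier, which
#'   is ignored by the average).
#' @return A tibble with one row per (subject,) domain: `domain`,
#'   `n_tests`, `tscore` (the composite).
#' @examples
#' composite_domain_tscores(tibble::tibble(
#'   domain = c("attention_working_memory", "attention_working_memory", "motor"),
#'   tscore = c(40, 50, 45)
#' ))
#' @export
composite_domain_tscores <- function(test_scores) {
  test_scores <- tibble::as_tibble(test_scores)
  if (!all(c("domain", "tscore") %in% names(test_scores))) {
    abort("`test_scores` needs columns 'domain' and 'tscore'.")
  }
  if (nrow(test_scores) == 0L) {
    abort("No test scores supplied: each scored domain needs at least one test.")
  }
  if (any(!is.finite(test_scores$tscore))) {
    abort("All T-scores must be finite.")
  }
  grp <- intersect(c("subject_id", "domain"), names(test_scores))
  test_scores |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(
      n_tests = dplyr::n(),
      tscore = mean(.data$tscore),
      .groups = "drop"
    )
}

#' Classify asymptomatic neurocognitive impairment (ANI)
#'
#' Frascati-style rule: a subject is ANI when everyday functioning is intact
#' (by self-report) but at least two of the six cognitive domains show
#' impairment, operationalized as a composite T-score below `threshold_t`
#' (default 40, i.e. one SD below the normative mean). Subjects with impaired
#' everyday functioning fall outside the ANI category and are returned as
#' `"unimpaired"` by this binary rule (the package does not grade MND/HAD).
#'
#' @param data Data frame with one column per domain key (see
#'   [cognitive_domains()]), holding composite T-scores, plus a
#'   `functional_status` column with values `"intact"` or `"impaired"`.
#' @param threshold_t Impairment cutoff on the T-score scale (default 40).
#' @return The input tibble with `n_impaired_domains` and `ani_status`
#'   (`"ANI"` or `"unimpaired"`) columns appended.
#' @export
classify_ani <- function(data, threshold_t = 40) {
  data <- tibble::as_tibble(data)
  doms <- cognitive_domains()
  missing_doms <- setdiff(doms, names(data))
  if (length(missing_doms)) {
    abort(sprintf(
      "Missing domain column(s): %s", paste(missing_doms, collapse = ", ")
    ))
  }
  if (!"functional_status" %in% names(data)) {
    abort("Missing 'functional_status' column (intact/impaired self-report).")
  }
  if (!all(data$functional_status %in% c("intact", "impaired"))) {
    abort("`functional_status` must be 'intact' or 'impaired'.")
  }
  scores <- as.matrix(data[doms])
  if (any(!is.finite(scores))) {
    abort("All six domain T-scores must be finite for every subject.")
  }
  n_imp <- rowSums(scores < threshold_t)
  data |>
    dplyr::mutate(
      n_impaired_domains = as.integer(n_imp),
      ani_status = dplyr::if_else(
        .data$functional_status == "intact" & n_imp >= 2L, "ANI", "unimpaired"
      )
    )
}
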