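#' Brain-predicted age differences (brain-PAD)
#'
#' Converts a wide table of per-structure predicted ages into brain-PADs:
#' `pad = predicted age - chronological age`, so a positive PAD means an
#' older-appearing structure (accelerated aging).
#'
#' @param data Data frame with one row per subject, a chronological-age
#'   column, and one predicted-age column per structure.
#' @param chron_age Name of the chronological-age column (default `"age"`).
#' @param predicted <[`tidy-select`][dplyr::dplyr_tidy_select]> columns
#'   holding predicted ages; defaults to every column whose name starts with
#'   `"pred_age"`. Output columns replace that prefix with `"pad"` (or, for
#'   non-prefixed selections, are prefixed with `"pad_"`).
#' @param id_cols <[`tidy-select`][dplyr::dplyr_tidy_select]> identifier
#'   columns carried through unchanged (default: `subject_id` if present).
#' @return A tibble with the id columns, the chronological age, and one
#'   signed PAD column (years) per selected structure. Rows whose predicted
#'   age is missing get `NA` with a warning naming the structures affected.
#' @examples
#' tbl <- tibble::tibble(
#'   subject_id = "s1", age = 50,
#'   pred_age_hippocampus = 55, pred_age_thalamus = 48
#' )
#' compute_brain_pad(tbl)
#' @export
compute_brain_pad <- function(data, chron_age = "age",
                              predicted = dplyr::starts_with("pred_age"),
                              id_cols = dplyr::any_of("subject_id")) {
  data <- tibble::as_tibble(data)
  if (!chron_age %in% names(data)) {
    abort(sprintf("Chronological-age column '%s' not found.", chron_age))
  }
  age <- data[[chron_age]]
  if (any(is.na(age)) || any(!is.finite(age)) || any(age <= 0)) {
    abort("Chronological ages must all be present, finite and positive.")
  }
  pred_cols <- names(dplyr::select(data, {{ predicted }}))
  if (!length(pred_cols)) {
    abort("No predicted-age columns selected.")
  }
  if (chron_age %in% pred_cols) {
    pred_cols <- setdiff(pred_cols, chron_age)
  }
  miss <- pred_cols[vapply(pred_cols, function(cl) anyNA(data[[cl]]), TRUE)]
  if (length(miss)) {
    warn(sprintf(
      "Missing predicted ages left as NA PADs for: %s",
      paste(miss, collapse = ", ")
    ))
  }
  ids <- dplyr::select(data, {{ id_cols }})
  pads <- purrr::map(pred_cols, function(cl) data[[cl]] - age)
  names(pads) <- ifelse(startsWith(pred_cols, "pred_age"),
    sub("^pred_age", "pad", pred_cols),
    paste0("pad_", pred_cols)
  )
  dplyr::bind_cols(
    ids,
    tibble::tibble(!!chron_age := age),
    tibble::as_tibble(pads)
  )
}
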