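#' Per-structure group comparison of brain-PADs
#'
#' The accelerated-aging table: for every structure (and the global predicted
#' age) the brain-PADs of the two groups are compared with the
#' assumption-gated test battery of [compare_groups()], and the raw p-values
#' receive Benjamini-Hochberg q-values as one analysis family.
#'
#' @param cohort Subject table with `group` (`"hc"`/`"hiv"`), `age` and
#'   `pred_age_*` columns (as produced by [generate_cohort()] or read from
#'   CSV).
#' @param method Test selection passed to [compare_groups()]: `"gated"`
#'   (default), `"t"`, or `"mann_whitney"`.
#' @param alpha_gate Gate level for the assumption checks.
#' @return A tibble with one row per structure: group means, `test_used`,
#'   `statistic`, `p_value`, `q_value`, gate diagnostics.
#' @export
pad_group_table <- function(cohort, method = "gated", alpha_gate = 0.05) {
  cohort <- tibble::as_tibble(cohort)
  check_cohort(cohort)
  pads <- compute_brain_pad(cohort,
    id_cols = dplyr::any_of(c("subject_id"))
  ) |>
    dplyr::mutate(group = cohort$group)
  pad_cols <- grep("^pad", names(pads), value = TRUE)
  rows <- purrr::map(pad_cols, function(cl) {
    cmp <- compare_groups(
      pads[[cl]][pads$group == "hc"], pads[[cl]][pads$group == "hiv"],
      alpha_gate = alpha_gate, method = method, labels = c("hc", "hiv")
    )
    dplyr::bind_cols(
      tibble::tibble(structure = sub("^pad_", "", cl)),
      tidy(cmp) |>
        dplyr::rename(mean_hc = "mean_a", mean_hiv = "mean_b",
          n_hc = "n_a", n_hiv = "n_b")
    )
  })
  out <- dplyr::bind_rows(rows) |>
    dplyr::mutate(q_value = fdr_adjust(.data$p_value), .after = "p_value")
  attr(out, "fdr_family") <- "pad_group"
  out
}

#' ALPS trajectory correlations against aging indices
#'
#' The trajectory table: linear regressions of the ALPS index on each aging
#' index (chronological age and every structure's predicted age or brain-PAD)
#' in the pooled sample and within each group. One Benjamini-Hochberg family
#' per call.
#'
#' @inheritParams pad_group_table
#' @param kinds Which aging indices to include: any of `"chronological"`,
#'   `"predicted_age"`, `"brain_pad"`.
#' @return A long tibble: `predictor`, `aging_index_kind`, `sample`
#'   (`pooled`/`hc`/`hiv`), `slope`, `r`, `p_value`, `q_value`, `n`.
#' @export
trajectory_table <- function(cohort,
                             kinds = c("chronological", "predicted_age")) {
  cohort <- tibble::as_tibble(cohort)
  check_cohort(cohort, need_alps = TRUE)
  kinds <- match.arg(kinds,
    c("chronological", "predicted_age", "brain_pad"),
    several.ok = TRUE
  )
  samples <- list(
    pooled = cohort,
    hc = dplyr::filter(cohort, .data$group == "hc"),
    hiv = dplyr::filter(cohort, .data$group == "hiv")
  )
  pred_cols <- grep("^pred_age", names(cohort), value = TRUE)
  specs <- list()
  if ("chronological" %in% kinds) {
    specs <- c(specs, list(list(
      predictor = "chronological_age", kind = "chronological", col = "age",
      pad = FALSE
    )))
  }
  for (kind in intersect(c("predicted_age", "brain_pad"), kinds)) {
    specs <- c(specs, purrr::map(pred_cols, function(cl) list(
      predictor = paste0(
        sub("^pred_age_?", "", cl) |> (\(s) if (s == "") "global" else s)(),
        if (kind == "brain_pad") "_pad" else ""
      ),
      kind = kind, col = cl, pad = (kind == "brain_pad")
    )))
  }
  rows <- purrr::map(specs, function(sp) {
    purrr::imap(samples, function(dat, nm) {
      x <- dat[[sp$col]]
      if (sp$pad) x <- x - dat$age
      fit <- fit_trajectory(x, dat$alps, kind = sp$kind, group = nm)
      tibble::tibble(
        predictor = sp$predictor, aging_index_kind = sp$kind, sample = nm,
        slope = fit$slope, r = fit$r, p_value = fit$p, n = fit$n
      )
    }) |> dplyr::bind_rows()
  })
  out <- dplyr::bind_rows(rows) |>
    dplyr::mutate(q_value = fdr_adjust(.data$p_value), .after = "p_value")
  attr(out, "fdr_family") <- "trajectory"
  out
}

#' Per-structure slope-equality tests between groups
#'
#' For every structure, the ALPS-versus-brain-PAD line is fitted separately
#' in the control and HIV groups and the slopes are compared with
#' [compare_slopes()]. One Benjamini-Hochberg family per call.
#'
#' @inheritParams pad_group_table
#' @return A tibble: `structure`, `slope_hc`, `slope_hiv`, `t`, `df`,
#'   `p_value`, `q_value`, `n_hc`, `n_hiv`.
#' @export
slope_table <- function(cohort) {
  cohort <- tibble::as_tibble(cohort)
  check_cohort(cohort, need_alps = TRUE)
  pred_cols <- setdiff(
    grep("^pred_age_", names(cohort), value = TRUE), "pred_age_global"
  )
  hc <- dplyr::filter(cohort, .data$group == "hc")
  hiv <- dplyr::filter(cohort, .data$group == "hiv")
  rows <- purrr::map(pred_cols, function(cl) {
    fit_hc <- fit_trajectory(hc[[cl]] - hc$age, hc$alps,
      kind = "brain_pad", group = "hc"
    )
    fit_hiv <- fit_trajectory(hiv[[cl]] - hiv$age, hiv$alps,
      kind = "brain_pad", group = "hiv"
    )
    sc <- compare_slopes(fit_hc, fit_hiv)
    tibble::tibble(
      structure = sub("^pred_age_", "", cl),
      slope_hc = sc$slope_a, slope_hiv = sc$slope_b,
      t = sc$t, df = sc$df, p_value = sc$p, n_hc = sc$n_a, n_hiv = sc$n_b
    )
  })
  out <- dplyr::bind_rows(rows) |>
    dplyr::mutate(q_value = fdr_adjust(.data$p_value), .after = "p_value")
  attr(out, "fdr_family") <- "slope_equality"
  out
}

#' Brain-PAD versus cognition, controlling for sex
#'
#' Partial correlations (Pearson by default, Spearman optionally) between
#' each structure's brain-PAD and each cognitive-domain composite T-score,
#' controlling for sex (coded 0/1). One Benjamini-Hochberg family per call.
#'
#' @inheritParams pad_group_table
#' @param domains Domain columns to correlate (default all six of
#'   [cognitive_domains()] that are present).
#' @param method `"pearson"` or `"spearman"`.
#' @return A tibble: `structure`, `domain`, `r`, `p_value`, `q_value`, `n`.
#' @export
pad_cognition_table <- function(cohort, domains = NULL,
                                method = c("pearson", "spearman")) {
  method <- match.arg(method)
  cohort <- tibble::as_tibble(cohort)
  check_cohort(cohort)
  if (is.null(domains)) {
    domains <- intersect(cognitive_domains(), names(cohort))
  }
  if (!length(domains)) {
    abort("No cognitive-domain columns found in the cohort table.")
  }
  sex01 <- as.integer(cohort$sex == "male")
  pred_cols <- setdiff(
    grep("^pred_age_", names(cohort), value = TRUE), "pred_age_global"
  )
  rows <- purrr::map(pred_cols, function(cl) {
    pad <- cohort[[cl]] - cohort$age
    purrr::map(domains, function(d) {
      pc <- partial_correlation(pad, cohort[[d]],
        covariates = sex01, method = method
      )
      tibble::tibble(
        structure = sub("^pred_age_", "", cl), domain = d,
        r = pc$r, p_value = pc$p_value, n = pc$n
      )
    }) |> dplyr::bind_rows()
  })
  out <- dplyr::bind_rows(rows) |>
    dplyr::mutate(q_value = fdr_adjust(.data$p_value), .after = "p_value")
  attr(out, "fdr_family") <- "pad_cognition"
  out
}

check_cohort <- function(cohort, need_alps = FALSE) {
  need <- c("group", "age")
  if (need_alps) need <- c(need, "alps")
  miss <- setdiff(need, names(cohort))
  if (length(miss)) {
    abort(sprintf("Cohort table lacks column(s): %s", paste(miss, collapse = ", ")))
  }
  if (!all(cohort$group %in% c("hc", "hiv"))) {
    abort("Cohort `group` must be 'hc' or 'hiv'.")
  }
  if (!length(grep("^pred_age", names(cohort)))) {
    abort("Cohort table has no `pred_age_*` columns.")
  }
  invisible(cohort)
}
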