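#' Assumption-gated two-group comparison
#'
#' Compares a measure between two groups the way the study battery does:
#' Shapiro-Wilk normality in each group and Levene's test of variance
#' homogeneity (Brown-Forsythe variant, centered at the median) are run at
#' `alpha_gate`; when all three pass, a pooled-variance independent t-test is
#' used, otherwise a Mann-Whitney U test (exact when `n1 * n2 <= 400` and
#' there are no ties, else the tie-corrected normal approximation). All
#' p-values are two-sided.
#'
#' @param x_a,x_b Numeric samples for the two groups (>= 3 observations each).
#' @param alpha_gate Significance level of the assumption gates (default 0.05).
#' @param method `"gated"` (default) applies the rule above; `"t"` or
#'   `"mann_whitney"` force one branch (the gate diagnostics are still
#'   recorded).
#' @param labels Length-2 character, group labels for reporting.
#' @return An object of class `group_comparison`; see [tidy.group_comparison()].
#' @examples
#' set.seed(1)
#' cmp <- compare_groups(rnorm(20, 50), rnorm(30, 52))
#' tidy(cmp)
#' @export
compare_groups <- function(x_a, x_b, alpha_gate = 0.05,
                           method = c("gated", "t", "mann_whitney"),
                           labels = c("a", "b")) {
  method <- match.arg(method)
  x_a <- as.numeric(x_a[is.finite(x_a)])
  x_b <- as.numeric(x_b[is.finite(x_b)])
  if (length(x_a) < 3L || length(x_b) < 3L) {
    abort("Each group needs at least 3 finite observations.")
  }
  stopifnot(length(labels) == 2L)

  safe_shapiro <- function(x) {
    tryCatch(shapiro.test(x)$p.value, error = function(e) NA_real_)
  }
  sw_a <- safe_shapiro(x_a)
  sw_b <- safe_shapiro(x_b)
  lev <- tryCatch(
    {
      g <- factor(rep(labels, c(length(x_a), length(x_b))))
      car::leveneTest(c(x_a, x_b) ~ g, center = median)[1, "Pr(>F)"]
    },
    error = function(e) NA_real_
  )
  gates_pass <- !is.na(sw_a) && !is.na(sw_b) && !is.na(lev) &&
    sw_a > alpha_gate && sw_b > alpha_gate && lev > alpha_gate

  # degenerate case: both groups constant at the same value
  if (sd(x_a) == 0 && sd(x_b) == 0 && mean(x_a) == mean(x_b)) {
    test_used <- if (method == "mann_whitney") "mann_whitney" else "t"
    out <- list(
      test_used = test_used, statistic = 0, p = 1,
      mean_a = mean(x_a), mean_b = mean(x_b),
      n_a = length(x_a), n_b = length(x_b),
      gates = list(shapiro_a = sw_a, shapiro_b = sw_b, levene = lev,
        passed = FALSE),
      labels = labels
    )
    return(structure(out, class = "group_comparison"))
  }

  use_t <- switch(method,
    gated = gates_pass,
    t = TRUE,
    mann_whitney = FALSE
  )
  if (use_t) {
    tt <- t.test(x_a, x_b, var.equal = TRUE)
    test_used <- "t"
    statistic <- unname(tt$statistic)
    p <- tt$p.value
  } else {
    n1 <- length(x_a)
    n2 <- length(x_b)
    ties <- anyDuplicated(c(x_a, x_b)) > 0L
    wt <- suppressWarnings(wilcox.test(
      x_a, x_b,
      exact = (n1 * n2 <= 400) && !ties, correct = FALSE
    ))
    test_used <- "mann_whitney"
    statistic <- unname(wt$statistic) # U for group a
    p <- wt$p.value
  }
  structure(
    list(
      test_used = test_used, statistic = statistic, p = p,
      mean_a = mean(x_a), mean_b = mean(x_b),
      n_a = length(x_a), n_b = length(x_b),
      gates = list(shapiro_a = sw_a, shapiro_b = sw_b, levene = lev,
        passed = gates_pass),
      labels = labels
    ),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf(
    "<group_comparison> %s (n=%d, mean %.4g) vs %s (n=%d, mean %.4g): %s, statistic = %.4g, p = %.4g\n",
    x$labels[1], x$n_a, x$mean_a, x$labels[2], x$n_b, x$mean_b,
    x$test_used, x$statistic, x$p
  ))
  invisible(x)
}

#' @rdname compare_groups
#' @param x A `group_comparison` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.group_comparison <- function(x, ...) {
  tibble::tibble(
    test_used = x$test_used, statistic = x$statistic, p_value = x$p,
    mean_a = x$mean_a, mean_b = x$mean_b, n_a = x$n_a, n_b = x$n_b,
    shapiro_p_a = x$gates$shapiro_a, shapiro_p_b = x$gates$shapiro_b,
    levene_p = x$gates$levene, gates_passed = x$gates$passed
  )
}

#' Linear aging-trajectory regression
#'
#' Ordinary least-squares regression of the ALPS glymphatic index on an aging
#' index (chronological age, a structure's predicted age, or its brain-PAD),
#' with the Pearson correlation and its two-sided p-value from the t
#' distribution on n - 2 degrees of freedom. Non-finite pairs are dropped
#' listwise (with a message).
#'
#' @param aging_index Numeric predictor (years).
#' @param alps Numeric response (ALPS index).
#' @param kind Which aging index this is: `"chronological"`,
#'   `"predicted_age"` or `"brain_pad"` (metadata only).
#' @param group Optional group label carried into reports.
#' @return An object of class `trajectory_fit` holding `slope`, `intercept`,
#'   `r`, `p`, `n`, `slope_se`, `residual_se`, the retained data, `kind` and
#'   `group`. `tidy()` and `glance()` methods are provided.
#' @examples
#' set.seed(1)
#' age <- runif(40, 20, 70)
#' fit <- fit_trajectory(age, 1.8 - 0.004 * age + rnorm(40, 0, 0.05))
#' glance(fit)
#' @export
fit_trajectory <- function(aging_index,
                           alps,
                           kind = c("chronological", "predicted_age", "brain_pad"),
                           group = NA_character_) {
  kind <- match.arg(kind)
  x <- as.numeric(aging_index)
  y <- as.numeric(alps)
  if (length(x) != length(y)) {
    abort("`aging_index` and `alps` must have the same length.")
  }
  keep <- is.finite(x) & is.finite(y)
  if (any(!keep)) {
    inform(sprintf("fit_trajectory: dropped %d non-finite pair(s).", sum(!keep)))
  }
  x <- x[keep]
  y <- y[keep]
  n <- length(x)
  if (n < 3L) {
    abort("Trajectory regression needs at least 3 complete pairs.")
  }
  if (sd(x) == 0) {
    abort("Zero-variance aging index: the trajectory slope is unidentified.")
  }
  if (sd(y) == 0) {
    # flat response: slope 0 by convention, no association
    fit <- list(
      slope = 0, intercept = y[1], r = 0, p = 1, n = n,
      slope_se = 0, residual_se = 0, x = x, y = y,
      kind = kind, group = group
    )
    return(structure(fit, class = "trajectory_fit"))
  }
  lmfit <- lm(y ~ x)
  # summary.lm warns on exact lines ("essentially perfect fit"); those are
  # legitimate inputs here (noise-free phantoms)
  sm <- suppressWarnings(summary(lmfit))
  r <- cor(x, y)
  # exact line: r = +-1 within fp noise -> p = 0
  if (abs(r) >= 1 - 1e-12) {
    p <- 0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * pt(-abs(tstat), df = n - 2)
  }
  structure(
    list(
      slope = unname(coef(lmfit)[2]),
      intercept = unname(coef(lmfit)[1]),
      r = r, p = p, n = n,
      slope_se = unname(sm$coefficients[2, 2]),
      residual_se = sm$sigma,
      x = x, y = y, kind = kind, group = group
    ),
    class = "trajectory_fit"
  )
}

#' @export
print.trajectory_fit <- function(x, ...) {
  cat(sprintf(
    "<trajectory_fit> alps ~ %s%s: slope = %.4g (SE %.3g), r = %.4f, p = %.4g, n = %d\n",
    x$kind, if (is.na(x$group)) "" else paste0(" [", x$group, "]"),
    x$slope, x$slope_se, x$r, x$p, x$n
  ))
  invisible(x)
}

#' @rdname fit_trajectory
#' @param x A `trajectory_fit` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.trajectory_fit <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", x$kind),
    estimate = c(x$intercept, x$slope),
    std.error = c(NA_real_, x$slope_se)
  )
}

#' @rdname fit_trajectory
#' @exportS3Method generics::glance
glance.trajectory_fit <- function(x, ...) {
  tibble::tibble(
    group = x$group, aging_index_kind = x$kind,
    slope = x$slope, intercept = x$intercept, slope_se = x$slope_se,
    r = x$r, p_value = x$p, n = x$n, residual_se = x$residual_se
  )
}

#' Test for equality of two regression slopes
#'
#' Tests whether two independently fitted trajectory lines share a slope:
#' `t = (b_a - b_b) / sqrt(SE_a^2 + SE_b^2)` referred to a t distribution on
#' `n_a + n_b - 4` degrees of freedom, two-sided. Swapping the groups flips
#' the sign of `t` and leaves `p` unchanged.
#'
#' @param fit_a,fit_b [fit_trajectory()] results for the two groups.
#' @return An object of class `slope_comparison` with `slope_a`, `slope_b`,
#'   `t`, `df`, `p`, group labels and per-group n.
#' @export
compare_slopes <- function(fit_a, fit_b) {
  stopifnot(inherits(fit_a, "trajectory_fit"), inherits(fit_b, "trajectory_fit"))
  if (fit_a$slope_se <= 0 || fit_b$slope_se <= 0) {
    abort("Degenerate fit (zero slope standard error) in one of the groups.")
  }
  tstat <- (fit_a$slope - fit_b$slope) / sqrt(fit_a$slope_se^2 + fit_b$slope_se^2)
  df <- fit_a$n + fit_b$n - 4
  structure(
    list(
      slope_a = fit_a$slope, slope_b = fit_b$slope,
      se_a = fit_a$slope_se, se_b = fit_b$slope_se,
      t = tstat, df = df, p = 2 * pt(-abs(tstat), df = df),
      group_a = fit_a$group, group_b = fit_b$group,
      n_a = fit_a$n, n_b = fit_b$n
    ),
    class = "slope_comparison"
  )
}

#' @export
print.slope_comparison <- function(x, ...) {
  cat(sprintf(
    "<slope_comparison> %s slope %.4g vs %s slope %.4g: t(%d) = %.4g, p = %.4g\n",
    x$group_a %||% "a", x$slope_a, x$group_b %||% "b", x$slope_b,
    x$df, x$t, x$p
  ))
  invisible(x)
}

#' @rdname compare_slopes
#' @param x A `slope_comparison` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.slope_comparison <- function(x, ...) {
  tibble::tibble(
    group_a = x$group_a, group_b = x$group_b,
    slope_a = x$slope_a, slope_b = x$slope_b,
    t = x$t, df = x$df, p_value = x$p, n_a = x$n_a, n_b = x$n_b
  )
}

#' Partial correlation controlling for covariates
#'
#' Residualizes `x` and `y` on the covariates (plus an intercept) by least
#' squares and correlates the residuals. The Spearman variant rank-transforms
#' `x`, `y` and the covariates first. The two-sided p-value comes from the t
#' distribution on `n - k - 2` degrees of freedom (`k` covariates). With no
#' covariates this reduces exactly to the plain Pearson (or Spearman)
#' correlation. Constant covariate columns are dropped with a warning; a
#' rank-deficient covariate matrix is an error.
#'
#' @param x,y Numeric vectors.
#' @param covariates Optional numeric vector, matrix or data frame of
#'   covariates (e.g. sex coded 0/1).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return A one-row tibble: `r`, `p_value`, `df`, `n`, `method`,
#'   `n_covariates`.
#' @export
partial_correlation <- function(x, y, covariates = NULL,
                                method = c("pearson", "spearman")) {
  method <- match.arg(method)
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y)) {
    abort("`x` and `y` must have the same length.")
  }
  if (is.null(covariates)) {
    Z <- matrix(numeric(0), nrow = length(x), ncol = 0)
  } else {
    Z <- as.matrix(as.data.frame(covariates))
    storage.mode(Z) <- "double"
    if (nrow(Z) != length(x)) {
      abort("Covariates must have one row per observation.")
    }
  }
  keep <- is.finite(x) & is.finite(y) &
    (if (ncol(Z)) rowSums(!is.finite(Z)) == 0L else TRUE)
  x <- x[keep]
  y <- y[keep]
  Z <- Z[keep, , drop = FALSE]
  if (ncol(Z)) {
    const <- apply(Z, 2, function(col) sd(col) == 0)
    if (any(const)) {
      warn(sprintf(
        "Dropping constant covariate column(s): %s",
        paste(colnames(Z)[const] %||% which(const), collapse = ", ")
      ))
      Z <- Z[, !const, drop = FALSE]
    }
  }
  k <- ncol(Z)
  n <- length(x)
  if (n <= k + 2L) {
    abort("Need n > k + 2 observations for a partial correlation.")
  }
  if (method == "spearman") {
    x <- rank(x)
    y <- rank(y)
    if (k) Z <- apply(Z, 2, rank)
  }
  M <- cbind(1, Z)
  if (qr(M)$rank < ncol(M)) {
    abort("Rank-deficient covariate matrix.")
  }
  rx <- lm.fit(M, x)$residuals
  ry <- lm.fit(M, y)$residuals
  r <- cor(rx, ry)
  df <- n - k - 2L
  if (abs(r) >= 1 - 1e-12) {
    p <- 0
  } else {
    tstat <- r * sqrt(df / (1 - r^2))
    p <- 2 * pt(-abs(tstat), df = df)
  }
  tibble::tibble(
    r = r, p_value = p, df = df, n = n, method = method, n_covariates = k
  )
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values, `q_(i) = min_{j >= i}(p_(j) * m / j)` capped at
#' 1, returned in input order. Applied per analysis family (one family per
#' report table in [run_study()]).
#'
#' @param pvals Numeric vector of p-values in `[0, 1]` (NAs preserved).
#' @return Numeric vector of q-values, same length and order.
#' @examples
#' fdr_adjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
fdr_adjust <- function(pvals) {
  pvals <- as.numeric(pvals)
  ok <- !is.na(pvals)
  if (any(pvals[ok] < 0 | pvals[ok] > 1)) {
    abort("All p-values must lie in [0, 1].")
  }
  p.adjust(pvals, method = "BH")
}
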