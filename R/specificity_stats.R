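#' Per-cell specificity ratios within one field
#'
#' The specificity ratio (SR) of a reporter-positive cell is its mean
#' antibody-channel intensity divided by the average of the mean intensities
#' of the reporter-negative cells in the same field. At least
#' `min_negatives` negative cells (default 20) are required per field;
#' negatives are never pooled across fields. SR = 1 means the antibody
#' stains positive and negative cells equally; SR > 1 means preferential
#' staining of positive cells.
#'
#' @param positive_means Mean antibody intensities of the positive cells.
#' @param negative_means Mean antibody intensities of the negative cells in
#'   the same field.
#' @param min_negatives Minimum number of negative cells required.
#' @param field_id Field identifier carried into the output.
#' @param cell_ids Optional ids for the positive cells (default 1..n).
#' @return Data frame with one row per positive cell: `field_id`,
#'   `cell_id`, `sr`.
#' @export
specificity_ratio <- function(positive_means, negative_means,
                              min_negatives = 20, field_id = "field",
                              cell_ids = NULL) {
  if (length(negative_means) < min_negatives) {
    stop("insufficient negative cells in field '", field_id, "': ",
         length(negative_means), " < ", min_negatives, call. = FALSE)
  }
  if (any(positive_means <= 0) || any(negative_means <= 0)) {
    stop("all cell means must be > 0 in field '", field_id, "'", call. = FALSE)
  }
  denom <- mean(negative_means)
  data.frame(
    field_id = field_id,
    cell_id = if (is.null(cell_ids)) seq_along(positive_means) else cell_ids,
    sr = positive_means / denom,
    stringsAsFactors = FALSE
  )
}

#' Specificity ratios from a per-cell measurement table
#'
#' Applies [specificity_ratio()] field by field to the output of
#' [mean_intensities()] / [quantify_field()], using the antibody channel
#' column, and pools the per-cell SR rows across fields.
#'
#' @param measurements Per-cell measurement table; must contain `field_id`,
#'   `cell_id`, `cell_class` and `antibody_col`.
#' @param antibody_col Column holding antibody-channel means.
#' @param min_negatives Minimum negative cells per field.
#' @return Data frame of SR records pooled across fields.
#' @export
sr_from_measurements <- function(measurements, antibody_col = "mean_antibody",
                                 min_negatives = 20) {
  stopifnot(antibody_col %in% names(measurements))
  out <- lapply(split(measurements, measurements$field_id), function(m) {
    pos <- m[m$cell_class == "positive", ]
    neg <- m[m$cell_class == "negative", ]
    specificity_ratio(pos[[antibody_col]], neg[[antibody_col]],
                      min_negatives = min_negatives,
                      field_id = m$field_id[1], cell_ids = pos$cell_id)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Hodges-Lehmann shift estimate with a distribution-free 95% CI
#'
#' The Hodges-Lehmann estimate of the shift between two samples is the
#' median of all `n_x * n_y` pairwise differences `x_i - y_j` (the median of
#' an even count is the mean of the two central order statistics). The
#' confidence interval is the Moses distribution-free interval: the K-th and
#' `(n_x*n_y + 1 - K)`-th sorted pairwise differences, with
#' `K = floor(n_x*n_y/2 - z * sqrt(n_x*n_y*(n_x+n_y+1)/12))` from the normal
#' approximation to the null Mann-Whitney distribution (`z` the standard
#' normal quantile for `conf_level`). K is clamped to at least 1, so for
#' very small samples the interval widens to the extreme differences.
#'
#' @param x,y Numeric samples (nonempty).
#' @param conf_level Confidence level (default 0.95).
#' @return A `group_comparison` list with `hl_estimate`, `ci_low`,
#'   `ci_high`, `conf_level`, `n_x`, `n_y`.
#' @export
hodges_lehmann_shift <- function(x, y, conf_level = 0.95) {
  if (length(x) < 1 || length(y) < 1) stop("samples must be nonempty", call. = FALSE)
  stopifnot(conf_level > 0, conf_level < 1)
  d <- sort(as.vector(outer(x, y, "-")))
  N <- length(d)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  K <- floor(N / 2 - z * sqrt(length(x) * length(y) * (length(x) + length(y) + 1) / 12))
  K <- max(1L, as.integer(K))
  structure(
    list(hl_estimate = stats::median(d), ci_low = d[K], ci_high = d[N + 1 - K],
         conf_level = conf_level, n_x = length(x), n_y = length(y)),
    class = "group_comparison"
  )
}

#' Mann-Whitney (Wilcoxon rank-sum) test
#'
#' U is computed from the rank sum of `x` in the combined sample using
#' midranks for ties. The p-value is exact when the combined sample size is
#' at most 12 and tie-free, otherwise from the normal approximation with tie
#' and continuity corrections (via [stats::wilcox.test()]).
#'
#' @param x,y Numeric samples (nonempty).
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @return A `group_comparison` list with `u_statistic` (U for `x`),
#'   `p_value`, `n_x`, `n_y`, `method` (`"exact"` or `"normal_approx"`).
#' @export
mann_whitney <- function(x, y, alternative = "two.sided") {
  if (length(x) < 1 || length(y) < 1) stop("samples must be nonempty", call. = FALSE)
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- any(duplicated(c(x, y)))
  exact <- (nx + ny <= 12) && !ties
  if (nx == ny && all(sort(x) == sort(y)) && length(unique(c(x, y))) == 1L) {
    # identical constant samples: U at its null mean, no evidence either way
    p <- 1
  } else {
    p <- suppressWarnings(
      stats::wilcox.test(x, y, alternative = alternative,
                         exact = exact, correct = TRUE)$p.value
    )
  }
  structure(
    list(u_statistic = u, p_value = p, n_x = nx, n_y = ny,
         alternative = alternative,
         method = if (exact) "exact" else "normal_approx"),
    class = "group_comparison"
  )
}

#' Normality checks (Shapiro-Wilk and Kolmogorov-Smirnov)
#'
#' Runs both tests the way SR-style data are screened before choosing
#' nonparametric inference. The KS test is against a normal with
#' sample-estimated mean and sd; because the parameters are estimated, its
#' p-value is anti-conservative (the Lilliefors caveat) and the result is
#' flagged `ks_approximate = TRUE`.
#'
#' @param x Numeric sample, `n >= 3`, non-constant.
#' @return List with `shapiro_wilk` (statistic, p), `kolmogorov_smirnov`
#'   (statistic, p) and `ks_approximate`.
#' @export
normality_tests <- function(x) {
  if (length(x) < 3) stop("need at least 3 observations", call. = FALSE)
  if (length(unique(x)) == 1L) {
    stop("sample is constant; normality tests are undefined", call. = FALSE)
  }
  sw <- stats::shapiro.test(x)
  ks <- suppressWarnings(stats::ks.test(x, "pnorm", mean(x), stats::sd(x)))
  list(
    shapiro_wilk = c(statistic = unname(sw$statistic), p_value = sw$p.value),
    kolmogorov_smirnov = c(statistic = unname(ks$statistic), p_value = ks$p.value),
    ks_approximate = TRUE
  )
}

#' Variance of log-normalized per-cell fluorescence in a field
#'
#' A knockout-control specificity metric: a specific antibody stains a
#' mixed field heterogeneously (some cells bright, some at background),
#' giving the log intensities a large spread, while in knockout tissue all
#' cells sit at similar background levels and the spread is small. The
#' statistic is the sample variance (n-1 denominator) of
#' `log(mean_i / normalizer)`; by default the normalizer is the field
#' median of all cell means, which makes the statistic invariant to overall
#' intensity scaling.
#'
#' @param cell_means Per-cell mean intensities of all cells in one field
#'   (`n >= 2`, all > 0).
#' @param normalizer `"field_median"` (default) or `"none"`.
#' @param field_id Field identifier.
#' @return Data frame row: `field_id`, `n_cells`, `log_variance`.
#' @export
log_variance <- function(cell_means, normalizer = c("field_median", "none"),
                         field_id = "field") {
  normalizer <- match.arg(normalizer)
  if (length(cell_means) < 2) stop("need at least 2 cells", call. = FALSE)
  if (any(cell_means <= 0)) stop("all cell means must be > 0", call. = FALSE)
  ref <- switch(normalizer, field_median = stats::median(cell_means), none = 1)
  data.frame(field_id = field_id, n_cells = length(cell_means),
             log_variance = stats::var(log(cell_means / ref)),
             stringsAsFactors = FALSE)
}

#' Compare a test condition against its control
#'
#' Applies the Hodges-Lehmann shift estimate (with its distribution-free
#' CI) and the two-sided Mann-Whitney test to a test group versus a control
#' group of SR values (or per-field log-variances). Inputs may be numeric
#' vectors or data frames carrying a `sr` or `log_variance` column.
#' Comparisons are two-sided at alpha = 0.05 with no multiple-testing
#' correction; this is recorded in the returned metadata.
#'
#' @param test,control Numeric vectors or SR / variance record data frames.
#' @param conf_level Confidence level for the HL interval.
#' @return A `group_comparison` list: `hl_estimate`, `ci_low`, `ci_high`,
#'   `u_statistic`, `p_value`, `n_x` (test), `n_y` (control), `conf_level`,
#'   `metadata`.
#' @export
compare_conditions <- function(test, control, conf_level = 0.95) {
  as_values <- function(v) {
    if (is.data.frame(v)) {
      col <- intersect(c("sr", "log_variance"), names(v))[1]
      if (is.na(col)) stop("data frame input needs an 'sr' or 'log_variance' column",
                           call. = FALSE)
      v <- v[[col]]
    }
    as.numeric(v)
  }
  x <- as_values(test); y <- as_values(control)
  hl <- hodges_lehmann_shift(x, y, conf_level = conf_level)
  mw <- mann_whitney(x, y)
  structure(
    list(hl_estimate = hl$hl_estimate, ci_low = hl$ci_low, ci_high = hl$ci_high,
         u_statistic = mw$u_statistic, p_value = mw$p_value,
         n_x = length(x), n_y = length(y), conf_level = conf_level,
         metadata = list(test = "mann_whitney_two_sided", alpha = 0.05,
                         multiple_testing_correction = "none",
                         mw_method = mw$method)),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("<group_comparison>\n")
  if (!is.null(x$hl_estimate)) {
    cat(sprintf("  HL shift: %.4g  [%.4g, %.4g] (%.0f%% CI)\n",
                x$hl_estimate, x$ci_low, x$ci_high, 100 * (x$conf_level %||% 0.95)))
  }
  if (!is.null(x$p_value)) {
    cat(sprintf("  Mann-Whitney U = %.4g, p = %.4g (n_x = %d, n_y = %d)\n",
                x$u_statistic %||% NA_real_, x$p_value, x$n_x, x$n_y))
  }
  invisible(x)
}

#' Grade a comparison on the -, +, ++ scale
#'
#' A configurable heuristic summarizing a Hodges-Lehmann comparison the way
#' antibody validation tables grade performance: `"-"` (poor) if the CI
#' contains 0 or the HL shift is below `t1`; `"+"` (regular) if
#' `t1 <= hl < t2`; `"++"` (good) if `hl >= t2`. Both bounds are closed at
#' the lower end. The default cut points (0.5 and 2 SR units) are a
#' documented heuristic, not a published convention.
#'
#' @param comparison A `group_comparison` with HL fields.
#' @param t1,t2 Cut points on the HL shift, `t1 < t2`.
#' @return One of `"-"`, `"+"`, `"++"`.
#' @export
grade_comparison <- function(comparison, t1 = 0.5, t2 = 2) {
  if (!is_number(t1) || !is_number(t2) || t1 >= t2) {
    stop("invalid grading thresholds: need t1 < t2", call. = FALSE)
  }
  ci_excludes_zero <- comparison$ci_low > 0 || comparison$ci_high < 0
  if (!ci_excludes_zero || comparison$hl_estimate < t1) return("-")
  if (comparison$hl_estimate < t2) return("+")
  "++"
}
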