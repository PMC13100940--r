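#' Parameters of the Monte Carlo power simulation
#'
#' Reference configuration for the nonparametric power / sample-size
#' simulation: per-cell specificity ratios are modeled as lognormal, the
#' null group has median `exp(log_mean_null)` (default 1, i.e. no
#' differential staining), and the alternative group is the same lognormal
#' scaled multiplicatively so that the group medians differ by
#' `median_difference` SR units. The multiplicative shift is the only
#' location change that keeps both groups exactly lognormal. Detection is a
#' two-sided Mann-Whitney test at level `alpha`.
#'
#' @param log_mean_null Log-scale location of the null group (default 0).
#' @param log_sd Log-scale spread shared by both groups (default 0.8).
#' @param median_difference Target difference in group medians, SR units
#'   (default 0.5).
#' @param alpha Significance level (default 0.05).
#' @param B Monte Carlo replicates (default 2000).
#' @param n_grid Strictly increasing per-group sample sizes searched by
#'   [required_n()] (default 10, 20, ..., 200).
#' @param seed Base seed; each grid size n uses the stream seeded
#'   `seed + n` so single-size runs and grid runs agree.
#' @return A validated `power_spec` list.
#' @export
power_spec <- function(log_mean_null = 0, log_sd = 0.8, median_difference = 0.5,
                       alpha = 0.05, B = 2000, n_grid = seq(10, 200, by = 10),
                       seed = 1) {
  spec <- list(log_mean_null = log_mean_null, log_sd = log_sd,
               median_difference = median_difference, alpha = alpha,
               B = as.integer(B), n_grid = as.integer(n_grid),
               test = "mann_whitney_two_sided", seed = as.integer(seed))
  stopifnot(spec$B >= 1, spec$alpha > 0, spec$alpha < 1, spec$log_sd > 0,
            length(spec$n_grid) >= 1, all(diff(spec$n_grid) > 0))
  class(spec) <- "power_spec"
  spec
}

#' Estimate power at one per-group sample size
#'
#' Draws `B` replicate pairs of samples of size `n`: group X from
#' `lognormal(log_mean_null, log_sd)` and group Y from the same distribution
#' scaled by `(m0 + median_difference) / m0` with `m0 = exp(log_mean_null)`,
#' so the group medians differ by `median_difference`. Each replicate is
#' tested with the two-sided Mann-Whitney test at `alpha`; power is the
#' rejection fraction. Deterministic for a given spec (the RNG stream is
#' seeded `spec$seed + n`).
#'
#' @param spec A [power_spec()].
#' @param n Per-group sample size, `n >= 2`.
#' @return A `power_result` list: `n`, `power`, `mc_se`
#'   (`sqrt(power * (1 - power) / B)`), `B`.
#' @export
simulate_power <- function(spec, n) {
  stopifnot(inherits(spec, "power_spec"))
  if (!is_count(n, 2)) stop("`n` must be an integer >= 2", call. = FALSE)
  m0 <- exp(spec$log_mean_null)
  shift <- log((m0 + spec$median_difference) / m0)
  rejected <- with_local_seed(spec$seed + n, {
    hits <- 0L
    for (b in seq_len(spec$B)) {
      x <- stats::rlnorm(n, spec$log_mean_null, spec$log_sd)
      y <- stats::rlnorm(n, spec$log_mean_null + shift, spec$log_sd)
      if (mann_whitney(x, y)$p_value < spec$alpha) hits <- hits + 1L
    }
    hits
  })
  p <- rejected / spec$B
  structure(list(n = as.integer(n), power = p,
                 mc_se = sqrt(p * (1 - p) / spec$B), B = spec$B),
            class = "power_result")
}

#' Smallest sample size on the grid reaching a target power
#'
#' Evaluates [simulate_power()] at every size in `spec$n_grid` in increasing
#' order and returns the first size whose estimated power reaches
#' `target_power`, together with the whole power curve. If no grid size
#' reaches the target the result carries `target_reached = FALSE` and
#' `n_required = NA` (still with the full curve).
#'
#' @param spec A [power_spec()].
#' @param target_power Target power (default 0.80).
#' @return A list: `n_required`, `power_at_n`, `target_power`,
#'   `target_reached`, and `curve` (data frame `n`, `power`, `mc_se`).
#' @export
required_n <- function(spec, target_power = 0.80) {
  stopifnot(inherits(spec, "power_spec"), length(spec$n_grid) >= 1)
  curve <- data.frame(n = integer(), power = numeric(), mc_se = numeric())
  for (n in spec$n_grid) {
    r <- simulate_power(spec, n)
    curve <- rbind(curve, data.frame(n = r$n, power = r$power, mc_se = r$mc_se))
  }
  hit <- which(curve$power >= target_power)
  list(
    n_required = if (length(hit)) curve$n[hit[1]] else NA_integer_,
    power_at_n = if (length(hit)) curve$power[hit[1]] else NA_real_,
    target_power = target_power,
    target_reached = length(hit) > 0,
    curve = curve
  )
}
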