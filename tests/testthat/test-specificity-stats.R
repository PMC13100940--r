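test_that("specificity ratio definition and the >= 20 negatives rule", {
  neg20 <- rep(100, 20)
  sr <- specificity_ratio(200, neg20)
  expect_equal(sr$sr, 2.0)
  expect_equal(specificity_ratio(mean(neg20), neg20)$sr, 1)  # equal staining -> SR 1
  expect_error(specificity_ratio(200, rep(100, 19), field_id = "f3"),
               "insufficient negative cells in field 'f3'")
  expect_error(specificity_ratio(c(200, -1), neg20), "> 0")
})

test_that("SR is invariant to a global intensity rescaling of the field", {
  set.seed(8)
  for (r in 1:5) {
    pos <- rlnorm(10, log(500), 0.3)
    neg <- rlnorm(25, log(100), 0.3)
    c_scale <- runif(1, 0.1, 10)
    expect_equal(specificity_ratio(pos * c_scale, neg * c_scale)$sr,
                 specificity_ratio(pos, neg)$sr)
  }
})

test_that("SRs are computed per field, never pooling negatives", {
  m <- rbind(
    data.frame(field_id = "a", cell_id = 1:22,
               cell_class = c("positive", "positive", rep("negative", 20)),
               mean_antibody = c(400, 600, rep(100, 20))),
    data.frame(field_id = "b", cell_id = 1:21,
               cell_class = c("positive", rep("negative", 20)),
               mean_antibody = c(400, rep(200, 20)))
  )
  sr <- sr_from_measurements(m)
  expect_equal(sr$sr[sr$field_id == "a"], c(4, 6))
  expect_equal(sr$sr[sr$field_id == "b"], 2)   # own field's denominator

  m$field_id[m$field_id == "b"][2:6] <- "c"    # field b drops below 20 negatives
  expect_error(sr_from_measurements(m), "insufficient negative cells")
})

test_that("Hodges-Lehmann estimate and Moses CI match the brute-force oracle", {
  expect_equal(hodges_lehmann_shift(c(1, 2, 3), c(0, 0))$hl_estimate, 2.0)
  x <- c(2.2, 0.4, 9)
  expect_equal(hodges_lehmann_shift(x, x)$hl_estimate, 0)

  set.seed(5)
  for (r in 1:25) {
    x <- rlnorm(sample(3:15, 1), 0, 0.8)
    y <- rlnorm(sample(3:15, 1), 0.2, 0.8)
    got <- hodges_lehmann_shift(x, y)
    ora <- oracle_hl(x, y)
    expect_equal(got$hl_estimate, ora$hl)
    expect_equal(got$ci_low, ora$ci_low)
    expect_equal(got$ci_high, ora$ci_high)
    expect_true(got$ci_low <= got$hl_estimate && got$hl_estimate <= got$ci_high)
    expect_true(all(c(got$ci_low, got$ci_high) %in% ora$diffs))
  }
  expect_error(hodges_lehmann_shift(numeric(0), 1), "nonempty")
})

test_that("HL shift of (x + delta, x) is exactly delta", {
  set.seed(6)
  for (r in 1:10) {
    x <- rlnorm(sample(5:20, 1), 0, 1)
    delta <- runif(1, -3, 3)
    expect_equal(hodges_lehmann_shift(x + delta, x)$hl_estimate, delta)
  }
})

test_that("Mann-Whitney U and p match exact enumeration on small tie-free samples", {
  mw <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(mw$u_statistic, 0)
  expect_equal(mw$p_value, 2 / 6)
  expect_identical(mw$method, "exact")

  set.seed(7)
  for (r in 1:20) {
    nx <- sample(3:6, 1); ny <- sample(3:6, 1)
    x <- rnorm(nx); y <- rnorm(ny)
    expect_equal(mann_whitney(x, y)$p_value, oracle_mw_exact_p(x, y))
  }
})

test_that("identical constant samples give p = 1 under the midrank convention", {
  mw <- mann_whitney(rep(5, 4), rep(5, 4))
  expect_equal(mw$p_value, 1)
  expect_equal(mw$u_statistic, 8)  # all midranks: U at its null mean
})

test_that("normal-approximation p stays within 0.02 of exact enumeration for sizes 8-12", {
  set.seed(9)
  for (r in 1:15) {
    nx <- sample(4:6, 1); ny <- sample(4:6, 1)
    x <- rnorm(nx); y <- rnorm(ny) + runif(1, 0, 1)
    approx_p <- suppressWarnings(
      stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
    )
    expect_lt(abs(approx_p - oracle_mw_exact_p(x, y)), 0.02)
  }
})

test_that("normality screens separate normal from lognormal samples", {
  sw_normal <- vapply(1:20, function(s) {
    set.seed(1000 + s)
    normality_tests(rnorm(500))$shapiro_wilk[["p_value"]]
  }, numeric(1))
  sw_lnorm <- vapply(1:20, function(s) {
    set.seed(2000 + s)
    normality_tests(rlnorm(500, 0, 0.8))$shapiro_wilk[["p_value"]]
  }, numeric(1))
  expect_gte(mean(sw_normal > 0.05), 0.90)
  expect_gte(mean(sw_lnorm < 0.05), 0.90)
  expect_error(normality_tests(c(1, 2)), "at least 3")
  expect_error(normality_tests(rep(3, 10)), "constant")
  expect_true(normality_tests(rnorm(50))$ks_approximate)
})

test_that("log-variance: zero for uniform fields, scale-invariant, errors on bad input", {
  expect_equal(log_variance(rep(123.4, 30))$log_variance, 0)
  set.seed(11)
  m <- rlnorm(40, log(300), 0.5)
  expect_equal(log_variance(m * 7)$log_variance, log_variance(m)$log_variance)
  expect_equal(log_variance(m, normalizer = "none")$log_variance,
               var(log(m)))
  expect_error(log_variance(100), "at least 2")
  expect_error(log_variance(c(10, -1)), "> 0")
})

test_that("mixed-class fields have higher log-variance than single-class fields", {
  wins <- vapply(1:20, function(s) {
    mixed <- generate_field(small_field_spec(), seed = 400 + s)
    single <- generate_field(small_field_spec(positive_fraction = 0),
                             seed = 400 + s)
    vm <- log_variance(quantify_field(mixed)$mean_antibody)$log_variance
    vs <- log_variance(quantify_field(single)$mean_antibody)$log_variance
    vm > vs
  }, logical(1))
  expect_gte(sum(wins), 18)
})

test_that("condition comparisons recover location shifts and generative effects", {
  set.seed(12)
  x <- rlnorm(40, 0, 0.5)
  same <- compare_conditions(x, x)
  expect_equal(same$hl_estimate, 0)
  expect_true(same$ci_low <= 0 && same$ci_high >= 0)
  shifted <- compare_conditions(x + 0.5, x)
  expect_equal(shifted$hl_estimate, 0.5)

  covered <- vapply(1:20, function(s) {
    set.seed(3000 + s)
    test_sr <- rlnorm(60, log(2), 0.4)    # generative effect k = 2
    ctrl_sr <- rlnorm(60, 0, 0.4)
    cmp <- compare_conditions(test_sr, ctrl_sr)
    cmp$ci_low <= 1 && 1 <= cmp$ci_high   # true median shift = k - 1 = 1
  }, logical(1))
  expect_gte(sum(covered), 17)
})

test_that("comparisons accept SR and variance record data frames", {
  sr_test <- data.frame(field_id = "a", cell_id = 1:30, sr = rlnorm(30, log(2), 0.3))
  sr_ctrl <- data.frame(field_id = "b", cell_id = 1:30, sr = rlnorm(30, 0, 0.3))
  cmp <- compare_conditions(sr_test, sr_ctrl)
  expect_gt(cmp$hl_estimate, 0)
  expect_identical(cmp$metadata$multiple_testing_correction, "none")
})

test_that("grading follows the documented boundary rules", {
  mk <- function(hl, lo, hi) structure(
    list(hl_estimate = hl, ci_low = lo, ci_high = hi), class = "group_comparison")
  expect_identical(grade_comparison(mk(3, -0.1, 5)), "-")   # CI contains 0
  expect_identical(grade_comparison(mk(0.3, 0.1, 0.5)), "-")
  expect_identical(grade_comparison(mk(0.5, 0.2, 0.9)), "+") # closed lower bound
  expect_identical(grade_comparison(mk(1.2, 0.5, 1.8)), "+")
  expect_identical(grade_comparison(mk(2, 1.5, 2.5)), "++")  # closed at t2
  expect_error(grade_comparison(mk(1, 0.5, 1.5), t1 = 2, t2 = 1), "t1 < t2")
})
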