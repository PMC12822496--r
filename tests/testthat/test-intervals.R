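fit_pure_normal <- function(n = 20000, mean = 16, sd = 2, seed = 21) {
  set.seed(seed)
  x <- rnorm(n, mean, sd)
  list(values = x, fit = fit_analyte(x, "normal"))
}

test_that("limits are parametric quantiles of the healthy component", {
  # exact check on a hand-built fit rather than an estimated one
  fit <- structure(list(
    components = list(list(family = "normal", role = "healthy",
                           params = c(mean = 16, sd = 2), weight = 1)),
    converged = TRUE, n_iterations = 1L, log_likelihood = 0,
    ks_main_part = 0, data_summary = c(n = 100, min = 10, max = 22)),
    class = "mixture_fit")
  ri <- reference_limits(fit, coverage = 0.95)
  # oracle: mu +/- z_0.975 sigma
  z <- stats::qnorm(0.975)
  expect_equal(ri$lower, 16 - 2 * z, tolerance = 1e-12)
  expect_equal(ri$upper, 16 + 2 * z, tolerance = 1e-12)
  expect_equal(round(c(ri$lower, ri$upper), 2), c(12.08, 19.92))
  # narrowing coverage pulls both limits toward the healthy median
  ri_tiny <- reference_limits(fit, coverage = 1e-6)
  expect_equal(ri_tiny$lower, 16, tolerance = 1e-4)
  expect_equal(ri_tiny$upper, 16, tolerance = 1e-4)
  # widening coverage widens the interval
  ri_99 <- reference_limits(fit, coverage = 0.99)
  expect_lt(ri_99$lower, ri$lower)
  expect_gt(ri_99$upper, ri$upper)
})

test_that("limits from the calibrated truth round-trip to the targets", {
  g <- first_tsh_gamma()
  fit <- structure(list(
    components = list(list(family = "gamma", role = "healthy",
                           params = g, weight = 1)),
    converged = TRUE, n_iterations = 1L, log_likelihood = 0,
    ks_main_part = 0, data_summary = c(n = 100, min = 0.1, max = 10)),
    class = "mixture_fit")
  ri <- reference_limits(fit, analyte = "TSH")
  expect_equal(round(ri$lower, 2), 0.40)
  expect_equal(round(ri$upper, 2), 4.09)
  expect_equal(format(ri), "0.40-4.09")
})

test_that("unconverged fits are refused with a diagnostic", {
  pf <- fit_pure_normal(n = 2000)
  fit <- pf$fit
  fit$converged <- FALSE
  expect_error(reference_limits(fit), "unconverged")
})

test_that("abnormal rate counts strict exceedances only", {
  ri <- reference_interval(0.09, 4.52)
  expect_equal(abnormal_rate(c(0.05, 1.0, 5.0), ri), 200 / 3)
  expect_equal(abnormal_rate(c(1, 2, 3), ri), 0)
  expect_equal(abnormal_rate(c(0.01, 5, 6), ri), 100)
  # values exactly at a limit are normal
  expect_equal(abnormal_rate(c(0.09, 4.52), ri), 0)
  # abnormal + inside = 100 exactly
  set.seed(22)
  x <- rgamma(500, 3, 2)
  expect_equal(abnormal_rate(x, ri) +
                 100 * mean(x >= ri$lower & x <= ri$upper), 100)
  expect_error(abnormal_rate(numeric(0), ri), "no values")
})

test_that("combined abnormal flag dominates the single-analyte flags", {
  set.seed(23)
  n <- 2000
  tsh <- rgamma(n, 3, 2)
  ft4 <- rnorm(n, 16, 2)
  gl <- guideline_intervals()
  fl <- abnormal_flags(tsh, ft4, gl$TSH$first, gl$FT4$first)
  expect_gte(mean(fl$any_abnormal), mean(fl$tsh_abnormal))
  expect_gte(mean(fl$any_abnormal), mean(fl$ft4_abnormal))
  expect_equal(fl$any_abnormal, fl$tsh_abnormal | fl$ft4_abnormal)
})

test_that("chi-square comparison matches the textbook formula", {
  # hand contingency: 10/90 abnormal under A, 20/80 under B
  x <- c(seq_len(10) * 0 + 2, rep(1, 80), rep(0.5, 10))
  ri_a <- reference_interval(0.4, 1.5)   # abnormal: the ten 2s
  ri_b <- reference_interval(0.7, 1.5)   # abnormal: 2s and 0.5s
  cr <- compare_abnormal_rates(x, ri_a, ri_b)
  # chi2 = n (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d)) by hand: 200/51
  expect_equal(cr$rate_a, 10)
  expect_equal(cr$rate_b, 20)
  expect_equal(cr$chi_square, 200 * (10 * 80 - 90 * 20)^2 /
                 (100 * 100 * 30 * 170), tolerance = 1e-12)
  expect_equal(cr$p_value,
               stats::pchisq(cr$chi_square, 1, lower.tail = FALSE))
})

test_that("identical intervals give chi-square 0 and p 1", {
  ri <- reference_interval(1, 2)
  cr <- compare_abnormal_rates(c(0.5, 1.5, 2.5), ri, ri)
  expect_equal(cr$chi_square, 0)
  expect_equal(cr$p_value, 1)
})

test_that("rate contrasts at the study's first-trimester scale are significant", {
  # abnormal counts yielding 5.75% vs 12.79% among 33 382 subjects
  n <- 33382L
  n_a <- round(0.0575 * n)          # abnormal under set A only (high side)
  n_extra <- round(0.1279 * n) - n_a  # additionally abnormal under set B
  x <- c(rep(2, n_a), rep(0.25, n_extra), rep(1, n - n_a - n_extra))
  ri_a <- reference_interval(0.1, 1.5)
  ri_b <- reference_interval(0.5, 1.5)
  cr <- compare_abnormal_rates(x, ri_a, ri_b)
  expect_equal(cr$rate_a, 5.75, tolerance = 0.01)
  expect_equal(cr$rate_b, 12.79, tolerance = 0.01)
  expect_lt(cr$p_value, 0.001)
})

test_that("the paired McNemar variant is available behind a flag", {
  set.seed(24)
  x <- rgamma(2000, 3, 2)
  cr <- compare_abnormal_rates(x, reference_interval(0.4, 4),
                               reference_interval(0.2, 5), paired = TRUE)
  expect_identical(cr$test, "mcnemar")
  expect_true(cr$p_value >= 0 && cr$p_value <= 1)
})

test_that("Kruskal-Wallis matches the hand rank formula and edge cases", {
  res <- kruskal_wallis(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  # H = 12/(N(N+1)) * sum R_i^2/n_i - 3(N+1) = 27/7
  expect_equal(res$H, 27 / 7, tolerance = 1e-9)
  expect_equal(res$df, 1)
  all_tied <- kruskal_wallis(rep(5, 9), rep(c("a", "b", "c"), 3))
  expect_equal(all_tied$H, 0)
  expect_equal(all_tied$p_value, 1)
  expect_error(kruskal_wallis(1:5, rep("a", 5)), "two")
})

test_that("an age-declining analyte is detected across bands", {
  set.seed(25)
  n_band <- 600
  bands <- c("20-25", "26-30", "31-35", "36-40", "41-45")
  means <- c(16.3, 16.1, 15.9, 15.5, 15.4)
  values <- unlist(lapply(seq_along(bands), function(i)
    rnorm(n_band, means[i], 2)))
  labels <- rep(bands, each = n_band)
  res <- kruskal_wallis(values, labels)
  expect_lt(res$p_value, 0.05)
})

test_that("guideline constants are the published six intervals", {
  gl <- guideline_intervals()
  expect_equal(c(gl$TSH$first$lower, gl$TSH$first$upper), c(0.09, 4.52))
  expect_equal(c(gl$TSH$second$lower, gl$TSH$second$upper), c(0.45, 4.32))
  expect_equal(c(gl$TSH$third$lower, gl$TSH$third$upper), c(0.30, 4.98))
  expect_equal(c(gl$FT4$first$lower, gl$FT4$first$upper), c(13.15, 20.78))
  expect_equal(c(gl$FT4$second$lower, gl$FT4$second$upper), c(9.77, 18.89))
  expect_equal(c(gl$FT4$third$lower, gl$FT4$third$upper), c(9.04, 15.22))
  expect_true(all(vapply(unlist(gl, recursive = FALSE),
                         function(ri) ri$source == "guidelines",
                         logical(1))))
})

test_that("estimated intervals carry display rounding by analyte", {
  ri_t <- reference_interval(0.39652, 4.0861, analyte = "TSH")
  ri_f <- reference_interval(12.238, 20.451, analyte = "FT4")
  expect_equal(format(ri_t), "0.40-4.09")
  expect_equal(format(ri_f), "12.2-20.5")
})
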