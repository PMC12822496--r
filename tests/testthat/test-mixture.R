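# ---- kernel density ----------------------------------------------------

test_that("density estimate integrates to one and finds the gamma mode", {
  set.seed(2)
  x <- rgamma(20000, shape = 2, rate = 1)
  d <- estimate_density(x)
  integral <- sum(diff(d$grid) * (head(d$density, -1) + tail(d$density, -1)) / 2)
  expect_equal(integral, 1, tolerance = 0.01)
  expect_true(all(d$density >= 0))
  # closed-form gamma mode (k - 1) / r = 1
  expect_equal(density_mode(d), 1, tolerance = 0.1)
})

test_that("density of a symmetric sample is symmetric about the center", {
  set.seed(3)
  x <- rnorm(20000)
  x <- c(x, -x)  # exactly symmetric
  d <- estimate_density(x)
  at <- seq(0.2, 2, by = 0.2)
  left <- approx(d$grid, d$density, -at)$y
  right <- approx(d$grid, d$density, at)$y
  expect_equal(left, right, tolerance = 0.02)
})

test_that("density estimation rejects tiny and degenerate samples", {
  expect_error(estimate_density(rnorm(10)), "insufficient")
  expect_error(estimate_density(rep(1, 100)), "bandwidth|constant")
})

# ---- weighted MLEs -----------------------------------------------------

test_that("weighted normal MLE matches hand arithmetic and subsetting", {
  expect_equal(weighted_normal_mle(c(1, 2, 3)),
               c(mean = 2, sd = sqrt(2 / 3)))
  # 0/1 weights equal the unweighted MLE on the selected subset
  set.seed(4)
  x <- rnorm(200, 5, 2)
  w <- as.numeric(seq_along(x) <= 120)
  expect_equal(weighted_normal_mle(x, w), weighted_normal_mle(x[1:120]))
  expect_error(weighted_normal_mle(x, rep(0, 200)), "zero")
  expect_error(weighted_normal_mle(x, c(1, rep(0, 199))), "degenerate")
})

test_that("weighted gamma MLE solves the score equation and is consistent", {
  set.seed(5)
  x <- rgamma(50000, shape = 2, rate = 1)
  est <- weighted_gamma_mle(x)
  expect_equal(unname(est["shape"]), 2, tolerance = 0.05)
  expect_equal(unname(est["rate"]), 1, tolerance = 0.05)
  # the score ln k - digamma(k) - (ln A - L) is solved to high precision
  A <- mean(x); L <- mean(log(x))
  expect_lt(abs(log(est["shape"]) - digamma(est["shape"]) - (log(A) - L)),
            1e-9)
  # rate is the shape over the weighted mean
  expect_equal(unname(est["rate"]), unname(est["shape"] / A),
               tolerance = 1e-12)
})

test_that("gamma MLE beats a brute-force grid on the log-likelihood", {
  set.seed(6)
  x <- rgamma(500, shape = 2, rate = 1)
  est <- weighted_gamma_mle(x)
  ll <- function(k, r) sum(dgamma(x, k, r, log = TRUE))
  grid <- expand.grid(k = seq(0.5, 5, length.out = 100),
                      r = seq(0.2, 3, length.out = 100))
  best_grid <- max(mapply(ll, grid$k, grid$r))
  expect_gte(ll(est["shape"], est["rate"]), best_grid)
})

test_that("gamma MLE honours weights and guards degenerate input", {
  set.seed(7)
  x <- rgamma(300, 3, 2)
  w <- as.numeric(seq_along(x) %% 2 == 0)
  expect_equal(weighted_gamma_mle(x, w), weighted_gamma_mle(x[w == 1]))
  expect_error(weighted_gamma_mle(c(-1, 1, 2)), "positive")
  expect_warning(est <- weighted_gamma_mle(rep(2, 50)), "capped")
  expect_equal(unname(est["shape"]), 1e6)
})

# ---- initialization ----------------------------------------------------

test_that("initialization centres the healthy component at the mode", {
  set.seed(8)
  x <- rnorm(5000, 10, 1.5)
  d <- estimate_density(x)
  init <- initialize_fit(d, x, specs = component_specs("normal", "healthy"))
  hc <- healthy_component(init)
  expect_equal(unname(hc$params[1]), 10, tolerance = 0.2)
  expect_equal(hc$weight, 1)  # single component takes all the weight
})

test_that("with bimodal data the healthy centre sits on the dominant mode", {
  set.seed(9)
  x <- c(rnorm(8000, 10, 1), rnorm(2000, 2, 1))
  d <- estimate_density(x)
  init <- initialize_fit(d, x, healthy_fraction_init = 0.8,
                         specs = component_specs("normal",
                                                 c("healthy", "patho_low")))
  hc <- healthy_component(init)
  # direct grid argmax as the oracle
  expect_equal(unname(hc$params[1]), d$grid[which.max(d$density)])
  expect_gt(unname(hc$params[1]), 9)
  expect_equal(hc$weight, 0.8)
  lowc <- init$components[[2]]
  expect_lt(lowc$params[1], hc$params[1])
})

# ---- EM ----------------------------------------------------------------

test_that("a single normal component reduces to the closed-form MLE", {
  set.seed(10)
  x <- rnorm(2000, 7, 3)
  d <- estimate_density(x)
  fit <- fit_mixture_em(x, initialize_fit(d, x,
                                          specs = component_specs("normal",
                                                                  "healthy")))
  hc <- healthy_component(fit)
  expect_true(fit$converged)
  expect_equal(unname(hc$params), c(mean(x), sd(x) * sqrt(1999 / 2000)),
               tolerance = 1e-6)
})

test_that("EM recovers two well-separated normal components", {
  set.seed(11)
  n <- 20000
  lab <- runif(n) < 0.7
  x <- ifelse(lab, rnorm(n, 0, 1), rnorm(n, 10, 1))
  d <- estimate_density(x)
  init <- initialize_fit(d, x, healthy_fraction_init = 0.6,
                         specs = component_specs("normal",
                                                 c("healthy", "patho_high")))
  fit <- fit_mixture_em(x, init)
  hc <- healthy_component(fit)
  expect_true(fit$converged)
  expect_equal(hc$weight, 0.7, tolerance = 0.02)
  expect_equal(unname(hc$params[1]), 0, tolerance = 0.05)
  other <- fit$components[[which(vapply(fit$components, function(co)
    co$role, character(1)) != "healthy")]]
  expect_equal(unname(other$params[1]), 10, tolerance = 0.05)
})

test_that("the EM log-likelihood trace is non-decreasing", {
  for (seed in 1:3) {
    set.seed(seed)
    x <- c(rgamma(3000, 4, 2), rgamma(200, 4, 2) * 5)
    d <- estimate_density(x)
    fit <- fit_mixture_em(x, initialize_fit(d, x,
                                            specs = component_specs("gamma")))
    expect_true(all(diff(fit$ll_trace) >= -1e-9 * abs(fit$ll_trace[-1])))
  }
})

test_that("component weights sum to one after fitting", {
  set.seed(12)
  x <- rgamma(3000, 3, 2)
  fit <- fit_analyte(x, "gamma")
  w <- sum(vapply(fit$components, function(co) co$weight, numeric(1)))
  expect_equal(w, 1, tolerance = 1e-10)
})

test_that("fitted parameters are scale-equivariant", {
  set.seed(13)
  x <- make_contaminated_tsh(8000, seed = 13)$values
  c_ <- 10
  fit1 <- fit_analyte(x, "gamma")
  fit2 <- fit_analyte(x * c_, "gamma")
  h1 <- healthy_component(fit1); h2 <- healthy_component(fit2)
  expect_equal(unname(h2$params["shape"]), unname(h1$params["shape"]),
               tolerance = 0.02)
  expect_equal(unname(1 / h2$params["rate"]),
               unname(c_ / h1$params["rate"]), tolerance = 0.02)
  expect_equal(h2$weight, h1$weight, tolerance = 0.02)
  expect_equal(fit2$ks_main_part, fit1$ks_main_part, tolerance = 0.005)
})

# ---- KS main part and model selection ---------------------------------

test_that("the KS main-part distance is a distance and shrinks with n", {
  set.seed(14)
  g <- first_tsh_gamma()
  small <- rgamma(500, g["shape"], g["rate"])
  large <- rgamma(50000, g["shape"], g["rate"])
  fit_s <- suppressWarnings(fit_analyte(small, "gamma"))
  fit_l <- fit_analyte(large, "gamma")
  for (f in list(fit_s, fit_l)) {
    expect_gte(f$ks_main_part, 0)
    expect_lte(f$ks_main_part, 1)
  }
  expect_lt(fit_l$ks_main_part, fit_s$ks_main_part)
})

test_that("a mis-specified family fits the main part worse", {
  set.seed(15)
  x <- rgamma(20000, shape = 1.5, rate = 2)  # strongly skewed
  d <- estimate_density(x)
  fit_gamma <- fit_mixture_em(x, initialize_fit(d, x,
    specs = component_specs("gamma", "healthy")))
  fit_norm <- fit_mixture_em(x, initialize_fit(d, x,
    specs = component_specs("normal", "healthy")))
  expect_lt(fit_gamma$ks_main_part, fit_norm$ks_main_part)
})

test_that("a single candidate is returned unchanged by selection", {
  set.seed(16)
  x <- rgamma(2000, 3, 2)
  d <- estimate_density(x)
  direct <- fit_mixture_em(x, initialize_fit(d, x,
    specs = component_specs("gamma", "healthy")))
  sel <- select_model(x, list(component_specs("gamma", "healthy")),
                      density = d)
  expect_equal(sel$components, direct$components, tolerance = 1e-12)
})

test_that("family selection follows the generating distribution", {
  set.seed(17)
  g <- first_tsh_gamma()
  x_skew <- rgamma(20000, g["shape"], g["rate"])
  p <- first_ft4_normal()
  x_sym <- rnorm(20000, p["mean"], p["sd"])
  both <- c(lapply(c("gamma", "normal"), function(fam)
    component_specs(fam, "healthy")))
  fit_skew <- select_model(x_skew, both)
  fit_sym <- select_model(x_sym, both)
  expect_equal(healthy_component(fit_skew)$family, "gamma")
  expect_equal(healthy_component(fit_sym)$family, "normal")
})

test_that("gamma components refuse non-positive data", {
  set.seed(18)
  x <- c(rnorm(100, 5, 1), -1)
  d <- estimate_density(x)
  expect_error(fit_mixture_em(x, initialize_fit(d, x,
    specs = component_specs("gamma"))), "positive")
})
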