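# Shared fixtures: the calibrated first-trimester healthy laws and small
# contaminated samples with known truth.

first_tsh_gamma <- function() {
  default_truth_params()$strata[[1]]$tsh_healthy
}

first_ft4_normal <- function() {
  default_truth_params()$strata[[1]]$ft4_healthy
}

# mixed TSH-like sample: healthy gamma plus multiplicative hypo/hyper
# displacement, mirroring the generator's contamination model
make_contaminated_tsh <- function(n, seed, hypo = 0.05, hyper = 0.05,
                                  shift = 4, scale = 0.05) {
  g <- first_tsh_gamma()
  set.seed(seed)
  lab <- sample(c("healthy", "hypo", "hyper"), n, replace = TRUE,
                prob = c(1 - hypo - hyper, hypo, hyper))
  x <- stats::rgamma(n, g["shape"], g["rate"])
  x[lab == "hypo"] <- x[lab == "hypo"] * shift
  x[lab == "hyper"] <- x[lab == "hyper"] * scale
  list(values = x, labels = lab, gamma = g)
}

make_contaminated_ft4 <- function(n, seed, hypo = 0.05, hyper = 0.05,
                                  delta = 3) {
  p <- first_ft4_normal()
  set.seed(seed)
  lab <- sample(c("healthy", "hypo", "hyper"), n, replace = TRUE,
                prob = c(1 - hypo - hyper, hypo, hyper))
  x <- stats::rnorm(n, p["mean"], p["sd"])
  x[lab == "hypo"] <- x[lab == "hypo"] - delta
  x[lab == "hyper"] <- x[lab == "hyper"] + delta
  list(values = x, labels = lab, normal = p)
}

# numerically integrated gamma CDF, independent of pgamma/qgamma
gamma_cdf_oracle <- function(q, shape, rate) {
  stats::integrate(function(t) stats::dgamma(t, shape, rate),
                   lower = 0, upper = q, rel.tol = 1e-10)$value
}
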