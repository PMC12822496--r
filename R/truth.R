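#' Calibrate gamma parameters to two tail quantiles
#'
#' Finds the (shape, rate) pair of a gamma distribution whose 2.5th and
#' 97.5th percentiles (or any other pair of probabilities) equal the given
#' limits.  The ratio of two gamma quantiles depends on the shape alone and
#' is strictly monotone in it, so the fit reduces to a one-dimensional root
#' find on the log quantile ratio followed by a closed-form rate.
#'
#' @param lower,upper target quantile values, `0 < lower < upper`.
#' @param probs probabilities the targets correspond to (default
#'   `c(0.025, 0.975)`).
#' @return named numeric vector `c(shape, rate)`.
#' @examples
#' p <- calibrate_gamma_quantiles(0.40, 4.09)
#' stats::qgamma(c(0.025, 0.975), p["shape"], p["rate"])
#' @export
calibrate_gamma_quantiles <- function(lower, upper, probs = c(0.025, 0.975)) {
  stopifnot(is.finite(lower), is.finite(upper), lower > 0, upper > lower,
            length(probs) == 2L, probs[1] < probs[2])
  target <- log(upper / lower)
  ratio <- function(log_shape) {
    k <- exp(log_shape)
    log(stats::qgamma(probs[2], k, 1)) - log(stats::qgamma(probs[1], k, 1)) - target
  }
  # quantile ratio decreases from +Inf (k -> 0) towards 1 (k -> Inf)
  root <- stats::uniroot(ratio, lower = log(1e-3), upper = log(1e6),
                         tol = 1e-12)
  shape <- exp(root$root)
  rate <- stats::qgamma(probs[1], shape, 1) / lower
  c(shape = shape, rate = rate)
}

#' Calibrate normal parameters to two tail quantiles
#'
#' Closed-form mean and standard deviation of the normal distribution whose
#' tail quantiles at `probs` equal the given limits.
#'
#' @inheritParams calibrate_gamma_quantiles
#' @return named numeric vector `c(mean, sd)`.
#' @examples
#' calibrate_normal_quantiles(12.2, 20.5)  # mean 16.35, sd 2.117
#' @export
calibrate_normal_quantiles <- function(lower, upper, probs = c(0.025, 0.975)) {
  stopifnot(is.finite(lower), is.finite(upper), upper > lower,
            length(probs) == 2L, probs[1] < probs[2])
  z <- stats::qnorm(probs)
  sd <- (upper - lower) / (z[2] - z[1])
  mean <- lower - z[1] * sd
  c(mean = mean, sd = sd)
}

#' Ground-truth parameters for one trimester stratum
#'
#' @param trimester `"first"`, `"second"` or `"third"`.
#' @param tsh_healthy numeric `c(shape, rate)` of the healthy TSH gamma law.
#' @param ft4_healthy numeric `c(mean, sd)` of the healthy FT4 normal law
#'   (pmol/L), evaluated at the reference age of 28 years.
#' @param hypo_fraction,hyper_fraction,tpoab_pos_fraction contaminating
#'   subpopulation proportions in `[0, 1)`; hypo + hyper must stay below 1.
#' @param age_slope_ft4 change in healthy FT4 mean per year of maternal age
#'   (pmol/L per year, non-positive).
#' @param hypo_tsh_shift multiplicative TSH displacement of the hypothyroid
#'   subpopulation (> 1).
#' @param hyper_tsh_scale multiplicative TSH displacement of the
#'   hyperthyroid subpopulation (in (0, 1)).
#' @return object of class `stratum_truth`.
#' @export
stratum_truth <- function(trimester,
                          tsh_healthy,
                          ft4_healthy,
                          hypo_fraction = 0.02,
                          hyper_fraction = 0.02,
                          tpoab_pos_fraction = 0.05,
                          age_slope_ft4 = -0.05,
                          hypo_tsh_shift = 4,
                          hyper_tsh_scale = 0.05) {
  trimester <- match.arg(trimester, c("first", "second", "third"))
  stopifnot(all(tsh_healthy > 0), ft4_healthy[2] > 0,
            hypo_fraction >= 0, hyper_fraction >= 0, tpoab_pos_fraction >= 0,
            hypo_fraction + hyper_fraction < 1,
            age_slope_ft4 <= 0, hypo_tsh_shift > 1,
            hyper_tsh_scale > 0, hyper_tsh_scale < 1)
  structure(list(trimester = trimester,
                 tsh_healthy = c(shape = unname(tsh_healthy[1]),
                                 rate = unname(tsh_healthy[2])),
                 ft4_healthy = c(mean = unname(ft4_healthy[1]),
                                 sd = unname(ft4_healthy[2])),
                 hypo_fraction = hypo_fraction,
                 hyper_fraction = hyper_fraction,
                 tpoab_pos_fraction = tpoab_pos_fraction,
                 age_slope_ft4 = age_slope_ft4,
                 hypo_tsh_shift = hypo_tsh_shift,
                 hyper_tsh_scale = hyper_tsh_scale),
            class = "stratum_truth")
}

#' Full generating model for a synthetic cohort
#'
#' Bundles the per-trimester healthy/pathologic laws with sample sizes, the
#' random seed and the rates at which cleaning-trigger ("dirty") records are
#' planted.  A fixed `synthetic_truth` regenerates a byte-identical cohort.
#'
#' @param strata list of three [stratum_truth()] objects (first, second,
#'   third trimester).
#' @param n_per_trimester integer vector of healthy+pathologic record counts
#'   per trimester.
#' @param seed integer seed governing the whole cohort.
#' @param dirty_record_rates named proportions of `n_per_trimester` at which
#'   each cleaning trigger is planted: `missing_value`, `male_sex`,
#'   `age_out_of_range`, `duplicate_patient`, `out_of_amr`,
#'   `tpoab_over_cutoff`.  Each planted record violates exactly one
#'   criterion so the exclusion funnel reconciles record-for-record.
#' @return object of class `synthetic_truth`.
#' @seealso [default_truth_params()], [generate_cohort()]
#' @export
synthetic_truth <- function(strata, n_per_trimester, seed = 1L,
                            dirty_record_rates = c(missing_value = 0.01,
                                                   male_sex = 0.005,
                                                   age_out_of_range = 0.01,
                                                   duplicate_patient = 0.01,
                                                   out_of_amr = 0.002,
                                                   tpoab_over_cutoff = 0.01)) {
  stopifnot(is.list(strata), length(strata) == 3L,
            all(vapply(strata, inherits, logical(1), "stratum_truth")),
            length(n_per_trimester) == 3L, all(n_per_trimester >= 0),
            length(seed) == 1L, is.finite(seed))
  rates <- c(missing_value = 0, male_sex = 0, age_out_of_range = 0,
             duplicate_patient = 0, out_of_amr = 0, tpoab_over_cutoff = 0)
  if (length(dirty_record_rates)) {
    stopifnot(!is.null(names(dirty_record_rates)),
              all(names(dirty_record_rates) %in% names(rates)),
              all(dirty_record_rates >= 0), all(dirty_record_rates < 1))
    rates[names(dirty_record_rates)] <- dirty_record_rates
  }
  structure(list(strata = strata,
                 n_per_trimester = as.integer(n_per_trimester),
                 seed = as.integer(seed),
                 dirty_record_rates = rates),
            class = "synthetic_truth")
}

# Printed trimester-specific healthy limits the default truth is calibrated
# to: TSH (mIU/L) and FT4 (pmol/L) 2.5/97.5 percentiles, first to third
# trimester.
.default_limits <- list(
  tsh = list(first = c(0.40, 4.09), second = c(0.57, 4.04),
             third = c(0.73, 4.07)),
  ft4 = list(first = c(12.2, 20.5), second = c(10.2, 18.2),
             third = c(9.0, 15.5))
)

#' Default ground-truth parameters
#'
#' Healthy-component parameters are calibrated deterministically so that the
#' healthy TSH gamma law and FT4 normal law reproduce the trimester-specific
#' 2.5/97.5 percentile limits of the reference population (TSH 0.40--4.09,
#' 0.57--4.04, 0.73--4.07 mIU/L; FT4 12.2--20.5, 10.2--18.2, 9.0--15.5
#' pmol/L, first to third trimester).  With two free parameters per family
#' the calibration targets the two tail limits; the implied median is then
#' whatever the law gives (for first-trimester TSH about 1.6 mIU/L, close to
#' but not exactly the observed 1.59).
#'
#' Sample sizes default to a scaled-down cohort (6000/4000/2000); pass
#' `n_per_trimester` to emulate the full population sizes.
#'
#' @param n_per_trimester records per trimester before dirty records.
#' @param seed integer seed stored in the truth object.
#' @param hypo_fraction,hyper_fraction,tpoab_pos_fraction contamination
#'   proportions applied to every stratum.
#' @param dirty_record_rates passed to [synthetic_truth()]; use `NULL` to
#'   keep the defaults or a named vector of zeros for a trigger-free cohort.
#' @return a [synthetic_truth()] object.
#' @examples
#' tr <- default_truth_params()
#' tr$strata[[1]]$tsh_healthy
#' @export
default_truth_params <- function(n_per_trimester = c(6000L, 4000L, 2000L),
                                 seed = 20140701L,
                                 hypo_fraction = 0.02,
                                 hyper_fraction = 0.02,
                                 tpoab_pos_fraction = 0.05,
                                 dirty_record_rates = NULL) {
  trimesters <- c("first", "second", "third")
  strata <- lapply(trimesters, function(tri) {
    stratum_truth(
      trimester = tri,
      tsh_healthy = calibrate_gamma_quantiles(.default_limits$tsh[[tri]][1],
                                              .default_limits$tsh[[tri]][2]),
      ft4_healthy = calibrate_normal_quantiles(.default_limits$ft4[[tri]][1],
                                               .default_limits$ft4[[tri]][2]),
      hypo_fraction = hypo_fraction,
      hyper_fraction = hyper_fraction,
      tpoab_pos_fraction = tpoab_pos_fraction
    )
  })
  if (is.null(dirty_record_rates))
    synthetic_truth(strata, n_per_trimester, seed = seed)
  else
    synthetic_truth(strata, n_per_trimester, seed = seed,
                    dirty_record_rates = dirty_record_rates)
}

#' @export
print.stratum_truth <- function(x, ...) {
  cat(sprintf("Stratum truth (%s trimester)\n", x$trimester))
  cat(sprintf("  TSH healthy  gamma(shape = %.4f, rate = %.4f)\n",
              x$tsh_healthy["shape"], x$tsh_healthy["rate"]))
  cat(sprintf("  FT4 healthy  normal(mean = %.3f, sd = %.3f) pmol/L\n",
              x$ft4_healthy["mean"], x$ft4_healthy["sd"]))
  cat(sprintf("  contamination: hypo %.1f%%, hyper %.1f%%, TPO-Ab+ %.1f%%\n",
              100 * x$hypo_fraction, 100 * x$hyper_fraction,
              100 * x$tpoab_pos_fraction))
  invisible(x)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("Synthetic cohort truth\n")
  cat(sprintf("  n per trimester: %s (seed %d)\n",
              paste(x$n_per_trimester, collapse = "/"), x$seed))
  for (s in x$strata) print(s)
  dirty <- x$dirty_record_rates[x$dirty_record_rates > 0]
  if (length(dirty))
    cat("  dirty-record rates:",
        paste(sprintf("%s %.2f%%", names(dirty), 100 * dirty),
              collapse = ", "), "\n")
  invisible(x)
}
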