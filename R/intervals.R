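#' Reference limits from a fitted mixture
#'
#' The lower and upper reference limits are the parametric inverse-CDF
#' quantiles of the HEALTHY component alone at `(1 - coverage)/2` and
#' `1 - (1 - coverage)/2` — percentiles of the estimated non-pathologic
#' distribution, not empirical percentiles of the data.  Full precision is
#' retained internally; display rounding (TSH 2 decimals, FT4 1 decimal)
#' is applied by `format()`/`print()` only.
#'
#' @param fit a converged `mixture_fit`.
#' @param coverage central coverage proportion (default 0.95, giving the
#'   2.5 and 97.5 percentiles).
#' @param analyte optional `"TSH"` or `"FT4"` (controls display rounding).
#' @param trimester,age_band optional stratum labels carried as metadata.
#' @param source `"fitted"` or `"guidelines"`.
#' @return object of class `reference_interval` with fields `lower`,
#'   `upper`, `coverage`, `analyte`, `trimester`, `age_band`, `source`.
#' @examples
#' set.seed(1)
#' fit <- fit_analyte(rnorm(5000, 16, 2), "normal")
#' reference_limits(fit, analyte = "FT4")
#' @export
reference_limits <- function(fit, coverage = 0.95, analyte = NA_character_,
                             trimester = NA_character_,
                             age_band = NA_character_, source = "fitted") {
  stopifnot(inherits(fit, "mixture_fit"), coverage > 0, coverage < 1)
  if (!isTRUE(fit$converged))
    stop("refusing to derive limits from an unconverged fit (",
         fit$n_iterations, " iterations, logLik ",
         format(fit$log_likelihood), ")")
  hc <- healthy_component(fit)
  alpha <- (1 - coverage) / 2
  lims <- .comp_quantile(hc, c(alpha, 1 - alpha))
  reference_interval(lower = lims[1], upper = lims[2], coverage = coverage,
                     analyte = analyte, trimester = trimester,
                     age_band = age_band, source = source)
}

#' Construct a reference interval
#'
#' @param lower,upper interval limits in analyte units, `lower < upper`.
#' @param coverage central coverage in (0, 1).
#' @param analyte,trimester,age_band,source metadata (see
#'   [reference_limits()]).
#' @return object of class `reference_interval`.
#' @export
reference_interval <- function(lower, upper, coverage = 0.95,
                               analyte = NA_character_,
                               trimester = NA_character_,
                               age_band = NA_character_,
                               source = "fitted") {
  stopifnot(lower < upper, coverage > 0, coverage < 1)
  structure(list(lower = unname(lower), upper = unname(upper),
                 coverage = coverage, analyte = analyte,
                 trimester = trimester, age_band = age_band,
                 source = source),
            class = "reference_interval")
}

.ri_decimals <- function(analyte) {
  if (identical(analyte, "TSH")) 2L else if (identical(analyte, "FT4")) 1L
  else 3L
}

#' @export
format.reference_interval <- function(x, ...) {
  d <- .ri_decimals(x$analyte)
  sprintf("%.*f-%.*f", d, round(x$lower, d), d, round(x$upper, d))
}

#' @export
print.reference_interval <- function(x, ...) {
  lab <- paste(stats::na.omit(c(x$analyte, x$trimester, x$age_band)),
               collapse = ", ")
  cat(sprintf("Reference interval%s: %s (%.0f%% coverage, %s)\n",
              if (nzchar(lab)) paste0(" [", lab, "]") else "",
              format(x), 100 * x$coverage, x$source))
  invisible(x)
}

#' Guideline trimester-specific reference intervals (Roche assays)
#'
#' The six built-in constants used as the comparison standard: TSH
#' 0.09--4.52, 0.45--4.32 and 0.30--4.98 mIU/L, and FT4 13.15--20.78,
#' 9.77--18.89 and 9.04--15.22 pmol/L for the first, second and third
#' trimester, taken from the American Thyroid Association pregnancy
#' guidelines (2nd edition) for laboratories on the Roche system.
#'
#' @return named list `guideline$TSH$first` etc. of
#'   [reference_interval()] objects with `source = "guidelines"`.
#' @export
guideline_intervals <- function() {
  tbl <- list(
    TSH = list(first = c(0.09, 4.52), second = c(0.45, 4.32),
               third = c(0.30, 4.98)),
    FT4 = list(first = c(13.15, 20.78), second = c(9.77, 18.89),
               third = c(9.04, 15.22)))
  out <- lapply(names(tbl), function(an)
    lapply(stats::setNames(names(tbl[[an]]), names(tbl[[an]])), function(tri)
      reference_interval(tbl[[an]][[tri]][1], tbl[[an]][[tri]][2],
                         analyte = an, trimester = tri,
                         source = "guidelines")))
  stats::setNames(out, names(tbl))
}

#' Abnormal rate under a reference interval
#'
#' Percent of values falling strictly outside the interval; a value exactly
#' at a limit counts as normal.
#'
#' @param values numeric vector (non-empty; `NA`s dropped).
#' @param ri a [reference_interval()].
#' @return percent in `[0, 100]`.
#' @examples
#' ri <- reference_interval(0.09, 4.52)
#' abnormal_rate(c(0.05, 1.0, 5.0), ri)  # 66.67
#' @export
abnormal_rate <- function(values, ri) {
  stopifnot(inherits(ri, "reference_interval"))
  values <- values[!is.na(values)]
  if (!length(values)) stop("no values to classify")
  100 * mean(values < ri$lower | values > ri$upper)
}

#' Per-subject abnormal flags, single analytes and combined
#'
#' Flags each subject abnormal under an interval pair; the combined flag is
#' TRUE when either analyte is out of its interval.  A missing analyte
#' value contributes no abnormality (treated as normal in the combined
#' flag).
#'
#' @param tsh,ft4 per-subject values (equal length).
#' @param ri_tsh,ri_ft4 [reference_interval()] objects.
#' @return data.frame with logical columns `tsh_abnormal`, `ft4_abnormal`,
#'   `any_abnormal`.
#' @export
abnormal_flags <- function(tsh, ft4, ri_tsh, ri_ft4) {
  stopifnot(length(tsh) == length(ft4))
  ab_t <- !is.na(tsh) & (tsh < ri_tsh$lower | tsh > ri_tsh$upper)
  ab_f <- !is.na(ft4) & (ft4 < ri_ft4$lower | ft4 > ri_ft4$upper)
  data.frame(tsh_abnormal = ab_t, ft4_abnormal = ab_f,
             any_abnormal = ab_t | ab_f)
}

#' Compare abnormal rates under two reference intervals
#'
#' Classifies the same value vector under interval sets A and B and tests
#' the difference in abnormal rates with a 2x2 chi-square test (1 df, no
#' continuity correction).  When any expected cell is below 1 the
#' chi-square is unreliable and a Fisher exact p-value is reported instead,
#' flagged in the result.  Because both classifications are of the same
#' subjects, a paired McNemar variant is available via `paired = TRUE`
#' (not the default).
#'
#' @param values the sample (or a logical pair via `flags_a`/`flags_b`).
#' @param ri_a,ri_b the two [reference_interval()] objects.
#' @param paired use McNemar's paired test instead of the two-sample
#'   chi-square.
#' @return object of class `comparison_row`: rates (%), `chi_square`,
#'   `p_value`, `test` used.
#' @examples
#' set.seed(1)
#' x <- rgamma(1000, 3, 2)
#' compare_abnormal_rates(x, reference_interval(0.4, 4.1),
#'                        reference_interval(0.09, 4.52))
#' @export
compare_abnormal_rates <- function(values, ri_a, ri_b, paired = FALSE) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (!n) stop("no values to classify")
  ab_a <- values < ri_a$lower | values > ri_a$upper
  ab_b <- values < ri_b$lower | values > ri_b$upper
  if (paired) {
    b <- sum(ab_a & !ab_b); c_ <- sum(!ab_a & ab_b)
    stat <- if (b + c_ > 0) (b - c_)^2 / (b + c_) else 0
    p <- if (b + c_ > 0) stats::pchisq(stat, df = 1, lower.tail = FALSE)
         else 1
    test <- "mcnemar"
  } else {
    tab <- rbind(A = c(abnormal = sum(ab_a), normal = n - sum(ab_a)),
                 B = c(abnormal = sum(ab_b), normal = n - sum(ab_b)))
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (identical(sum(ab_a), sum(ab_b))) {
      stat <- 0; p <- 1; test <- "chi_square"
    } else if (any(expected < 1)) {
      stat <- NA_real_
      p <- stats::fisher.test(tab)$p.value
      test <- "fisher_exact"
    } else {
      ct <- stats::chisq.test(tab, correct = FALSE)
      stat <- unname(ct$statistic); p <- ct$p.value; test <- "chi_square"
    }
  }
  structure(list(rate_a = 100 * mean(ab_a), rate_b = 100 * mean(ab_b),
                 chi_square = stat, p_value = p, n = n, test = test),
            class = "comparison_row")
}

#' @export
print.comparison_row <- function(x, ...) {
  cat(sprintf(
    "Abnormal rates: %.2f%% vs %.2f%% (n = %d); %s = %s, p = %s\n",
    x$rate_a, x$rate_b, x$n, x$test,
    if (is.na(x$chi_square)) "-" else sprintf("%.3f", x$chi_square),
    format.pval(x$p_value, digits = 3)))
  invisible(x)
}

#' Kruskal-Wallis rank test across groups
#'
#' Tie-corrected Kruskal-Wallis H with a chi-square reference distribution
#' on (groups - 1) degrees of freedom, used to compare analyte levels
#' across the five maternal age bands.
#'
#' @param values numeric vector.
#' @param group_labels group membership, same length; at least two
#'   non-empty groups.
#' @return list with `H`, `p_value`, `df`.
#' @examples
#' kruskal_wallis(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
#' @export
kruskal_wallis <- function(values, group_labels) {
  g <- factor(group_labels)
  keep <- !is.na(values) & !is.na(g)
  g <- droplevels(g[keep])
  if (nlevels(g) < 2L) stop("need at least two non-empty groups")
  if (length(unique(values[keep])) == 1L)  # fully tied: H is 0 by convention
    return(list(H = 0, p_value = 1, df = nlevels(g) - 1L))
  kt <- stats::kruskal.test(values[keep], g)
  list(H = unname(kt$statistic), p_value = kt$p.value,
       df = unname(kt$parameter))
}
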