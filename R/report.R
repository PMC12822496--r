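#' Assemble the full study-style report
#'
#' Combines the stratified cohort, the per-(analyte, trimester) mixture
#' fits and the guideline constants into the standard result set: (a) a
#' population-distribution table of counts and percentages by age band and
#' trimester, (b) per-age-band medians with fitted limits and a
#' Kruskal-Wallis p-value per analyte and trimester, (c) an abnormal-rate
#' comparison of fitted versus guideline intervals (single analytes and
#' the combined either-abnormal subject flag), and (d) a side-by-side
#' interval listing for display.  Missing strata yield explicit gaps, not
#' errors.
#'
#' @param fits nested list `fits$TSH$first` ... of `mixture_fit` objects
#'   (may have `NULL` gaps).
#' @param cohort a [stratify_cohort()] result.
#' @param guideline guideline interval set (default
#'   [guideline_intervals()]).
#' @param coverage coverage for fitted limits (default 0.95).
#' @return object of class `ri_report` with data-frame elements
#'   `population`, `age_bands`, `abnormal_rates`, `intervals`.
#' @export
build_report <- function(fits, cohort, guideline = guideline_intervals(),
                         coverage = 0.95) {
  stopifnot(inherits(cohort, "stratified_cohort"))
  rec <- cohort$records
  trimesters <- c("first", "second", "third")
  analytes <- c(TSH = "tsh", FT4 = "ft4")

  # (a) population distribution
  tab <- table(rec$age_band, rec$trimester)
  pop <- data.frame(age_band = rownames(tab),
                    total = as.integer(rowSums(tab)),
                    total_pct = round(100 * rowSums(tab) / nrow(rec)))
  for (tri in trimesters) {
    cnt <- tab[, tri]
    tot <- sum(cnt)
    pop[[tri]] <- as.integer(cnt)
    pop[[paste0(tri, "_pct")]] <-
      if (tot > 0) round(100 * cnt / tot) else NA_integer_
  }
  rownames(pop) <- NULL

  # fitted intervals per analyte x trimester
  ri_fit <- list()
  gaps <- character(0)
  for (an in names(analytes)) {
    ri_fit[[an]] <- list()
    for (tri in trimesters) {
      f <- fits[[an]][[tri]]
      if (is.null(f)) {
        gaps <- c(gaps, paste(an, tri))
        ri_fit[[an]][[tri]] <- NULL
      } else {
        ri_fit[[an]][[tri]] <- reference_limits(f, coverage = coverage,
                                                analyte = an,
                                                trimester = tri)
      }
    }
  }

  # (b) age-band medians + fitted limits + Kruskal-Wallis
  ab_rows <- list()
  for (an in names(analytes)) {
    col <- analytes[[an]]
    for (tri in trimesters) {
      sel <- rec$trimester == tri
      if (!any(sel)) next
      kw <- tryCatch(kruskal_wallis(rec[[col]][sel], rec$age_band[sel]),
                     error = function(e) list(H = NA_real_,
                                              p_value = NA_real_))
      for (band in levels(rec$age_band)) {
        v <- rec[[col]][sel & rec$age_band == band]
        ab_rows[[length(ab_rows) + 1L]] <- data.frame(
          analyte = an, trimester = tri, age_band = band,
          n = length(v),
          median = if (length(v)) stats::median(v) else NA_real_,
          kw_p = kw$p_value)
      }
      ri <- ri_fit[[an]][[tri]]
      ab_rows[[length(ab_rows) + 1L]] <- data.frame(
        analyte = an, trimester = tri, age_band = "all",
        n = sum(sel), median = stats::median(rec[[col]][sel]),
        kw_p = kw$p_value)
    }
  }
  age_bands <- do.call(rbind, ab_rows)

  # (c) abnormal rates: guideline vs fitted, per analyte + combined
  cmp_rows <- list()
  for (tri in trimesters) {
    sel <- rec$trimester == tri
    if (!any(sel)) next
    ri_t <- ri_fit$TSH[[tri]]; ri_f <- ri_fit$FT4[[tri]]
    if (is.null(ri_t) || is.null(ri_f)) next
    g_t <- guideline$TSH[[tri]]; g_f <- guideline$FT4[[tri]]
    for (an in names(analytes)) {
      cr <- compare_abnormal_rates(rec[[analytes[[an]]]][sel],
                                   if (an == "TSH") g_t else g_f,
                                   if (an == "TSH") ri_t else ri_f)
      cmp_rows[[length(cmp_rows) + 1L]] <- data.frame(
        trimester = tri, measure = an,
        rate_guidelines = cr$rate_a, rate_fitted = cr$rate_b,
        chi_square = cr$chi_square, p_value = cr$p_value)
    }
    fl_g <- abnormal_flags(rec$tsh[sel], rec$ft4[sel], g_t, g_f)
    fl_r <- abnormal_flags(rec$tsh[sel], rec$ft4[sel], ri_t, ri_f)
    n <- sum(sel)
    tab2 <- rbind(c(sum(fl_g$any_abnormal), n - sum(fl_g$any_abnormal)),
                  c(sum(fl_r$any_abnormal), n - sum(fl_r$any_abnormal)))
    ct <- if (sum(fl_g$any_abnormal) == sum(fl_r$any_abnormal))
      list(statistic = 0, p.value = 1)
    else stats::chisq.test(tab2, correct = FALSE)
    cmp_rows[[length(cmp_rows) + 1L]] <- data.frame(
      trimester = tri, measure = "TSH and/or FT4",
      rate_guidelines = 100 * mean(fl_g$any_abnormal),
      rate_fitted = 100 * mean(fl_r$any_abnormal),
      chi_square = unname(ct$statistic), p_value = ct$p.value)
  }
  abnormal_rates <- if (length(cmp_rows)) do.call(rbind, cmp_rows) else
    data.frame()

  # (d) interval side-by-side listing
  int_rows <- list()
  for (an in names(analytes)) {
    for (tri in trimesters) {
      ri <- ri_fit[[an]][[tri]]
      g <- guideline[[an]][[tri]]
      int_rows[[length(int_rows) + 1L]] <- data.frame(
        analyte = an, trimester = tri,
        fitted_lower = if (is.null(ri)) NA_real_ else ri$lower,
        fitted_upper = if (is.null(ri)) NA_real_ else ri$upper,
        guideline_lower = g$lower, guideline_upper = g$upper)
    }
  }
  intervals <- do.call(rbind, int_rows)

  structure(list(population = pop, age_bands = age_bands,
                 abnormal_rates = abnormal_rates, intervals = intervals,
                 gaps = gaps, coverage = coverage),
            class = "ri_report")
}

#' @export
print.ri_report <- function(x, ...) {
  cat("== Population distribution ==\n")
  print(x$population, row.names = FALSE)
  cat("\n== Reference intervals (fitted vs guidelines) ==\n")
  iv <- x$intervals
  for (i in seq_len(nrow(iv))) {
    d <- .ri_decimals(iv$analyte[i])
    cat(sprintf("  %-4s %-7s fitted %s  guidelines %.*f-%.*f\n",
                iv$analyte[i], iv$trimester[i],
                if (is.na(iv$fitted_lower[i])) "   (missing)   "
                else sprintf("%.*f-%.*f", d, round(iv$fitted_lower[i], d),
                             d, round(iv$fitted_upper[i], d)),
                d, iv$guideline_lower[i], d, iv$guideline_upper[i]))
  }
  if (nrow(x$abnormal_rates)) {
    cat("\n== Abnormal rates (guidelines vs fitted), % ==\n")
    ar <- x$abnormal_rates
    for (i in seq_len(nrow(ar)))
      cat(sprintf("  %-7s %-14s %6.2f vs %6.2f   p = %s\n",
                  ar$trimester[i], ar$measure[i], ar$rate_guidelines[i],
                  ar$rate_fitted[i], format.pval(ar$p_value[i], digits = 3)))
  }
  if (length(x$gaps))
    cat("\nMissing strata:", paste(x$gaps, collapse = "; "), "\n")
  invisible(x)
}

#' Write report tables as delimited text
#'
#' Writes `population.tsv`, `age_bands.tsv`, `abnormal_rates.tsv` and
#' `intervals.tsv` into a directory.
#'
#' @param report an `ri_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "ri_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in c("population", "age_bands", "abnormal_rates", "intervals"))
    utils::write.table(report[[nm]], file.path(dir, paste0(nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
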