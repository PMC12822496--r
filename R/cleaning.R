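#' Cleaning configuration for the exclusion cascade
#'
#' Thresholds of the record-exclusion cascade: analytes must lie strictly
#' inside the analytical measurement range (AMR) of the assay, the TPO-Ab
#' cutoff is strict (a value of exactly 34 IU/ml is retained), and age
#' bounds are inclusive (20 and 45 are retained).
#'
#' @param age_min,age_max inclusive maternal age bounds in years.
#' @param tsh_amr,ft4_amr length-2 AMR intervals (mIU/L, pmol/L); records
#'   strictly outside are excluded.
#' @param tpoab_cutoff exclusion threshold, IU/ml (strict `>`).
#' @param require_female drop records whose sex is not female.
#' @param dedup_policy only `"drop_all_rows_of_multi_record_patients"` is
#'   implemented: a patient with more than one record over the input period
#'   loses all of them.
#' @return object of class `cleaning_config`.
#' @export
cleaning_config <- function(age_min = 20, age_max = 45,
                            tsh_amr = c(0.005, 100.00),
                            ft4_amr = c(0.3, 100),
                            tpoab_cutoff = 34,
                            require_female = TRUE,
                            dedup_policy = "drop_all_rows_of_multi_record_patients") {
  dedup_policy <- match.arg(dedup_policy)
  stopifnot(age_min < age_max, tsh_amr[1] < tsh_amr[2],
            ft4_amr[1] < ft4_amr[2], tpoab_cutoff > 0)
  structure(list(age_min = age_min, age_max = age_max,
                 tsh_amr = tsh_amr, ft4_amr = ft4_amr,
                 tpoab_cutoff = tpoab_cutoff,
                 require_female = isTRUE(require_female),
                 dedup_policy = dedup_policy),
            class = "cleaning_config")
}

.criteria_names <- c("missing_values", "age_missing", "not_female",
                     "age_out_of_range", "multiple_records", "out_of_amr",
                     "tpoab_positive")

#' Apply the exclusion cascade to raw laboratory records
#'
#' Applies the seven exclusion criteria in their stated order — (1) missing
#' analyte values, (2) missing age, (3) sex not female, (4) age outside
#' 20--45 years, (5) more than one record for the same patient over the
#' input period (all of that patient's records dropped), (6) TSH or FT4
#' strictly outside the AMR, (7) TPO-Ab strictly above the cutoff — and
#' attributes each excluded record to the FIRST criterion it violates, so
#' the funnel reconciles.  Records whose gestational week is missing or
#' below 4 (before the first trimester's start) are excluded afterwards and
#' logged separately as `invalid_week`.
#'
#' @param records data frame of laboratory records (see [read_cohort()] for
#'   the column contract).  Non-integer ages are floored.
#' @param config a [cleaning_config()].
#' @return list with `retained` (clean records) and `report` (an
#'   `exclusion_report` holding per-criterion counts, `n_input`,
#'   `n_retained` and `invalid_week`).
#' @examples
#' cohort <- generate_cohort(default_truth_params(c(300, 200, 100)))
#' res <- clean_cohort(cohort)
#' res$report
#' @export
clean_cohort <- function(records, config = cleaning_config()) {
  if (is.null(records) || nrow(records) == 0L) {
    report <- structure(list(counts = stats::setNames(integer(7), .criteria_names),
                             invalid_week = 0L, n_input = 0L, n_retained = 0L),
                        class = "exclusion_report")
    return(list(retained = records, report = report))
  }
  stopifnot(inherits(config, "cleaning_config"))
  n <- nrow(records)
  age <- floor(as.numeric(records$age))
  tsh <- as.numeric(records$tsh)
  ft4 <- as.numeric(records$ft4)
  tpo <- as.numeric(records$tpo_ab)
  pid <- as.character(records$patient_id)
  sex <- as.character(records$sex)
  no_pid <- is.na(pid) | !nzchar(pid)

  # (5) keys on patient_id across the whole input period
  dup_ids <- unique(pid[!no_pid][duplicated(pid[!no_pid])])

  crit <- cbind(
    missing_values = is.na(tsh) | is.na(ft4) | is.na(tpo) | no_pid,
    age_missing = is.na(age),
    not_female = if (config$require_female)
      is.na(sex) | sex != "female" else rep(FALSE, n),
    age_out_of_range = !is.na(age) &
      (age < config$age_min | age > config$age_max),
    multiple_records = !no_pid & pid %in% dup_ids,
    out_of_amr = (!is.na(tsh) &
                    (tsh < config$tsh_amr[1] | tsh > config$tsh_amr[2])) |
                 (!is.na(ft4) &
                    (ft4 < config$ft4_amr[1] | ft4 > config$ft4_amr[2])),
    tpoab_positive = !is.na(tpo) & tpo > config$tpoab_cutoff
  )
  first_hit <- apply(crit, 1L, function(v) {
    w <- which(v)
    if (length(w)) w[1] else 0L
  })
  counts <- stats::setNames(
    vapply(seq_along(.criteria_names),
           function(i) sum(first_hit == i), integer(1)),
    .criteria_names)

  keep <- first_hit == 0L
  wk <- suppressWarnings(as.numeric(records$gestational_week))
  bad_week <- keep & (is.na(wk) | wk < 4)
  invalid_week <- sum(bad_week)
  keep <- keep & !bad_week

  retained <- records[keep, , drop = FALSE]
  rownames(retained) <- NULL
  report <- structure(list(counts = counts,
                           invalid_week = as.integer(invalid_week),
                           n_input = n,
                           n_retained = nrow(retained)),
                      class = "exclusion_report")
  list(retained = retained, report = report)
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat("Exclusion cascade\n")
  cat(sprintf("  %-20s %d\n", "records in", x$n_input))
  labels <- c("missing values", "age missing", "sex not female",
              "age outside 20-45", "multiple records", "outside AMR",
              "TPO-Ab positive")
  for (i in seq_along(labels))
    cat(sprintf("  - %-18s %d\n", labels[i], x$counts[i]))
  cat(sprintf("  - %-18s %d\n", "invalid gest. week", x$invalid_week))
  cat(sprintf("  %-20s %d\n", "records retained", x$n_retained))
  invisible(x)
}

#' Write an exclusion report as a structured text funnel
#'
#' @param report an `exclusion_report` from [clean_cohort()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_exclusion_report <- function(report, path) {
  stopifnot(inherits(report, "exclusion_report"))
  lines <- c(sprintf("n_input\t%d", report$n_input),
             sprintf("%s\t%d", names(report$counts), report$counts),
             sprintf("invalid_week\t%d", report$invalid_week),
             sprintf("n_retained\t%d", report$n_retained))
  writeLines(lines, path)
  invisible(path)
}

#' Assign a gestational trimester from completed weeks
#'
#' Weeks 4--12 map to the first trimester, 13--27 to the second, and 28 or
#' later to the third.  Weeks below 4 (or missing) return `NA`: the
#' trimester definition starts at week 4 and such records are excluded
#' upstream as invalid.
#'
#' @param gestational_week completed weeks of gestation (vectorised).
#' @return character vector in `c("first", "second", "third")`, `NA` where
#'   invalid.
#' @examples
#' assign_trimester(c(4, 12, 13, 27, 28, 3))
#' @export
assign_trimester <- function(gestational_week) {
  wk <- as.numeric(gestational_week)
  out <- rep(NA_character_, length(wk))
  out[!is.na(wk) & wk >= 4 & wk <= 12] <- "first"
  out[!is.na(wk) & wk >= 13 & wk <= 27] <- "second"
  out[!is.na(wk) & wk >= 28] <- "third"
  out
}

#' Assign a 5-year maternal age band
#'
#' The five closed bands 20-25, 26-30, 31-35, 36-40 and 41-45 years.  Ages
#' outside 20--45 are a contract violation (cleaning guarantees the range)
#' and raise an error.
#'
#' @param age age in completed years (vectorised).
#' @return character vector of band labels.
#' @export
assign_age_band <- function(age) {
  a <- floor(as.numeric(age))
  if (any(is.na(a) | a < 20 | a > 45))
    stop("age outside [20, 45]: cleaning should have excluded it")
  cut_points <- c(20, 26, 31, 36, 41, 46)
  labels <- c("20-25", "26-30", "31-35", "36-40", "41-45")
  labels[findInterval(a, cut_points)]
}

#' Stratify a cleaned cohort by trimester and age band
#'
#' Annotates retained records with trimester and age band and exposes
#' per-stratum analyte value vectors.  Every retained record lands in
#' exactly one trimester and one age band.
#'
#' @param records cleaned records (output of [clean_cohort()]).
#' @return object of class `stratified_cohort`: the annotated records plus
#'   accessor [stratum_values()].
#' @export
stratify_cohort <- function(records) {
  tri <- assign_trimester(records$gestational_week)
  stopifnot(!anyNA(tri))
  band <- assign_age_band(records$age)
  records$trimester <- factor(tri, levels = c("first", "second", "third"))
  records$age_band <- factor(band, levels = names(.age_band_limits))
  structure(list(records = records), class = "stratified_cohort")
}

#' Extract one stratum's analyte values
#'
#' @param cohort a `stratified_cohort`.
#' @param analyte `"tsh"` or `"ft4"`.
#' @param trimester `"first"`, `"second"` or `"third"`.
#' @param age_band optional band label to restrict further.
#' @return numeric vector of values.
#' @export
stratum_values <- function(cohort, analyte = c("tsh", "ft4"),
                           trimester = c("first", "second", "third"),
                           age_band = NULL) {
  stopifnot(inherits(cohort, "stratified_cohort"))
  analyte <- match.arg(analyte)
  trimester <- match.arg(trimester)
  rec <- cohort$records
  sel <- rec$trimester == trimester
  if (!is.null(age_band)) sel <- sel & rec$age_band == age_band
  as.numeric(rec[[analyte]][sel])
}

#' @export
print.stratified_cohort <- function(x, ...) {
  cat("Stratified cohort:", nrow(x$records), "records\n")
  print(table(x$records$trimester, x$records$age_band))
  invisible(x)
}
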