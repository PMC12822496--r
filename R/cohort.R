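# Age-band sampling probabilities for generated cohorts, mirroring the
# observed population distribution (22/44/23/9/2 % across the five 5-year
# bands from 20-25 to 41-45).
.age_band_probs <- c(`20-25` = 0.22, `26-30` = 0.44, `31-35` = 0.23,
                     `36-40` = 0.09, `41-45` = 0.02)
.age_band_limits <- list(`20-25` = c(20L, 25L), `26-30` = c(26L, 30L),
                         `31-35` = c(31L, 35L), `36-40` = c(36L, 40L),
                         `41-45` = c(41L, 45L))
.gestational_week_range <- list(first = c(4L, 12L), second = c(13L, 27L),
                                third = c(28L, 40L))

.sample_ages <- function(n) {
  band <- sample(names(.age_band_probs), n, replace = TRUE,
                 prob = .age_band_probs)
  lo <- vapply(.age_band_limits[band], `[`, integer(1), 1L)
  hi <- vapply(.age_band_limits[band], `[`, integer(1), 2L)
  lo + floor(stats::runif(n) * (hi - lo + 1L))
}

.empty_cohort <- function() {
  data.frame(patient_id = character(), age = integer(), sex = character(),
             gestational_week = integer(), tsh = numeric(), ft4 = numeric(),
             tpo_ab = numeric(), truth_label = character(),
             dirty_reason = character(), stringsAsFactors = FALSE)
}

.generate_stratum <- function(st, n, dirty_rates, id_prefix) {
  if (n == 0L) return(.empty_cohort())
  wk <- .gestational_week_range[[st$trimester]]
  n_hypo <- round(n * st$hypo_fraction)
  n_hyper <- round(n * st$hyper_fraction)
  n_tpo <- round(n * st$tpoab_pos_fraction)
  n_healthy <- n - n_hypo - n_hyper - n_tpo
  stopifnot(n_healthy >= 0)
  label <- c(rep("healthy", n_healthy), rep("hypo", n_hypo),
             rep("hyper", n_hyper), rep("tpoab_pos", n_tpo))

  age <- .sample_ages(n)
  tsh <- stats::rgamma(n, shape = st$tsh_healthy["shape"],
                       rate = st$tsh_healthy["rate"])
  ft4 <- stats::rnorm(n, mean = st$ft4_healthy["mean"] +
                        st$age_slope_ft4 * (age - 28),
                      sd = st$ft4_healthy["sd"])
  tpo_ab <- stats::runif(n, 5, 30)

  is_hypo <- label == "hypo"
  is_hyper <- label == "hyper"
  is_tpo <- label == "tpoab_pos"
  # hypothyroid: TSH displaced up, FT4 down; hyperthyroid: the reverse;
  # TPO-Ab positives carry elevated TSH and an antibody titre above cutoff
  tsh[is_hypo] <- tsh[is_hypo] * st$hypo_tsh_shift
  ft4[is_hypo] <- ft4[is_hypo] - 3
  tsh[is_hyper] <- tsh[is_hyper] * st$hyper_tsh_scale
  ft4[is_hyper] <- ft4[is_hyper] + 3
  tsh[is_tpo] <- tsh[is_tpo] * 1.5
  tpo_ab[is_tpo] <- stats::runif(sum(is_tpo), 40, 300)

  cohort <- data.frame(
    patient_id = sprintf("%s%06d", id_prefix, seq_len(n)),
    age = as.integer(age),
    sex = "female",
    gestational_week = wk[1] + floor(stats::runif(n) * (wk[2] - wk[1] + 1L)),
    tsh = tsh, ft4 = ft4, tpo_ab = tpo_ab,
    truth_label = label, dirty_reason = NA_character_,
    stringsAsFactors = FALSE)

  # dirty records: each violates exactly ONE cleaning criterion so the
  # exclusion funnel reconciles against planted counts record-for-record
  dirty <- .empty_cohort()
  next_id <- n
  add_dirty <- function(k, reason, mutate) {
    if (k <= 0) return()
    base <- data.frame(
      patient_id = sprintf("%sD%06d", id_prefix, next_id + seq_len(k)),
      age = as.integer(.sample_ages(k)),
      sex = "female",
      gestational_week = wk[1] +
        floor(stats::runif(k) * (wk[2] - wk[1] + 1L)),
      tsh = stats::rgamma(k, st$tsh_healthy["shape"], st$tsh_healthy["rate"]),
      ft4 = stats::rnorm(k, st$ft4_healthy["mean"], st$ft4_healthy["sd"]),
      tpo_ab = stats::runif(k, 5, 30),
      truth_label = "dirty", dirty_reason = reason,
      stringsAsFactors = FALSE)
    next_id <<- next_id + k
    dirty <<- rbind(dirty, mutate(base))
  }
  rates <- dirty_rates
  add_dirty(round(n * rates["missing_value"]), "missing_value", function(d) {
    slot <- rep_len(c("tsh", "ft4", "tpo_ab"), nrow(d))
    for (s in unique(slot)) d[slot == s, s] <- NA_real_
    d
  })
  add_dirty(round(n * rates["male_sex"]), "male_sex", function(d) {
    d$sex <- "male"
    d
  })
  add_dirty(round(n * rates["age_out_of_range"]), "age_out_of_range",
            function(d) {
    d$age <- sample(c(18L, 19L, 46L, 47L, 50L), nrow(d), replace = TRUE)
    d
  })
  n_dup <- 2L * (round(n * rates["duplicate_patient"]) %/% 2L)
  add_dirty(n_dup, "duplicate_patient", function(d) {
    half <- nrow(d) %/% 2L
    d$patient_id <- rep(d$patient_id[seq_len(half)], 2L)
    d
  })
  add_dirty(round(n * rates["out_of_amr"]), "out_of_amr", function(d) {
    kind <- rep_len(c("tsh_high", "tsh_low", "ft4_high"), nrow(d))
    d$tsh[kind == "tsh_high"] <- stats::runif(sum(kind == "tsh_high"), 101, 200)
    d$tsh[kind == "tsh_low"] <- stats::runif(sum(kind == "tsh_low"), 0.0001, 0.004)
    d$ft4[kind == "ft4_high"] <- stats::runif(sum(kind == "ft4_high"), 101, 200)
    d
  })
  add_dirty(round(n * rates["tpoab_over_cutoff"]), "tpoab_over_cutoff",
            function(d) {
    d$tpo_ab <- stats::runif(nrow(d), 40, 300)
    d
  })

  out <- rbind(cohort, dirty)
  out[sample.int(nrow(out)), , drop = FALSE]
}

#' Generate a synthetic laboratory cohort with known ground truth
#'
#' Draws, for each trimester stratum, healthy records from the calibrated
#' gamma (TSH) and normal (FT4) laws — the FT4 mean declining with maternal
#' age — plus hypothyroid, hyperthyroid and TPO-Ab-positive contamination
#' and cleaning-trigger ("dirty") records.  Every record carries a
#' `truth_label` (and, for dirty records, a `dirty_reason`) so downstream
#' cleaning and estimation can be validated against the generating truth.
#' Regeneration from the same `synthetic_truth` object is bit-identical.
#'
#' @param truth a [synthetic_truth()] object.
#' @return `data.frame` with columns `patient_id`, `age`, `sex`,
#'   `gestational_week`, `tsh`, `ft4`, `tpo_ab`, `truth_label`,
#'   `dirty_reason`.
#' @examples
#' cohort <- generate_cohort(default_truth_params(n_per_trimester =
#'   c(500, 300, 200)))
#' table(cohort$truth_label)
#' @export
generate_cohort <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  parts <- vector("list", 3L)
  prefixes <- c("F", "S", "T")
  for (i in seq_len(3L)) {
    # deterministic per-stratum substream derived from the cohort seed
    set.seed((truth$seed + i * 1009L) %% .Machine$integer.max)
    parts[[i]] <- .generate_stratum(truth$strata[[i]],
                                    truth$n_per_trimester[i],
                                    truth$dirty_record_rates,
                                    prefixes[i])
  }
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Planted cleaning-trigger counts of a synthetic cohort
#'
#' Tallies, from the generator's bookkeeping columns, how many records were
#' planted to violate each exclusion criterion.  TPO-Ab positives comprise
#' both the pathologic subpopulation and any dirty-record trigger.
#'
#' @param cohort data frame from [generate_cohort()].
#' @return named integer vector over the cleaning criteria.
#' @export
planted_counts <- function(cohort) {
  stopifnot(all(c("truth_label", "dirty_reason") %in% names(cohort)))
  reason <- cohort$dirty_reason
  c(missing_values = sum(reason == "missing_value", na.rm = TRUE),
    age_missing = 0L,
    not_female = sum(reason == "male_sex", na.rm = TRUE),
    age_out_of_range = sum(reason == "age_out_of_range", na.rm = TRUE),
    multiple_records = sum(reason == "duplicate_patient", na.rm = TRUE),
    out_of_amr = sum(reason == "out_of_amr", na.rm = TRUE),
    tpoab_positive = sum(cohort$truth_label == "tpoab_pos") +
      sum(reason == "tpoab_over_cutoff", na.rm = TRUE))
}

#' Write / read a cohort as tab-delimited text
#'
#' The on-disk format is a TSV with the canonical header `patient_id, age,
#' sex, gestational_week, tsh, ft4, tpo_ab` plus, when present and
#' `keep_truth = TRUE`, the synthetic bookkeeping columns `truth_label` and
#' `dirty_reason`.
#'
#' @param cohort data frame of laboratory records.
#' @param path file path.
#' @param keep_truth keep synthetic truth columns on write (default TRUE).
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()` the
#'   data frame.
#' @export
write_cohort <- function(cohort, path, keep_truth = TRUE) {
  cols <- c("patient_id", "age", "sex", "gestational_week",
            "tsh", "ft4", "tpo_ab")
  if (keep_truth)
    cols <- c(cols, intersect(c("truth_label", "dirty_reason"),
                              names(cohort)))
  stopifnot(all(cols %in% names(cohort)))
  utils::write.table(cohort[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  out <- utils::read.table(path, header = TRUE, sep = "\t",
                           na.strings = c("", "NA"),
                           colClasses = c(patient_id = "character"),
                           stringsAsFactors = FALSE)
  required <- c("patient_id", "age", "sex", "gestational_week",
                "tsh", "ft4", "tpo_ab")
  missing <- setdiff(required, names(out))
  if (length(missing))
    stop("cohort file lacks required columns: ",
         paste(missing, collapse = ", "))
  out
}
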