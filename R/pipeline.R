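#' Pipeline configuration
#'
#' Exactly one of `input` (path to a cohort TSV) or `truth` (a
#' [synthetic_truth()] simulate block) must be supplied.
#'
#' @param input optional path to a cohort file (see [read_cohort()]).
#' @param truth optional [synthetic_truth()] to simulate a cohort from.
#' @param cleaning a [cleaning_config()].
#' @param coverage reference-interval coverage (default 0.95).
#' @param healthy_fraction_init initial healthy proportion for EM.
#' @param tol,max_iter EM settings.
#' @param seed integer seed for all randomness (overrides `truth$seed`).
#' @param out_dir output directory for artifacts.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, truth = NULL,
                            cleaning = cleaning_config(),
                            coverage = 0.95,
                            healthy_fraction_init = 0.90,
                            tol = 1e-8, max_iter = 2000L,
                            seed = NULL, out_dir = tempfile("mixref-run-")) {
  if (is.null(input) == is.null(truth))
    stop("exactly one of `input` and `truth` must be given")
  if (!is.null(truth)) {
    stopifnot(inherits(truth, "synthetic_truth"))
    if (!is.null(seed)) truth$seed <- as.integer(seed)
  }
  structure(list(input = input, truth = truth, cleaning = cleaning,
                 coverage = coverage,
                 healthy_fraction_init = healthy_fraction_init,
                 tol = tol, max_iter = as.integer(max_iter),
                 seed = if (is.null(seed)) truth$seed else as.integer(seed),
                 out_dir = out_dir),
            class = "pipeline_config")
}

# polynomial rolling hash (mod a Mersenne prime) of the deparsed config,
# so every artifact can declare the configuration that produced it
.config_hash <- function(config) {
  txt <- paste(deparse(config[setdiff(names(config), "out_dir")]),
               collapse = "")
  h <- 5381
  for (b in utf8ToInt(txt)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full indirect reference-interval pipeline
#'
#' Orchestrates simulate (or load) -> clean -> stratify -> per-stratum
#' mixture fit -> report.  Writes the cohort, the exclusion funnel, one
#' mixture-fit document per (analyte, trimester), the interval table and
#' the comparison report into `config$out_dir`; every artifact directory
#' carries a `config_hash` so reruns are traceable.  Identical
#' configuration and seed give byte-identical artifacts.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress stage progress messages.
#' @return invisibly, a list with `report` (the [build_report()] result),
#'   `fits`, `exclusion_report`, `intervals`, `config_hash`, `out_dir`.
#' @examples
#' \donttest{
#' cfg <- pipeline_config(truth = default_truth_params(c(1500, 1000, 800)))
#' res <- run_pipeline(cfg)
#' res$report$intervals
#' }
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- .config_hash(config)
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
    say("[%s] done in %.1fs", name, proc.time()[["elapsed"]] - t0)
    out
  }

  cohort <- stage("simulate/load", {
    if (!is.null(config$truth)) {
      co <- generate_cohort(config$truth)
      write_cohort(co, file.path(config$out_dir, "cohort.tsv"))
      co
    } else read_cohort(config$input)
  })

  cleaned <- stage("clean", {
    res <- clean_cohort(cohort, config$cleaning)
    write_cohort(res$retained, file.path(config$out_dir, "cleaned.tsv"),
                 keep_truth = "truth_label" %in% names(res$retained))
    write_exclusion_report(res$report,
                           file.path(config$out_dir,
                                     "exclusion_report.tsv"))
    res
  })

  strat <- stage("stratify", stratify_cohort(cleaned$retained))

  fits <- stage("fit", {
    families <- c(TSH = "gamma", FT4 = "normal")
    out <- list()
    for (an in names(families)) {
      out[[an]] <- list()
      for (tri in c("first", "second", "third")) {
        v <- stratum_values(strat, tolower(an), tri)
        out[[an]][[tri]] <- if (length(v) >= 30L) {
          f <- fit_analyte(v, families[[an]],
                           healthy_fraction_init =
                             config$healthy_fraction_init,
                           tol = config$tol, max_iter = config$max_iter)
          write_mixture_fit(f, file.path(config$out_dir,
                                         sprintf("fit_%s_%s.tsv",
                                                 tolower(an), tri)))
          f
        } else NULL
      }
    }
    out
  })

  report <- stage("report", {
    rep <- build_report(fits, strat, coverage = config$coverage)
    write_report(rep, config$out_dir)
    rep
  })

  writeLines(c(sprintf("config_hash\t%s", hash),
               sprintf("seed\t%s", config$seed),
               sprintf("coverage\t%g", config$coverage)),
             file.path(config$out_dir, "run_info.tsv"))

  invisible(list(report = report, fits = fits,
                 exclusion_report = cleaned$report,
                 intervals = report$intervals,
                 config_hash = hash, out_dir = config$out_dir))
}
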