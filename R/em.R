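# ---- component primitives ---------------------------------------------

#' Component specifications for a mixture fit
#'
#' A spec names the parametric family and the role each component plays.
#' Exactly one component per fit has role `"healthy"`; pathologic
#' components are seeded below (`"patho_low"`) or above (`"patho_high"`)
#' the dominant mode.
#'
#' @param family `"gamma"` (right-skewed analytes such as TSH) or
#'   `"normal"` (approximately symmetric analytes such as FT4).
#' @param roles character vector of roles, exactly one `"healthy"`.
#' @return list of spec lists (class `component_spec` each).
#' @export
component_specs <- function(family = c("gamma", "normal"),
                            roles = c("healthy", "patho_low", "patho_high")) {
  family <- match.arg(family)
  stopifnot(sum(roles == "healthy") == 1L,
            all(roles %in% c("healthy", "patho_low", "patho_high")))
  lapply(roles, function(r)
    structure(list(family = family, role = r), class = "component_spec"))
}

.comp_logdens <- function(comp, x) {
  if (comp$family == "gamma")
    stats::dgamma(x, shape = comp$params[1], rate = comp$params[2],
                  log = TRUE)
  else
    stats::dnorm(x, mean = comp$params[1], sd = comp$params[2], log = TRUE)
}

.comp_cdf <- function(comp, x) {
  if (comp$family == "gamma")
    stats::pgamma(x, shape = comp$params[1], rate = comp$params[2])
  else
    stats::pnorm(x, mean = comp$params[1], sd = comp$params[2])
}

.comp_quantile <- function(comp, p) {
  if (comp$family == "gamma")
    stats::qgamma(p, shape = comp$params[1], rate = comp$params[2])
  else
    stats::qnorm(p, mean = comp$params[1], sd = comp$params[2])
}

# gamma (shape, rate) with a given mode m > 0 and standard deviation s:
# solving mode = (k-1)/r, var = k/r^2
.gamma_from_mode_sd <- function(m, s) {
  m <- max(m, 1e-8)
  r <- (m + sqrt(m^2 + 4 * s^2)) / (2 * s^2)
  c(shape = 1 + m * r, rate = r)
}

#' Mixture cumulative distribution function
#'
#' @param fit a `mixture_fit`.
#' @param x numeric quantiles.
#' @return weighted sum of component CDFs at `x`.
#' @export
mixture_cdf <- function(fit, x) {
  stopifnot(inherits(fit, "mixture_fit"))
  Reduce(`+`, lapply(fit$components,
                     function(co) co$weight * .comp_cdf(co, x)))
}

#' The healthy (non-pathologic) component of a fit
#'
#' @param fit a `mixture_fit`.
#' @return the component list (family, role, params, weight).
#' @export
healthy_component <- function(fit) {
  stopifnot(inherits(fit, "mixture_fit"))
  roles <- vapply(fit$components, function(co) co$role, character(1))
  fit$components[[which(roles == "healthy")[1]]]
}

.new_mixture_fit <- function(components, values, ll = NA_real_,
                             ll_trace = numeric(), n_iterations = 0L,
                             converged = FALSE, ks = NA_real_) {
  structure(list(components = components,
                 log_likelihood = ll,
                 ll_trace = ll_trace,
                 n_iterations = n_iterations,
                 converged = converged,
                 ks_main_part = ks,
                 data_summary = c(n = length(values), min = min(values),
                                  max = max(values))),
            class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("Mixture fit: %d component(s), n = %d, logLik = %.3f%s\n",
              length(x$components), x$data_summary["n"],
              x$log_likelihood,
              if (isTRUE(x$converged)) ""
              else " (NOT converged)"))
  for (co in x$components) {
    pn <- if (co$family == "gamma") c("shape", "rate") else c("mean", "sd")
    cat(sprintf("  %-10s %-6s w = %.4f  %s = %.5g, %s = %.5g\n",
                co$role, co$family, co$weight,
                pn[1], co$params[1], pn[2], co$params[2]))
  }
  if (is.finite(x$ks_main_part))
    cat(sprintf("  KS (main part) = %.5f\n", x$ks_main_part))
  invisible(x)
}

# ---- initialization ----------------------------------------------------

#' Initialize a mixture fit from a kernel density estimate
#'
#' The healthy component is centred at the global density mode with spread
#' taken from the interquartile range of the sample's central region
#' (IQR / 1.349, the normal-consistent scale); pathologic components are
#' seeded at the far lower / upper sample percentiles with an inflated
#' spread; the healthy component receives `healthy_fraction_init` of the
#' weight and the pathologic components split the remainder.
#'
#' @param density a [estimate_density()] result for `values`.
#' @param values the sample.
#' @param healthy_fraction_init initial healthy-population proportion
#'   (default 0.90, the assumed healthy:pathologic ratio; the EM result is
#'   insensitive to moderate variation of this starting value).
#' @param specs component specifications from [component_specs()].
#' @return an unconverged `mixture_fit` suitable as `init` for
#'   [fit_mixture_em()].
#' @export
initialize_fit <- function(density, values, healthy_fraction_init = 0.90,
                           specs = component_specs("gamma")) {
  stopifnot(inherits(density, "density_estimate"),
            healthy_fraction_init > 0, healthy_fraction_init < 1)
  mode <- density_mode(density)
  iqr <- stats::IQR(values)
  s0 <- max(iqr / 1.349, 1e-6)
  q <- stats::quantile(values, c(0.01, 0.99), names = FALSE)
  c_low <- min(q[1], mode - 2 * s0)
  c_high <- max(q[2], mode + 2 * s0)
  n_patho <- sum(vapply(specs, function(sp) sp$role != "healthy",
                        logical(1)))
  w_patho <- if (n_patho) (1 - healthy_fraction_init) / n_patho else 0
  components <- lapply(specs, function(sp) {
    centre <- switch(sp$role, healthy = mode, patho_low = c_low,
                     patho_high = c_high)
    spread <- if (sp$role == "healthy") s0 else 1.5 * s0
    params <- if (sp$family == "gamma")
      .gamma_from_mode_sd(centre, spread)
    else c(mean = centre, sd = spread)
    list(family = sp$family, role = sp$role, params = params,
         weight = if (sp$role == "healthy") healthy_fraction_init
                  else w_patho)
  })
  if (n_patho == 0L) components[[1]]$weight <- 1
  .new_mixture_fit(components, values)
}

# ---- EM ----------------------------------------------------------------

.log_mix_matrix <- function(components, values) {
  vapply(components,
         function(co) log(co$weight) + .comp_logdens(co, values),
         numeric(length(values)))
}

.row_logsumexp <- function(m) {
  mx <- do.call(pmax, c(as.data.frame(m), na.rm = TRUE))
  mx + log(rowSums(exp(m - mx)))
}

#' Fit a finite mixture by expectation-maximization
#'
#' Standard EM for a mixture of gamma and/or normal components:
#' responsibilities from current component densities and weights (computed
#' in log space with log-sum-exp renormalization), M-step through
#' [weighted_normal_mle()] / [weighted_gamma_mle()] plus weight updates,
#' stopping when the relative log-likelihood change falls below `tol` or at
#' `max_iter`.  A collapsing component (weight below 1e-4, or a degenerate
#' M-step) is pruned and the reduced mixture refitted from scratch; the
#' healthy component is never pruned.  After convergence the healthy
#' component is expected to hold the largest weight; if it does not, the
#' largest-weight component is re-identified as healthy with a warning.
#'
#' @param values numeric sample (strictly positive if any gamma component).
#' @param init initial `mixture_fit` from [initialize_fit()].
#' @param tol relative log-likelihood convergence tolerance (default 1e-8).
#' @param max_iter iteration cap (default 2000).
#' @param quiet suppress pruning messages.
#' @return a converged `mixture_fit` with log-likelihood trace; the trace
#'   is non-decreasing (EM ascent property).
#' @export
fit_mixture_em <- function(values, init, tol = 1e-8, max_iter = 2000L,
                           quiet = TRUE) {
  stopifnot(inherits(init, "mixture_fit"), length(values) >= 30L)
  if (any(vapply(init$components, function(co) co$family == "gamma",
                 logical(1))) && any(values <= 0))
    stop("gamma components require strictly positive values")
  components <- init$components
  n <- length(values)

  repeat {
    K <- length(components)
    ll_trace <- numeric(0)
    ll_prev <- -Inf
    converged <- FALSE
    pruned <- FALSE
    for (iter in seq_len(max_iter)) {
      lm <- .log_mix_matrix(components, values)
      lse <- .row_logsumexp(lm)
      ll <- sum(lse)
      ll_trace <- c(ll_trace, ll)
      if (is.finite(ll_prev) &&
          abs(ll - ll_prev) < tol * (abs(ll_prev) + 1e-12)) {
        converged <- TRUE
        break
      }
      ll_prev <- ll
      resp <- exp(lm - lse)
      w_new <- colSums(resp) / n
      drop_idx <- integer(0)
      for (j in seq_len(K)) {
        role <- components[[j]]$role
        if (w_new[j] < 1e-4 && role != "healthy") {
          drop_idx <- c(drop_idx, j)
          next
        }
        params <- tryCatch({
          if (components[[j]]$family == "gamma")
            weighted_gamma_mle(values, resp[, j])
          else
            weighted_normal_mle(values, resp[, j])
        }, error = function(e) NULL, warning = function(w) NULL)
        if (is.null(params)) {
          if (role == "healthy")
            stop("healthy component degenerated during EM")
          drop_idx <- c(drop_idx, j)
          next
        }
        components[[j]]$params <- params
        components[[j]]$weight <- w_new[j]
      }
      if (length(drop_idx)) {
        if (!quiet)
          message("pruning ", length(drop_idx),
                  " collapsed component(s); refitting")
        components <- components[-drop_idx]
        wsum <- sum(vapply(components, function(co) co$weight, numeric(1)))
        for (j in seq_along(components))
          components[[j]]$weight <- components[[j]]$weight / wsum
        pruned <- TRUE
        break
      }
    }
    if (!pruned) break
  }

  # renormalize weights against accumulated floating error
  wsum <- sum(vapply(components, function(co) co$weight, numeric(1)))
  for (j in seq_along(components))
    components[[j]]$weight <- components[[j]]$weight / wsum

  roles <- vapply(components, function(co) co$role, character(1))
  weights <- vapply(components, function(co) co$weight, numeric(1))
  if (roles[which.max(weights)] != "healthy") {
    warning("healthy component no longer dominant; ",
            "re-identifying the largest-weight component as healthy")
    components[[which(roles == "healthy")]]$role <-
      roles[which.max(weights)]
    components[[which.max(weights)]]$role <- "healthy"
  }

  fit <- .new_mixture_fit(components, values, ll = ll_trace[length(ll_trace)],
                          ll_trace = ll_trace,
                          n_iterations = length(ll_trace),
                          converged = converged)
  fit$ks_main_part <- ks_main_part(fit, values)
  fit
}

# ---- diagnostics & selection ------------------------------------------

#' Kolmogorov-Smirnov distance on the main part of the data
#'
#' The "main part" — the dominant central region assumed to represent the
#' healthy population — is operationalized as the interval between the
#' healthy component's 5th and 95th percentiles.  The statistic is the
#' supremum distance between the fitted full-mixture CDF and the empirical
#' CDF of the whole sample, taken over sample points inside that region.
#'
#' @param fit a `mixture_fit`.
#' @param values the sample the fit was computed on.
#' @param region_probs healthy-component quantile probabilities bounding
#'   the main part (default `c(0.05, 0.95)`).
#' @return KS distance in `[0, 1]`.
#' @export
ks_main_part <- function(fit, values, region_probs = c(0.05, 0.95)) {
  stopifnot(inherits(fit, "mixture_fit"),
            length(region_probs) == 2L, region_probs[1] < region_probs[2])
  hc <- healthy_component(fit)
  bounds <- .comp_quantile(hc, region_probs)
  xs <- sort(values)
  n <- length(xs)
  idx <- which(xs >= bounds[1] & xs <= bounds[2])
  if (!length(idx)) stop("empty main-part region")
  Fx <- mixture_cdf(fit, xs[idx])
  d <- pmax(abs(Fx - idx / n), abs(Fx - (idx - 1) / n))
  max(d)
}

#' Fit candidate mixture structures and select by main-part fit
#'
#' Fits every candidate component-spec set by EM and selects by the
#' Kolmogorov-Smirnov main-part distance under a smallest-adequate-model
#' rule: a candidate is *adequate* when its KS distance is below the
#' canonical 95% Kolmogorov critical scale `1.36 / sqrt(n)`; among
#' adequate candidates the most parsimonious wins (ties by smaller KS,
#' then higher log-likelihood), and only when no candidate is adequate is
#' the minimum-KS fit returned.  Adequacy at the critical scale means the
#' data cannot distinguish the fit from the truth in the main part, so
#' adding contamination components would only chase sampling noise in the
#' tails; genuine contamination misfit exceeds the scale and still forces
#' the richer model.
#'
#' @param values the sample.
#' @param candidate_spec_sets list of spec sets (each from
#'   [component_specs()]).
#' @param healthy_fraction_init passed to [initialize_fit()].
#' @param density optional precomputed [estimate_density()] result.
#' @param ... passed to [fit_mixture_em()].
#' @return the selected `mixture_fit`, with attribute `"candidates"`
#'   holding per-candidate diagnostics.
#' @export
select_model <- function(values, candidate_spec_sets,
                         healthy_fraction_init = 0.90,
                         density = NULL, ...) {
  stopifnot(length(candidate_spec_sets) >= 1L)
  if (is.null(density)) density <- estimate_density(values)
  fits <- vector("list", length(candidate_spec_sets))
  errs <- character(0)
  cand_warnings <- vector("list", length(candidate_spec_sets))
  for (i in seq_along(candidate_spec_sets)) {
    # muffle candidate warnings; only the selected fit's are re-issued
    fits[[i]] <- tryCatch(
      withCallingHandlers({
        init <- initialize_fit(density, values, healthy_fraction_init,
                               specs = candidate_spec_sets[[i]])
        fit_mixture_em(values, init, ...)
      }, warning = function(w) {
        cand_warnings[[i]] <<- c(cand_warnings[[i]], conditionMessage(w))
        invokeRestart("muffleWarning")
      }),
      error = function(e) {
        errs <<- c(errs, conditionMessage(e))
        NULL
      })
  }
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok))
    stop("all candidate fits failed: ", paste(errs, collapse = "; "))
  fits <- fits[ok]
  cand_warnings <- cand_warnings[ok]
  ks <- vapply(fits, function(f) f$ks_main_part, numeric(1))
  ncomp <- vapply(fits, function(f) length(f$components), numeric(1))
  ll <- vapply(fits, function(f) f$log_likelihood, numeric(1))
  # smallest adequate model: adequacy at the 95% Kolmogorov critical scale
  crit <- 1.36 / sqrt(length(values))
  adequate <- ks <= crit
  ord <- if (any(adequate))
    order(!adequate, ncomp, ks, -ll)
  else
    order(ks, ncomp, -ll)
  best <- fits[[ord[1]]]
  for (msg in unique(cand_warnings[[ord[1]]])) warning(msg, call. = FALSE)
  attr(best, "candidates") <- data.frame(ks = ks, n_components = ncomp,
                                         log_likelihood = ll)
  best
}

#' Default candidate structures for one analyte
#'
#' Healthy-only, healthy plus one low or high pathologic component, and
#' healthy plus both — all in the analyte's family.
#'
#' @param family `"gamma"` or `"normal"`.
#' @return list of component-spec sets.
#' @export
default_candidates <- function(family = c("gamma", "normal")) {
  family <- match.arg(family)
  list(component_specs(family, "healthy"),
       component_specs(family, c("healthy", "patho_low")),
       component_specs(family, c("healthy", "patho_high")),
       component_specs(family, c("healthy", "patho_low", "patho_high")))
}

#' Fit one analyte's mixed sample end to end
#'
#' Convenience wrapper: kernel density estimate, initialization, EM over
#' the default candidate structures, and model selection by main-part KS
#' distance.
#'
#' @param values the sample.
#' @param family healthy-component family (`"gamma"` for right-skewed
#'   analytes, `"normal"` for symmetric ones).
#' @param healthy_fraction_init initial healthy proportion.
#' @param candidates candidate spec sets (default [default_candidates()]).
#' @param ... passed to [fit_mixture_em()].
#' @return selected `mixture_fit`.
#' @examples
#' set.seed(7)
#' x <- c(rgamma(2000, 4, 2), rgamma(100, 4, 2) * 5)
#' fit <- fit_analyte(x, "gamma")
#' healthy_component(fit)$params
#' @export
fit_analyte <- function(values, family = c("gamma", "normal"),
                        healthy_fraction_init = 0.90,
                        candidates = NULL, ...) {
  family <- match.arg(family)
  if (is.null(candidates)) candidates <- default_candidates(family)
  select_model(values, candidates,
               healthy_fraction_init = healthy_fraction_init, ...)
}

#' Write a mixture fit as a structured text document
#'
#' @param fit a `mixture_fit`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_mixture_fit <- function(fit, path) {
  stopifnot(inherits(fit, "mixture_fit"))
  lines <- c(
    sprintf("n\t%d", fit$data_summary["n"]),
    sprintf("log_likelihood\t%.10g", fit$log_likelihood),
    sprintf("n_iterations\t%d", fit$n_iterations),
    sprintf("converged\t%s", fit$converged),
    sprintf("ks_main_part\t%.10g", fit$ks_main_part),
    vapply(fit$components, function(co)
      sprintf("component\t%s\t%s\t%.10g\t%.10g\t%.10g",
              co$role, co$family, co$params[1], co$params[2], co$weight),
      character(1)))
  writeLines(lines, path)
  invisible(path)
}
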