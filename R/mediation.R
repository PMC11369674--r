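as_effect <- function(x, label) {
  if (inherits(x, "mr_estimate")) {
    list(beta = x$beta, se = x$se, pvalue = x$pvalue)
  } else if (is.numeric(x) && length(x) == 1) {
    list(beta = x, se = NA_real_, pvalue = NA_real_)
  } else {
    stop(sprintf("%s must be an mr_estimate or a single number", label),
         call. = FALSE)
  }
}

#' Two-step MR mediation decomposition
#'
#' Decomposes a total causal effect c (exposure on outcome) into an indirect
#' effect through a mediator, estimated by the product of coefficients
#' a x b (a: exposure on mediator; b: mediator on outcome), and a direct
#' effect c' = c - a x b. The proportion mediated is the signed ratio
#' (a x b) / c. Its standard error uses the delta method, treating the three
#' estimates as independent: var(ab) = a^2 var(b) + b^2 var(a), then
#' var(ab/c) = var(ab)/c^2 + (ab)^2 var(c)/c^4; the 95% interval is
#' proportion +/- 1.96 SE. A seeded Monte-Carlo interval (normal resampling
#' of a, b, c) is available as an alternative.
#'
#' When the indirect and total effects have opposite signs the mediator
#' masks (suppresses) part of the direct effect rather than transmitting it;
#' [classify_mediation()] formalizes this.
#'
#' @param c_est total-effect estimate (`mr_estimate` or bare number).
#' @param a_est exposure-to-mediator estimate.
#' @param b_est mediator-to-outcome estimate.
#' @param exposure,mediator,outcome trait labels.
#' @param alpha significance level for the classification.
#' @param ci_method `"delta"` (default) or `"montecarlo"`.
#' @param n_sim,seed Monte-Carlo controls (used when `ci_method =
#'   "montecarlo"`).
#' @return An object of class `mr_mediation`: list with `c`, `a`, `b`,
#'   `indirect`, `direct`, `proportion`, `proportion_se`,
#'   `proportion_ci_low`, `proportion_ci_high`, `indirect_se`,
#'   `indirect_pvalue`, `classification` and the labels.
#' @examples
#' # replaying a published lipid -> inflammatory protein -> DVT triplet
#' m <- mr_mediate(0.0014, 0.0850, 0.0021,
#'                 exposure = "TAG(58:7)", mediator = "CCL20", outcome = "DVT")
#' m$proportion * 100   # percent of the total effect carried by the mediator
#' @export
mr_mediate <- function(c_est, a_est, b_est,
                       exposure = "exposure", mediator = "mediator",
                       outcome = "outcome", alpha = 0.05,
                       ci_method = c("delta", "montecarlo"),
                       n_sim = 10000, seed = NULL) {
  ci_method <- match.arg(ci_method)
  ce <- as_effect(c_est, "c_est")
  ae <- as_effect(a_est, "a_est")
  be <- as_effect(b_est, "b_est")
  indirect <- ae$beta * be$beta
  direct <- ce$beta - indirect
  var_ind <- ae$beta^2 * be$se^2 + be$beta^2 * ae$se^2
  ind_se <- sqrt(var_ind)
  ind_p <- if (!is.na(ind_se) && ind_se > 0)
    2 * pnorm(-abs(indirect / ind_se)) else NA_real_

  if (ce$beta == 0) {
    prop <- NA_real_; prop_se <- NA_real_; ci <- c(NA_real_, NA_real_)
  } else {
    prop <- indirect / ce$beta
    var_prop <- var_ind / ce$beta^2 + indirect^2 * ce$se^2 / ce$beta^4
    prop_se <- sqrt(var_prop)
    if (ci_method == "delta" || is.na(prop_se)) {
      ci <- c(prop - 1.96 * prop_se, prop + 1.96 * prop_se)
    } else {
      if (is.null(seed)) stop("Monte-Carlo interval requires a seed", call. = FALSE)
      draws <- local_seed(seed, {
        a_d <- rnorm(n_sim, ae$beta, ae$se)
        b_d <- rnorm(n_sim, be$beta, be$se)
        c_d <- rnorm(n_sim, ce$beta, ce$se)
        a_d * b_d / c_d
      })
      ci <- unname(stats::quantile(draws, c(0.025, 0.975)))
    }
  }
  res <- structure(list(
    exposure = exposure, mediator = mediator, outcome = outcome,
    c = ce$beta, a = ae$beta, b = be$beta,
    c_se = ce$se, a_se = ae$se, b_se = be$se,
    c_pvalue = ce$pvalue,
    indirect = indirect, direct = direct,
    indirect_se = ind_se, indirect_pvalue = ind_p,
    proportion = prop, proportion_se = prop_se,
    proportion_ci_low = ci[1], proportion_ci_high = ci[2],
    alpha = alpha, ci_method = ci_method,
    classification = NA_character_), class = "mr_mediation")
  res$classification <- classify_mediation(res, alpha)
  res
}

#' Classify a mediation result as mediation, masking or none
#'
#' `"masking"` when the indirect effect is nominally significant and its sign
#' opposes the total effect's sign (the mediator suppresses part of the
#' direct effect); `"mediation"` when the signs agree and both effects are
#' significant; `"none"` otherwise. When standard errors are unavailable
#' (point-value replays of published tables) significance cannot be tested
#' and classification falls back to signs alone. When the total effect is
#' exactly zero no sign comparison is possible and a significant indirect
#' effect is labelled `"mediation"`.
#'
#' @param result an `mr_mediation` object.
#' @param alpha significance level.
#' @return One of `"mediation"`, `"masking"`, `"none"`.
#' @export
classify_mediation <- function(result, alpha = 0.05) {
  stopifnot(inherits(result, "mr_mediation"), alpha > 0, alpha < 1)
  sig_ind <- if (is.na(result$indirect_pvalue)) result$indirect != 0
             else result$indirect_pvalue < alpha
  sig_c <- if (is.na(result$c_pvalue)) result$c != 0
           else result$c_pvalue < alpha
  if (!sig_ind) return("none")
  if (result$c == 0) return("mediation")
  if (!sig_c) return("none")
  if (sign(result$indirect) == sign(result$c)) "mediation" else "masking"
}

#' @export
print.mr_mediation <- function(x, ...) {
  cat(sprintf("Two-step MR mediation: %s -> %s -> %s\n",
              x$exposure, x$mediator, x$outcome))
  cat(sprintf("  total c = %.4g; a = %.4g; b = %.4g\n", x$c, x$a, x$b))
  cat(sprintf("  indirect (a x b) = %.4g; direct (c - a x b) = %.4g\n",
              x$indirect, x$direct))
  if (!is.na(x$proportion)) {
    cat(sprintf("  proportion mediated = %.2f%% (95%% CI %.2f%%, %.2f%%)\n",
                100 * x$proportion, 100 * x$proportion_ci_low,
                100 * x$proportion_ci_high))
  } else {
    cat("  proportion mediated: undefined (total effect is zero)\n")
  }
  cat(sprintf("  classification: %s\n", x$classification))
  invisible(x)
}

#' Tabulate mediation decompositions
#'
#' One row per exposure/mediator/outcome triplet with the full decomposition,
#' the proportion mediated as a percentage with its 95% interval, and the
#' classification. Masking rows report the magnitude of the proportion (with
#' the `classification` column carrying the masking flag), matching the
#' convention of printing |indirect/total| for suppression effects; the
#' signed proportion is kept alongside.
#'
#' @param results list of `mr_mediation` objects (possibly empty).
#' @return data.frame with columns `exposure`, `mediator`, `outcome`, `c`,
#'   `a`, `b`, `indirect`, `direct`, `proportion_signed_pct`,
#'   `proportion_pct`, `proportion_se_pct`, `ci_low_pct`, `ci_high_pct`,
#'   `classification`.
#' @export
mediated_proportion_table <- function(results) {
  cols <- c("exposure", "mediator", "outcome", "c", "a", "b", "indirect",
            "direct", "proportion_signed_pct", "proportion_pct",
            "proportion_se_pct", "ci_low_pct", "ci_high_pct",
            "classification")
  if (length(results) == 0) {
    out <- as.data.frame(setNames(replicate(length(cols), character(0),
                                            simplify = FALSE), cols))
    return(out)
  }
  out <- do.call(rbind, lapply(results, function(r) {
    stopifnot(inherits(r, "mr_mediation"))
    data.frame(exposure = r$exposure, mediator = r$mediator,
               outcome = r$outcome, c = r$c, a = r$a, b = r$b,
               indirect = r$indirect, direct = r$direct,
               proportion_signed_pct = 100 * r$proportion,
               proportion_pct = 100 * abs(r$proportion),
               proportion_se_pct = 100 * r$proportion_se,
               ci_low_pct = 100 * r$proportion_ci_low,
               ci_high_pct = 100 * r$proportion_ci_high,
               classification = r$classification,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
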