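# Causal-estimate container shared by all estimators. Effects are on the
# outcome scale per unit exposure; for binary outcomes that is log-odds, so
# exp(beta) is an odds ratio. The 95% interval uses the conventional 1.96
# normal multiplier throughout (summary-data MR convention: normal, not t,
# reference).
new_mr_estimate <- function(method, beta, se, n_snp, pvalue = NULL, ...) {
  if (is.null(pvalue)) {
    pvalue <- if (se > 0) 2 * pnorm(-abs(beta / se)) else as.numeric(beta == 0)
  }
  pvalue <- max(pvalue, .Machine$double.xmin)
  structure(list(method = method, beta = beta, se = se, pvalue = pvalue,
                 or = exp(beta), ci_low = exp(beta - 1.96 * se),
                 ci_high = exp(beta + 1.96 * se), n_snp = n_snp, ...),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("%s: beta = %.4g (SE %.4g), p = %.3g, OR = %.3f [%.3f, %.3f], %d SNP(s)\n",
              x$method, x$beta, x$se, x$pvalue, x$or, x$ci_low, x$ci_high,
              x$n_snp))
  invisible(x)
}

#' @export
as.data.frame.mr_estimate <- function(x, ...) {
  data.frame(method = x$method, n_snp = x$n_snp, beta = x$beta, se = x$se,
             pvalue = x$pvalue, or = x$or, ci_low = x$ci_low,
             ci_high = x$ci_high, stringsAsFactors = FALSE)
}

#' @export
coef.mr_estimate <- function(object, ...) setNames(object$beta, object$method)

pair_vectors <- function(pair) {
  stopifnot(inherits(pair, "harmonized_pair"))
  d <- pair$data
  list(bx = d$BETA_EXP, sx = d$SE_EXP, by = d$BETA_OUT, sy = d$SE_OUT,
       snp = d$SNP)
}

#' Wald ratio estimate for a single instrument
#'
#' The per-variant causal estimate: outcome beta divided by exposure beta,
#' with the first-order standard error `sy / |bx|` (exposure-side uncertainty
#' ignored, the standard summary-data convention).
#'
#' @param bx,by exposure and outcome per-allele effects for one variant.
#' @param sy outcome standard error.
#' @return An `mr_estimate` with method `"wald"`.
#' @export
mr_wald_ratio <- function(bx, by, sy) {
  if (bx == 0) stop("degenerate instrument: exposure beta is zero", call. = FALSE)
  new_mr_estimate("wald", beta = by / bx, se = sy / abs(bx), n_snp = 1L)
}

#' Inverse-variance weighted estimate
#'
#' Weighted least-squares regression of outcome betas on exposure betas
#' through the origin with weights 1 / se_outcome^2 — equivalently the
#' inverse-variance meta-analysis of per-variant Wald ratios. The fixed
#' model reports the nominal SE `1 / sqrt(sum(bx^2 / sy^2))`; the
#' multiplicative random-effects model inflates it by
#' `sqrt(max(1, Q / (n_snp - 1)))` where Q is Cochran's heterogeneity
#' statistic. The default picks random-multiplicative with three or more
#' instruments and fixed otherwise.
#'
#' @param pair a `harmonized_pair`.
#' @param model `"auto"`, `"fixed"` or `"random_multiplicative"`.
#' @return An `mr_estimate` (method `"ivw_fixed"` or `"ivw_random"`) with
#'   extra fields `Q`, `Q_df`, `Q_pvalue`.
#' @export
mr_ivw <- function(pair, model = c("auto", "fixed", "random_multiplicative")) {
  model <- match.arg(model)
  v <- pair_vectors(pair)
  n <- length(v$bx)
  if (n < 1) stop("no instruments", call. = FALSE)
  if (all(v$bx == 0)) stop("degenerate instruments: all exposure betas zero", call. = FALSE)
  if (n == 1) return(mr_wald_ratio(v$bx, v$by, v$sy))
  if (model == "auto") model <- if (n >= 3) "random_multiplicative" else "fixed"
  w <- 1 / v$sy^2
  sxx <- sum(w * v$bx^2)
  beta <- sum(w * v$bx * v$by) / sxx
  se_fixed <- sqrt(1 / sxx)
  q <- sum(w * (v$by - beta * v$bx)^2)
  q_df <- n - 1L
  q_p <- pchisq(q, df = q_df, lower.tail = FALSE)
  if (model == "fixed") {
    new_mr_estimate("ivw_fixed", beta = beta, se = se_fixed, n_snp = n,
                    Q = q, Q_df = q_df, Q_pvalue = q_p, model = model)
  } else {
    se <- se_fixed * sqrt(max(1, q / q_df))
    new_mr_estimate("ivw_random", beta = beta, se = se, n_snp = n,
                    Q = q, Q_df = q_df, Q_pvalue = q_p, model = model)
  }
}

#' MR-Egger regression
#'
#' Weighted least-squares of outcome betas on exposure betas with a free
#' intercept (weights 1 / se_outcome^2). Each variant is first re-signed so
#' its exposure beta is non-negative (the estimate depends on allele
#' orientation; this convention pins it down). The intercept and its p-value
#' form the directional-pleiotropy test; the slope is the
#' pleiotropy-adjusted causal estimate. Coefficient SEs are inflated by
#' `max(1, sigma)` where sigma^2 is the weighted residual mean square
#' (multiplicative random effects with a floor at the nominal SE); p-values
#' use the normal reference.
#'
#' @param pair a `harmonized_pair` with at least 3 variants.
#' @return A list of class `mr_egger` with `mr_estimate` elements `slope`
#'   (method `"egger_slope"`) and `intercept` (method `"egger_intercept"`).
#' @export
mr_egger <- function(pair) {
  v <- pair_vectors(pair)
  n <- length(v$bx)
  if (n < 3) stop("MR-Egger requires at least 3 instruments", call. = FALSE)
  flip <- sign(v$bx)
  flip[flip == 0] <- 1
  bx <- v$bx * flip
  by <- v$by * flip
  w <- 1 / v$sy^2
  # weighted normal equations for (intercept, slope)
  sw <- sum(w); swx <- sum(w * bx); swxx <- sum(w * bx^2)
  swy <- sum(w * by); swxy <- sum(w * bx * by)
  det <- sw * swxx - swx^2
  if (det <= 0) stop("degenerate design in MR-Egger", call. = FALSE)
  slope <- (sw * swxy - swx * swy) / det
  intercept <- (swxx * swy - swx * swxy) / det
  resid <- by - intercept - slope * bx
  sigma2 <- sum(w * resid^2) / (n - 2)
  infl <- max(1, sigma2)
  se_slope <- sqrt(infl * sw / det)
  se_intercept <- sqrt(infl * swxx / det)
  structure(list(
    slope = new_mr_estimate("egger_slope", beta = slope, se = se_slope,
                            n_snp = n),
    intercept = new_mr_estimate("egger_intercept", beta = intercept,
                                se = se_intercept, n_snp = n)),
    class = "mr_egger")
}

#' @export
print.mr_egger <- function(x, ...) {
  print(x$slope); print(x$intercept)
  invisible(x)
}

# Weighted 50th percentile with linear interpolation over cumulative
# normalized weights: sort ratios, set p_j = (cumsum(w) - w/2) / sum(w),
# interpolate the ratio at p = 0.5.
weighted_median_point <- function(x, w) {
  ord <- order(x)
  x <- x[ord]; w <- w[ord]
  p <- (cumsum(w) - 0.5 * w) / sum(w)
  if (0.5 <= p[1]) return(x[1])
  n <- length(x)
  if (0.5 >= p[n]) return(x[n])
  j <- max(which(p <= 0.5))
  if (p[j] == 0.5) return(x[j])
  x[j] + (x[j + 1] - x[j]) * (0.5 - p[j]) / (p[j + 1] - p[j])
}

median_engine <- function(pair, weights = c("inverse_variance", "uniform"),
                          n_boot = 1000, seed = NULL, method_label) {
  weights <- match.arg(weights)
  v <- pair_vectors(pair)
  keep <- v$bx != 0
  if (any(!keep)) {
    warning(sprintf("%d variant(s) with zero exposure beta excluded", sum(!keep)))
  }
  if (sum(keep) == 0) stop("all instruments degenerate (exposure beta zero)", call. = FALSE)
  bx <- v$bx[keep]; sx <- v$sx[keep]; by <- v$by[keep]; sy <- v$sy[keep]
  n <- length(bx)
  if (n < 3) stop("median estimators require at least 3 instruments", call. = FALSE)
  stopifnot(n_boot >= 100)
  if (is.null(seed)) stop("a bootstrap seed is required for reproducibility", call. = FALSE)

  ratio_w <- function(b_x, b_y) {
    r <- b_y / b_x
    w <- if (weights == "inverse_variance") b_x^2 / sy^2 else rep(1, length(r))
    weighted_median_point(r, w)
  }
  est <- ratio_w(bx, by)

  boot <- local_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      ratio_w(rnorm(n, bx, sx), rnorm(n, by, sy))
    }, numeric(1))
  })
  se <- stats::sd(boot)
  new_mr_estimate(method_label, beta = est, se = se, n_snp = n,
                  n_boot = n_boot, seed = seed)
}

#' Weighted median estimate
#'
#' The weighted 50th percentile of per-variant Wald ratios, with weights the
#' inverse first-order variance of each ratio (`bx^2 / sy^2`). Consistent
#' when at least half of the total weight comes from valid instruments, so
#' it tolerates some invalid SNPs. The SE comes from a seeded parametric
#' bootstrap that resamples exposure and outcome betas from normals with
#' their reported SEs.
#'
#' @param pair a `harmonized_pair` with at least 3 usable variants.
#' @param n_boot bootstrap replicates (at least 100; default 1000).
#' @param seed integer seed for the bootstrap (required; the global RNG
#'   state is restored afterwards).
#' @return An `mr_estimate` with method `"weighted_median"`.
#' @export
mr_weighted_median <- function(pair, n_boot = 1000, seed = NULL) {
  median_engine(pair, "inverse_variance", n_boot, seed, "weighted_median")
}

#' Simple median estimate
#'
#' As [mr_weighted_median()] but with uniform weights: the plain median of
#' per-variant Wald ratios (midpoint convention for even counts).
#'
#' @inheritParams mr_weighted_median
#' @return An `mr_estimate` with method `"simple_median"`.
#' @export
mr_simple_median <- function(pair, n_boot = 1000, seed = NULL) {
  median_engine(pair, "uniform", n_boot, seed, "simple_median")
}

#' Fit the univariable two-sample MR estimator suite
#'
#' Runs IVW (the primary estimator), MR-Egger, weighted median and simple
#' median on one harmonized exposure-outcome pair, together with the
#' sensitivity battery (Cochran's Q, Egger intercept, leave-one-out). With a
#' single instrument the Wald ratio is reported alone.
#'
#' @param pair a `harmonized_pair`.
#' @param methods subset of `c("ivw", "egger", "weighted_median",
#'   "simple_median")`.
#' @param model IVW model passed to [mr_ivw()].
#' @param n_boot,seed bootstrap controls for the median estimators.
#' @return An object of class `mr_fit`: list with `estimates` (named list of
#'   `mr_estimate`), `egger` (full `mr_egger` object or NULL), `pair`, and
#'   the call. `summary()` adds heterogeneity, pleiotropy and leave-one-out
#'   diagnostics; `as.data.frame()` gives the tidy results table.
#' @examples
#' set.seed(1)
#' bx <- runif(8, 0.05, 0.2)
#' by <- 0.3 * bx + rnorm(8, 0, 0.01)
#' pair <- mrmediate:::pair_from_vectors(bx, rep(0.01, 8), by, rep(0.01, 8))
#' fit <- mr_fit(pair, seed = 42)
#' fit
#' @export
mr_fit <- function(pair,
                   methods = c("ivw", "egger", "weighted_median", "simple_median"),
                   model = "auto", n_boot = 1000, seed = NULL) {
  methods <- match.arg(methods, several.ok = TRUE)
  v <- pair_vectors(pair)
  n <- length(v$bx)
  if (n == 0) stop("no instruments in pair", call. = FALSE)
  estimates <- list()
  egger_obj <- NULL
  if (n == 1) {
    estimates$wald <- mr_wald_ratio(v$bx, v$by, v$sy)
  } else {
    if ("ivw" %in% methods) {
      est <- mr_ivw(pair, model = model)
      estimates[[est$method]] <- est
    }
    if ("egger" %in% methods && n >= 3) {
      egger_obj <- mr_egger(pair)
      estimates$egger_slope <- egger_obj$slope
      estimates$egger_intercept <- egger_obj$intercept
    }
    if ("weighted_median" %in% methods && n >= 3) {
      estimates$weighted_median <- mr_weighted_median(pair, n_boot, seed)
    }
    if ("simple_median" %in% methods && n >= 3) {
      estimates$simple_median <- mr_simple_median(pair, n_boot, seed)
    }
  }
  structure(list(estimates = estimates, egger = egger_obj, pair = pair,
                 n_snp = n, call = match.call()),
            class = "mr_fit")
}

#' @export
print.mr_fit <- function(x, ...) {
  cat(sprintf("Two-sample MR: %s -> %s (%d instruments)\n",
              x$pair$exposure_name, x$pair$outcome_name, x$n_snp))
  for (est in x$estimates) print(est)
  invisible(x)
}

#' @export
as.data.frame.mr_fit <- function(x, ...) {
  out <- do.call(rbind, lapply(x$estimates, as.data.frame))
  out <- cbind(exposure = x$pair$exposure_name,
               outcome = x$pair$outcome_name, out)
  rownames(out) <- NULL
  out
}

#' @export
coef.mr_fit <- function(object, ...) {
  vapply(object$estimates, function(e) e$beta, numeric(1))
}

#' @export
confint.mr_fit <- function(object, parm, level = 0.95, ...) {
  z <- qnorm(1 - (1 - level) / 2)
  betas <- coef(object)
  ses <- vapply(object$estimates, function(e) e$se, numeric(1))
  out <- cbind(betas - z * ses, betas + z * ses)
  colnames(out) <- sprintf("%g %%", c((1 - level) / 2, 1 - (1 - level) / 2) * 100)
  if (!missing(parm)) out <- out[parm, , drop = FALSE]
  out
}

#' @export
summary.mr_fit <- function(object, ...) {
  pair <- object$pair
  n <- object$n_snp
  q <- if (n >= 2) cochran_q(pair) else NULL
  loo <- if (n >= 3) leave_one_out(pair) else NULL
  structure(list(fit = object, q = q, loo = loo), class = "summary.mr_fit")
}

#' @export
print.summary.mr_fit <- function(x, ...) {
  print(x$fit)
  if (!is.null(x$q)) {
    cat(sprintf("Heterogeneity: Q = %.3f on %d df, p = %.3g\n",
                x$q$q, x$q$df, x$q$pvalue))
  }
  if (!is.null(x$fit$egger)) {
    ei <- x$fit$egger$intercept
    cat(sprintf("Pleiotropy (Egger intercept): %.4g, p = %.3g\n",
                ei$beta, ei$pvalue))
  }
  if (!is.null(x$loo)) {
    n_flag <- sum(x$loo$flagged)
    cat(sprintf("Leave-one-out: %d of %d exclusions flagged\n",
                n_flag, nrow(x$loo)))
  }
  invisible(x)
}

#' @export
plot.mr_fit <- function(x, ...) {
  v <- pair_vectors(x$pair)
  flip <- sign(v$bx); flip[flip == 0] <- 1
  bx <- v$bx * flip; by <- v$by * flip; sy <- v$sy; sx <- v$sx
  plot(bx, by, pch = 19,
       xlab = sprintf("per-allele effect on %s", x$pair$exposure_name),
       ylab = sprintf("per-allele effect on %s", x$pair$outcome_name),
       main = "Instrument effects with fitted causal slopes", ...)
  segments(bx, by - 1.96 * sy, bx, by + 1.96 * sy, col = "grey60")
  segments(bx - 1.96 * sx, by, bx + 1.96 * sx, by, col = "grey60")
  cols <- c(ivw_fixed = "black", ivw_random = "black",
            weighted_median = "forestgreen", simple_median = "orange")
  shown <- character(0); shown_col <- character(0)
  for (nm in names(x$estimates)) {
    if (nm %in% names(cols)) {
      abline(0, x$estimates[[nm]]$beta, col = cols[nm], lwd = 2)
      shown <- c(shown, nm); shown_col <- c(shown_col, cols[nm])
    }
  }
  if (!is.null(x$egger)) {
    abline(x$egger$intercept$beta, x$egger$slope$beta,
           col = "steelblue", lwd = 2, lty = 2)
    shown <- c(shown, "egger"); shown_col <- c(shown_col, "steelblue")
  }
  if (length(shown) > 0) {
    legend("topleft", legend = shown, col = shown_col, lwd = 2, bty = "n")
  }
  invisible(x)
}

#' @export
residuals.mr_fit <- function(object, method = NULL, ...) {
  v <- pair_vectors(object$pair)
  ests <- object$estimates
  if (is.null(method)) {
    method <- intersect(c("ivw_random", "ivw_fixed", "wald"), names(ests))[1]
  }
  if (is.na(method) || !method %in% names(ests)) {
    stop("no such fitted method", call. = FALSE)
  }
  setNames(v$by - ests[[method]]$beta * v$bx, v$snp)
}
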