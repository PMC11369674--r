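#' Cochran's Q heterogeneity test
#'
#' Q = sum over instruments of w_j (r_j - beta_ivw)^2, where r_j = by_j/bx_j
#' are per-variant Wald ratios, w_j = bx_j^2 / sy_j^2 their first-order
#' inverse variances (the IVW ratio weights), and beta_ivw the fixed-effect
#' IVW estimate (the standard centering). The p-value uses a chi-square
#' reference with n_snp - 1 degrees of freedom; small p signals
#' heterogeneity among the per-variant causal estimates.
#'
#' @param pair a `harmonized_pair` with at least 2 variants.
#' @return A list of class `cochran_q` with elements `q`, `df`, `pvalue`.
#' @export
cochran_q <- function(pair) {
  v <- pair_vectors(pair)
  n <- length(v$bx)
  if (n < 2) stop("Cochran's Q requires at least 2 instruments", call. = FALSE)
  fit <- mr_ivw(pair, model = "fixed")
  structure(list(q = fit$Q, df = fit$Q_df, pvalue = fit$Q_pvalue),
            class = "cochran_q")
}

#' @export
print.cochran_q <- function(x, ...) {
  cat(sprintf("Cochran's Q = %.4f on %d df, p = %.4g\n", x$q, x$df, x$pvalue))
  invisible(x)
}

#' Leave-one-out sensitivity analysis
#'
#' Refits the IVW estimator excluding each instrument in turn. A row is
#' flagged when the re-estimate changes sign relative to the full-sample
#' estimate or when it crosses nominal significance (p passing `alpha` in
#' either direction) — either indicates the result leans on that single
#' variant.
#'
#' @param pair a `harmonized_pair` with at least 3 variants.
#' @param model IVW model (default `"auto"`, matching [mr_ivw()]).
#' @param alpha significance level used for the crossing flag.
#' @return data.frame with columns `left_out`, `beta`, `se`, `pvalue`,
#'   `sign_change`, `significance_change`, `flagged`; one row per variant.
#' @export
leave_one_out <- function(pair, model = "auto", alpha = 0.05) {
  v <- pair_vectors(pair)
  n <- length(v$bx)
  if (n < 3) stop("leave-one-out requires at least 3 instruments", call. = FALSE)
  full <- mr_ivw(pair, model = model)
  rows <- lapply(seq_len(n), function(i) {
    sub <- pair
    sub$data <- pair$data[-i, , drop = FALSE]
    est <- mr_ivw(sub, model = model)
    data.frame(left_out = v$snp[i], beta = est$beta, se = est$se,
               pvalue = est$pvalue, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$sign_change <- sign(out$beta) != sign(full$beta)
  out$significance_change <- (out$pvalue < alpha) != (full$pvalue < alpha)
  out$flagged <- out$sign_change | out$significance_change
  rownames(out) <- NULL
  out
}
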