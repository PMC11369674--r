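#' Assemble a multivariable MR input
#'
#' Selects instruments per exposure (significance threshold plus optional LD
#' clumping), unions them, deduplicates by variant id, and aligns every
#' exposure and the outcome to a common effect-allele frame (the frame of the
#' first exposure carrying each variant). Variants missing from any trait
#' are dropped and logged.
#'
#' @param exposures named list of `sumstats` objects (at least 2).
#' @param outcome a `sumstats` object.
#' @param p_threshold per-exposure instrument significance threshold.
#' @param ld optional `ld_matrix` for clumping.
#' @param r2_max,window_kb clumping parameters (used when `ld` is given).
#' @param palindrome_eaf_limit passed to [harmonize()].
#' @return An object of class `mvmr_input`: list with `variant_ids`,
#'   `beta_exposures` / `se_exposures` (variants x exposures matrices),
#'   `beta_outcome`, `se_outcome`, `exposure_names`, `dropped`.
#' @export
build_mvmr_input <- function(exposures, outcome, p_threshold = 5e-8,
                             ld = NULL, r2_max = 0.001, window_kb = 5000,
                             palindrome_eaf_limit = 0.42) {
  stopifnot(is.list(exposures), length(exposures) >= 2,
            inherits(outcome, "sumstats"))
  if (is.null(names(exposures)) || any(names(exposures) == "")) {
    names(exposures) <- vapply(exposures, function(s) s$trait_name, character(1))
  }
  selected <- lapply(exposures, function(s) {
    sel <- select_significant(s, p_threshold)
    if (!is.null(ld) && nrow(sel$data) > 0) sel <- clump(sel, ld, r2_max, window_kb)
    sel
  })
  # reference allele frame: first exposure contributing each union variant
  ref <- do.call(rbind, lapply(selected, function(s) s$data))
  ref <- ref[!duplicated(ref$SNP), , drop = FALSE]
  if (nrow(ref) == 0) stop("no instruments survive selection for any exposure",
                           call. = FALSE)
  ref_set <- sumstats(ref, trait_name = "mvmr_reference")

  dropped <- data.frame(SNP = character(), trait = character(),
                        reason = character(), stringsAsFactors = FALSE)
  align <- function(trait) {
    pr <- harmonize(ref_set, trait, palindrome_eaf_limit)
    miss <- setdiff(ref_set$data$SNP, pr$data$SNP)
    reasons <- pr$dropped$reason[match(miss, pr$dropped$SNP)]
    reasons[is.na(reasons)] <- "absent_from_trait"
    list(pair = pr,
         dropped = data.frame(SNP = miss,
                              trait = rep(trait$trait_name, length(miss)),
                              reason = reasons, stringsAsFactors = FALSE))
  }
  aligned_exp <- lapply(exposures, align)
  aligned_out <- align(outcome)
  for (a in c(aligned_exp, list(aligned_out))) dropped <- rbind(dropped, a$dropped)

  keep <- Reduce(intersect, c(lapply(aligned_exp, function(a) a$pair$data$SNP),
                              list(aligned_out$pair$data$SNP)))
  if (length(keep) == 0) stop("no variant present in every trait", call. = FALSE)
  keep <- ref_set$data$SNP[ref_set$data$SNP %in% keep]

  get_cols <- function(a, what) {
    d <- a$pair$data[match(keep, a$pair$data$SNP), ]
    d[[what]]
  }
  bX <- vapply(aligned_exp, get_cols, numeric(length(keep)), what = "BETA_OUT")
  sX <- vapply(aligned_exp, get_cols, numeric(length(keep)), what = "SE_OUT")
  if (is.null(dim(bX))) { bX <- matrix(bX, nrow = length(keep)); sX <- matrix(sX, nrow = length(keep)) }
  colnames(bX) <- colnames(sX) <- names(exposures)
  if (nrow(dropped) > 0) {
    message(sprintf("build_mvmr_input: %d variant-trait pair(s) dropped", nrow(dropped)))
  }
  structure(list(variant_ids = keep,
                 beta_exposures = bX, se_exposures = sX,
                 beta_outcome = get_cols(aligned_out, "BETA_OUT"),
                 se_outcome = get_cols(aligned_out, "SE_OUT"),
                 exposure_names = names(exposures),
                 outcome_name = outcome$trait_name,
                 dropped = dropped),
            class = "mvmr_input")
}

#' Multivariable MR by inverse-variance weighted regression
#'
#' Weighted least-squares regression of outcome betas on the matrix of
#' exposure betas without intercept, weights 1 / se_outcome^2. Each
#' coefficient is the direct effect of that exposure on the outcome holding
#' the other exposures fixed. SEs come from the weighted normal equations
#' (fixed-effect); measurement error in exposure betas is ignored, the
#' standard summary-data MVMR convention. P-values use the normal reference.
#'
#' @param input an `mvmr_input` (or a list with `beta_exposures`,
#'   `se_exposures`, `beta_outcome`, `se_outcome`, `exposure_names`).
#' @return An object of class `mvmr_fit`: named list of `mr_estimate`
#'   objects (method `"mvmr_ivw"`), one per exposure, plus the input.
#' @export
mvmr_fit <- function(input) {
  X <- as.matrix(input$beta_exposures)
  y <- input$beta_outcome
  sy <- input$se_outcome
  nms <- input$exposure_names
  if (is.null(nms)) nms <- colnames(X)
  p <- ncol(X)
  n <- nrow(X)
  stopifnot(length(y) == n, length(sy) == n)
  if (n <= p) stop("need more variants than exposures", call. = FALSE)
  w <- 1 / sy^2
  # an exposure with no instrument signal (all-zero column) contributes
  # nothing: coefficient 0 with infinite SE, fitted on the remaining columns
  zero_col <- colSums(X != 0) == 0
  act <- which(!zero_col)
  if (length(act) == 0) stop("all exposure-beta columns are zero", call. = FALSE)
  Xa <- X[, act, drop = FALSE]
  qr_x <- qr(Xa * sqrt(w))
  if (qr_x$rank < length(act)) {
    bad <- nms[act][qr_x$pivot[(qr_x$rank + 1):length(act)]]
    stop(sprintf("collinear exposure-beta columns: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  XtWX <- crossprod(Xa, Xa * w)
  XtWy <- crossprod(Xa, y * w)
  beta <- rep(0, p)
  se <- rep(Inf, p)
  beta[act] <- solve(XtWX, XtWy)[, 1]
  se[act] <- sqrt(diag(solve(XtWX)))
  ests <- lapply(seq_len(p), function(j) {
    new_mr_estimate("mvmr_ivw", beta = beta[j], se = se[j], n_snp = n,
                    exposure = nms[j])
  })
  names(ests) <- nms
  structure(list(estimates = ests, input = input, n_snp = n),
            class = "mvmr_fit")
}

#' @export
print.mvmr_fit <- function(x, ...) {
  cat(sprintf("Multivariable MR (IVW weighted regression): %d exposures, %d variants\n",
              length(x$estimates), x$n_snp))
  for (nm in names(x$estimates)) {
    e <- x$estimates[[nm]]
    cat(sprintf("  %s: beta = %.4g (SE %.4g), p = %.3g, OR = %.3f [%.3f, %.3f]\n",
                nm, e$beta, e$se, e$pvalue, e$or, e$ci_low, e$ci_high))
  }
  invisible(x)
}

#' @export
coef.mvmr_fit <- function(object, ...) {
  vapply(object$estimates, function(e) e$beta, numeric(1))
}

#' @export
as.data.frame.mvmr_fit <- function(x, ...) {
  out <- do.call(rbind, lapply(names(x$estimates), function(nm) {
    cbind(exposure = nm, as.data.frame(x$estimates[[nm]]))
  }))
  rownames(out) <- NULL
  out
}
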