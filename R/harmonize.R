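#' Allele-harmonize exposure and outcome summary statistics
#'
#' Two-sample MR requires the outcome effect for every instrument to be
#' expressed per copy of the exposure's effect allele. Variants are matched by
#' variant identifier; when the outcome's effect/other alleles are swapped
#' relative to the exposure, the outcome beta's sign is flipped and its EAF
#' replaced by 1 - EAF. Strand-ambiguous (palindromic A/T or C/G) variants are
#' retained only when both allele frequencies fall on the same side of 0.5
#' and both lie outside `[palindrome_eaf_limit, 1 - palindrome_eaf_limit]`
#' (so the effect allele can be identified from frequency alone); otherwise
#' they are dropped with reason `"palindromic_ambiguous"`. Allele pairs that
#' cannot be reconciled are dropped with reason `"allele_mismatch"`.
#'
#' Harmonization is idempotent: harmonizing an already-harmonized pair
#' changes nothing.
#'
#' @param exposure,outcome `sumstats` objects.
#' @param palindrome_eaf_limit frequency band half-width defining ambiguity
#'   for palindromic variants (default 0.42: variants with aligned EAF in
#'   (0.42, 0.58) on either trait are considered unresolvable).
#' @return An object of class `harmonized_pair`: list with `exposure_name`,
#'   `outcome_name`, `data` (aligned data.frame with exposure and outcome
#'   effect columns and a `FLIPPED` flag) and `dropped` (data.frame of
#'   variant id and reason).
#' @export
harmonize <- function(exposure, outcome, palindrome_eaf_limit = 0.42) {
  stopifnot(inherits(exposure, "sumstats"), inherits(outcome, "sumstats"))
  stopifnot(palindrome_eaf_limit > 0, palindrome_eaf_limit < 0.5)
  ex <- exposure$data
  ou <- outcome$data
  shared <- intersect(ex$SNP, ou$SNP)
  if (length(shared) == 0) {
    stop(sprintf("no shared variants between '%s' and '%s'",
                 exposure$trait_name, outcome$trait_name), call. = FALSE)
  }
  ex <- ex[match(shared, ex$SNP), ]
  ou <- ou[match(shared, ou$SNP), ]

  direct <- ex$EA == ou$EA & ex$OA == ou$OA
  swapped <- ex$EA == ou$OA & ex$OA == ou$EA
  mismatch <- !direct & !swapped

  beta_out <- ifelse(swapped, -ou$BETA, ou$BETA)
  eaf_out <- ifelse(swapped, 1 - ou$EAF, ou$EAF)

  comp <- c(A = "T", T = "A", C = "G", G = "C")
  palindromic <- !mismatch & nchar(ex$EA) == 1 & nchar(ex$OA) == 1 &
    !is.na(comp[ex$EA]) & comp[ex$EA] == ex$OA
  pal_ok <- !is.na(ex$EAF) & !is.na(eaf_out) &
    sign(ex$EAF - 0.5) == sign(eaf_out - 0.5) &
    pmin(ex$EAF, 1 - ex$EAF) < palindrome_eaf_limit &
    pmin(eaf_out, 1 - eaf_out) < palindrome_eaf_limit
  pal_drop <- palindromic & !pal_ok

  reason <- rep(NA_character_, length(shared))
  reason[mismatch] <- "allele_mismatch"
  reason[pal_drop] <- "palindromic_ambiguous"
  keep <- is.na(reason)

  dropped <- data.frame(SNP = shared[!keep], reason = reason[!keep],
                        stringsAsFactors = FALSE)
  dat <- data.frame(
    SNP = shared[keep], CHR = ex$CHR[keep], POS = ex$POS[keep],
    EA = ex$EA[keep], OA = ex$OA[keep],
    EAF_EXP = ex$EAF[keep], BETA_EXP = ex$BETA[keep], SE_EXP = ex$SE[keep],
    P_EXP = ex$P[keep], N_EXP = ex$N[keep],
    EAF_OUT = eaf_out[keep], BETA_OUT = beta_out[keep], SE_OUT = ou$SE[keep],
    P_OUT = ou$P[keep], N_OUT = ou$N[keep],
    FLIPPED = swapped[keep],
    stringsAsFactors = FALSE)
  rownames(dat) <- NULL
  structure(list(exposure_name = exposure$trait_name,
                 outcome_name = outcome$trait_name,
                 data = dat, dropped = dropped,
                 palindrome_eaf_limit = palindrome_eaf_limit),
            class = "harmonized_pair")
}

#' @export
print.harmonized_pair <- function(x, ...) {
  cat(sprintf("Harmonized pair: %s (exposure) -> %s (outcome)\n",
              x$exposure_name, x$outcome_name))
  cat(sprintf("  %d aligned variants (%d allele-flipped); %d dropped\n",
              nrow(x$data), sum(x$data$FLIPPED), nrow(x$dropped)))
  if (nrow(x$dropped) > 0) {
    tab <- table(x$dropped$reason)
    cat("  drop reasons:",
        paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' @export
nobs.harmonized_pair <- function(object, ...) nrow(object$data)

# Reconstruct the two trait-level sets from a pair (internal; used to verify
# idempotence and to re-enter pipeline stages that expect sumstats objects).
pair_to_sets <- function(pair) {
  d <- pair$data
  expo <- sumstats(data.frame(SNP = d$SNP, CHR = d$CHR, POS = d$POS,
                              EA = d$EA, OA = d$OA, EAF = d$EAF_EXP,
                              BETA = d$BETA_EXP, SE = d$SE_EXP, P = d$P_EXP,
                              N = d$N_EXP, stringsAsFactors = FALSE),
                   pair$exposure_name)
  outc <- sumstats(data.frame(SNP = d$SNP, CHR = d$CHR, POS = d$POS,
                              EA = d$EA, OA = d$OA, EAF = d$EAF_OUT,
                              BETA = d$BETA_OUT, SE = d$SE_OUT, P = d$P_OUT,
                              N = d$N_OUT, stringsAsFactors = FALSE),
                   pair$outcome_name)
  list(exposure = expo, outcome = outc)
}

# Minimal constructor for a pair from bare effect vectors (internal; used by
# estimator tests and the simulator-driven screens where alleles are already
# aligned by construction).
pair_from_vectors <- function(bx, sx, by, sy, snp = NULL,
                              exposure_name = "exposure",
                              outcome_name = "outcome") {
  n <- length(bx)
  stopifnot(length(sx) == n, length(by) == n, length(sy) == n)
  if (is.null(snp)) snp <- sprintf("rs%05d", seq_len(n))
  dat <- data.frame(SNP = snp, CHR = NA_character_, POS = NA_real_,
                    EA = "A", OA = "G",
                    EAF_EXP = NA_real_, BETA_EXP = bx, SE_EXP = sx,
                    P_EXP = 2 * pnorm(-abs(bx / sx)), N_EXP = NA_real_,
                    EAF_OUT = NA_real_, BETA_OUT = by, SE_OUT = sy,
                    P_OUT = 2 * pnorm(-abs(by / sy)), N_OUT = NA_real_,
                    FLIPPED = FALSE, stringsAsFactors = FALSE)
  structure(list(exposure_name = exposure_name, outcome_name = outcome_name,
                 data = dat,
                 dropped = data.frame(SNP = character(), reason = character(),
                                      stringsAsFactors = FALSE),
                 palindrome_eaf_limit = NA_real_),
            class = "harmonized_pair")
}
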