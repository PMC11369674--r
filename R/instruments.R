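#' Construct an LD matrix object
#'
#' Pairwise squared correlations (r squared) between candidate instruments,
#' with base-pair positions used by window-based clumping.
#'
#' @param r2 square symmetric numeric matrix with unit diagonal and entries
#'   in \[0, 1\]; dimnames give variant ids (or pass `variant_ids`).
#' @param positions integer vector of base-pair positions, one per variant.
#' @param variant_ids character vector of ids (defaults to `rownames(r2)`).
#' @param chromosomes optional chromosome labels, one per variant.
#' @return An object of class `ld_matrix`.
#' @export
ld_matrix <- function(r2, positions, variant_ids = rownames(r2),
                      chromosomes = NULL) {
  r2 <- as.matrix(r2)
  if (is.null(variant_ids)) stop("variant ids required", call. = FALSE)
  stopifnot(nrow(r2) == ncol(r2), length(positions) == nrow(r2),
            length(variant_ids) == nrow(r2))
  if (max(abs(r2 - t(r2))) > 1e-8) stop("r2 matrix must be symmetric", call. = FALSE)
  if (any(abs(diag(r2) - 1) > 1e-8)) stop("r2 diagonal must be 1", call. = FALSE)
  if (any(r2 < -1e-12 | r2 > 1 + 1e-12)) stop("r2 entries must lie in [0,1]", call. = FALSE)
  dimnames(r2) <- list(variant_ids, variant_ids)
  if (is.null(chromosomes)) chromosomes <- rep(NA_character_, length(variant_ids))
  structure(list(variant_ids = variant_ids, r2 = r2,
                 positions = as.numeric(positions),
                 chromosomes = as.character(chromosomes)),
            class = "ld_matrix")
}

#' @export
print.ld_matrix <- function(x, ...) {
  cat(sprintf("LD matrix: %d variants; mean off-diagonal r2 = %.4g\n",
              length(x$variant_ids),
              if (length(x$variant_ids) > 1)
                mean(x$r2[upper.tri(x$r2)]) else 0))
  invisible(x)
}

#' Read an LD matrix from a TSV file
#'
#' Two layouts are supported. `format = "square"`: a square matrix with a
#' header row and first column both holding variant ids. `format = "long"`:
#' three columns `id1`, `id2`, `r2`; unlisted pairs default to r2 = 0 and the
#' matrix is symmetrized. Positions are taken from `positions` (named by
#' variant id) since LD files rarely carry coordinates.
#'
#' @param path TSV file path.
#' @param format `"square"` or `"long"`.
#' @param positions named numeric vector of base-pair positions.
#' @param chromosomes optional named chromosome vector.
#' @return An `ld_matrix` object.
#' @export
read_ld_matrix <- function(path, format = c("square", "long"),
                           positions, chromosomes = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (format == "square") {
    raw <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                      stringsAsFactors = FALSE)
    ids <- as.character(raw[[1]])
    m <- as.matrix(raw[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    dimnames(m) <- list(ids, colnames(raw)[-1])
    m <- m[, ids, drop = FALSE]
  } else {
    raw <- read.delim(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
    ids <- unique(c(raw$id1, raw$id2))
    m <- diag(1, length(ids))
    dimnames(m) <- list(ids, ids)
    for (i in seq_len(nrow(raw))) {
      m[raw$id1[i], raw$id2[i]] <- raw$r2[i]
      m[raw$id2[i], raw$id1[i]] <- raw$r2[i]
    }
  }
  pos <- positions[ids]
  if (any(is.na(pos))) stop("positions missing for some LD variants", call. = FALSE)
  chr <- if (is.null(chromosomes)) NULL else chromosomes[ids]
  ld_matrix(m, positions = pos, variant_ids = ids, chromosomes = chr)
}

#' Select genome-wide-significant variants
#'
#' Returns the subset of a summary-statistics set with p-value strictly below
#' the threshold (conventionally 5e-8), preserving row order.
#'
#' @param x a `sumstats` object.
#' @param p_threshold significance threshold in (0, 1\].
#' @return A `sumstats` object with the retained rows.
#' @export
select_significant <- function(x, p_threshold = 5e-8) {
  stopifnot(inherits(x, "sumstats"), p_threshold > 0, p_threshold <= 1)
  out <- x
  out$data <- x$data[x$data$P < p_threshold, , drop = FALSE]
  rownames(out$data) <- NULL
  out$n_dropped[] <- 0L
  out
}

#' Greedy LD clumping
#'
#' Repeatedly keeps the remaining variant with the smallest p-value, then
#' discards all remaining variants on the same chromosome within `window_kb`
#' kilobases having r squared greater than `r2_max` with it (the standard
#' clumping rule, e.g. r2 = 0.001 within 5000 kb). Ties on p-value are broken
#' by chromosome, then position, then variant id, so the result does not
#' depend on input row order. Cross-chromosome pairs are never clumped.
#'
#' @param candidates a `sumstats` object (typically already thresholded).
#' @param ld an `ld_matrix` covering every candidate.
#' @param r2_max maximum permitted r squared between retained variants within
#'   the window.
#' @param window_kb window half-width in kilobases.
#' @return A `sumstats` object with kept variants sorted by chromosome and
#'   position.
#' @export
clump <- function(candidates, ld, r2_max = 0.001, window_kb = 5000) {
  stopifnot(inherits(candidates, "sumstats"), inherits(ld, "ld_matrix"))
  d <- candidates$data
  if (nrow(d) == 0) return(candidates)
  missing_ld <- setdiff(d$SNP, ld$variant_ids)
  if (length(missing_ld) > 0) {
    stop(sprintf("candidate variant(s) absent from LD matrix: %s",
                 paste(missing_ld, collapse = ", ")), call. = FALSE)
  }
  idx <- match(d$SNP, ld$variant_ids)
  r2 <- ld$r2[idx, idx, drop = FALSE]
  pos <- d$POS
  chr <- d$CHR
  # deterministic priority: p, then chr, then pos, then id
  ord <- order(d$P, chr, pos, d$SNP)
  alive <- rep(TRUE, nrow(d))
  kept <- integer(0)
  for (i in ord) {
    if (!alive[i]) next
    kept <- c(kept, i)
    alive[i] <- FALSE
    conflict <- alive & chr == chr[i] &
      abs(pos - pos[i]) <= window_kb * 1000 &
      r2[i, ] > r2_max
    conflict[is.na(conflict)] <- FALSE
    alive[conflict] <- FALSE
  }
  out <- candidates
  out$data <- d[kept[order(chr[kept], pos[kept], d$SNP[kept])], , drop = FALSE]
  rownames(out$data) <- NULL
  out
}

#' Per-variant variance explained in the exposure
#'
#' Computes the share of exposure variance attributable to one variant from
#' its effect size, allele frequency and sample size, using
#' SD = SE * sqrt(N) as the phenotypic scale. Mode `"squared"` evaluates
#' 2 * MAF * (1 - MAF) * (beta / SD)^2, the dimensionally consistent variance
#' share. Mode `"paper_verbatim"` evaluates 2 * MAF * (1 - MAF) * (beta / SD)
#' without the square, reproducing a formula sometimes printed in the
#' applied literature; it is kept so published arithmetic can be replayed
#' exactly, never silently corrected.
#'
#' @param beta per-allele effect estimate.
#' @param se its standard error (> 0).
#' @param eaf effect-allele frequency in (0, 1); MAF = min(eaf, 1 - eaf).
#' @param n GWAS sample size.
#' @param mode `"squared"` (default) or `"paper_verbatim"`.
#' @return Numeric vector of variance shares.
#' @export
variance_explained <- function(beta, se, eaf, n,
                               mode = c("squared", "paper_verbatim")) {
  mode <- match.arg(mode)
  if (any(is.na(eaf)) || any(is.na(n))) {
    stop("eaf and n are required to compute variance explained", call. = FALSE)
  }
  stopifnot(all(se > 0), all(eaf > 0 & eaf < 1), all(n > 0))
  maf <- pmin(eaf, 1 - eaf)
  sd_trait <- se * sqrt(n)
  ratio <- beta / sd_trait
  if (mode == "squared") 2 * maf * (1 - maf) * ratio^2
  else 2 * maf * (1 - maf) * ratio
}

#' Instrument-strength F statistic
#'
#' F = ((n - k - 1) / k) * (r2 / (1 - r2)), where n is the exposure GWAS
#' sample size, k the number of instruments, and r2 the variance they
#' explain. F > 10 is the conventional bar for minimal weak-instrument bias.
#'
#' @param r2 variance explained, in \[0, 1).
#' @param n exposure sample size (n > k + 1).
#' @param k number of instruments (k = 1 for a per-variant F).
#' @return Numeric F values.
#' @export
f_statistic <- function(r2, n, k = 1) {
  stopifnot(all(k >= 1), all(n > k + 1))
  if (any(r2 < 0 | r2 >= 1)) stop("r2 must lie in [0, 1)", call. = FALSE)
  ((n - k - 1) / k) * (r2 / (1 - r2))
}

#' Build an instrument set with strength diagnostics
#'
#' For each variant in a (selected, clumped) set, computes the variance
#' explained and a per-variant F statistic (k = 1 convention); also reports
#' the joint F over the whole set (k = set size, summed r2) since both
#' per-variant and set-level readings of instrument strength appear in
#' practice.
#'
#' @param x a `sumstats` object with EAF and N available.
#' @param mode variance-explained mode passed to [variance_explained()].
#' @return An object of class `instrument_set`: list with `variant_ids`,
#'   `r2_explained`, `f_stat` (per-variant), `k`, `n_exposure`, `joint_r2`,
#'   `joint_f`, and the underlying `data`.
#' @export
instrument_strength <- function(x, mode = "squared") {
  stopifnot(inherits(x, "sumstats"))
  d <- x$data
  usable <- !is.na(d$EAF) & !is.na(d$N)
  if (any(!usable)) {
    warning(sprintf("%d variant(s) lack EAF or N; excluded from r2/F", sum(!usable)))
    d <- d[usable, , drop = FALSE]
  }
  n_exp <- if (nrow(d) > 0) max(d$N) else NA_real_
  r2 <- if (nrow(d) > 0)
    variance_explained(d$BETA, d$SE, d$EAF, d$N, mode = mode) else numeric(0)
  f_per <- if (nrow(d) > 0) f_statistic(r2, n = d$N, k = 1) else numeric(0)
  joint_r2 <- sum(r2)
  joint_f <- if (nrow(d) > 0 && joint_r2 < 1 && n_exp > nrow(d) + 1)
    f_statistic(joint_r2, n = n_exp, k = nrow(d)) else NA_real_
  structure(list(variant_ids = d$SNP, r2_explained = r2, f_stat = f_per,
                 k = nrow(d), n_exposure = n_exp,
                 joint_r2 = joint_r2, joint_f = joint_f, data = d),
            class = "instrument_set")
}

#' @export
print.instrument_set <- function(x, ...) {
  cat(sprintf("Instrument set: k = %d variants (N = %s)\n", x$k,
              format(x$n_exposure)))
  if (x$k > 0) {
    cat(sprintf("  per-variant F: min %.2f, median %.2f, max %.2f\n",
                min(x$f_stat), median(x$f_stat), max(x$f_stat)))
    cat(sprintf("  joint r2 = %.4g, joint F = %.2f\n", x$joint_r2, x$joint_f))
  }
  invisible(x)
}

#' Drop weak instruments
#'
#' Retains variants whose per-variant F statistic is strictly greater than
#' `f_min` (default 10).
#'
#' @param instruments an `instrument_set`.
#' @param f_min strength floor.
#' @return An `instrument_set` restricted to strong instruments.
#' @export
filter_weak <- function(instruments, f_min = 10) {
  stopifnot(inherits(instruments, "instrument_set"), f_min >= 0)
  keep <- instruments$f_stat > f_min
  out <- instruments
  out$variant_ids <- instruments$variant_ids[keep]
  out$r2_explained <- instruments$r2_explained[keep]
  out$f_stat <- instruments$f_stat[keep]
  out$k <- sum(keep)
  out$data <- instruments$data[keep, , drop = FALSE]
  out$joint_r2 <- sum(out$r2_explained)
  out$joint_f <- if (out$k > 0 && out$joint_r2 < 1 &&
                       out$n_exposure > out$k + 1)
    f_statistic(out$joint_r2, n = out$n_exposure, k = out$k) else NA_real_
  out
}
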