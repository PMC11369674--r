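#' Define a structural model for three-trait GWAS simulation
#'
#' The generator draws per-variant summary statistics for an exposure, a
#' mediator and a binary outcome (log-odds scale) under an
#' exposure -> mediator -> outcome structural model:
#' \itemize{
#'   \item exposure marginal betas: gamma_j + noise;
#'   \item mediator marginal betas: a * gamma_j + gamma_mediator_j + noise
#'     (gamma_mediator are mediator-specific, pQTL-style instrument effects
#'     — without them the mediator-to-outcome link would not be separately
#'     identifiable by two-step MR);
#'   \item outcome marginal betas: (direct + a*b) * gamma_j +
#'     b * gamma_mediator_j + pleiotropy_j + noise.
#' }
#' Standard errors follow the standard 1/sqrt(2*MAF*(1-MAF)*N) scaling for a
#' unit-variance trait, noise is independent across traits (non-overlapping
#' samples, the two-sample MR assumption), and the LD matrix is
#' block-diagonal with constant within-block r squared. The implied total
#' effect c_true = direct_true + a_true * b_true is recorded on the model.
#'
#' When `gamma` / `gamma_mediator` are `NULL` they are drawn at simulation
#' time (magnitudes uniform on `gamma_magnitude`, random signs). With a
#' mediated model (a_true or b_true nonzero) half the variants are exposure
#' instruments and half mediator instruments; otherwise all variants
#' instrument the exposure.
#'
#' @param n_variants number of variants.
#' @param n_exposure,n_mediator,n_outcome GWAS sample sizes.
#' @param maf_range minor-allele-frequency range, within (0, 0.5].
#' @param gamma optional vector of variant-to-exposure effects.
#' @param gamma_mediator optional vector of variant-to-mediator direct
#'   effects.
#' @param gamma_magnitude range of |effect| used when auto-drawing
#'   instrument effects.
#' @param a_true exposure-to-mediator causal effect.
#' @param b_true mediator-to-outcome causal effect (log-odds per unit).
#' @param direct_true direct exposure-to-outcome effect (log-odds).
#' @param pleiotropy_sd,pleiotropy_mean per-variant direct variant-to-outcome
#'   effects ~ N(mean, sd); a nonzero mean gives directional pleiotropy.
#' @param ld_block_size variants per LD block.
#' @param ld_r2 within-block squared correlation.
#' @param seed integer seed making the whole simulation deterministic.
#' @return An object of class `structural_model`.
#' @export
structural_model <- function(n_variants = 100,
                             n_exposure = 200000, n_mediator = 200000,
                             n_outcome = 400000,
                             maf_range = c(0.05, 0.5),
                             gamma = NULL, gamma_mediator = NULL,
                             gamma_magnitude = c(0.02, 0.08),
                             a_true = 0.1, b_true = 0.3, direct_true = 0.06,
                             pleiotropy_sd = 0, pleiotropy_mean = 0,
                             ld_block_size = 4, ld_r2 = 0.3,
                             seed = 1L) {
  stopifnot(n_variants >= 1, n_exposure > 2, n_mediator > 2, n_outcome > 2,
            length(maf_range) == 2, maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            pleiotropy_sd >= 0, ld_block_size >= 1,
            ld_r2 >= 0, ld_r2 <= 1, is.numeric(seed))
  if (!is.null(gamma)) stopifnot(length(gamma) == n_variants)
  if (!is.null(gamma_mediator)) stopifnot(length(gamma_mediator) == n_variants)
  structure(list(n_variants = as.integer(n_variants),
                 n_exposure = n_exposure, n_mediator = n_mediator,
                 n_outcome = n_outcome, maf_range = maf_range,
                 gamma = gamma, gamma_mediator = gamma_mediator,
                 gamma_magnitude = gamma_magnitude,
                 a_true = a_true, b_true = b_true, direct_true = direct_true,
                 c_true = direct_true + a_true * b_true,
                 pleiotropy_sd = pleiotropy_sd,
                 pleiotropy_mean = pleiotropy_mean,
                 ld_block_size = as.integer(ld_block_size), ld_r2 = ld_r2,
                 seed = as.integer(seed)),
            class = "structural_model")
}

#' @export
print.structural_model <- function(x, ...) {
  cat("Structural model for three-trait summary-statistic simulation\n")
  cat(sprintf("  %d variants; N = %g / %g / %g (exposure/mediator/outcome)\n",
              x$n_variants, x$n_exposure, x$n_mediator, x$n_outcome))
  cat(sprintf("  a = %g, b = %g, direct = %g => total c = %g\n",
              x$a_true, x$b_true, x$direct_true, x$c_true))
  cat(sprintf("  pleiotropy ~ N(%g, %g); LD blocks of %d at r2 = %g; seed %d\n",
              x$pleiotropy_mean, x$pleiotropy_sd, x$ld_block_size, x$ld_r2,
              x$seed))
  invisible(x)
}

#' Simulate three-trait GWAS summary statistics
#'
#' Draws one realization of the structural model: exposure, mediator and
#' outcome `sumstats` objects on a shared variant panel plus a block-diagonal
#' `ld_matrix`. Deterministic given the seed; the caller's RNG state is left
#' untouched.
#'
#' @param model a [structural_model()].
#' @param seed override of the model's seed.
#' @return A list of class `mr_simulation` with elements `exposure`,
#'   `mediator`, `outcome`, `ld` and `truth` (realized gamma vectors and all
#'   structural parameters, including `c_true` and the true proportion
#'   mediated when defined).
#' @export
simulate_sumstats <- function(model, seed = model$seed) {
  stopifnot(inherits(model, "structural_model"))
  m <- model$n_variants
  local_seed(seed, {
    maf <- runif(m, model$maf_range[1], model$maf_range[2])

    gamma <- model$gamma
    gamma_med <- model$gamma_mediator
    if (is.null(gamma) || is.null(gamma_med)) {
      mediated <- model$a_true != 0 || model$b_true != 0
      n_exp_iv <- if (mediated) floor(m / 2) else m
      mag <- function(k) runif(k, model$gamma_magnitude[1],
                               model$gamma_magnitude[2]) *
        sample(c(-1, 1), k, replace = TRUE)
      if (is.null(gamma)) {
        gamma <- rep(0, m)
        if (n_exp_iv > 0) gamma[seq_len(n_exp_iv)] <- mag(n_exp_iv)
      }
      if (is.null(gamma_med)) {
        gamma_med <- rep(0, m)
        if (n_exp_iv < m) gamma_med[(n_exp_iv + 1):m] <- mag(m - n_exp_iv)
      }
    }

    se_x <- 1 / sqrt(2 * maf * (1 - maf) * model$n_exposure)
    se_m <- 1 / sqrt(2 * maf * (1 - maf) * model$n_mediator)
    se_y <- 1 / sqrt(2 * maf * (1 - maf) * model$n_outcome)

    pleio <- rnorm(m, model$pleiotropy_mean, model$pleiotropy_sd)
    bx <- gamma + rnorm(m, 0, se_x)
    bm <- model$a_true * gamma + gamma_med + rnorm(m, 0, se_m)
    by <- model$c_true * gamma + model$b_true * gamma_med + pleio +
      rnorm(m, 0, se_y)

    n_blocks <- ceiling(m / model$ld_block_size)
    block <- rep(seq_len(n_blocks), each = model$ld_block_size)[seq_len(m)]
    chr <- as.character(((block - 1) %% 22) + 1)
    block_on_chr <- stats::ave(block, chr, FUN = function(b) match(b, unique(b)))
    within <- stats::ave(seq_len(m), block, FUN = seq_along)
    pos <- block_on_chr * 1e7 + within * 1e3
    snp <- sprintf("rs%06d", seq_len(m))

    r2 <- outer(block, block, function(i, j) ifelse(i == j, model$ld_r2, 0))
    diag(r2) <- 1
    ld <- ld_matrix(r2, positions = pos, variant_ids = snp,
                    chromosomes = chr)

    mk <- function(beta, se, n, name, type) {
      sumstats(data.frame(SNP = snp, CHR = chr, POS = pos,
                          EA = "A", OA = "G", EAF = maf,
                          BETA = beta, SE = se,
                          P = pmax(2 * pnorm(-abs(beta / se)),
                                   .Machine$double.xmin), N = n,
                          stringsAsFactors = FALSE),
               trait_name = name, trait_type = type)
    }
    truth <- list(gamma = gamma, gamma_mediator = gamma_med, maf = maf,
                  pleiotropy = pleio,
                  a_true = model$a_true, b_true = model$b_true,
                  direct_true = model$direct_true, c_true = model$c_true,
                  proportion_true = if (model$c_true != 0)
                    model$a_true * model$b_true / model$c_true else NA_real_,
                  seed = seed)
    structure(list(exposure = mk(bx, se_x, model$n_exposure, "exposure",
                                 "continuous"),
                   mediator = mk(bm, se_m, model$n_mediator, "mediator",
                                 "continuous"),
                   outcome = mk(by, se_y, model$n_outcome, "outcome",
                                "binary"),
                   ld = ld, truth = truth, model = model),
              class = "mr_simulation")
  })
}

#' @export
simulate.structural_model <- function(object, nsim = 1, seed = object$seed, ...) {
  sims <- lapply(seq_len(nsim) - 1L, function(k) {
    simulate_sumstats(object, seed = seed + k)
  })
  if (nsim == 1) sims[[1]] else sims
}

#' Derive a masking scenario from a base model
#'
#' Returns a model whose direct effect opposes the indirect path a x b and
#' exceeds it in magnitude (|direct| = `ratio` x |a x b|), so the total
#' effect's sign opposes the indirect effect's: downstream two-step
#' decomposition classifies the mediator as masking.
#'
#' @param base a `structural_model` with a nonzero indirect path.
#' @param ratio |direct| / |a x b|, greater than 1.
#' @return A `structural_model` with the masking geometry.
#' @export
make_masking_scenario <- function(base, ratio = 2) {
  stopifnot(inherits(base, "structural_model"), ratio > 1)
  ab <- base$a_true * base$b_true
  if (ab == 0) {
    stop("masking requires a nonzero indirect path (a_true * b_true != 0)",
         call. = FALSE)
  }
  structural_model(n_variants = base$n_variants,
                   n_exposure = base$n_exposure,
                   n_mediator = base$n_mediator,
                   n_outcome = base$n_outcome,
                   maf_range = base$maf_range,
                   gamma = base$gamma, gamma_mediator = base$gamma_mediator,
                   gamma_magnitude = base$gamma_magnitude,
                   a_true = base$a_true, b_true = base$b_true,
                   direct_true = -ratio * ab,
                   pleiotropy_sd = base$pleiotropy_sd,
                   pleiotropy_mean = base$pleiotropy_mean,
                   ld_block_size = base$ld_block_size, ld_r2 = base$ld_r2,
                   seed = base$seed)
}

#' Write a simulation to disk in the standard formats
#'
#' Writes `exposure.tsv`, `mediator.tsv`, `outcome.tsv` (canonical
#' summary-statistics layout), `ld.tsv` (square matrix with id header
#' row/column) and `truth.yaml` (all structural parameters and realized
#' per-variant effects) into a directory.
#'
#' @param sim an `mr_simulation`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "mr_simulation"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_sumstats(sim$exposure, file.path(dir, "exposure.tsv"))
  write_sumstats(sim$mediator, file.path(dir, "mediator.tsv"))
  write_sumstats(sim$outcome, file.path(dir, "outcome.tsv"))
  ldm <- as.data.frame(sim$ld$r2)
  ldm <- cbind(SNP = sim$ld$variant_ids, ldm)
  write.table(ldm, file.path(dir, "ld.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  truth <- sim$truth
  truth$gamma <- as.numeric(truth$gamma)
  truth$gamma_mediator <- as.numeric(truth$gamma_mediator)
  truth$maf <- as.numeric(truth$maf)
  truth$pleiotropy <- as.numeric(truth$pleiotropy)
  yaml::write_yaml(truth, file.path(dir, "truth.yaml"))
  invisible(dir)
}
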