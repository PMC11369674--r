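#' Construct a summary-statistics set
#'
#' A `sumstats` object holds one trait's per-variant GWAS associations:
#' variant identifier, genomic coordinates, effect/other allele, effect-allele
#' frequency, per-allele effect size (log-odds for binary traits), its
#' standard error, p-value and GWAS sample size.
#'
#' Rows violating the record invariants (non-positive standard error, p-value
#' outside (0, 1], empty or identical alleles, allele frequency outside
#' (0, 1)) are dropped with a message giving per-reason counts. Missing EAF is
#' allowed (`NA`); such variants are retained but excluded from any
#' variance-explained or F-statistic computation that needs allele frequency.
#'
#' @param data data.frame with canonical columns `SNP`, `CHR`, `POS`, `EA`,
#'   `OA`, `EAF`, `BETA`, `SE`, `P`, `N` (`CHR`, `POS`, `EAF`, `N` may be
#'   missing/NA).
#' @param trait_name character scalar naming the trait.
#' @param trait_type `"continuous"` or `"binary"` (effects on log-odds scale).
#' @return An object of class `sumstats`: a list with elements `trait_name`,
#'   `trait_type`, `data` (validated data.frame) and `n_dropped` (named
#'   integer vector of drop counts by reason).
#' @examples
#' d <- data.frame(SNP = c("rs1", "rs2"), CHR = 1, POS = c(1e5, 2e5),
#'                 EA = c("A", "C"), OA = c("G", "T"), EAF = c(0.2, 0.4),
#'                 BETA = c(0.03, -0.02), SE = 0.005, P = c(1e-9, 4e-5),
#'                 N = 50000)
#' sumstats(d, "LDL", "continuous")
#' @export
sumstats <- function(data, trait_name = "trait", trait_type = c("continuous", "binary")) {
  trait_type <- match.arg(trait_type)
  stopifnot(is.data.frame(data))
  canonical <- c("SNP", "CHR", "POS", "EA", "OA", "EAF", "BETA", "SE", "P", "N")
  for (col in setdiff(canonical, names(data))) data[[col]] <- NA
  data <- data[, canonical]
  data$SNP <- as.character(data$SNP)
  data$CHR <- as.character(data$CHR)
  data$EA <- toupper(as.character(data$EA))
  data$OA <- toupper(as.character(data$OA))
  for (col in c("POS", "EAF", "BETA", "SE", "P", "N")) {
    data[[col]] <- suppressWarnings(as.numeric(data[[col]]))
  }

  drops <- c(missing_core = 0L, bad_se = 0L, bad_pvalue = 0L,
             bad_alleles = 0L, bad_eaf = 0L, duplicate_id = 0L)
  ok <- rep(TRUE, nrow(data))

  bad <- ok & (is.na(data$SNP) | data$SNP == "" | is.na(data$BETA) |
                 is.na(data$SE) | is.na(data$P))
  drops["missing_core"] <- sum(bad); ok[bad] <- FALSE
  bad <- ok & data$SE <= 0
  drops["bad_se"] <- sum(bad); ok[bad] <- FALSE
  bad <- ok & (data$P <= 0 | data$P > 1)
  drops["bad_pvalue"] <- sum(bad); ok[bad] <- FALSE
  bad <- ok & (is.na(data$EA) | is.na(data$OA) | data$EA == "" |
                 data$OA == "" | data$EA == data$OA |
                 !grepl("^[ACGT]+$", data$EA) | !grepl("^[ACGT]+$", data$OA))
  drops["bad_alleles"] <- sum(bad); ok[bad] <- FALSE
  bad <- ok & !is.na(data$EAF) & (data$EAF <= 0 | data$EAF >= 1)
  drops["bad_eaf"] <- sum(bad); ok[bad] <- FALSE
  data <- data[ok, , drop = FALSE]

  dup <- duplicated(data$SNP)
  drops["duplicate_id"] <- sum(dup)
  data <- data[!dup, , drop = FALSE]
  rownames(data) <- NULL

  if (any(drops > 0)) {
    msg <- paste(sprintf("%s=%d", names(drops)[drops > 0], drops[drops > 0]),
                 collapse = ", ")
    message(sprintf("sumstats('%s'): dropped %d row(s): %s",
                    trait_name, sum(drops), msg))
  }
  structure(list(trait_name = trait_name, trait_type = trait_type,
                 data = data, n_dropped = drops),
            class = "sumstats")
}

#' @export
print.sumstats <- function(x, ...) {
  cat(sprintf("GWAS summary statistics: %s (%s trait)\n",
              x$trait_name, x$trait_type))
  cat(sprintf("  %d variants; %d row(s) dropped at validation\n",
              nrow(x$data), sum(x$n_dropped)))
  print(head(x$data, 5))
  if (nrow(x$data) > 5) cat(sprintf("  ... %d more rows\n", nrow(x$data) - 5))
  invisible(x)
}

#' @export
nobs.sumstats <- function(object, ...) nrow(object$data)

#' Column dialects for summary-statistics files
#'
#' A dialect maps the canonical column names to the names used in a file and
#' records the scale the effect is reported on (`"beta"` or `"or"`; odds
#' ratios are log-transformed on read). Two presets ship with the package:
#' `"canonical"` (columns SNP, CHR, POS, EA, OA, EAF, BETA, SE, P, N) and
#' `"odds_ratio"` (as canonical but with an `OR` column in place of `BETA`).
#'
#' @param mapping named character vector: names are canonical columns, values
#'   the file's column names. Unmentioned canonical columns keep their name.
#' @param effect_scale `"beta"` or `"or"`.
#' @return A list of class `sumstats_dialect`.
#' @export
sumstats_dialect <- function(mapping = character(), effect_scale = c("beta", "or")) {
  effect_scale <- match.arg(effect_scale)
  canonical <- c("SNP", "CHR", "POS", "EA", "OA", "EAF", "BETA", "SE", "P", "N")
  full <- setNames(canonical, canonical)
  stopifnot(all(names(mapping) %in% canonical))
  full[names(mapping)] <- mapping
  structure(list(mapping = full, effect_scale = effect_scale),
            class = "sumstats_dialect")
}

dialect_presets <- function(name) {
  switch(name,
    canonical  = sumstats_dialect(),
    odds_ratio = sumstats_dialect(c(BETA = "OR"), effect_scale = "or"),
    stop(sprintf("unknown dialect '%s'", name), call. = FALSE))
}

#' Read GWAS summary statistics from a delimited file
#'
#' Reads a tab-separated table with a header row (missing values coded `NA`),
#' renames columns through a dialect, log-transforms odds ratios when the
#' dialect declares an odds-ratio effect scale, and validates records via
#' [sumstats()].
#'
#' @param path path to a TSV file.
#' @param trait_name trait label (defaults to the file's base name).
#' @param trait_type `"continuous"` or `"binary"`.
#' @param dialect a [sumstats_dialect()] object or preset name
#'   (`"canonical"`, `"odds_ratio"`).
#' @return A `sumstats` object.
#' @export
read_sumstats <- function(path, trait_name = NULL,
                          trait_type = c("continuous", "binary"),
                          dialect = "canonical") {
  trait_type <- match.arg(trait_type)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (is.character(dialect)) dialect <- dialect_presets(dialect)
  stopifnot(inherits(dialect, "sumstats_dialect"))
  raw <- read.delim(path, header = TRUE, sep = "\t", na.strings = "NA",
                    stringsAsFactors = FALSE, check.names = FALSE)
  required <- dialect$mapping[c("SNP", "BETA", "SE", "P")]
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop(sprintf("required column(s) absent from %s: %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  out <- data.frame(row.names = seq_len(nrow(raw)))
  for (canon in names(dialect$mapping)) {
    src <- dialect$mapping[[canon]]
    out[[canon]] <- if (src %in% names(raw)) raw[[src]] else NA
  }
  if (dialect$effect_scale == "or") {
    out$BETA <- log(suppressWarnings(as.numeric(out$BETA)))
  }
  if (is.null(trait_name)) {
    trait_name <- sub("\\.[^.]*$", "", basename(path))
  }
  sumstats(out, trait_name = trait_name, trait_type = trait_type)
}

#' Write summary statistics to a canonical TSV
#'
#' Writes the canonical tab-separated layout (columns SNP, CHR, POS, EA, OA,
#' EAF, BETA, SE, P, N; missing values as `NA`) so that
#' `read_sumstats(write_sumstats(x, f))` round-trips the record collection.
#'
#' @param x a `sumstats` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(x, path) {
  stopifnot(inherits(x, "sumstats"))
  write.table(x$data, path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "NA")
  invisible(path)
}
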