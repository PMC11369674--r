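empty_screen_table <- function() {
  data.frame(exposure = character(), outcome = character(),
             method = character(), n_snp = integer(), beta = numeric(),
             se = numeric(), pvalue = numeric(), or = numeric(),
             ci_low = numeric(), ci_high = numeric(), q = numeric(),
             q_pvalue = numeric(), egger_intercept_pvalue = numeric(),
             status = character(), reason = character(),
             selected = logical(), stringsAsFactors = FALSE)
}

select_instruments <- function(trait, p_threshold, ld = NULL,
                               r2_max = 0.001, window_kb = 5000,
                               f_min = 10) {
  sel <- select_significant(trait, p_threshold)
  if (!is.null(ld) && nrow(sel$data) > 0) {
    sel <- clump(sel, ld, r2_max = r2_max, window_kb = window_kb)
  }
  if (f_min > 0 && nrow(sel$data) > 0 &&
      all(!is.na(sel$data$EAF)) && all(!is.na(sel$data$N))) {
    strength <- instrument_strength(sel)
    strong <- filter_weak(strength, f_min)
    sel$data <- sel$data[sel$data$SNP %in% strong$variant_ids, , drop = FALSE]
    rownames(sel$data) <- NULL
  }
  sel
}

screen_one <- function(exposure, outcome, p_threshold, ld, r2_max, window_kb,
                       f_min, alpha, n_boot, seed, palindrome_eaf_limit,
                       methods) {
  sel <- select_instruments(exposure, p_threshold, ld, r2_max, window_kb, f_min)
  if (nrow(sel$data) == 0) {
    return(list(status = "skipped", reason = "no_significant_instruments",
                fit = NULL))
  }
  pair <- tryCatch(harmonize(sel, outcome, palindrome_eaf_limit),
                   error = function(e) NULL)
  if (is.null(pair) || nrow(pair$data) == 0) {
    return(list(status = "skipped", reason = "no_shared_variants", fit = NULL))
  }
  fit <- mr_fit(pair, methods = methods, n_boot = n_boot, seed = seed)
  list(status = "ok", reason = NA_character_, fit = fit)
}

primary_estimate <- function(fit) {
  nm <- intersect(c("ivw_random", "ivw_fixed", "wald"), names(fit$estimates))[1]
  fit$estimates[[nm]]
}

#' Screen many exposures against one outcome
#'
#' For each exposure: instruments are selected (genome-wide significance,
#' optional LD clumping, per-variant F filter), harmonized to the outcome,
#' and the full estimator suite plus sensitivity battery is fitted. An
#' exposure is flagged `selected` when its primary (IVW) p-value falls below
#' `alpha`. Exposures with no surviving instrument are reported as skipped
#' rows, not errors.
#'
#' @param exposures named list of `sumstats` objects.
#' @param outcome a `sumstats` object.
#' @param p_threshold instrument significance threshold (default 5e-8).
#' @param ld optional `ld_matrix` enabling clumping.
#' @param r2_max,window_kb clumping parameters (defaults 0.001 and 5000 kb).
#' @param f_min per-variant F floor (default 10; applied when EAF and N are
#'   available).
#' @param alpha screening significance level (default 0.05, uncorrected —
#'   the raw-p screening convention; set `adjust = "BH"` for a
#'   Benjamini-Hochberg variant, which is not the default behaviour).
#' @param adjust `"none"` or `"BH"` (applied to the primary p-values before
#'   the `selected` flag).
#' @param n_boot,seed bootstrap controls; each exposure uses `seed + its
#'   index` so runs are reproducible yet streams differ across exposures.
#' @param palindrome_eaf_limit passed to [harmonize()].
#' @param methods estimator subset passed to [mr_fit()].
#' @return An object of class `mr_screen`: list with `table` (tidy results,
#'   one row per exposure x method plus skip rows), `fits` (named list of
#'   `mr_fit` or NULL), `alpha`.
#' @export
mr_screen <- function(exposures, outcome, p_threshold = 5e-8, ld = NULL,
                      r2_max = 0.001, window_kb = 5000, f_min = 10,
                      alpha = 0.05, adjust = c("none", "BH"),
                      n_boot = 1000, seed = 1,
                      palindrome_eaf_limit = 0.42,
                      methods = c("ivw", "egger", "weighted_median",
                                  "simple_median")) {
  adjust <- match.arg(adjust)
  methods <- match.arg(methods, several.ok = TRUE)
  stopifnot(is.list(exposures))
  if (is.null(names(exposures)) || any(names(exposures) == "")) {
    names(exposures) <- vapply(exposures, function(s) s$trait_name, character(1))
  }
  fits <- vector("list", length(exposures))
  names(fits) <- names(exposures)
  rows <- list()
  for (i in seq_along(exposures)) {
    nm <- names(exposures)[i]
    res <- screen_one(exposures[[i]], outcome, p_threshold, ld, r2_max,
                      window_kb, f_min, alpha, n_boot, seed + i,
                      palindrome_eaf_limit, methods)
    if (res$status == "skipped") {
      rows[[length(rows) + 1]] <- data.frame(
        exposure = nm, outcome = outcome$trait_name, method = NA_character_,
        n_snp = 0L, beta = NA_real_, se = NA_real_, pvalue = NA_real_,
        or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
        q = NA_real_, q_pvalue = NA_real_, egger_intercept_pvalue = NA_real_,
        status = "skipped", reason = res$reason, stringsAsFactors = FALSE)
    } else {
      fits[[nm]] <- res$fit
      tab <- as.data.frame(res$fit)
      q <- if (res$fit$n_snp >= 2) cochran_q(res$fit$pair) else NULL
      tab$q <- if (is.null(q)) NA_real_ else q$q
      tab$q_pvalue <- if (is.null(q)) NA_real_ else q$pvalue
      tab$egger_intercept_pvalue <- if (!is.null(res$fit$egger))
        res$fit$egger$intercept$pvalue else NA_real_
      tab$status <- "ok"
      tab$reason <- NA_character_
      rows[[length(rows) + 1]] <- tab
    }
  }
  table <- if (length(rows) == 0) empty_screen_table()
           else do.call(rbind, rows)
  rownames(table) <- NULL
  # selected flag from each exposure's primary estimate
  prim <- vapply(names(fits), function(nm) {
    if (is.null(fits[[nm]])) NA_real_ else primary_estimate(fits[[nm]])$pvalue
  }, numeric(1))
  padj <- if (adjust == "BH") stats::p.adjust(prim, method = "BH") else prim
  table$selected <- logical(nrow(table))
  for (nm in names(fits)) {
    if (!is.null(fits[[nm]])) {
      table$selected[table$exposure == nm] <- !is.na(padj[nm]) && padj[nm] < alpha
    }
  }
  structure(list(table = table, fits = fits, alpha = alpha,
                 outcome_name = outcome$trait_name),
            class = "mr_screen")
}

#' @export
print.mr_screen <- function(x, ...) {
  ok <- !vapply(x$fits, is.null, logical(1))
  sel <- unique(x$table$exposure[x$table$selected])
  cat(sprintf("MR screen against %s: %d exposure(s), %d fitted, %d skipped, %d selected at alpha = %g\n",
              x$outcome_name, length(x$fits), sum(ok), sum(!ok), length(sel),
              x$alpha))
  invisible(x)
}

#' Reverse-direction MR screen
#'
#' Tests whether the outcome trait, used as the exposure, causally affects
#' each target trait: instruments are selected for `exposure` once, then
#' harmonized and fitted against every target. Used to rule out reverse
#' causation behind a forward screen.
#'
#' @param exposure the trait whose instruments are used (the original
#'   outcome).
#' @param targets named list of `sumstats` objects to test as outcomes.
#' @inheritParams mr_screen
#' @return An `mr_screen` object (targets appear in the `outcome` role).
#' @export
reverse_screen <- function(exposure, targets, p_threshold = 5e-8, ld = NULL,
                           r2_max = 0.001, window_kb = 5000, f_min = 10,
                           alpha = 0.05, n_boot = 1000, seed = 1,
                           palindrome_eaf_limit = 0.42,
                           methods = c("ivw", "egger", "weighted_median",
                                       "simple_median")) {
  stopifnot(is.list(targets))
  methods <- match.arg(methods, several.ok = TRUE)
  if (is.null(names(targets)) || any(names(targets) == "")) {
    names(targets) <- vapply(targets, function(s) s$trait_name, character(1))
  }
  sel <- select_instruments(exposure, p_threshold, ld, r2_max, window_kb, f_min)
  fits <- vector("list", length(targets))
  names(fits) <- names(targets)
  rows <- list()
  for (i in seq_along(targets)) {
    nm <- names(targets)[i]
    if (nrow(sel$data) == 0) {
      status <- "skipped"; reason <- "no_significant_instruments"; fit <- NULL
    } else {
      pair <- tryCatch(harmonize(sel, targets[[i]], palindrome_eaf_limit),
                       error = function(e) NULL)
      if (is.null(pair) || nrow(pair$data) == 0) {
        status <- "skipped"; reason <- "no_shared_variants"; fit <- NULL
      } else {
        fit <- mr_fit(pair, methods = methods, n_boot = n_boot,
                      seed = seed + i)
        status <- "ok"; reason <- NA_character_
      }
    }
    if (is.null(fit)) {
      rows[[length(rows) + 1]] <- data.frame(
        exposure = exposure$trait_name, outcome = nm, method = NA_character_,
        n_snp = 0L, beta = NA_real_, se = NA_real_, pvalue = NA_real_,
        or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
        q = NA_real_, q_pvalue = NA_real_, egger_intercept_pvalue = NA_real_,
        status = status, reason = reason, stringsAsFactors = FALSE)
    } else {
      fits[[nm]] <- fit
      tab <- as.data.frame(fit)
      tab$outcome <- nm
      q <- if (fit$n_snp >= 2) cochran_q(fit$pair) else NULL
      tab$q <- if (is.null(q)) NA_real_ else q$q
      tab$q_pvalue <- if (is.null(q)) NA_real_ else q$pvalue
      tab$egger_intercept_pvalue <- if (!is.null(fit$egger))
        fit$egger$intercept$pvalue else NA_real_
      tab$status <- "ok"
      tab$reason <- NA_character_
      rows[[length(rows) + 1]] <- tab
    }
  }
  table <- if (length(rows) == 0) empty_screen_table()
           else do.call(rbind, rows)
  rownames(table) <- NULL
  table$selected <- logical(nrow(table))
  for (nm in names(fits)) {
    if (!is.null(fits[[nm]])) {
      table$selected[table$outcome == nm] <-
        primary_estimate(fits[[nm]])$pvalue < alpha
    }
  }
  structure(list(table = table, fits = fits, alpha = alpha,
                 outcome_name = exposure$trait_name),
            class = "mr_screen")
}

load_trait_entry <- function(entry) {
  if (inherits(entry, "sumstats")) return(entry)
  stopifnot(is.list(entry), !is.null(entry$path))
  read_sumstats(entry$path,
                trait_name = entry$name,
                trait_type = if (is.null(entry$trait_type)) "continuous"
                             else entry$trait_type,
                dialect = if (is.null(entry$dialect)) "canonical"
                          else entry$dialect)
}

workflow_params <- function(cfg) {
  p <- cfg$parameters
  if (is.null(p)) p <- list()
  defaults <- list(p_threshold = 5e-8, clump_r2 = 0.001, clump_kb = 5000,
                   f_min = 10, alpha = 0.05, n_boot = 1000, seed = 1,
                   palindrome_eaf_limit = 0.42)
  for (nm in names(defaults)) if (is.null(p[[nm]])) p[[nm]] <- defaults[[nm]]
  p
}

collect_loo <- function(screens) {
  rows <- list()
  for (stage in names(screens)) {
    sc <- screens[[stage]]
    for (nm in names(sc$fits)) {
      fit <- sc$fits[[nm]]
      if (is.null(fit) || fit$n_snp < 3) next
      loo <- leave_one_out(fit$pair)
      loo <- cbind(stage = stage, exposure = fit$pair$exposure_name,
                   outcome = fit$pair$outcome_name, loo)
      rows[[length(rows) + 1]] <- loo
    }
  }
  if (length(rows) == 0) {
    return(data.frame(stage = character(), exposure = character(),
                      outcome = character(), left_out = character(),
                      beta = numeric(), se = numeric(), pvalue = numeric(),
                      sign_change = logical(), significance_change = logical(),
                      flagged = logical(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full mediation-screening workflow
#'
#' Executes the complete pipeline from a configuration: (1) forward screen
#' of every exposure against the outcome (total effects c); (2) forward
#' screen of every mediator against the outcome (effects b); (3) pairwise
#' exposure-to-mediator MR among the survivors (effects a); (4) two-step
#' mediation decomposition for every triplet in which all three links pass
#' `alpha`; (5) multivariable MR over all surviving exposures and mediators
#' jointly. Tidy TSV tables, a leave-one-out table, a YAML manifest
#' (input checksums, every threshold, seed) and a log are written to the
#' output directory; a run with identical config and seed reproduces the
#' tables byte for byte.
#'
#' @param config path to a YAML file or an equivalent list with entries
#'   `exposures`, `mediators` (lists of `{name, path, dialect, trait_type}`
#'   entries, or `sumstats` objects directly), `outcome`, optional `ld`
#'   (`{path, format}` or an `ld_matrix`), `parameters` (`p_threshold`,
#'   `clump_r2`, `clump_kb`, `f_min`, `alpha`, `n_boot`, `seed`,
#'   `palindrome_eaf_limit`) and `output_dir`.
#' @return Invisibly, a list with `screen` (combined screen table),
#'   `mediation` (mediation table), `mvmr` (MVMR table or NULL), `loo`,
#'   `manifest`, and `results` (the `mr_mediation` objects).
#' @export
run_mediation_workflow <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  stopifnot(is.list(cfg), !is.null(cfg$exposures), !is.null(cfg$outcome))
  out_dir <- if (is.null(cfg$output_dir)) "." else cfg$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- workflow_params(cfg)
  log_lines <- character(0)
  note <- function(fmt, ...) {
    log_lines <<- c(log_lines, sprintf(fmt, ...))
  }

  exposures <- lapply(cfg$exposures, load_trait_entry)
  names(exposures) <- vapply(exposures, function(s) s$trait_name, character(1))
  mediators <- if (is.null(cfg$mediators)) list()
               else lapply(cfg$mediators, load_trait_entry)
  if (length(mediators) > 0) {
    names(mediators) <- vapply(mediators, function(s) s$trait_name, character(1))
  }
  outcome <- load_trait_entry(cfg$outcome)

  ld <- NULL
  if (!is.null(cfg$ld)) {
    if (inherits(cfg$ld, "ld_matrix")) {
      ld <- cfg$ld
    } else {
      all_dat <- do.call(rbind, lapply(c(exposures, mediators, list(outcome)),
                                       function(s) s$data[, c("SNP", "CHR", "POS")]))
      all_dat <- all_dat[!duplicated(all_dat$SNP), ]
      ld <- read_ld_matrix(cfg$ld$path,
                           format = if (is.null(cfg$ld$format)) "square"
                                    else cfg$ld$format,
                           positions = setNames(all_dat$POS, all_dat$SNP),
                           chromosomes = setNames(all_dat$CHR, all_dat$SNP))
    }
  }
  note("workflow: %d exposure(s), %d mediator(s), outcome '%s'",
       length(exposures), length(mediators), outcome$trait_name)
  note("parameters: p_threshold=%g clump_r2=%g clump_kb=%g f_min=%g alpha=%g n_boot=%d seed=%d",
       p$p_threshold, p$clump_r2, p$clump_kb, p$f_min, p$alpha,
       as.integer(p$n_boot), as.integer(p$seed))

  screen_args <- list(outcome = outcome, p_threshold = p$p_threshold,
                      ld = ld, r2_max = p$clump_r2, window_kb = p$clump_kb,
                      f_min = p$f_min, alpha = p$alpha, n_boot = p$n_boot,
                      palindrome_eaf_limit = p$palindrome_eaf_limit)

  fwd <- do.call(mr_screen, c(list(exposures = exposures,
                                   seed = p$seed), screen_args))
  surv_exp <- unique(fwd$table$exposure[fwd$table$selected])
  note("forward screen (exposure -> outcome): %d of %d selected",
       length(surv_exp), length(exposures))

  med_screen <- NULL
  surv_med <- character(0)
  if (length(mediators) > 0) {
    med_screen <- do.call(mr_screen, c(list(exposures = mediators,
                                            seed = p$seed + 1000),
                                       screen_args))
    surv_med <- unique(med_screen$table$exposure[med_screen$table$selected])
    note("forward screen (mediator -> outcome): %d of %d selected",
         length(surv_med), length(mediators))
  }

  # pairwise exposure -> mediator among survivors
  em_screens <- list()
  mediation_results <- list()
  for (e in surv_exp) {
    for (m in surv_med) {
      em <- mr_screen(exposures[e], mediators[[m]],
                      p_threshold = p$p_threshold, ld = ld,
                      r2_max = p$clump_r2, window_kb = p$clump_kb,
                      f_min = p$f_min, alpha = p$alpha, n_boot = p$n_boot,
                      seed = p$seed + 2000 + length(em_screens),
                      palindrome_eaf_limit = p$palindrome_eaf_limit)
      em_screens[[paste(e, m, sep = " -> ")]] <- em
      a_ok <- any(em$table$selected)
      if (!a_ok) next
      c_est <- primary_estimate(fwd$fits[[e]])
      a_est <- primary_estimate(em$fits[[e]])
      b_est <- primary_estimate(med_screen$fits[[m]])
      mediation_results[[length(mediation_results) + 1]] <-
        mr_mediate(c_est, a_est, b_est, exposure = e, mediator = m,
                   outcome = outcome$trait_name, alpha = p$alpha)
    }
  }
  note("triplets passing all three links at alpha = %g: %d",
       p$alpha, length(mediation_results))
  mediation_table <- mediated_proportion_table(mediation_results)

  mvmr_table <- NULL
  surv_all <- c(exposures[surv_exp], mediators[surv_med])
  if (length(surv_all) >= 2) {
    mv <- tryCatch({
      inp <- build_mvmr_input(surv_all, outcome,
                              p_threshold = p$p_threshold, ld = ld,
                              r2_max = p$clump_r2, window_kb = p$clump_kb,
                              palindrome_eaf_limit = p$palindrome_eaf_limit)
      mvmr_fit(inp)
    }, error = function(e) {
      note("mvmr skipped: %s", conditionMessage(e))
      NULL
    })
    if (!is.null(mv)) {
      mvmr_table <- as.data.frame(mv)
      mvmr_table$outcome <- outcome$trait_name
      note("mvmr: %d exposures jointly on %d variants",
           length(mv$estimates), mv$n_snp)
    }
  } else {
    note("mvmr skipped: fewer than 2 surviving traits")
  }

  screens <- c(list(exposure_outcome = fwd),
               if (!is.null(med_screen)) list(mediator_outcome = med_screen),
               setNames(em_screens,
                        paste0("exposure_mediator:", names(em_screens))))
  screen_table <- do.call(rbind, lapply(names(screens), function(nm) {
    cbind(stage = nm, screens[[nm]]$table)
  }))
  rownames(screen_table) <- NULL
  loo_table <- collect_loo(screens)

  input_files <- character(0)
  for (entry in c(cfg$exposures, cfg$mediators, list(cfg$outcome))) {
    if (is.list(entry) && !is.null(entry$path)) {
      input_files <- c(input_files, entry$path)
    }
  }
  if (is.list(cfg$ld) && !is.null(cfg$ld$path)) {
    input_files <- c(input_files, cfg$ld$path)
  }
  checksums <- if (length(input_files) > 0)
    as.list(setNames(unname(md5sum(input_files)), basename(input_files)))
  else list()
  manifest <- list(
    inputs = checksums,
    parameters = p[order(names(p))],
    n_exposures = length(exposures), n_mediators = length(mediators),
    selected_exposures = as.list(sort(surv_exp)),
    selected_mediators = as.list(sort(surv_med)),
    n_triplets = length(mediation_results),
    outputs = list("screen_results.tsv", "mediation.tsv", "mvmr.tsv",
                   "loo.tsv"))

  write_tsv_stable(screen_table, file.path(out_dir, "screen_results.tsv"))
  write_tsv_stable(mediation_table, file.path(out_dir, "mediation.tsv"))
  if (!is.null(mvmr_table)) {
    write_tsv_stable(mvmr_table, file.path(out_dir, "mvmr.tsv"))
  } else {
    write_tsv_stable(data.frame(exposure = character(), method = character(),
                                n_snp = integer(), beta = numeric(),
                                se = numeric(), pvalue = numeric(),
                                stringsAsFactors = FALSE),
                     file.path(out_dir, "mvmr.tsv"))
  }
  write_tsv_stable(loo_table, file.path(out_dir, "loo.tsv"))
  yaml::write_yaml(manifest, file.path(out_dir, "run_manifest.yaml"))
  writeLines(log_lines, file.path(out_dir, "run.log"))

  invisible(list(screen = screen_table, mediation = mediation_table,
                 mvmr = mvmr_table, loo = loo_table, manifest = manifest,
                 results = mediation_results))
}
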