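test_that("the forward screen flags exactly the truly causal exposures", {
  bat <- make_battery(20, true_idx = c(2, 5, 9, 14, 17), c_effect = 0.3,
                      seed = 21)
  sc <- mr_screen(bat$exposures, bat$outcome, seed = 1, n_boot = 100,
                  methods = "ivw")
  flagged <- sort(unique(sc$table$exposure[sc$table$selected]))
  # every true effect is detected; false flags stay near the nominal rate
  expect_true(all(sprintf("X%02d", c(2, 5, 9, 14, 17)) %in% flagged))
  expect_lte(length(setdiff(flagged, sprintf("X%02d", c(2, 5, 9, 14, 17)))), 3)
})

test_that("alpha = 1 flags every exposure with instruments", {
  bat <- make_battery(5, true_idx = 1, seed = 22)
  sc <- mr_screen(bat$exposures, bat$outcome, alpha = 1, seed = 1,
                  n_boot = 100, methods = "ivw")
  expect_true(all(sc$table$selected[sc$table$status == "ok"]))
})

test_that("an exposure with no significant variant is skipped, not an error", {
  bat <- make_battery(3, true_idx = 1, seed = 23)
  weak <- bat$exposures[[1]]
  weak$data$P <- rep(0.5, nrow(weak$data))  # nothing genome-wide significant
  exposures <- c(bat$exposures[2:3], list(X00 = weak))
  sc <- mr_screen(exposures, bat$outcome, seed = 1, n_boot = 100,
                  methods = "ivw")
  skipped <- sc$table[sc$table$status == "skipped", ]
  expect_equal(skipped$exposure, "X00")
  expect_equal(skipped$reason, "no_significant_instruments")
  expect_false(any(sc$table$selected[sc$table$exposure == "X00"]))
})

test_that("the reverse screen controls type-I error under the null", {
  bat <- make_battery(1, true_idx = integer(0), seed = 31, n_gwas = 2e5)
  dvt <- bat$exposures[[1]]
  snp <- dvt$data$SNP
  se <- dvt$data$SE[1]
  set.seed(99)
  targets <- lapply(1:200, function(i) {
    make_set(snp, rnorm(length(snp), 0, se), se,
             pos = dvt$data$POS, name = sprintf("T%03d", i))
  })
  sc <- reverse_screen(dvt, targets, seed = 7, n_boot = 100,
                       methods = "ivw")
  frac <- mean(sc$table$selected[sc$table$status == "ok"])
  expect_lte(frac, 0.105)

  # empty target list gives an empty table
  sc0 <- reverse_screen(dvt, list(), seed = 1)
  expect_equal(nrow(sc0$table), 0)
})

test_that("a strong injected reverse effect is flagged", {
  bat <- make_battery(1, true_idx = integer(0), seed = 32)
  dvt <- bat$exposures[[1]]
  se <- dvt$data$SE[1]
  set.seed(5)
  target <- make_set(dvt$data$SNP, 0.4 * dvt$data$BETA + rnorm(nrow(dvt$data), 0, se),
                     se, pos = dvt$data$POS, name = "hit")
  sc <- reverse_screen(dvt, list(hit = target), seed = 2, n_boot = 100,
                       methods = "ivw")
  expect_true(all(sc$table$selected))
})

workflow_config <- function(sim, dir, n_boot = 200, seed = 11, with_ld = TRUE) {
  write_simulation(sim, dir)
  list(
    exposures = list(list(name = "lipid", path = file.path(dir, "exposure.tsv"))),
    mediators = list(list(name = "protein", path = file.path(dir, "mediator.tsv"))),
    outcome = list(name = "dvt", path = file.path(dir, "outcome.tsv"),
                   trait_type = "binary"),
    ld = if (with_ld) list(path = file.path(dir, "ld.tsv"), format = "square"),
    parameters = list(n_boot = n_boot, seed = seed),
    output_dir = file.path(dir, "out"))
}

test_that("the workflow recovers a true mediated path with covering CI", {
  m <- structural_model(n_variants = 40, ld_block_size = 1, ld_r2 = 0,
                        seed = 41)
  sim <- simulate_sumstats(m)
  dir <- file.path(tempdir(), "wf_mediated")
  cfg <- workflow_config(sim, dir, with_ld = FALSE)
  res <- run_mediation_workflow(cfg)
  expect_equal(nrow(res$mediation), 1)
  expect_equal(res$mediation$exposure, "lipid")
  expect_equal(res$mediation$classification, "mediation")
  truth_pct <- 100 * sim$truth$proportion_true
  expect_gt(truth_pct, res$mediation$ci_low_pct)
  expect_lt(truth_pct, res$mediation$ci_high_pct)
  # output files exist
  for (f in c("screen_results.tsv", "mediation.tsv", "mvmr.tsv", "loo.tsv",
              "run_manifest.yaml", "run.log")) {
    expect_true(file.exists(file.path(dir, "out", f)), label = f)
  }
})

test_that("a masking scenario is classified as masking end-to-end", {
  base <- structural_model(n_variants = 40, ld_block_size = 1, ld_r2 = 0,
                           seed = 43)
  sim <- simulate_sumstats(make_masking_scenario(base, ratio = 3))
  dir <- file.path(tempdir(), "wf_masking")
  cfg <- workflow_config(sim, dir, with_ld = FALSE)
  res <- run_mediation_workflow(cfg)
  expect_equal(nrow(res$mediation), 1)
  expect_equal(res$mediation$classification, "masking")
})

test_that("no surviving triplet yields an empty table and a valid manifest", {
  m <- structural_model(n_variants = 40, a_true = 0, b_true = 0.3,
                        direct_true = 0.06, ld_block_size = 1, ld_r2 = 0,
                        seed = 47)
  sim <- simulate_sumstats(m)
  dir <- file.path(tempdir(), "wf_null")
  cfg <- workflow_config(sim, dir, with_ld = FALSE)
  res <- run_mediation_workflow(cfg)
  expect_equal(nrow(res$mediation), 0)
  expect_equal(res$manifest$n_triplets, 0)
  man <- yaml::read_yaml(file.path(dir, "out", "run_manifest.yaml"))
  expect_true(all(c("inputs", "parameters", "n_triplets") %in% names(man)))
  expect_equal(length(man$inputs), 3)
})

test_that("workflow runs with identical config and seed are byte-identical", {
  m <- structural_model(n_variants = 40, seed = 53)  # with LD blocks
  sim <- simulate_sumstats(m)
  dir <- file.path(tempdir(), "wf_det")
  cfg <- workflow_config(sim, dir, with_ld = TRUE)
  cfg$output_dir <- file.path(dir, "out1")
  run_mediation_workflow(cfg)
  cfg$output_dir <- file.path(dir, "out2")
  run_mediation_workflow(cfg)
  for (f in c("screen_results.tsv", "mediation.tsv", "mvmr.tsv", "loo.tsv",
              "run_manifest.yaml")) {
    expect_identical(unname(tools::md5sum(file.path(dir, "out1", f))),
                     unname(tools::md5sum(file.path(dir, "out2", f))),
                     label = f)
  }
  # the manifest records checksums for every input file and all thresholds
  man <- yaml::read_yaml(file.path(dir, "out1", "run_manifest.yaml"))
  expect_equal(length(man$inputs), 4)
  expect_true(all(c("p_threshold", "clump_r2", "clump_kb", "f_min", "alpha",
                    "n_boot", "seed") %in% names(man$parameters)))
})
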