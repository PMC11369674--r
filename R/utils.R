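# Evaluate an expression under a given RNG seed, restoring the caller's RNG
# state afterwards so seeded internals (bootstraps, simulators) never perturb
# the session stream.
local_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  expr
}

# Fixed-format table writer shared by all pipeline outputs: identical inputs
# give byte-identical files (no timestamps, locale-independent formatting).
write_tsv_stable <- function(df, path, digits = 10) {
  out <- df
  for (col in names(out)) {
    if (is.numeric(out[[col]])) {
      out[[col]] <- formatC(out[[col]], digits = digits, format = "g")
      out[[col]][out[[col]] %in% c("NA", "NaN")] <- "NA"
    }
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}
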