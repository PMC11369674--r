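test_that("significance selection applies a strict threshold in order", {
  s <- make_set(c("rs1", "rs2", "rs3"), c(0.1, 0.1, 0.1), 0.01,
                p = c(1e-9, 1e-7, 4.9e-8))
  sel <- select_significant(s, 5e-8)
  expect_equal(sel$data$SNP, c("rs1", "rs3"))
  expect_equal(nrow(select_significant(s, 1)$data), 3)
  empty <- s; empty$data <- s$data[0, ]
  expect_equal(nrow(select_significant(empty, 5e-8)$data), 0)
})

simple_ld <- function(snp, pos, r2_off, chr = NULL) {
  m <- diag(1, length(snp))
  m[upper.tri(m)] <- r2_off[upper.tri(m)]
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  ld_matrix(m, positions = pos, variant_ids = snp, chromosomes = chr)
}

test_that("clumping keeps the most significant of a correlated pair", {
  s <- make_set(c("rs1", "rs2"), c(0.1, 0.1), 0.01, p = c(1e-20, 1e-10),
                pos = c(1e6, 1e6 + 1e4))
  r2 <- matrix(c(1, 0.9, 0.9, 1), 2)
  ld <- ld_matrix(r2, positions = c(1e6, 1e6 + 1e4),
                  variant_ids = c("rs1", "rs2"))
  kept <- clump(s, ld, r2_max = 0.001, window_kb = 5000)
  expect_equal(kept$data$SNP, "rs1")

  # independent variants survive together
  ld0 <- ld_matrix(diag(1, 2), positions = c(1e6, 1e6 + 1e4),
                   variant_ids = c("rs1", "rs2"))
  expect_equal(nrow(clump(s, ld0)$data), 2)
})

test_that("a missing LD entry is a configuration error naming the variant", {
  s <- make_set(c("rs1", "rsX"), c(0.1, 0.1), 0.01)
  ld <- ld_matrix(matrix(1), positions = 1e6, variant_ids = "rs1")
  expect_error(clump(s, ld), "rsX")
})

test_that("clumping satisfies the pairwise rule against a brute-force check", {
  for (seed in 1:6) {
    set.seed(seed)
    n <- 12
    snp <- sprintf("rs%02d", 1:n)
    chr <- as.character(sample(1:2, n, TRUE))
    pos <- sample.int(8e6, n)
    blocks <- sample(1:4, n, TRUE)
    r2 <- outer(blocks, blocks, function(i, j) ifelse(i == j, 0.8, 0))
    diag(r2) <- 1
    s <- make_set(snp, rnorm(n, 0, 0.05), 0.01, p = runif(n, 1e-30, 1e-8),
                  chr = chr, pos = pos)
    ld <- ld_matrix(r2, positions = pos, variant_ids = snp,
                    chromosomes = chr)
    kept <- clump(s, ld, r2_max = 0.001, window_kb = 5000)$data

    # no kept pair violates the rule
    if (nrow(kept) > 1) {
      for (i in 1:(nrow(kept) - 1)) for (j in (i + 1):nrow(kept)) {
        same_chr <- kept$CHR[i] == kept$CHR[j]
        close <- abs(kept$POS[i] - kept$POS[j]) <= 5000 * 1000
        rr <- r2[match(kept$SNP[i], snp), match(kept$SNP[j], snp)]
        expect_true(!same_chr || !close || rr <= 0.001)
      }
    }
    # every dropped variant conflicts with a kept variant of no larger p
    dropped <- setdiff(snp, kept$SNP)
    for (d in dropped) {
      di <- match(d, snp)
      conflict <- vapply(seq_len(nrow(kept)), function(k) {
        ki <- match(kept$SNP[k], snp)
        s$data$P[ki] <= s$data$P[di] &&
          chr[ki] == chr[di] &&
          abs(pos[ki] - pos[di]) <= 5000 * 1000 &&
          r2[ki, di] > 0.001
      }, logical(1))
      expect_true(any(conflict))
    }
  }
})

test_that("clumping is invariant to input row order", {
  set.seed(77)
  n <- 10
  snp <- sprintf("rs%02d", 1:n)
  pos <- sort(sample.int(3e6, n))
  blocks <- rep(1:2, each = 5)
  r2 <- outer(blocks, blocks, function(i, j) ifelse(i == j, 0.7, 0))
  diag(r2) <- 1
  s <- make_set(snp, rnorm(n, 0, 0.05), 0.01, p = runif(n, 1e-20, 1e-8),
                pos = pos)
  ld <- ld_matrix(r2, positions = pos, variant_ids = snp)
  k1 <- clump(s, ld)
  perm <- s; perm$data <- perm$data[sample(n), ]
  k2 <- clump(perm, ld)
  expect_equal(k2$data$SNP, k1$data$SNP)
})

test_that("variance explained matches hand evaluation and is MAF-symmetric", {
  # SD = se * sqrt(n) = 0.01 * 100 = 1; 2 * 0.3 * 0.7 * (0.1/1)^2
  expect_equal(variance_explained(0.1, 0.01, 0.3, 10000, mode = "squared"),
               2 * 0.3 * 0.7 * 0.01)
  expect_equal(variance_explained(0.1, 0.01, 0.3, 10000, mode = "paper_verbatim"),
               2 * 0.3 * 0.7 * 0.1)
  expect_equal(variance_explained(0, 0.01, 0.3, 10000), 0)
  expect_equal(variance_explained(0, 0.01, 0.3, 10000, mode = "paper_verbatim"), 0)
  expect_equal(variance_explained(0.1, 0.01, 0.7, 10000),
               variance_explained(0.1, 0.01, 0.3, 10000))
  expect_error(variance_explained(0.1, 0.01, NA, 10000), "required")
})

test_that("the F statistic follows its closed form and monotonicity", {
  expect_equal(f_statistic(0, 1000, 1), 0)
  expect_equal(f_statistic(0.01, 1000, 1), 998 * 0.01 / 0.99)
  # linearity in r2/(1-r2)
  r2a <- 0.01; r2b <- 2 * r2a / (1 + r2a)  # doubles r2/(1-r2)
  expect_equal(f_statistic(r2b, 1000, 1), 2 * f_statistic(r2a, 1000, 1))
  expect_error(f_statistic(1, 1000, 1), "r2")
  # monotone in r2 and n
  f <- f_statistic(seq(0, 0.5, 0.05), 1000, 1)
  expect_true(all(diff(f) > 0))
  expect_true(f_statistic(0.01, 2000, 1) > f_statistic(0.01, 1000, 1))
})

test_that("weak-instrument filtering uses a strict F floor", {
  s <- make_set(c("rs1", "rs2", "rs3"), c(0.004, 0.011, 0.0095), 0.001,
                eaf = 0.5, n = 1e4)
  inst <- instrument_strength(s)
  expect_equal(inst$k, 3)
  f5 <- filter_weak(inst, 10)
  # keep only variants with F strictly above 10
  expect_equal(f5$variant_ids, inst$variant_ids[inst$f_stat > 10])
  expect_equal(filter_weak(inst, 0)$k, 3)
  all_weak <- filter_weak(inst, max(inst$f_stat))
  expect_equal(all_weak$k, sum(inst$f_stat > max(inst$f_stat)))
})

test_that("per-variant and joint F readings are both reported", {
  s <- make_set(c("rs1", "rs2"), c(0.05, 0.06), 0.005, eaf = 0.3, n = 5e4)
  inst <- instrument_strength(s)
  expect_length(inst$f_stat, 2)
  expect_equal(inst$joint_r2, sum(inst$r2_explained))
  expect_equal(inst$joint_f,
               f_statistic(inst$joint_r2, n = 5e4, k = 2))
})

test_that("LD matrices round-trip through square and long TSV formats", {
  snp <- c("rs1", "rs2", "rs3")
  pos <- c(1e6, 2e6, 3e6)
  r2 <- matrix(c(1, 0.5, 0, 0.5, 1, 0.2, 0, 0.2, 1), 3)
  ld <- ld_matrix(r2, positions = pos, variant_ids = snp)

  f1 <- tempfile(fileext = ".tsv")
  sq <- cbind(SNP = snp, as.data.frame(ld$r2))
  write.table(sq, f1, sep = "\t", quote = FALSE, row.names = FALSE)
  ld1 <- read_ld_matrix(f1, "square", positions = setNames(pos, snp))
  expect_equal(unname(ld1$r2), unname(r2))

  f2 <- tempfile(fileext = ".tsv")
  long <- data.frame(id1 = c("rs1", "rs1", "rs2"),
                     id2 = c("rs2", "rs3", "rs3"), r2 = c(0.5, 0, 0.2))
  write.table(long, f2, sep = "\t", quote = FALSE, row.names = FALSE)
  ld2 <- read_ld_matrix(f2, "long", positions = setNames(pos, snp))
  expect_equal(ld2$r2[ld1$variant_ids, ld1$variant_ids], ld1$r2)

  expect_error(ld_matrix(matrix(c(1, 0.5, 0.4, 1), 2), positions = 1:2,
                         variant_ids = c("a", "b")), "symmetric")
})
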