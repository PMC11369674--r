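# Independent oracles for the closed-form estimators: each reformulates the
# statistic through lm()/loops rather than the package's normal-equation
# arithmetic.

oracle_ivw <- function(bx, by, sy) {
  fit <- lm(by ~ 0 + bx, weights = 1 / sy^2)
  sm <- summary(fit)
  beta <- unname(coef(fit)[1])
  se_fixed <- unname(sm$coefficients[1, 2] / sm$sigma)
  q <- sum((1 / sy^2) * (by - beta * bx)^2)
  list(beta = beta, se_fixed = se_fixed, q = q)
}

oracle_egger <- function(bx, by, sy) {
  flip <- ifelse(bx < 0, -1, 1)
  fit <- lm(I(by * flip) ~ I(bx * flip), weights = 1 / sy^2)
  sm <- summary(fit)
  nominal_se <- sm$coefficients[, 2] / sm$sigma
  infl <- max(1, sm$sigma)
  list(intercept = unname(coef(fit)[1]), slope = unname(coef(fit)[2]),
       se_intercept = unname(nominal_se[1]) * infl,
       se_slope = unname(nominal_se[2]) * infl)
}

oracle_weighted_median <- function(r, w) {
  ord <- order(r)
  r <- r[ord]; w <- w[ord]
  p <- (cumsum(w) - w / 2) / sum(w)
  if (0.5 <= p[1]) return(r[1])
  if (0.5 >= p[length(p)]) return(r[length(r)])
  approx(p, r, xout = 0.5, ties = "ordered")$y
}

oracle_q <- function(bx, by, sy) {
  w <- bx^2 / sy^2
  r <- by / bx
  beta <- sum(w * r) / sum(w)
  q <- 0
  for (j in seq_along(r)) q <- q + w[j] * (r[j] - beta)^2
  q
}

oracle_mvmr <- function(X, y, sy) {
  fit <- lm(y ~ 0 + X, weights = 1 / sy^2)
  sm <- summary(fit)
  list(beta = unname(coef(fit)),
       se = unname(sm$coefficients[, 2] / sm$sigma))
}

# Random estimator fixture: exposure/outcome effect vectors with noise.
random_fixture <- function(seed, n = 8) {
  set.seed(seed)
  bx <- runif(n, 0.03, 0.2) * sample(c(-1, 1), n, replace = TRUE)
  sx <- runif(n, 0.003, 0.01)
  sy <- runif(n, 0.005, 0.02)
  by <- 0.25 * bx + rnorm(n, 0, sy)
  list(bx = bx, sx = sx, by = by, sy = sy)
}

fixture_pair <- function(f) {
  mrmediate:::pair_from_vectors(f$bx, f$sx, f$by, f$sy)
}

# A sumstats object from a compact spec, defaulting unstated columns.
make_set <- function(snp, beta, se, p = NULL, ea = "A", oa = "G",
                     eaf = 0.25, chr = "1", pos = NULL, n = 1e5,
                     name = "trait", type = "continuous") {
  k <- length(snp)
  if (is.null(p)) p <- 2 * pnorm(-abs(beta / se))
  if (is.null(pos)) pos <- seq_len(k) * 1e6
  sumstats(data.frame(SNP = snp, CHR = rep_len(chr, k), POS = pos,
                      EA = rep_len(ea, k), OA = rep_len(oa, k),
                      EAF = rep_len(eaf, k), BETA = beta, SE = rep_len(se, k),
                      P = p, N = rep_len(n, k), stringsAsFactors = FALSE),
           trait_name = name, trait_type = type)
}

# Battery of exposures over a shared variant panel: each exposure has strong
# instruments on its own 5-variant block; the outcome responds only to the
# exposures listed in true_idx with effect c_effect.
make_battery <- function(n_exposures, true_idx, c_effect = 0.3, seed = 1,
                         n_gwas = 2e5) {
  set.seed(seed)
  k <- 5
  m <- n_exposures * k
  snp <- sprintf("rs%05d", seq_len(m))
  pos <- seq_len(m) * 1e7
  se <- rep(1 / sqrt(2 * 0.25 * 0.75 * n_gwas), m)
  gam <- matrix(0, m, n_exposures)
  exposures <- vector("list", n_exposures)
  for (i in seq_len(n_exposures)) {
    rows <- ((i - 1) * k + 1):(i * k)
    gam[rows, i] <- runif(k, 0.04, 0.08) * sample(c(-1, 1), k, TRUE)
    beta <- gam[, i] + rnorm(m, 0, se)
    exposures[[i]] <- make_set(snp, beta, se[1], pos = pos,
                               name = sprintf("X%02d", i), n = n_gwas)
  }
  names(exposures) <- sprintf("X%02d", seq_len(n_exposures))
  true_effect <- rowSums(gam[, true_idx, drop = FALSE]) * c_effect
  by <- true_effect + rnorm(m, 0, se)
  outcome <- make_set(snp, by, se[1], pos = pos, name = "Y", n = n_gwas,
                      type = "binary")
  list(exposures = exposures, outcome = outcome, gamma = gam)
}
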