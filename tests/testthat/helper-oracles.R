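# Independent line-by-line transcription of the Weir & Cockerham (1984)
# two-population estimator, scalar per marker. Deliberately written as plain
# loops over the printed formulas so it shares no code with the package's
# vectorised implementation.
wc_fst_oracle <- function(d1, d2) {
  m <- ncol(d1)
  theta <- rep(NA_real_, m)
  for (j in seq_len(m)) {
    x1 <- d1[, j]; x1 <- x1[!is.na(x1)]
    x2 <- d2[, j]; x2 <- x2[!is.na(x2)]
    n1 <- length(x1); n2 <- length(x2)
    if (n1 < 2 || n2 < 2) next
    r <- 2
    p1 <- sum(x1) / (2 * n1)
    p2 <- sum(x2) / (2 * n2)
    h1 <- sum(x1 == 1) / n1
    h2 <- sum(x2 == 1) / n2
    nbar <- (n1 + n2) / r
    nc <- (n1 + n2 - (n1^2 + n2^2) / (n1 + n2)) / (r - 1)
    pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
    s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
    hbar <- (n1 * h1 + n2 * h2) / (n1 + n2)
    a <- (nbar / nc) *
      (s2 - (1 / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
    cc <- hbar / 2
    if ((a + b + cc) != 0) theta[j] <- a / (a + b + cc)
  }
  theta
}

# Random two-population toy dataset with missingness.
rand_toy_pops <- function(max_n = 20, max_m = 50, miss = 0.15) {
  n1 <- sample(2:max_n, 1)
  n2 <- sample(2:max_n, 1)
  m <- sample(5:max_m, 1)
  pr <- c((1 - miss) * c(0.35, 0.25, 0.40), miss)
  list(d1 = matrix(sample(c(0L, 1L, 2L, NA), n1 * m, TRUE, pr), n1, m),
       d2 = matrix(sample(c(0L, 1L, 2L, NA), n2 * m, TRUE, pr), n2, m))
}

# Two Balding-Nichols pools of HWE diploids around ancestral p ~ U(0.1, 0.9),
# as genotype matrices (uses the current RNG stream).
bn_two_pools <- function(F, n, m) {
  p <- stats::runif(m, 0.1, 0.9)
  sh1 <- p * (1 - F) / F
  sh2 <- (1 - p) * (1 - F) / F
  p1 <- stats::rbeta(m, sh1, sh2)
  p2 <- stats::rbeta(m, sh1, sh2)
  list(d1 = matrix(stats::rbinom(n * m, 2L, rep(p1, each = n)), n, m),
       d2 = matrix(stats::rbinom(n * m, 2L, rep(p2, each = n)), n, m),
       p1 = p1, p2 = p2, p = p)
}

# Genotype matrix from two pool dosage matrices plus pop labels.
pops_to_gm <- function(d1, d2, map = NULL) {
  d <- rbind(d1, d2)
  rownames(d) <- sprintf("s%03d", seq_len(nrow(d)))
  colnames(d) <- sprintf("m%03d", seq_len(ncol(d)))
  gm <- genotype_matrix(d, map = map)
  gm$samples$pop <- rep(c("A", "B"), c(nrow(d1), nrow(d2)))
  gm
}

# Weighted (ratio-of-sums) genome-wide theta of an fst_result.
weighted_theta <- function(fr) fr$summary$weighted_theta

# Bin table builder for LD-decay fits (200 x 5-kb bins up to 1 Mb).
make_bins <- function(mean_r2, n_pairs = 50, window = 5000, max_dist = 1e6) {
  nb <- max_dist / window
  stopifnot(length(mean_r2) == nb)
  b <- data.frame(bin = 0:(nb - 1), left = (0:(nb - 1)) * window,
                  right = (1:nb) * window, mid = (0:(nb - 1)) * window + window / 2,
                  n_pairs = n_pairs, mean_r2 = mean_r2)
  attr(b, "window") <- window
  attr(b, "max_dist") <- max_dist
  b
}

# Shape check on an evaluated decay curve: non-increasing and convex.
expect_mdcx <- function(fit, tol = 1e-8) {
  f <- fit$grid$r2
  expect_lte(max(diff(f)), tol)
  expect_gte(min(diff(diff(f))), -tol)
}

# Small simulated-population helper: single neutral pool of homozygous lines.
single_pool_population <- function(config) {
  ff <- breedpop:::.draw_founder_frequencies(config)
  pop <- simulate_founders(ff, config)
  pop$pools <- pop$pools["SS"]
  pop
}
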