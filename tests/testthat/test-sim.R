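# Small configuration used by several blocks: 5 eras at reduced census.
small_cfg <- function(seed, ...) {
  sim_config(n_chromosomes = 4, markers_per_chromosome = 120,
             founders_per_pool = 30, lines_per_pool_per_era = 80,
             generations_per_era = 3, seed = seed, ...)
}

test_that("identical configurations give bit-identical outputs", {
  cfg <- small_cfg(5)
  s1 <- simulate_program(cfg)
  s2 <- simulate_program(cfg)
  expect_identical(s1$genotypes$dosages, s2$genotypes$dosages)
  expect_identical(s1$genotypes$samples, s2$genotypes$samples)
  expect_identical(s1$qtl, s2$qtl)
  s3 <- simulate_program(small_cfg(6))
  expect_false(identical(s1$genotypes$dosages, s3$genotypes$dosages))
})

test_that("founder draws follow the Balding-Nichols divergence model", {
  cfg <- sim_config(n_chromosomes = 5, markers_per_chromosome = 400, seed = 3,
                    founder_F = c(SS = 1e-4, IDT = 1e-4, LAN = 1e-4))
  ff <- draw_founder_frequencies(cfg)
  # F -> 0 limit: pool frequencies hug the ancestral ones
  for (k in 1:3)
    expect_gt(mean(abs(ff$pool_freqs[, k] - ff$ancestral_p) < 0.02), 0.99)
  ff2 <- draw_founder_frequencies(cfg)
  expect_identical(ff, ff2)

  # estimator recovery at F = 0.25 from sampled diploids
  for (seed in 1:3) {
    set.seed(seed)
    bn <- bn_two_pools(F = 0.25, n = 200, m = 5000)
    gm <- pops_to_gm(bn$d1, bn$d2)
    th <- weighted_theta(wc_fst(gm, gm$samples$pop))
    expect_gt(th, 0.22); expect_lt(th, 0.28)
  }
})

test_that("founders are fully homozygous and match their pool frequencies", {
  cfg <- sim_config(n_chromosomes = 4, markers_per_chromosome = 150,
                    founders_per_pool = 40, seed = 17)
  ff <- draw_founder_frequencies(cfg)
  pop <- simulate_founders(ff, cfg)
  expect_named(pop$pools, c("SS", "IDT", "LAN"))
  for (pn in names(pop$pools)) {
    p <- pop$pools[[pn]]
    expect_identical(p$h1, p$h2)                        # no heterozygous calls
    expect_equal(nrow(p$h1), 40L)
    phat <- colMeans(p$h1)
    rmse <- sqrt(mean((phat - ff$pool_freqs[, pn])^2))
    expect_lt(rmse, 0.09)  # binomial sampling sd at n = 40 is ~0.079 at p = .5
    expect_equal(unname(rowSums(p$anc)), rep(1, 40))
  }
})

test_that("one neutral generation conserves allele frequencies at large census", {
  cfg <- sim_config(n_chromosomes = 3, markers_per_chromosome = 100,
                    founders_per_pool = 2000, lines_per_pool_per_era = 2000,
                    selection = "neutral", migration_idt_lan = 0, seed = 23)
  pop <- single_pool_population(cfg)
  p0 <- colMeans(pop$pools$SS$h1 + pop$pools$SS$h2) / 2
  pop1 <- advance_generation(pop, cfg)
  p1 <- colMeans(pop1$pools$SS$h1 + pop1$pools$SS$h2) / 2
  expect_lt(abs(mean(p1 - p0)), 0.005)
})

test_that("recombination follows the Haldane map function", {
  set.seed(41)
  layout <- list(idx = list(1:50), relpos = list(seq(0, 1, length.out = 50)))
  h1 <- rep(0L, 50); h2 <- rep(1L, 50)
  lambda <- 1.5
  n <- 6000
  ends_recomb <- 0; switches <- 0
  for (i in seq_len(n)) {
    g <- breedpop:::.gamete(h1, h2, layout, lambda)
    ends_recomb <- ends_recomb + (g[1] != g[50])
    switches <- switches + sum(diff(g) != 0)
  }
  # recombination fraction between chromosome ends: Haldane (1 - exp(-2d))/2
  r_exp <- (1 - exp(-2 * lambda)) / 2
  expect_lt(abs(ends_recomb / n - r_exp), 3 * sqrt(r_exp * (1 - r_exp) / n) + 0.005)
  # observable crossover count per meiosis close to the map length in Morgans
  expect_lt(abs(switches / n - lambda) / lambda, 0.05)
})

test_that("doubled-haploid offspring are fully homozygous", {
  cfg <- small_cfg(9)
  pop <- single_pool_population(cfg)
  nxt <- advance_generation(pop, cfg)
  expect_identical(nxt$pools$SS$h1, nxt$pools$SS$h2)
  expect_equal(nrow(nxt$pools$SS$h1), cfg$lines_per_pool_per_era)

  cfg2 <- small_cfg(9, make_dh = FALSE)
  nxt2 <- advance_generation(single_pool_population(cfg2), cfg2)
  expect_false(identical(nxt2$pools$SS$h1, nxt2$pools$SS$h2))
})

test_that("truncation selection raises mean genetic value", {
  for (seed in 1:3) {
    cfg <- sim_config(n_chromosomes = 4, markers_per_chromosome = 100,
                      founders_per_pool = 80, lines_per_pool_per_era = 80,
                      selection = "additive", h2 = 0.8, n_qtl = 60,
                      migration_idt_lan = 0, seed = 100 + seed)
    set.seed(cfg$seed)
    ff <- breedpop:::.draw_founder_frequencies(cfg)
    pop <- simulate_founders(ff, cfg)
    pop$pools <- pop$pools["SS"]
    qtl <- list(index = sort(sample.int(400, 60)), effect = rnorm(60), dominance = 0)
    gv <- function(p) mean((p$pools$SS$h1 + p$pools$SS$h2)[, qtl$index] %*% qtl$effect)
    g0 <- gv(pop)
    for (t in 1:5) pop <- advance_generation(pop, cfg, qtl = qtl)
    expect_gt(gv(pop), g0)
  }
})

test_that("the programmed merge produces the documented era/pool layout", {
  sim <- simulate_program(small_cfg(44))
  st <- sim$genotypes$samples
  expect_setequal(unique(st$pool[st$era < 3]), c("SS", "IDT", "LAN"))
  expect_setequal(unique(st$pool[st$era >= 3]), c("SS", "NSS"))
  expect_true(all(table(st$era, st$pool)[, "SS"] == 80))
  expect_setequal(unique(st$group), c("SS", "NSS"))
  expect_true(all(st$subgroup[st$group == "NSS"] %in% c("IDT", "LAN")))
  # ancestry truth: rows sum to one, SS stays pure without SS-side migration
  expect_equal(st$anc_ss + st$anc_idt + st$anc_lan, rep(1, nrow(st)))
  expect_true(all(st$anc_ss[st$pool == "SS"] == 1))
  # DH lines carry no heterozygous calls
  expect_false(any(sim$genotypes$dosages == 1L))
})

test_that("the simulated program reproduces the homogenization trajectories", {
  sim <- simulate_program(small_cfg(7))
  gmx <- sim$genotypes
  st <- gmx$samples
  pairfst <- function(era, col, a, b) {
    sel <- st$era == era & st[[col]] %in% c(a, b)
    wc_fst(subset_genotypes(gmx, samples = which(sel)),
           st[[col]][sel])$summary$mean_theta
  }
  expect_gt(pairfst(4, "group", "SS", "NSS"), pairfst(0, "group", "SS", "NSS"))
  expect_lt(pairfst(4, "subgroup", "IDT", "LAN"),
            0.25 * pairfst(0, "subgroup", "IDT", "LAN"))
  nss_div <- function(era) {
    ft <- allele_frequencies(
      subset_genotypes(gmx, samples = which(st$era == era & st$group == "NSS")))
    c(he = mean(ft$he[ft$defined]), p05 = mean(ft$maf[ft$defined] < 0.05))
  }
  d0 <- nss_div(0); d4 <- nss_div(4)
  expect_lt(d4["he"], d0["he"])
  expect_gt(d4["p05"], d0["p05"])
})
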