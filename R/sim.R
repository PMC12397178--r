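#' Configuration of a simulated two-heterotic-group breeding program
#'
#' Describes a forward-time inbred-development program with three ancestral
#' founder pools (Stiff Stalk SS, Iodent IDT, Lancaster LAN), recurrent
#' selection with optional testers from the opposite pool, doubled-haploid
#' (DH) line production, gene flow between IDT and LAN, and a programmed
#' merge of IDT and LAN into a single Non-Stiff Stalk (NSS) pool at
#' `merge_era`. Founder pools diverge from a common ancestral allele-frequency
#' distribution under the Balding-Nichols model with per-pool drift
#' parameters `founder_F`.
#'
#' @param n_chromosomes,markers_per_chromosome genome dimensions
#' @param chrom_length_bp physical chromosome length (marker positions are
#'   drawn uniformly and sorted)
#' @param map_length_cM genetic chromosome length; crossovers per meiosis are
#'   Poisson with mean `map_length_cM / 100` placed uniformly on the map
#'   (Haldane, no interference)
#' @param ancestral_p_range uniform range of ancestral allele frequencies
#' @param founder_F named Balding-Nichols drift parameters for SS, IDT, LAN
#' @param founders_per_pool fully homozygous founder lines per pool
#' @param eras number of eras; each era spans `generations_per_era`
#'   breeding cycles
#' @param lines_per_pool_per_era pool census and number of lines recorded per
#'   pool per era
#' @param selection `"neutral"`, `"additive"` (truncation on own genetic
#'   value) or `"testcross"` (truncation on mean hybrid value with a fixed
#'   opposite-pool tester, including dominance at heterozygous QTL)
#' @param n_qtl,effect_sd,h2,selected_fraction genetic architecture and
#'   selection intensity
#' @param dominance_degree dominance effect at a heterozygous QTL as a
#'   multiple of the absolute additive effect (`NULL` picks 0 for additive
#'   and 0.5 for testcross selection)
#' @param migration_idt_lan per-generation probability that an IDT offspring
#'   is replaced by an IDT x LAN cross derivative (and symmetrically), before
#'   the merge
#' @param merge_era era index at which IDT and LAN become one NSS pool
#' @param make_dh produce fully homozygous DH offspring (one doubled gamete
#'   per line); `FALSE` gives random-mating diploids (two independent
#'   gametes), the classical Wright-Fisher mode
#' @param seed integer seed recorded in all outputs
#' @return a validated list of class `sim_config`
#' @export
sim_config <- function(n_chromosomes = 10, markers_per_chromosome = 200,
                       chrom_length_bp = 100e6, map_length_cM = 150,
                       ancestral_p_range = c(0.1, 0.9),
                       founder_F = c(SS = 0.20, IDT = 0.25, LAN = 0.15),
                       founders_per_pool = 40,
                       eras = 5, generations_per_era = 4,
                       lines_per_pool_per_era = 150,
                       selection = c("testcross", "additive", "neutral"),
                       n_qtl = 100, effect_sd = 1, h2 = 0.5,
                       selected_fraction = 0.2, dominance_degree = NULL,
                       migration_idt_lan = 0.05, merge_era = 3,
                       make_dh = TRUE, seed = 1L) {
  selection <- match.arg(selection)
  if (is.null(dominance_degree))
    dominance_degree <- if (selection == "testcross") 0.5 else 0
  cfg <- list(n_chromosomes = as.integer(n_chromosomes),
              markers_per_chromosome = as.integer(markers_per_chromosome),
              chrom_length_bp = chrom_length_bp, map_length_cM = map_length_cM,
              ancestral_p_range = ancestral_p_range, founder_F = founder_F,
              founders_per_pool = as.integer(founders_per_pool),
              eras = as.integer(eras),
              generations_per_era = as.integer(generations_per_era),
              lines_per_pool_per_era = as.integer(lines_per_pool_per_era),
              selection = selection, n_qtl = as.integer(n_qtl),
              effect_sd = effect_sd, h2 = h2,
              selected_fraction = selected_fraction,
              dominance_degree = dominance_degree,
              migration_idt_lan = migration_idt_lan,
              merge_era = as.integer(merge_era), make_dh = make_dh,
              seed = as.integer(seed))
  stopifnot(cfg$n_chromosomes >= 1, cfg$markers_per_chromosome >= 2,
            all(cfg$founder_F > 0 & cfg$founder_F < 1),
            all(names(cfg$founder_F) == c("SS", "IDT", "LAN")),
            cfg$selected_fraction > 0, cfg$selected_fraction <= 1,
            cfg$h2 >= 0, cfg$h2 <= 1,
            cfg$migration_idt_lan >= 0, cfg$migration_idt_lan < 1,
            cfg$merge_era < cfg$eras,
            diff(cfg$ancestral_p_range) >= 0)
  structure(cfg, class = "sim_config")
}

#' Draw the marker map and Balding-Nichols founder-pool allele frequencies
#'
#' Ancestral frequencies are uniform on `ancestral_p_range`; each pool's
#' frequency at a marker is an independent
#' `Beta(p (1 - F) / F, (1 - p)(1 - F) / F)` draw around the ancestral `p`,
#' so that the expected pairwise differentiation between pools is governed by
#' the drift parameters `founder_F`. Seeds the RNG from `config$seed`, so
#' identical configurations give identical frequencies.
#'
#' @param config a [sim_config()]
#' @return list with `map` (marker map `data.frame`), `ancestral_p` and
#'   `pool_freqs` (markers x 3 matrix, columns SS, IDT, LAN).
#' @export
draw_founder_frequencies <- function(config) {
  set.seed(config$seed)
  .draw_founder_frequencies(config)
}

.draw_founder_frequencies <- function(config) {
  m_per <- config$markers_per_chromosome
  map <- do.call(rbind, lapply(seq_len(config$n_chromosomes), function(ch) {
    pos <- sort(sample.int(config$chrom_length_bp, m_per))
    data.frame(marker_id = sprintf("chr%02d_m%04d", ch, seq_len(m_per)),
               chrom = sprintf("chr%02d", ch), pos = pos, stringsAsFactors = FALSE)
  }))
  m <- nrow(map)
  p <- stats::runif(m, config$ancestral_p_range[1], config$ancestral_p_range[2])
  pool_freqs <- vapply(config$founder_F, function(F) {
    stats::rbeta(m, p * (1 - F) / F, (1 - p) * (1 - F) / F)
  }, numeric(m))
  colnames(pool_freqs) <- names(config$founder_F)
  rownames(pool_freqs) <- map$marker_id
  list(map = map, ancestral_p = p, pool_freqs = pool_freqs)
}

#' Simulate fully homozygous founder lines for each ancestral pool
#'
#' Each founder is an inbred line: its single (doubled) haplotype carries the
#' alternate allele at marker `m` with probability equal to the pool
#' frequency, so founders contain no heterozygous calls.
#'
#' @param founder_freqs output of [draw_founder_frequencies()]
#' @param config a [sim_config()]
#' @return a `sim_population`: list of pools, each with haplotype matrices
#'   `h1`, `h2` (0/1), an ancestry matrix `anc` (rows sum to 1) and a census
#'   multiplier `n_units`.
#' @export
simulate_founders <- function(founder_freqs, config) {
  map <- founder_freqs$map
  pools <- lapply(colnames(founder_freqs$pool_freqs), function(pool) {
    n <- config$founders_per_pool
    m <- nrow(map)
    h <- matrix(stats::rbinom(n * m, 1L, rep(founder_freqs$pool_freqs[, pool], each = n)),
                n, m)
    anc <- matrix(0, n, 3, dimnames = list(NULL, c("SS", "IDT", "LAN")))
    anc[, pool] <- 1
    list(name = pool, h1 = h, h2 = h, anc = anc, n_units = 1L)
  })
  names(pools) <- colnames(founder_freqs$pool_freqs)
  structure(list(pools = pools, map = map), class = "sim_population")
}

# Precompute per-chromosome marker indices and relative genetic positions.
.chrom_layout <- function(map, chrom_length_bp) {
  chs <- unique(map$chrom)
  list(idx = lapply(chs, function(ch) which(map$chrom == ch)),
       relpos = lapply(chs, function(ch) map$pos[map$chrom == ch] / chrom_length_bp))
}

# One meiosis: recombine two haplotypes into a gamete. Crossover counts are
# Poisson(map_length_cM/100) per chromosome, positions uniform on the genetic
# map (Haldane, no interference).
.gamete <- function(h1, h2, layout, lambda) {
  g <- h1
  for (c in seq_along(layout$idx)) {
    ix <- layout$idx[[c]]
    k <- stats::rpois(1L, lambda)
    start <- sample.int(2L, 1L) - 1L
    if (k == 0L) {
      if (start == 1L) g[ix] <- h2[ix]
      next
    }
    seg <- findInterval(layout$relpos[[c]], sort(stats::runif(k)))
    use2 <- (seg + start) %% 2L == 1L
    if (any(use2)) g[ix[use2]] <- h2[ix[use2]]
  }
  g
}

# Genetic values of candidate lines. d: dosage matrix restricted to QTL.
.genetic_values <- function(dq, effects) drop(dq %*% effects)

# Expected testcross value against a fixed homozygous tester: hybrid dosage
# (d_i + d_t)/2 plus dominance at QTL where line and tester differ.
.testcross_values <- function(dq, dt, effects, dom) {
  hyb <- sweep(dq, 2, dt, "+") / 2
  het <- sweep(dq, 2, dt, "!=")
  drop(hyb %*% effects) + drop(het %*% (dom * abs(effects)))
}

.select_parents <- function(pool, config, qtl, tester_dq) {
  n <- nrow(pool$h1)
  if (config$selection == "neutral") return(seq_len(n))
  dq <- (pool$h1 + pool$h2)[, qtl$index, drop = FALSE]
  g <- if (config$selection == "additive") .genetic_values(dq, qtl$effect)
       else .testcross_values(dq, tester_dq, qtl$effect, config$dominance_degree)
  vg <- stats::var(g)
  noise <- if (vg > 0 && config$h2 > 0 && config$h2 < 1)
    stats::rnorm(n, 0, sqrt(vg * (1 - config$h2) / config$h2)) else 0
  phen <- g + noise
  n_sel <- max(2L, ceiling(config$selected_fraction * n))
  order(phen, decreasing = TRUE)[seq_len(n_sel)]
}

# Cross two parents of a pool (or pools) and produce one offspring.
# DH mode: one recombinant gamete of the F1, doubled. Non-DH: one gamete
# from each parent (random union of gametes).
.make_offspring <- function(pa, pb, popa, popb, layout, lambda, make_dh) {
  if (make_dh) {
    g <- .gamete(popa$h1[pa, ], popb$h1[pb, ], layout, lambda)
    list(h1 = g, h2 = g)
  } else {
    list(h1 = .gamete(popa$h1[pa, ], popa$h2[pa, ], layout, lambda),
         h2 = .gamete(popb$h1[pb, ], popb$h2[pb, ], layout, lambda))
  }
}

#' Advance a simulated population by one breeding cycle
#'
#' For every pool: (i) parents are chosen according to the selection mode
#' (neutral: all lines; additive: truncation on own genetic value with
#' heritability `h2`; testcross: truncation on expected hybrid value with a
#' fixed tester drawn from the opposite side, including dominance at
#' heterozygous QTL); (ii) offspring are produced from random ordered pairs
#' of distinct selected parents, each offspring being a doubled haploid of a
#' recombinant F1 gamete (`make_dh = TRUE`) or a random union of parental
#' gametes (`make_dh = FALSE`); (iii) before the merge era, IDT offspring are
#' replaced with probability `migration_idt_lan` by IDT x LAN cross
#' derivatives, and symmetrically for LAN. Ancestry fractions of an offspring
#' are the average of its parents' fractions.
#'
#' @param pop a `sim_population`
#' @param config a [sim_config()]
#' @param qtl QTL table (built by [simulate_program()]; `NULL` implies
#'   neutral evolution)
#' @return the next-generation `sim_population`
#' @export
advance_generation <- function(pop, config, qtl = NULL) {
  layout <- .chrom_layout(pop$map, config$chrom_length_bp)
  lambda <- config$map_length_cM / 100
  pools <- pop$pools
  use_sel <- config$selection != "neutral" && !is.null(qtl)

  # fixed testers per pool for this cycle, from the opposite heterotic side
  tester_dq <- list()
  if (use_sel && config$selection == "testcross") {
    ss_side <- intersect(names(pools), "SS")
    nss_side <- setdiff(names(pools), "SS")
    pick_tester <- function(from_pools) {
      pn <- sample(from_pools, 1L)
      i <- sample.int(nrow(pools[[pn]]$h1), 1L)
      (pools[[pn]]$h1[i, ] + pools[[pn]]$h2[i, ])[qtl$index]
    }
    for (pn in names(pools))
      tester_dq[[pn]] <- if (pn %in% nss_side) pick_tester(ss_side) else pick_tester(nss_side)
  }

  selected <- lapply(names(pools), function(pn) {
    idx <- if (use_sel)
      .select_parents(pools[[pn]], config, qtl, tester_dq[[pn]])
    else seq_len(nrow(pools[[pn]]$h1))
    if (length(idx) < 2L) .stopf("selected set smaller than 2 in pool %s", pn)
    idx
  })
  names(selected) <- names(pools)

  cross_within <- function(pool, sel, n_off) {
    pa <- sample(sel, n_off, replace = TRUE)
    pb <- sample(sel, n_off, replace = TRUE)
    clash <- pa == pb
    while (any(clash) && length(sel) > 1L) {
      pb[clash] <- sample(sel, sum(clash), replace = TRUE)
      clash <- pa == pb
    }
    h1 <- matrix(0L, n_off, ncol(pool$h1)); h2 <- h1
    for (o in seq_len(n_off)) {
      off <- .make_offspring(pa[o], pb[o], pool, pool, layout, lambda, config$make_dh)
      h1[o, ] <- off$h1; h2[o, ] <- off$h2
    }
    list(h1 = h1, h2 = h2, anc = (pool$anc[pa, , drop = FALSE] +
                                    pool$anc[pb, , drop = FALSE]) / 2)
  }

  nxt <- pools
  for (pn in names(pools)) {
    n_off <- config$lines_per_pool_per_era * pools[[pn]]$n_units
    off <- cross_within(pools[[pn]], selected[[pn]], n_off)
    nxt[[pn]]$h1 <- off$h1; nxt[[pn]]$h2 <- off$h2; nxt[[pn]]$anc <- off$anc
  }

  # gene flow between IDT and LAN while both pools exist
  if (all(c("IDT", "LAN") %in% names(pools)) && config$migration_idt_lan > 0) {
    for (side in list(c("IDT", "LAN"), c("LAN", "IDT"))) {
      a <- side[1]; b <- side[2]
      n_off <- nrow(nxt[[a]]$h1)
      mig <- which(stats::runif(n_off) < config$migration_idt_lan)
      for (o in mig) {
        pa <- sample(selected[[a]], 1L)
        pb <- sample(selected[[b]], 1L)
        off <- .make_offspring(pa, pb, pools[[a]], pools[[b]], layout, lambda,
                               config$make_dh)
        nxt[[a]]$h1[o, ] <- off$h1; nxt[[a]]$h2[o, ] <- off$h2
        nxt[[a]]$anc[o, ] <- (pools[[a]]$anc[pa, ] + pools[[b]]$anc[pb, ]) / 2
      }
    }
  }
  structure(list(pools = nxt, map = pop$map), class = "sim_population")
}

.merge_nss <- function(pop) {
  if (!all(c("IDT", "LAN") %in% names(pop$pools))) return(pop)
  idt <- pop$pools$IDT; lan <- pop$pools$LAN
  nss <- list(name = "NSS",
              h1 = rbind(idt$h1, lan$h1), h2 = rbind(idt$h2, lan$h2),
              anc = rbind(idt$anc, lan$anc),
              n_units = idt$n_units + lan$n_units)
  pop$pools <- c(pop$pools[setdiff(names(pop$pools), c("IDT", "LAN"))],
                 list(NSS = nss))
  pop
}

#' Run a full simulated breeding program
#'
#' Executes the configured number of eras sequentially: founders are drawn,
#' each era runs `generations_per_era` breeding cycles, IDT and LAN are
#' merged into the NSS pool at the start of `merge_era`, and after each era
#' `lines_per_pool_per_era` lines per pool are recorded with era labels. The
#' output genotypes, sample table (pool labels, two-group and ancestral
#' three-group assignments, true pedigree-expected ancestry fractions) and
#' QTL truth form the validation surface for every analysis module.
#' Deterministic under `config$seed`.
#'
#' @param config a [sim_config()]
#' @return an object of class `sim_output`: list with `genotypes`
#'   (a [genotype_matrix()] whose sample table carries `era`, `year`, `pool`,
#'   `group` (SS/NSS), `subgroup` (SS/IDT/LAN: ancestry majority before the
#'   merge, and a median split along the residual IDT-LAN ancestry gradient
#'   within the merged NSS pool afterwards, mirroring the cluster assignment
#'   a K = 3 structure analysis yields on a homogenized pool), `line_type`,
#'   `is_dh` and ancestry fractions `anc_ss`, `anc_idt`, `anc_lan`),
#'   `qtl` (marker indices, additive effects, dominance) and `config`.
#' @export
simulate_program <- function(config) {
  set.seed(config$seed)
  ff <- .draw_founder_frequencies(config)
  pop <- simulate_founders(ff, config)

  m <- nrow(ff$map)
  qtl_idx <- sort(sample.int(m, min(config$n_qtl, m)))
  qtl <- list(index = qtl_idx,
              effect = stats::rnorm(length(qtl_idx), 0, config$effect_sd),
              dominance = config$dominance_degree)

  era_years <- c(1985, 1995, 2005, 2015, 2021)
  dos <- list(); meta <- list()
  for (era in 0:(config$eras - 1L)) {
    if (era == config$merge_era) pop <- .merge_nss(pop)
    for (g in seq_len(config$generations_per_era))
      pop <- advance_generation(pop, config, qtl = qtl)
    for (pn in names(pop$pools)) {
      pool <- pop$pools[[pn]]
      n <- nrow(pool$h1)
      take <- if (n > config$lines_per_pool_per_era)
        sort(sample.int(n, config$lines_per_pool_per_era)) else seq_len(n)
      d <- pool$h1[take, , drop = FALSE] + pool$h2[take, , drop = FALSE]
      rownames(d) <- sprintf("E%d_%s_%03d", era, pn, seq_along(take))
      anc <- pool$anc[take, , drop = FALSE]
      if (pn == "SS") {
        subgroup <- rep("SS", nrow(anc))
      } else if (pn %in% c("IDT", "LAN")) {
        subgroup <- c("IDT", "LAN")[max.col(anc[, c("IDT", "LAN"), drop = FALSE],
                                            ties.method = "first")]
      } else {
        # merged NSS pool: every line converges towards the pool-mean ancestry,
        # so split along the residual Iodent-Lancaster ancestry gradient
        # (median split), emulating the balanced K = 3 cluster assignment a
        # structure analysis produces on a homogenized pool.
        delta <- anc[, "IDT"] - anc[, "LAN"]
        subgroup <- ifelse(delta >= stats::median(delta), "IDT", "LAN")
      }
      meta[[length(meta) + 1L]] <- data.frame(
        sample_id = rownames(d),
        year = if (era <= length(era_years) - 1) era_years[era + 1L] else 2021 + era,
        era = era, pool = pn,
        group = ifelse(pn == "SS", "SS", "NSS"),
        subgroup = subgroup, line_type = "inbred", is_dh = config$make_dh,
        anc_ss = anc[, "SS"], anc_idt = anc[, "IDT"], anc_lan = anc[, "LAN"],
        stringsAsFactors = FALSE)
      dos[[length(dos) + 1L]] <- d
    }
  }
  d_all <- do.call(rbind, dos)
  colnames(d_all) <- ff$map$marker_id
  st <- do.call(rbind, meta)
  gm <- genotype_matrix(d_all, map = ff$map, samples = st)
  structure(list(genotypes = gm,
                 qtl = data.frame(marker_id = ff$map$marker_id[qtl$index],
                                  chrom = ff$map$chrom[qtl$index],
                                  pos = ff$map$pos[qtl$index],
                                  effect = qtl$effect,
                                  dominance = qtl$dominance),
                 founder_freqs = ff, config = config),
            class = "sim_output")
}

#' @export
print.sim_output <- function(x, ...) {
  st <- x$genotypes$samples
  cat(sprintf("sim_output: %d lines x %d markers, eras %s (seed %d)\n",
              nrow(st), ncol(x$genotypes$dosages),
              paste(sort(unique(st$era)), collapse = ","), x$config$seed))
  print(table(era = st$era, pool = st$pool))
  invisible(x)
}

#' Write a simulated dataset as plain-text files
#'
#' Emits the dosage matrix (`genotypes.csv`), the sample metadata
#' (`samples.csv`), the marker map (`markers.csv`), the QTL truth
#' (`qtl.csv`) and the configuration echo (`config.yaml`, seed included)
#' into `dir`.
#'
#' @param sim a `sim_output`
#' @param dir output directory (created if needed)
#' @param vcf also write `genotypes.vcf`
#' @return `dir`, invisibly
#' @export
write_sim_output <- function(sim, dir, vcf = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_dosage_matrix(sim$genotypes, file.path(dir, "genotypes.csv"))
  utils::write.csv(sim$genotypes$samples, file.path(dir, "samples.csv"), row.names = FALSE)
  utils::write.csv(sim$genotypes$map, file.path(dir, "markers.csv"), row.names = FALSE)
  utils::write.csv(sim$qtl, file.path(dir, "qtl.csv"), row.names = FALSE)
  yaml::write_yaml(unclass(sim$config), file.path(dir, "config.yaml"))
  if (vcf) write_vcf_genotypes(sim$genotypes, file.path(dir, "genotypes.vcf"))
  invisible(dir)
}
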