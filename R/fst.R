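#' Two-population Weir-Cockerham fixation index, per marker
#'
#' Implements the Weir & Cockerham (1984) variance-component estimator of
#' F_ST (theta) for two populations with unequal sample sizes, including the
#' observed-heterozygosity term, matching the estimator used by PLINK 1.9 on
#' diploid genotypes. For each marker with populations of sizes `n_1`, `n_2`
#' (non-missing genotypes), allele frequencies `p_i` and heterozygote
#' frequencies `h_i`:
#' \deqn{\bar n = (n_1+n_2)/2, \quad
#'       n_c = (n_1+n_2 - (n_1^2+n_2^2)/(n_1+n_2))/(r-1), \quad r = 2}
#' \deqn{\bar p = (n_1 p_1 + n_2 p_2)/(n_1+n_2), \quad
#'       s^2 = \sum_i n_i (p_i-\bar p)^2 / ((r-1)\bar n), \quad
#'       \bar h = (n_1 h_1 + n_2 h_2)/(n_1+n_2)}
#' and the among-population (`a`), among-individual (`b`) and
#' within-individual (`c`) components follow the 1984 formulas, with
#' `theta = a / (a + b + c)`. Per-marker theta can be negative (no clamping)
#' and is undefined where either population has fewer than two called
#' genotypes or where `a + b + c = 0` (marker monomorphic in both pools).
#'
#' @param gm a [genotype_matrix()]
#' @param labels per-sample population assignment (vector recycled against
#'   samples, or the name of a sample-table column). Exactly two non-missing
#'   levels are required; samples with `NA` labels are ignored.
#' @param high_threshold threshold for the high-differentiation proportion
#'   passed to [fst_summary()].
#' @return an object of class `fst_result`: list with `per_marker`
#'   (`data.frame` columns `marker_id, chrom, pos, a, b, c, theta, defined`),
#'   `summary` (see [fst_summary()]) and `pops` (the two labels).
#' @references Weir, B.S. & Cockerham, C.C. (1984) Estimating F-statistics
#'   for the analysis of population structure. Evolution 38:1358-1370.
#' @export
wc_fst <- function(gm, labels, high_threshold = 0.75) {
  lab <- .resolve_labels(gm, labels)
  lv <- levels(lab)
  d1 <- gm$dosages[!is.na(lab) & lab == lv[1], , drop = FALSE]
  d2 <- gm$dosages[!is.na(lab) & lab == lv[2], , drop = FALSE]
  if (nrow(d1) < 2 || nrow(d2) < 2)
    .stopf("each population needs at least 2 samples (got %d and %d)", nrow(d1), nrow(d2))
  comp <- .wc_components(d1, d2)
  per <- data.frame(marker_id = gm$map$marker_id, chrom = gm$map$chrom,
                    pos = gm$map$pos, a = comp$a, b = comp$b, c = comp$c,
                    theta = comp$theta, defined = comp$defined,
                    stringsAsFactors = FALSE)
  structure(list(per_marker = per,
                 summary = fst_summary(per, high_threshold = high_threshold),
                 pops = lv),
            class = "fst_result")
}

.resolve_labels <- function(gm, labels) {
  if (is.character(labels) && length(labels) == 1L && labels %in% names(gm$samples))
    labels <- gm$samples[[labels]]
  if (length(labels) != nrow(gm$dosages))
    .stopf("labels length %d != %d samples", length(labels), nrow(gm$dosages))
  lab <- factor(labels)
  if (nlevels(lab) != 2L)
    .stopf("exactly 2 population labels required, got %d", nlevels(lab))
  lab
}

# Vectorised WC 1984 components over markers for two dosage submatrices.
.wc_components <- function(d1, d2) {
  n1 <- colSums(!is.na(d1)); n2 <- colSums(!is.na(d2))
  p1 <- ifelse(n1 > 0, colSums(d1, na.rm = TRUE) / (2 * n1), NA_real_)
  p2 <- ifelse(n2 > 0, colSums(d2, na.rm = TRUE) / (2 * n2), NA_real_)
  h1 <- ifelse(n1 > 0, colSums(d1 == 1L, na.rm = TRUE) / n1, NA_real_)
  h2 <- ifelse(n2 > 0, colSums(d2 == 1L, na.rm = TRUE) / n2, NA_real_)
  r <- 2
  nsum <- n1 + n2
  nbar <- nsum / r
  nc <- (nsum - (n1^2 + n2^2) / nsum) / (r - 1)
  pbar <- ifelse(nsum > 0, (n1 * p1 + n2 * p2) / nsum, NA_real_)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- ifelse(nsum > 0, (n1 * h1 + n2 * h2) / nsum, NA_real_)
  a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  tot <- a + b + cc
  defined <- n1 >= 2 & n2 >= 2 & !is.na(tot) & tot != 0
  theta <- ifelse(defined, a / tot, NA_real_)
  a[!defined] <- NA_real_; b[!defined] <- NA_real_; cc[!defined] <- NA_real_
  list(a = a, b = b, c = cc, theta = theta, defined = defined)
}

#' Genome-wide and per-chromosome F_ST summaries
#'
#' The headline value `mean_theta` is the unweighted genome-wide average of
#' the defined per-marker thetas; the ratio-of-sums variant
#' `weighted_theta = sum(a) / sum(a + b + c)` is also reported. `p_high` is
#' the fraction of defined markers with theta strictly above
#' `high_threshold`.
#'
#' @param per_marker per-marker table from [wc_fst()] (`theta`, `defined`,
#'   `a`, `b`, `c`, `chrom` columns).
#' @param high_threshold strict threshold for high-differentiation markers.
#' @return a list with `mean_theta`, `weighted_theta`, `var_theta`, `p_high`,
#'   `n_defined` and `per_chromosome` (a `data.frame` with the same fields
#'   per chromosome).
#' @export
fst_summary <- function(per_marker, high_threshold = 0.75) {
  if (!any(per_marker$defined)) .stopf("no defined markers")
  one <- function(pm) {
    th <- pm$theta[pm$defined]
    tot <- pm$a[pm$defined] + pm$b[pm$defined] + pm$c[pm$defined]
    data.frame(mean_theta = mean(th),
               weighted_theta = sum(pm$a[pm$defined]) / sum(tot),
               var_theta = if (length(th) > 1) stats::var(th) else NA_real_,
               p_high = mean(th > high_threshold),
               n_defined = length(th))
  }
  g <- one(per_marker)
  per_chrom <- do.call(rbind, lapply(split(per_marker, per_marker$chrom), function(pm) {
    if (!any(pm$defined)) return(NULL)
    cbind(data.frame(chrom = pm$chrom[1], stringsAsFactors = FALSE), one(pm))
  }))
  rownames(per_chrom) <- NULL
  c(as.list(g), list(high_threshold = high_threshold, per_chromosome = per_chrom))
}

#' @export
print.fst_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Weir-Cockerham F_ST: %s vs %s\n", x$pops[1], x$pops[2]))
  cat(sprintf("  mean theta = %.4f  (ratio-of-sums %.4f)  over %d defined markers\n",
              s$mean_theta, s$weighted_theta, s$n_defined))
  cat(sprintf("  var theta = %.4f  P[theta > %.2f] = %.4f\n",
              s$var_theta, s$high_threshold, s$p_high))
  invisible(x)
}

#' Resampling variance protocol for the genome-wide F_ST
#'
#' Mimics a bootstrap: each replicate draws a fraction `frac` of the samples
#' (per population by default) at random with replacement, recomputes the
#' per-marker Weir-Cockerham theta on the subsample and records the
#' genome-wide unweighted mean over the markers defined in that replicate.
#' By default only inbred lines are resampled (selection lines contain many
#' full-sib and half-sib families that would deflate dissimilarity).
#'
#' @inheritParams wc_fst
#' @param frac fraction of each population drawn per replicate.
#' @param reps number of replicates.
#' @param with_replacement sample with replacement (default). With
#'   `frac = 1` and `with_replacement = FALSE` every replicate reproduces the
#'   full-data estimate exactly.
#' @param per_group draw `ceiling(frac * n_g)` samples within each population
#'   (default); `FALSE` draws from the pooled case, and a replicate missing
#'   one population entirely yields an `NA` replicate mean.
#' @param inbreds_only restrict to samples whose `line_type` is `"inbred"`
#'   (ignored when the sample table has no `line_type` column).
#' @param seed integer seed; the caller's RNG state is left untouched.
#' @return list with `replicate_means`, `mean`, `sd`, and the protocol record
#'   (`frac`, `reps`, `with_replacement`, `per_group`, `seed`, `n_per_group`).
#' @export
bootstrap_fst <- function(gm, labels, frac = 0.10, reps = 200,
                          with_replacement = TRUE, per_group = TRUE,
                          inbreds_only = TRUE, seed = NULL) {
  lab <- .resolve_labels(gm, labels)
  keep <- !is.na(lab)
  if (inbreds_only && "line_type" %in% names(gm$samples))
    keep <- keep & gm$samples$line_type == "inbred"
  d <- gm$dosages[keep, , drop = FALSE]
  lab <- droplevels(lab[keep])
  if (nlevels(lab) != 2L) .stopf("exactly 2 population labels required after filtering")
  idx <- split(seq_len(nrow(d)), lab)
  ng <- vapply(idx, length, 1L)
  draw <- pmax(ceiling(frac * ng), if (with_replacement) 1L else 0L)
  too_small <- draw < 2L | (!with_replacement & draw > ng)
  if (per_group && any(too_small))
    .stopf("group too small for resampling: %s (n = %d, frac = %.2f)",
           names(ng)[too_small][1], ng[too_small][1], frac)

  means <- .with_seed(seed, {
    vapply(seq_len(reps), function(r) {
      if (per_group) {
        i1 <- sample(idx[[1]], draw[1], replace = with_replacement)
        i2 <- sample(idx[[2]], draw[2], replace = with_replacement)
      } else {
        n_tot <- nrow(d)
        take <- max(ceiling(frac * n_tot), 2L)
        ii <- sample(seq_len(n_tot), take, replace = with_replacement)
        i1 <- ii[lab[ii] == levels(lab)[1]]
        i2 <- ii[lab[ii] == levels(lab)[2]]
        if (length(i1) < 2L || length(i2) < 2L) return(NA_real_)
      }
      comp <- .wc_components(d[i1, , drop = FALSE], d[i2, , drop = FALSE])
      if (!any(comp$defined)) return(NA_real_)
      mean(comp$theta[comp$defined])
    }, numeric(1))
  })
  list(replicate_means = means,
       mean = mean(means, na.rm = TRUE), sd = stats::sd(means, na.rm = TRUE),
       frac = frac, reps = reps, with_replacement = with_replacement,
       per_group = per_group, seed = seed, n_per_group = ng)
}
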