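#' Pairwise Hamming distances between lines
#'
#' The normalized Hamming distance between two lines is the proportion of
#' jointly non-missing markers at which their genotypes differ. By default a
#' mismatch is counted whenever the two dosages differ at all, independent of
#' the allelic state (a heterozygote differs from both homozygotes); the
#' allele-level variant (`allele_level = TRUE`) instead counts
#' `|d_i - d_j| / 2` per marker, so a heterozygote is at distance one half
#' from either homozygote.
#'
#' @param gm a [genotype_matrix()]
#' @param samples optional sample subset (mask, indices or ids)
#' @param allele_level count allele differences instead of genotype mismatches
#' @return an object of class `hamming_dist`: list with `d` (symmetric matrix
#'   of distances in `[0, 1]`, zero diagonal, `NA` for pairs with no jointly
#'   called marker) and `n_overlap` (matrix of jointly non-missing marker
#'   counts).
#' @examples
#' gm <- genotype_matrix(rbind(a = c(0, 1, 2, 2, NA), b = c(0, 2, 2, 0, 1)))
#' hamming_matrix(gm)$d["a", "b"]  # 2 mismatches / 4 overlapping markers
#' @export
hamming_matrix <- function(gm, samples = NULL, allele_level = FALSE) {
  if (!is.null(samples)) gm <- subset_genotypes(gm, samples = samples)
  d <- gm$dosages
  if (nrow(d) < 2) .stopf("need at least 2 samples")
  obs <- !is.na(d)
  storage.mode(obs) <- "double"
  overlap <- obs %*% t(obs)
  if (allele_level) {
    x <- d; x[is.na(x)] <- 0; storage.mode(x) <- "double"
    # sum |d_i - d_j|/2 over overlap = (d_i^2 + d_j^2 - 2 d_i d_j) is wrong for
    # L1; use the identity |a-b| = a + b - 2*min(a,b) via indicator expansion.
    i0 <- obs * (d == 0); i1 <- obs * (d == 1); i2 <- obs * (d == 2)
    i0[is.na(i0)] <- 0; i1[is.na(i1)] <- 0; i2[is.na(i2)] <- 0
    # pairwise sum of |a-b|: terms 0-1 and 1-2 contribute 1, 0-2 contributes 2
    mism <- (i0 %*% t(i1) + i1 %*% t(i0) + i1 %*% t(i2) + i2 %*% t(i1) +
               2 * (i0 %*% t(i2) + i2 %*% t(i0))) / 2
  } else {
    mism <- overlap
    for (v in c(0, 1, 2)) {
      iv <- obs * (d == v)
      iv[is.na(iv)] <- 0
      mism <- mism - iv %*% t(iv)
    }
  }
  dist <- ifelse(overlap > 0, mism / overlap, NA_real_)
  diag(dist) <- ifelse(diag(overlap) > 0, 0, NA_real_)
  dimnames(dist) <- dimnames(overlap) <- list(rownames(d), rownames(d))
  structure(list(d = dist, n_overlap = overlap, allele_level = allele_level),
            class = "hamming_dist")
}

#' @export
print.hamming_dist <- function(x, ...) {
  cat(sprintf("hamming_dist: %d samples, mean distance %.4f (%s-level)\n",
              nrow(x$d), mean(x$d[upper.tri(x$d)], na.rm = TRUE),
              if (x$allele_level) "allele" else "genotype"))
  invisible(x)
}

#' Era-stratified within- and between-group distance summaries
#'
#' Summarises a Hamming distance matrix per era for a list of group pairs,
#' in the shape of a between/within-group evolution table. Both members of a
#' pair must belong to the era being summarised; within-group cells
#' (`A == B`) exclude self-pairs. Pair order is immaterial.
#'
#' @param dm a `hamming_dist` from [hamming_matrix()]
#' @param meta sample table with `sample_id`, `era` and the grouping column;
#'   rows are matched to the distance matrix by `sample_id`.
#' @param pairs list of length-2 character vectors `c(groupA, groupB)`;
#'   use `c("SS", "SS")` for a within-group summary.
#' @param grouping name of the grouping column in `meta`.
#' @return `data.frame` with one row per (era, pair): `era`, `group_a`,
#'   `group_b`, `n_pairs`, `mean`, `sd`.
#' @export
group_distance_summary <- function(dm, meta, pairs, grouping = "group") {
  ids <- rownames(dm$d)
  m <- meta[match(ids, meta$sample_id), , drop = FALSE]
  if (anyNA(m$sample_id)) .stopf("distance matrix contains samples absent from meta")
  if (!all(c("era", grouping) %in% names(m)))
    .stopf("meta needs 'era' and '%s' columns", grouping)
  grp <- as.character(m[[grouping]])
  known <- unique(grp[!is.na(grp)])
  for (p in pairs)
    if (!all(p %in% known)) .warnf("pair (%s, %s): label absent from data", p[1], p[2])

  rows <- list()
  for (e in sort(unique(m$era[!is.na(m$era)]))) {
    for (p in pairs) {
      ia <- which(m$era == e & grp == p[1])
      ib <- which(m$era == e & grp == p[2])
      if (p[1] == p[2]) {
        if (length(ia) < 2) { vals <- numeric(0) } else {
          sub <- dm$d[ia, ia, drop = FALSE]
          vals <- sub[upper.tri(sub)]
        }
      } else {
        vals <- as.vector(dm$d[ia, ib, drop = FALSE])
      }
      vals <- vals[!is.na(vals)]
      rows[[length(rows) + 1L]] <- data.frame(
        era = e, group_a = p[1], group_b = p[2], n_pairs = length(vals),
        mean = if (length(vals)) mean(vals) else NA_real_,
        sd = if (length(vals) > 1) stats::sd(vals) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
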