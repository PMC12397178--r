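#' Per-marker allele frequencies, MAF and expected heterozygosity
#'
#' Counts alleles over non-missing genotypes only; heterozygous calls
#' contribute one allele of each type. Markers with no called genotype are
#' flagged `defined = FALSE` and excluded from all downstream summaries.
#'
#' @param gm a [genotype_matrix()]
#' @return a `data.frame` (one row per marker) with columns `marker_id`,
#'   `chrom`, `pos`, `n_called` (alleles observed, i.e. 2 x non-missing
#'   genotypes), `alt_count`, `p_alt`, `maf`, `he` (gene diversity
#'   `2 p (1 - p)` with `p` the major-allele frequency) and `defined`.
#' @examples
#' gm <- genotype_matrix(matrix(c(0, 0, 1, 2), 4, 1))
#' allele_frequencies(gm)[, c("n_called", "alt_count", "p_alt", "maf")]
#' @export
allele_frequencies <- function(gm) {
  d <- gm$dosages
  if (length(d) == 0L) .stopf("empty genotype matrix")
  n_geno <- colSums(!is.na(d))
  alt <- colSums(d, na.rm = TRUE)
  n_called <- 2L * n_geno
  p_alt <- ifelse(n_called > 0, alt / n_called, NA_real_)
  maf <- pmin(p_alt, 1 - p_alt)
  he <- 2 * p_alt * (1 - p_alt)  # symmetric in p vs 1-p: equals 2 p_major (1 - p_major)
  data.frame(marker_id = gm$map$marker_id, chrom = gm$map$chrom, pos = gm$map$pos,
             n_called = n_called, alt_count = alt, p_alt = p_alt,
             maf = maf, he = he, defined = n_called > 0,
             stringsAsFactors = FALSE)
}

#' Expected heterozygosity summary
#'
#' @param ft a frequency table from [allele_frequencies()]
#' @return a list with `he` (per-marker vector, NA where undefined), `mean`
#'   and `sd` over defined markers.
#' @export
expected_heterozygosity <- function(ft) {
  if (!any(ft$defined)) .stopf("no defined markers")
  he <- ifelse(ft$defined, ft$he, NA_real_)
  list(he = he, mean = mean(he, na.rm = TRUE), sd = stats::sd(he, na.rm = TRUE))
}

#' MAF-check fixation indicators
#'
#' Proportions of defined markers in the extreme tails of the minor-allele
#' frequency spectrum, using strict inequalities: `P[MAF < 0.01]`
#' (effectively monomorphic markers), `P[MAF < 0.05]` (extreme-tail markers,
#' close to fixation) and `P[MAF > 0.45]` (hyper-polymorphic markers).
#'
#' @param ft a frequency table from [allele_frequencies()] (any data frame
#'   with `maf`, `he` and `defined` columns works).
#' @param lt,gt strict lower / upper MAF thresholds.
#' @return a one-row `data.frame` with `n_markers_defined`, `mean_maf`,
#'   `sd_maf`, `mean_he`, `sd_he` and one proportion column per threshold
#'   (`p_maf_lt_001`, `p_maf_lt_005`, `p_maf_gt_045` for the defaults).
#' @examples
#' ft <- data.frame(maf = c(0, 0.04, 0.2, 0.5), defined = TRUE)
#' ft$he <- 2 * ft$maf * (1 - ft$maf)
#' maf_checks(ft)
#' @export
maf_checks <- function(ft, lt = c(0.01, 0.05), gt = 0.45) {
  maf <- ft$maf[ft$defined]
  if (length(maf) == 0L) .stopf("no defined markers")
  he <- ft$he[ft$defined]
  out <- data.frame(n_markers_defined = length(maf),
                    mean_maf = mean(maf), sd_maf = stats::sd(maf),
                    mean_he = mean(he), sd_he = stats::sd(he))
  for (t in lt) out[[.maf_col("lt", t)]] <- mean(maf < t)
  for (t in gt) out[[.maf_col("gt", t)]] <- mean(maf > t)
  out
}

.maf_col <- function(side, t) {
  sprintf("p_maf_%s_%s", side, gsub("[.]", "", sprintf("%.2f", t)))
}

#' Diversity summaries stratified by era and group
#'
#' Computes [maf_checks()] per (era, group) cell plus a `GLOBAL` pseudo-group
#' pooling all samples of the era. Cells with fewer than `min_n` samples are
#' kept but flagged `low_support`.
#'
#' @param gm a [genotype_matrix()] whose sample table has `era` and the
#'   grouping column.
#' @param grouping name of the sample-table column holding group labels
#'   (`"group"` for the two-group configuration, `"subgroup"` for the
#'   ancestral three-group configuration).
#' @param min_n minimum cell size before flagging.
#' @param line_type optional filter on the sample-table `line_type` column
#'   (e.g. `"inbred"`); `NULL` keeps all lines.
#' @return long-format `data.frame`: one row per (era, group).
#' @export
era_group_diversity <- function(gm, grouping = "group", min_n = 5, line_type = NULL) {
  st <- gm$samples
  if (!"era" %in% names(st)) .stopf("sample table needs an 'era' column")
  if (!grouping %in% names(st)) .stopf("sample table needs a '%s' column", grouping)
  keep <- rep(TRUE, nrow(st))
  if (!is.null(line_type) && "line_type" %in% names(st))
    keep <- keep & st$line_type %in% line_type
  keep <- keep & !is.na(st$era) & !is.na(st[[grouping]])
  if (!any(keep)) .stopf("no samples left after filtering")
  st <- st[keep, , drop = FALSE]
  gm <- subset_genotypes(gm, samples = which(keep))

  rows <- list()
  for (e in sort(unique(st$era))) {
    in_era <- st$era == e
    grps <- c("GLOBAL", sort(unique(st[[grouping]][in_era])))
    for (g in grps) {
      sel <- in_era & (g == "GLOBAL" | st[[grouping]] == g)
      if (!any(sel)) next
      ft <- allele_frequencies(subset_genotypes(gm, samples = which(sel)))
      if (!any(ft$defined)) next
      s <- maf_checks(ft)
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(era = e, group = g, n_samples = sum(sel),
                   low_support = sum(sel) < min_n, stringsAsFactors = FALSE), s)
    }
  }
  do.call(rbind, rows)
}
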