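#' Biallelic SNP genotype matrix for inbred-line collections
#'
#' The central container of the package: a samples x markers matrix of allele
#' dosages (0/1/2 counts of the alternate allele, `NA` for missing calls),
#' together with a marker map (chromosome, physical position) and a sample
#' metadata table (registration year, era, heterotic group, line type, doubled
#' haploid flag). All statistics in the package operate on this object.
#'
#' Dosages count alternate (non-reference) alleles; every downstream statistic
#' (minor-allele frequency, expected heterozygosity, r-squared, Weir-Cockerham
#' theta, Hamming distance) is invariant to flipping allele polarity, so the
#' orientation of the array is immaterial.
#'
#' @param dosages numeric or integer matrix, samples in rows, markers in
#'   columns, values in `{0, 1, 2, NA}`. Row and column names are used as
#'   sample and marker identifiers (generated when absent).
#' @param map optional `data.frame` with columns `marker_id`, `chrom`, `pos`
#'   (1-based bp) and optionally `ref`, `alt`. Defaults to a single chromosome
#'   with unit spacing.
#' @param samples optional `data.frame` with column `sample_id` and any of
#'   `year`, `era`, `group`, `subgroup`, `line_type`, `is_dh`.
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosages`, `map`, `samples`.
#' @examples
#' gm <- genotype_matrix(matrix(c(0, 2, 1, NA), 2, 2,
#'   dimnames = list(c("s1", "s2"), c("m1", "m2"))))
#' n_samples(gm); n_markers(gm)
#' @export
genotype_matrix <- function(dosages, map = NULL, samples = NULL) {
  if (!is.matrix(dosages)) .stopf("'dosages' must be a matrix")
  mode(dosages) <- "integer"
  bad <- !(dosages %in% c(0L, 1L, 2L, NA))
  if (any(bad)) .stopf("dosages must be 0, 1, 2 or NA (%d offending cells)", sum(bad))
  if (is.null(rownames(dosages)))
    rownames(dosages) <- sprintf("sample_%d", seq_len(nrow(dosages)))
  if (is.null(colnames(dosages)))
    colnames(dosages) <- sprintf("marker_%d", seq_len(ncol(dosages)))
  if (anyDuplicated(rownames(dosages)))
    .stopf("duplicate sample id: %s", rownames(dosages)[duplicated(rownames(dosages))][1])
  if (anyDuplicated(colnames(dosages)))
    .stopf("duplicate marker id: %s", colnames(dosages)[duplicated(colnames(dosages))][1])

  if (is.null(map)) {
    map <- data.frame(marker_id = colnames(dosages), chrom = "1",
                      pos = seq_len(ncol(dosages)), stringsAsFactors = FALSE)
  }
  map <- as.data.frame(map, stringsAsFactors = FALSE)
  need <- c("marker_id", "chrom", "pos")
  if (!all(need %in% names(map))) .stopf("map needs columns %s", paste(need, collapse = ", "))
  if (nrow(map) != ncol(dosages)) .stopf("map rows (%d) != markers (%d)", nrow(map), ncol(dosages))
  if (!identical(as.character(map$marker_id), colnames(dosages)))
    .stopf("map marker_id must match dosage column names (same order)")

  if (is.null(samples)) {
    samples <- data.frame(sample_id = rownames(dosages), stringsAsFactors = FALSE)
  }
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(samples)) .stopf("samples needs a sample_id column")
  if (nrow(samples) != nrow(dosages)) .stopf("samples rows (%d) != genotype rows (%d)",
                                             nrow(samples), nrow(dosages))
  if (!identical(as.character(samples$sample_id), rownames(dosages)))
    .stopf("samples sample_id must match dosage row names (same order)")

  structure(list(dosages = dosages, map = map, samples = samples),
            class = "genotype_matrix")
}

#' @rdname genotype_matrix
#' @param gm a `genotype_matrix`
#' @export
n_samples <- function(gm) nrow(gm$dosages)

#' @rdname genotype_matrix
#' @export
n_markers <- function(gm) ncol(gm$dosages)

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d markers (%d chromosomes)\n",
              nrow(x$dosages), ncol(x$dosages), length(unique(x$map$chrom))))
  miss <- mean(is.na(x$dosages))
  het <- mean(x$dosages == 1L, na.rm = TRUE)
  cat(sprintf("  missing: %.2f%%  heterozygous calls: %.2f%%\n", 100 * miss, 100 * het))
  extra <- setdiff(names(x$samples), "sample_id")
  if (length(extra)) cat("  sample metadata:", paste(extra, collapse = ", "), "\n")
  invisible(x)
}

#' Read genotypes from a dosage-matrix text file or a VCF
#'
#' The dosage-matrix dialect is a delimited text table: first column
#' `sample_id`, header row of marker ids, cells in `{0, 1, 2, NA}`. VCF input
#' is parsed with \pkg{vcfR}; only biallelic SNP records are kept and the
#' number of skipped multi-allelic records is reported with a message.
#'
#' @param path file path.
#' @param format `"dosage_matrix"` or `"vcf"`.
#' @param sep field separator for the dosage-matrix dialect.
#' @param map,samples optional marker map / sample table attached to the
#'   result (dosage-matrix format only).
#' @return a [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("dosage_matrix", "vcf"), sep = ",",
                           map = NULL, samples = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) .stopf("file not found: %s", path)
  if (format == "vcf") return(.read_vcf(path))

  tab <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                           stringsAsFactors = FALSE, na.strings = c("NA", ""))
  if (ncol(tab) < 2) .stopf("dosage matrix needs a sample_id column plus markers: %s", path)
  ids <- as.character(tab[[1]])
  if (anyDuplicated(ids)) .stopf("duplicate sample id in %s: %s", path, ids[duplicated(ids)][1])
  mk <- colnames(tab)[-1]
  if (anyDuplicated(mk)) .stopf("duplicate marker id in %s: %s", path, mk[duplicated(mk)][1])
  d <- as.matrix(tab[, -1, drop = FALSE])
  suppressWarnings(storage.mode(d) <- "integer")
  chk <- as.matrix(tab[, -1, drop = FALSE])
  bad <- which(!is.na(chk) & is.na(d), arr.ind = TRUE)
  if (nrow(bad)) .stopf("unparseable dosage at line %d, marker %s in %s",
                        bad[1, 1] + 1L, mk[bad[1, 2]], path)
  dimnames(d) <- list(ids, mk)
  genotype_matrix(d, map = map, samples = samples)
}

.read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  ref <- fix[, "REF"]
  keep <- !is.na(alt) & !grepl(",", alt) & nchar(alt) == 1L & nchar(ref) == 1L
  n_skip <- sum(!keep)
  if (n_skip > 0)
    message(sprintf("read_genotypes: skipped %d multi-allelic/non-SNP record(s)", n_skip))
  if (!any(keep)) .stopf("no biallelic SNP records in %s", path)
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  ref <- ref[keep]
  alt <- alt[keep]
  ids <- fix[, "ID"]
  noid <- is.na(ids) | ids == "." | ids == ""
  ids[noid] <- paste0(fix[noid, "CHROM"], "_", fix[noid, "POS"])
  if (anyDuplicated(ids)) .stopf("duplicate marker id in %s: %s", path, ids[duplicated(ids)][1])
  if (anyDuplicated(colnames(gt)))
    .stopf("duplicate sample id in %s: %s", path,
           colnames(gt)[duplicated(colnames(gt))][1])
  g <- gsub("|", "/", gt, fixed = TRUE)
  d <- matrix(NA_integer_, nrow = ncol(gt), ncol = nrow(gt),
              dimnames = list(colnames(gt), ids))
  d[t(g == "0/0")] <- 0L
  d[t(g == "0/1" | g == "1/0")] <- 1L
  d[t(g == "1/1")] <- 2L
  unknown <- !is.na(g) & !(g %in% c("0/0", "0/1", "1/0", "1/1", "./."))
  if (any(unknown)) {
    i <- which(unknown, arr.ind = TRUE)[1, ]
    .stopf("unparseable GT '%s' at record %s in %s", g[unknown][1], ids[i[1]], path)
  }
  map <- data.frame(marker_id = ids, chrom = fix[, "CHROM"],
                    pos = as.integer(fix[, "POS"]),
                    ref = ref, alt = alt, stringsAsFactors = FALSE)
  genotype_matrix(d, map = map)
}

#' Write genotypes in the dosage-matrix text dialect
#'
#' Round-trips exactly through [read_genotypes()]: dosages, missingness and
#' marker order are preserved bit for bit.
#' @param gm a `genotype_matrix`
#' @param path output file
#' @param sep field separator
#' @return `path`, invisibly.
#' @export
write_dosage_matrix <- function(gm, path, sep = ",") {
  tab <- data.frame(sample_id = rownames(gm$dosages), gm$dosages,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write genotypes as a minimal VCF (v4.2, GT field only)
#'
#' Homozygous reference/alternate dosages are emitted as `0/0` / `1/1`,
#' heterozygotes as `0/1` and missing calls as `./.`.
#' @inheritParams write_dosage_matrix
#' @return `path`, invisibly.
#' @export
write_vcf_genotypes <- function(gm, path) {
  map <- gm$map
  ref <- if ("ref" %in% names(map)) map$ref else rep("A", nrow(map))
  alt <- if ("alt" %in% names(map)) map$alt else rep("T", nrow(map))
  gt <- matrix("./.", nrow = ncol(gm$dosages), ncol = nrow(gm$dosages))
  dt <- t(gm$dosages)
  gt[!is.na(dt) & dt == 0L] <- "0/0"
  gt[!is.na(dt) & dt == 1L] <- "0/1"
  gt[!is.na(dt) & dt == 2L] <- "1/1"
  body <- cbind(map$chrom, map$pos, map$marker_id, ref, alt, ".", "PASS", ".", "GT", gt)
  lines <- c("##fileformat=VCFv4.2",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
                     "FORMAT", rownames(gm$dosages)), collapse = "\t"),
             apply(body, 1, paste, collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a sample metadata table
#'
#' Delimited text with columns `sample_id, year, group, subgroup, line_type,
#' is_dh` (all but `sample_id` optional). CRLF line endings are tolerated.
#' @param path file path
#' @param sep field separator
#' @return a `data.frame`
#' @export
read_sample_table <- function(path, sep = ",") {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  tab <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                           stringsAsFactors = FALSE, na.strings = c("NA", ""))
  if (!"sample_id" %in% names(tab)) .stopf("metadata needs a sample_id column: %s", path)
  tab$sample_id <- as.character(tab$sample_id)
  if (anyDuplicated(tab$sample_id))
    .stopf("duplicate sample id in %s: %s", path, tab$sample_id[duplicated(tab$sample_id)][1])
  if ("is_dh" %in% names(tab)) tab$is_dh <- as.logical(tab$is_dh)
  tab
}

#' Subset a genotype matrix by samples and/or markers
#'
#' @param gm a `genotype_matrix`
#' @param samples logical mask, integer indices or sample ids; `NULL` keeps all.
#' @param markers logical mask, integer indices or marker ids; `NULL` keeps all.
#' @return a `genotype_matrix` with metadata sliced consistently.
#' @export
subset_genotypes <- function(gm, samples = NULL, markers = NULL) {
  si <- .resolve_index(samples, rownames(gm$dosages), "sample")
  mi <- .resolve_index(markers, colnames(gm$dosages), "marker")
  if (length(si) == 0L) .stopf("empty sample selection")
  if (length(mi) == 0L) .stopf("empty marker selection")
  genotype_matrix(gm$dosages[si, mi, drop = FALSE],
                  map = gm$map[mi, , drop = FALSE],
                  samples = gm$samples[si, , drop = FALSE])
}

.resolve_index <- function(sel, ids, what) {
  if (is.null(sel)) return(seq_along(ids))
  if (is.logical(sel)) {
    if (length(sel) != length(ids)) .stopf("%s mask length %d != %d", what, length(sel), length(ids))
    return(which(sel))
  }
  if (is.character(sel)) {
    i <- match(sel, ids)
    if (anyNA(i)) .stopf("unknown %s id: %s", what, sel[is.na(i)][1])
    return(i)
  }
  sel <- as.integer(sel)
  if (any(sel < 1L | sel > length(ids))) .stopf("%s index out of range", what)
  sel
}

#' Assign era labels from registration years
#'
#' Eras are non-overlapping ten-year registration intervals: with the default
#' boundaries, years before 1990 map to era 0, 1990-1999 to era 1, 2000-2009
#' to era 2, 2010-2019 to era 3 and 2020 onwards to era 4. Missing years give
#' missing eras.
#'
#' @param years integer vector (NA allowed)
#' @param boundaries strictly increasing year cutpoints; era `k` covers
#'   `[boundaries[k], boundaries[k+1])`.
#' @return integer era labels `0..length(boundaries)`.
#' @examples
#' assign_eras(c(1989, 1990, 2019, 2020, NA))
#' @export
assign_eras <- function(years, boundaries = c(1990, 2000, 2010, 2020)) {
  if (is.unsorted(boundaries, strictly = TRUE)) .stopf("boundaries must be strictly increasing")
  if (length(years) == 0L) return(integer(0))
  findInterval(as.numeric(years), boundaries)
}

#' Quality control of a genotype matrix
#'
#' Filtering proceeds in a fixed, documented order: (1) samples failing the
#' call-rate threshold are removed (call rate checked before heterozygosity,
#' so a sample failing both is reported for call rate); (2) samples exceeding
#' the heterozygosity threshold are removed; (3) heterozygous calls in doubled
#' haploid (DH) lines are set to missing; (4) markers failing the call-rate
#' threshold, computed on the retained samples, are removed. The sample
#' heterozygosity rate is the number of dosage-1 calls over non-missing calls.
#'
#' The operation is idempotent: re-applying it to its own output changes
#' nothing.
#'
#' @param gm a `genotype_matrix`
#' @param sample_call_min minimum sample call rate (fraction of non-missing calls)
#' @param sample_het_max maximum sample heterozygosity rate
#' @param marker_call_min minimum marker call rate
#' @param dh_het_to_missing set heterozygous calls of DH samples to missing
#'   (requires an `is_dh` column in the sample table; samples without the flag
#'   are treated as non-DH)
#' @param samples_first compute marker call rate after removing failing
#'   samples (default); `FALSE` computes it on the input matrix.
#' @return a list with elements `genotypes` (filtered `genotype_matrix`) and
#'   `report` (a `qc_report`: removal ids with reasons, counts, call rates
#'   before/after).
#' @export
qc_filter <- function(gm, sample_call_min = 0.90, sample_het_max = 0.15,
                      marker_call_min = 0.90, dh_het_to_missing = TRUE,
                      samples_first = TRUE) {
  d <- gm$dosages
  if (length(d) == 0L) .stopf("empty genotype matrix")
  call_before <- mean(!is.na(d))

  n_called <- rowSums(!is.na(d))
  call_rate <- n_called / ncol(d)
  het_rate <- ifelse(n_called > 0, rowSums(d == 1L, na.rm = TRUE) / n_called, 0)
  rm_call <- call_rate < sample_call_min
  rm_het <- !rm_call & het_rate > sample_het_max
  sample_reasons <- character(0)
  removed_samples <- character(0)
  if (any(rm_call | rm_het)) {
    removed_samples <- rownames(d)[rm_call | rm_het]
    sample_reasons <- ifelse(rm_call[rm_call | rm_het], "call_rate", "heterozygosity")
  }
  keep_s <- !(rm_call | rm_het)
  if (!any(keep_s)) .stopf("empty after QC: all samples removed")

  d2 <- d[keep_s, , drop = FALSE]
  samples2 <- gm$samples[keep_s, , drop = FALSE]

  het_set <- 0L
  if (dh_het_to_missing && "is_dh" %in% names(samples2)) {
    dh <- which(!is.na(samples2$is_dh) & samples2$is_dh)
    if (length(dh)) {
      sub <- d2[dh, , drop = FALSE]
      hits <- !is.na(sub) & sub == 1L
      het_set <- sum(hits)
      sub[hits] <- NA_integer_
      d2[dh, ] <- sub
    }
  }

  marker_call <- if (samples_first) colMeans(!is.na(d2)) else colMeans(!is.na(d))
  keep_m <- marker_call >= marker_call_min
  removed_markers <- colnames(d2)[!keep_m]
  if (!any(keep_m)) .stopf("empty after QC: all markers removed")
  d2 <- d2[, keep_m, drop = FALSE]

  out <- genotype_matrix(d2, map = gm$map[keep_m, , drop = FALSE], samples = samples2)
  report <- structure(list(
    samples_removed = data.frame(sample_id = removed_samples, reason = sample_reasons,
                                 stringsAsFactors = FALSE),
    n_samples_removed = length(removed_samples),
    markers_removed = removed_markers,
    n_markers_removed = length(removed_markers),
    het_calls_set_missing = het_set,
    call_rate_before = call_before,
    call_rate_after = mean(!is.na(d2)),
    n_samples_in = nrow(d), n_samples_out = nrow(d2),
    n_markers_in = ncol(d), n_markers_out = ncol(d2)
  ), class = "qc_report")
  list(genotypes = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("QC: %d/%d samples kept, %d/%d markers kept\n",
              x$n_samples_out, x$n_samples_in, x$n_markers_out, x$n_markers_in))
  cat(sprintf("  samples removed: %d  markers removed: %d  DH het calls set missing: %d\n",
              x$n_samples_removed, x$n_markers_removed, x$het_calls_set_missing))
  cat(sprintf("  call rate %.4f -> %.4f\n", x$call_rate_before, x$call_rate_after))
  invisible(x)
}

#' Fill missing dosages with the per-marker major-allele genotype
#'
#' Simple deterministic completion used where a statistic needs a complete
#' matrix (the eigenstrat PCA offers mean-fill as its default instead).
#' Missing cells get dosage 2 when the alternate allele is the major allele,
#' 0 when it is the minor allele, and 0 on an exact tie.
#' @param gm a `genotype_matrix`
#' @return a complete `genotype_matrix`
#' @export
fill_major_allele <- function(gm) {
  d <- gm$dosages
  p <- colMeans(d, na.rm = TRUE) / 2
  fill <- ifelse(!is.na(p) & p > 0.5, 2L, 0L)
  idx <- which(is.na(d), arr.ind = TRUE)
  if (nrow(idx)) d[idx] <- fill[idx[, 2]]
  d[is.na(d)] <- 0L  # all-missing markers: arbitrary reference fill
  genotype_matrix(d, map = gm$map, samples = gm$samples)
}
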