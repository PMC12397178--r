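#' Configuration for a full temporal diversity analysis
#'
#' Exactly one of `simulate` (a [sim_config()]) or `input` (a list with
#' `genotypes`, optional `format`, `metadata`, `qmatrix` file paths) must be
#' given. Module toggles and parameters control which report tables are
#' produced.
#'
#' @param simulate a [sim_config()] describing a simulated breeding program
#' @param input list of input file paths (`genotypes`, `format`
#'   (`"dosage_matrix"` or `"vcf"`), `metadata`, optionally `qmatrix` and
#'   `qmatrix_k`)
#' @param grouping sample-table column with the two-group labels
#' @param subgrouping sample-table column with the ancestral three-group
#'   labels (set `NULL` to skip subgroup analyses)
#' @param era_boundaries year cutpoints for [assign_eras()] (used when the
#'   metadata has `year` but no `era`)
#' @param modules named logical toggles: `diversity`, `fst`, `bootstrap`,
#'   `distance`, `ld`, `structure`
#' @param qc run [qc_filter()] on the input
#' @param bootstrap_frac,bootstrap_reps resampling protocol parameters
#' @param ld_max_dist,ld_window,ld_n_basis LD-decay parameters
#' @param high_fst_threshold strict threshold for `P[theta > t]`
#' @param cmap_threshold admixed classification threshold
#' @param min_cell_n minimum (era x group) cell size for LD/F_ST tables
#' @param n_pcs retained principal components
#' @param seed master seed; per-stage seeds are derived from it by fixed
#'   offsets so that toggling one stage never shifts another stage's draws
#' @param out_dir optional output directory for [write_report_bundle()]
#' @return a list of class `analysis_config`
#' @export
analysis_config <- function(simulate = NULL, input = NULL,
                            grouping = "group", subgrouping = "subgroup",
                            era_boundaries = c(1990, 2000, 2010, 2020),
                            modules = list(),
                            qc = !is.null(input),
                            bootstrap_frac = 0.10, bootstrap_reps = 200,
                            ld_max_dist = 1e6, ld_window = 5000, ld_n_basis = 20,
                            high_fst_threshold = 0.75, cmap_threshold = 0.75,
                            min_cell_n = 10, n_pcs = 5,
                            seed = 1L, out_dir = NULL) {
  if (is.null(simulate) == is.null(input))
    .stopf("exactly one of 'simulate' or 'input' must be given")
  def <- list(diversity = TRUE, fst = TRUE, bootstrap = TRUE, distance = TRUE,
              ld = TRUE, structure = TRUE)
  def[names(modules)] <- modules
  structure(list(simulate = simulate, input = input, grouping = grouping,
                 subgrouping = subgrouping, era_boundaries = era_boundaries,
                 modules = def, qc = qc,
                 bootstrap_frac = bootstrap_frac, bootstrap_reps = bootstrap_reps,
                 ld_max_dist = ld_max_dist, ld_window = ld_window,
                 ld_n_basis = ld_n_basis,
                 high_fst_threshold = high_fst_threshold,
                 cmap_threshold = cmap_threshold, min_cell_n = min_cell_n,
                 n_pcs = n_pcs, seed = as.integer(seed), out_dir = out_dir),
            class = "analysis_config")
}

.log_stage <- function(verbose, fmt, ...) {
  if (verbose) message(format(Sys.time(), "%H:%M:%S "), sprintf(fmt, ...))
}

#' Run the full temporal diversity analysis
#'
#' Orchestrates data acquisition (simulation or file input + QC), then per
#' (era x group) cell: diversity summaries, Weir-Cockerham F_ST evolution
#' with the resampling variance protocol, Hamming-distance summaries,
#' LD-decay metrics, and population-structure metrics (eigenstrat PCA,
#' supervised admixture against per-era group reference frequencies, CMAP
#' admixed fractions, BIC-over-K diagnostic). All randomness derives from
#' `cfg$seed` via fixed per-stage offsets, so the bundle is reproducible
#' bit for bit.
#'
#' @param cfg an [analysis_config()]
#' @param verbose log per-stage progress to stderr
#' @return an object of class `report_bundle`: list of data frames
#'   (`diversity`, `fst_evolution`, `fst_bootstrap`, `hamming`, `ld`,
#'   `pca`, `cmap`, `kmeans_bic`) plus `manifest`. Written to
#'   `cfg$out_dir` when set (see [write_report_bundle()]).
#' @export
run_analysis <- function(cfg, verbose = FALSE) {
  stopifnot(inherits(cfg, "analysis_config"))
  t0 <- Sys.time()

  .log_stage(verbose, "stage data: acquiring genotypes")
  if (!is.null(cfg$simulate)) {
    sim <- simulate_program(cfg$simulate)
    gm <- sim$genotypes
  } else {
    gm <- read_genotypes(cfg$input$genotypes,
                         format = cfg$input$format %||% "dosage_matrix")
    if (!is.null(cfg$input$metadata)) {
      st <- read_sample_table(cfg$input$metadata)
      i <- match(rownames(gm$dosages), st$sample_id)
      if (anyNA(i)) .stopf("stage data: sample %s missing from metadata",
                           rownames(gm$dosages)[is.na(i)][1])
      gm$samples <- cbind(gm$samples["sample_id"],
                          st[i, setdiff(names(st), "sample_id"), drop = FALSE])
    }
    if (cfg$qc) gm <- qc_filter(gm)$genotypes
  }
  st <- gm$samples
  if (!"era" %in% names(st) && "year" %in% names(st)) {
    st$era <- assign_eras(st$year, cfg$era_boundaries)
    gm$samples <- st
  }
  if (!"era" %in% names(st)) .stopf("stage data: no era or year in sample metadata")
  eras <- sort(unique(st$era[!is.na(st$era)]))
  grp <- as.character(st[[cfg$grouping]])
  sub <- if (!is.null(cfg$subgrouping) && cfg$subgrouping %in% names(st))
    as.character(st[[cfg$subgrouping]]) else NULL

  bundle <- list()

  if (cfg$modules$diversity) {
    .log_stage(verbose, "stage diversity")
    div <- tryCatch({
      tabs <- list(cbind(grouping = cfg$grouping,
                         era_group_diversity(gm, grouping = cfg$grouping)))
      if (!is.null(sub))
        tabs <- c(tabs, list(cbind(grouping = cfg$subgrouping,
                                   era_group_diversity(gm, grouping = cfg$subgrouping))))
      do.call(rbind, tabs)
    }, error = function(e) .stopf("stage diversity failed: %s", conditionMessage(e)))
    bundle$diversity <- div
  }

  if (cfg$modules$fst) {
    .log_stage(verbose, "stage differentiation")
    pair_sets <- list(c("SS", "NSS"))
    if (!is.null(sub)) pair_sets <- c(pair_sets,
                                      list(c("IDT", "LAN"), c("SS", "IDT"), c("SS", "LAN")))
    rows <- list(); boots <- list()
    for (e in eras) {
      for (pr in pair_sets) {
        lab <- if (all(pr %in% grp)) grp else sub
        if (is.null(lab)) next
        sel <- st$era == e & !is.na(lab) & lab %in% pr
        if (sum(sel & lab == pr[1]) < 2 || sum(sel & lab == pr[2]) < 2) next
        sgm <- subset_genotypes(gm, samples = which(sel))
        fr <- tryCatch(wc_fst(sgm, lab[sel], high_threshold = cfg$high_fst_threshold),
                       error = function(e2) .stopf("stage fst failed in era %s (%s-%s): %s",
                                                   e, pr[1], pr[2], conditionMessage(e2)))
        s <- fr$summary
        rows[[length(rows) + 1L]] <- data.frame(
          era = e, pop_a = pr[1], pop_b = pr[2],
          n_a = sum(sel & lab == pr[1]), n_b = sum(sel & lab == pr[2]),
          mean_theta = s$mean_theta, weighted_theta = s$weighted_theta,
          var_theta = s$var_theta, p_high = s$p_high, n_defined = s$n_defined,
          stringsAsFactors = FALSE)
        if (cfg$modules$bootstrap && identical(pr, c("SS", "NSS")) &&
            min(sum(sel & lab == pr[1]), sum(sel & lab == pr[2])) * cfg$bootstrap_frac >= 2) {
          bs <- bootstrap_fst(sgm, lab[sel], frac = cfg$bootstrap_frac,
                              reps = cfg$bootstrap_reps,
                              seed = cfg$seed + 1000L + e)
          boots[[length(boots) + 1L]] <- data.frame(
            era = e, pop_a = pr[1], pop_b = pr[2], reps = bs$reps, frac = bs$frac,
            boot_mean = bs$mean, boot_sd = bs$sd, stringsAsFactors = FALSE)
        }
      }
    }
    bundle$fst_evolution <- do.call(rbind, rows)
    if (length(boots)) bundle$fst_bootstrap <- do.call(rbind, boots)
  }

  if (cfg$modules$distance) {
    .log_stage(verbose, "stage distance")
    keep <- if ("line_type" %in% names(st)) st$line_type == "inbred" else rep(TRUE, nrow(st))
    keep <- keep & !is.na(st$era)
    dm <- hamming_matrix(gm, samples = which(keep))
    meta2 <- st[keep, , drop = FALSE]
    pairs <- list(c("SS", "NSS"), c("SS", "SS"), c("NSS", "NSS"))
    ham <- group_distance_summary(dm, meta2, pairs, grouping = cfg$grouping)
    if (!is.null(sub)) {
      pairs3 <- list(c("IDT", "LAN"), c("IDT", "IDT"), c("LAN", "LAN"))
      ham <- rbind(ham, group_distance_summary(dm, meta2, pairs3,
                                               grouping = cfg$subgrouping))
    }
    bundle$hamming <- ham
  }

  if (cfg$modules$ld) {
    .log_stage(verbose, "stage LD decay")
    rows <- list()
    for (e in eras) {
      for (g in intersect(c("SS", "NSS"), unique(grp))) {
        sel <- st$era == e & !is.na(grp) & grp == g
        if (sum(sel) < cfg$min_cell_n) next
        sgm <- subset_genotypes(gm, samples = which(sel))
        prs <- pairwise_ld(sgm, max_dist = cfg$ld_max_dist)
        bins <- bin_ld(prs, window = cfg$ld_window)
        if (sum(bins$n_pairs > 0) < 5) next
        fit <- fit_ldd(bins, n_basis = cfg$ld_n_basis)
        met <- ld_metrics(fit)
        rows[[length(rows) + 1L]] <- data.frame(
          era = e, group = g, n_samples = sum(sel), n_pairs = nrow(prs),
          r2_at_0 = met$r2_at_0, r2_at_1mb = met$r2_at_1mb,
          mean_ld = met$mean_ld, stringsAsFactors = FALSE)
      }
    }
    bundle$ld <- do.call(rbind, rows)
  }

  if (cfg$modules$structure) {
    .log_stage(verbose, "stage structure")
    pca <- pca_eigenstrat(gm, n_components = cfg$n_pcs)
    bundle$pca <- data.frame(sample_id = rownames(pca$coordinates),
                             era = st$era, group = grp,
                             pca$coordinates, stringsAsFactors = FALSE)
    bundle$pca_variance <- data.frame(axis = seq_along(pca$variance_explained),
                                      variance_explained = pca$variance_explained)
    bundle$kmeans_bic <- kmeans_bic(pca, K_range = 1:min(10, nrow(st) - 1),
                                    n_pcs = cfg$n_pcs, seed = cfg$seed + 2000L)
    grp2 <- intersect(c("SS", "NSS"), unique(grp))
    cm_rows <- list()
    if (length(grp2) == 2) {
      for (e in eras) {
        sel <- st$era == e & !is.na(grp)
        if (sum(sel) < cfg$min_cell_n) next
        if (any(vapply(grp2, function(g) sum(sel & grp == g), 1L) < 2)) next
        sgm <- subset_genotypes(gm, samples = which(sel))
        panels <- vapply(grp2, function(g) {
          ft <- allele_frequencies(subset_genotypes(sgm, samples = grp[sel] == g))
          ifelse(ft$defined, ft$p_alt, 0.5)
        }, numeric(ncol(sgm$dosages)))
        Q <- supervised_admixture(sgm, panels)
        ct <- cmap(Q, threshold = cfg$cmap_threshold)
        cm_rows[[length(cm_rows) + 1L]] <- data.frame(
          era = e, n = nrow(ct), mean_cmap = mean(ct$cmap),
          admixed_fraction = mean(ct$admixed), stringsAsFactors = FALSE)
      }
    }
    if (length(cm_rows)) bundle$cmap <- do.call(rbind, cm_rows)
  }

  bundle$manifest <- list(
    package = "breedpop",
    version = as.character(utils::packageVersion("breedpop")),
    seed = cfg$seed,
    config = .manifest_config(cfg),
    n_samples = nrow(st), n_markers = ncol(gm$dosages),
    eras = eras)
  .log_stage(verbose, "done in %.1f s", as.numeric(difftime(Sys.time(), t0, "secs")))
  bundle <- structure(bundle, class = "report_bundle")
  if (!is.null(cfg$out_dir)) write_report_bundle(bundle, cfg$out_dir)
  bundle
}

.manifest_config <- function(cfg) {
  out <- unclass(cfg)
  out$out_dir <- NULL
  if (!is.null(out$simulate)) out$simulate <- unclass(out$simulate)
  out
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("report_bundle with tables:",
      paste(setdiff(names(x), "manifest"), collapse = ", "), "\n")
  cat(sprintf("  %d samples x %d markers, seed %d\n",
              x$manifest$n_samples, x$manifest$n_markers, x$manifest$seed))
  invisible(x)
}

#' Write a report bundle as delimited text plus a JSON manifest
#'
#' One CSV per table and a `manifest.json` sufficient to re-run the analysis
#' bit-identically (no timestamps are written, so identical config + seed
#' give byte-identical bundles).
#'
#' @param bundle a `report_bundle` from [run_analysis()]
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_report_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in setdiff(names(bundle), "manifest")) {
    if (is.data.frame(bundle[[nm]]))
      utils::write.csv(bundle[[nm]], file.path(dir, paste0(nm, ".csv")), row.names = FALSE)
  }
  jsonlite::write_json(bundle$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA, null = "null")
  invisible(dir)
}
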