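#' Intrachromosomal pairwise linkage disequilibrium (r-squared)
#'
#' LD between two markers is the squared Pearson correlation of their dosage
#' vectors over jointly non-missing samples (the composite, unphased measure;
#' on near-fully inbred material it coincides with the haplotype measure).
#' Only pairs on the same chromosome within `max_dist` bp are considered;
#' pairs with undefined correlation (a marker monomorphic in the subset) are
#' always dropped, and pairs with r-squared exactly zero are dropped when
#' `drop_zero = TRUE` (keeping only non-null pairwise correlations).
#'
#' @param gm a [genotype_matrix()] with positions sorted within chromosomes
#' @param max_dist maximum pair distance in bp
#' @param drop_zero drop pairs with r-squared exactly 0
#' @return `data.frame` with one row per retained pair: `chrom`, `id_a`,
#'   `pos_a`, `id_b`, `pos_b`, `dist`, `r2`; attribute `max_dist`.
#' @export
pairwise_ld <- function(gm, max_dist = 1e6, drop_zero = TRUE) {
  out <- list()
  for (ch in unique(gm$map$chrom)) {
    mi <- which(gm$map$chrom == ch)
    pos <- gm$map$pos[mi]
    if (is.unsorted(pos)) .stopf("markers not sorted by position on chromosome %s", ch)
    if (length(mi) < 2) next
    d <- gm$dosages[, mi, drop = FALSE]
    suppressWarnings(cc <- stats::cor(d, use = "pairwise.complete.obs"))
    ij <- which(upper.tri(cc), arr.ind = TRUE)
    dist <- pos[ij[, 2]] - pos[ij[, 1]]
    keep <- dist <= max_dist
    ij <- ij[keep, , drop = FALSE]; dist <- dist[keep]
    r2 <- cc[ij]^2
    keep2 <- !is.na(r2) & (!drop_zero | r2 != 0)
    ij <- ij[keep2, , drop = FALSE]
    if (!nrow(ij)) next
    out[[length(out) + 1L]] <- data.frame(
      chrom = ch,
      id_a = gm$map$marker_id[mi][ij[, 1]], pos_a = pos[ij[, 1]],
      id_b = gm$map$marker_id[mi][ij[, 2]], pos_b = pos[ij[, 2]],
      dist = dist[keep2], r2 = r2[keep2], stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(0), id_a = character(0), pos_a = integer(0),
               id_b = character(0), pos_b = integer(0), dist = numeric(0),
               r2 = numeric(0), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "max_dist") <- max_dist
  res
}

#' Bin LD pairs into non-overlapping distance windows
#'
#' Pairs are assigned to 5-kb (by default) half-open windows
#' `[k w, (k+1) w)` by `floor(dist / w)`; a pair at exactly `max_dist` is
#' assigned to the last bin. Empty bins are retained with `n_pairs = 0` and
#' `mean_r2 = NA` so that the bin table always tiles `[0, max_dist)`.
#'
#' @param pairs pair table from [pairwise_ld()]
#' @param window bin width in bp
#' @param max_dist upper end of the binned range (taken from the pair table
#'   attribute when available)
#' @return `data.frame` with `bin` (0-based), `left`, `right`, `mid`,
#'   `n_pairs`, `mean_r2`; attributes `window`, `max_dist`.
#' @export
bin_ld <- function(pairs, window = 5000, max_dist = NULL) {
  max_dist <- max_dist %||% attr(pairs, "max_dist") %||% 1e6
  n_bins <- ceiling(max_dist / window)
  if (nrow(pairs) && any(pairs$dist > max_dist)) .stopf("pair distance exceeds max_dist")
  bin <- pmin(floor(pairs$dist / window), n_bins - 1L)
  n <- tabulate(bin + 1L, nbins = n_bins)
  s <- rep(0, n_bins)
  if (nrow(pairs)) {
    agg <- tapply(pairs$r2, factor(bin, levels = 0:(n_bins - 1L)), sum)
    s[!is.na(agg)] <- agg[!is.na(agg)]
  }
  out <- data.frame(bin = 0:(n_bins - 1L), left = (0:(n_bins - 1L)) * window,
                    right = (1:n_bins) * window,
                    mid = (0:(n_bins - 1L)) * window + window / 2,
                    n_pairs = n, mean_r2 = ifelse(n > 0, s / n, NA_real_))
  attr(out, "window") <- window
  attr(out, "max_dist") <- max_dist
  out
}

#' Shape-constrained LD-decay curve fit
#'
#' Fits a monotone-decreasing, convex penalized B-spline through the binned
#' mean r-squared values, weighting each bin by its pair count. The curve is
#' a cubic B-spline with a second-order difference penalty whose smoothing
#' parameter is chosen by generalized cross-validation over a fixed
#' log-spaced grid; monotonicity and convexity are imposed as linear
#' inequality constraints on the (knot-scaled) coefficient differences. The
#' constrained weighted penalized least-squares problem is solved exactly by
#' reparameterizing the coefficient vector so that the constraints become
#' non-negativity, then running Lawson-Hanson non-negative least squares;
#' the returned curve therefore satisfies the shape constraints by
#' construction.
#'
#' Derived scalars: `r2_at_0` and `r2_at_1mb` are endpoint evaluations,
#' `auc` is the trapezoid-rule area under the fitted curve on a 1-kb grid
#' over `[0, max_dist]`, and `mean_ld = auc / max_dist` (the distance
#' covered).
#'
#' @param bins bin table from [bin_ld()]
#' @param n_basis number of B-spline basis functions (capped at the number of
#'   non-empty bins)
#' @param penalty_order difference order of the smoothness penalty
#' @param lambda_grid candidate smoothing parameters for GCV
#' @param grid_step evaluation grid step (bp) for the AUC
#' @return an object of class `ldd_fit`: knots, coefficients, the chosen
#'   smoothing parameter, the evaluated curve (`grid`), and the scalars
#'   `r2_at_0`, `r2_at_1mb`, `auc`, `mean_ld`. Use [predict.ldd_fit()] to
#'   evaluate the curve at arbitrary distances.
#' @export
fit_ldd <- function(bins, n_basis = 20, penalty_order = 2,
                    lambda_grid = 10^seq(-4, 4, length.out = 17),
                    grid_step = 1000) {
  max_dist <- attr(bins, "max_dist") %||% max(bins$right)
  use <- bins$n_pairs > 0 & !is.na(bins$mean_r2)
  if (sum(use) < 5) .stopf("need at least 5 non-empty bins, got %d", sum(use))
  x <- bins$mid[use] / max_dist
  y <- bins$mean_r2[use]
  w <- bins$n_pairs[use] / mean(bins$n_pairs[use])
  nb <- sum(use)

  ord <- 4L
  K <- max(min(n_basis, nb), ord)
  n_inner <- K - ord
  inner <- if (n_inner > 0) seq(0, 1, length.out = n_inner + 2)[-c(1, n_inner + 2)] else numeric(0)
  knots <- c(rep(0, ord), inner, rep(1, ord))
  B <- splines::splineDesign(knots, x, ord = ord)
  D <- diff(diag(K), differences = penalty_order)
  P <- crossprod(D)

  # GCV over the unconstrained penalized smoother
  BtWB <- crossprod(B * w, B)
  BtWy <- crossprod(B * w, y)
  gcv <- vapply(lambda_grid, function(l) {
    M <- BtWB + l * P + diag(1e-10, K)
    beta <- solve(M, BtWy)
    edf <- sum(diag(solve(M, BtWB)))
    rss <- sum(w * (y - drop(B %*% beta))^2)
    nb * rss / (nb - min(edf, nb - 0.5))^2
  }, numeric(1))
  lambda <- lambda_grid[which.min(gcv)]

  # constrained solve: beta = M_par %*% c(v+, v-, u, s_1..s_{K-2}), all >= 0,
  # encoding Delta_j <= 0 (monotone decreasing) and Delta_{j+1} >= Delta_j
  # (convex), with Delta_j the knot-scaled coefficient differences that
  # control the sign of the spline's first and second derivatives.
  h <- (knots[(1:(K - 1)) + ord] - knots[(1:(K - 1)) + 1]) / (ord - 1)
  Hc <- c(0, cumsum(h))              # Hc[j] = sum_{i<j} h_i
  Mpar <- matrix(0, K, K + 1)
  Mpar[, 1] <- 1; Mpar[, 2] <- -1    # free intercept v = v+ - v-
  for (j in seq_len(K)) {
    Mpar[j, 3] <- -Hc[j]             # u coefficient
    if (K > 2) for (l in seq_len(K - 2))
      Mpar[j, 3 + l] <- -Hc[min(j - 1, l) + 1]
  }
  Caug <- rbind(sqrt(w) * (B %*% Mpar), sqrt(lambda) * (D %*% Mpar),
                sqrt(1e-8) * Mpar)
  daug <- c(sqrt(w) * y, rep(0, nrow(D) + K))
  sol <- pracma::lsqnonneg(Caug, daug)
  beta <- drop(Mpar %*% sol$x)

  grid_d <- seq(0, max_dist, by = grid_step)
  Bg <- splines::splineDesign(knots, grid_d / max_dist, ord = ord)
  fg <- drop(Bg %*% beta)
  auc <- .trapz(grid_d, fg)
  structure(list(knots = knots, ord = ord, coef = beta, max_dist = max_dist,
                 lambda = lambda, gcv = data.frame(lambda = lambda_grid, gcv = gcv),
                 grid = data.frame(dist = grid_d, r2 = fg),
                 r2_at_0 = fg[1], r2_at_1mb = fg[length(fg)],
                 auc = auc, mean_ld = auc / max_dist,
                 n_bins_used = nb),
            class = "ldd_fit")
}

#' Evaluate a fitted LD-decay curve
#' @param object an `ldd_fit`
#' @param dist distances in bp (clamped to the fitted range)
#' @param ... unused
#' @return fitted r-squared values
#' @export
predict.ldd_fit <- function(object, dist, ...) {
  x <- pmin(pmax(dist / object$max_dist, 0), 1)
  drop(splines::splineDesign(object$knots, x, ord = object$ord) %*% object$coef)
}

#' @export
print.ldd_fit <- function(x, ...) {
  cat(sprintf("LD decay fit (%d bins, lambda = %.3g):\n", x$n_bins_used, x$lambda))
  cat(sprintf("  r2 at 0 = %.4f  r2 at %g bp = %.4f  mean LD = %.4f\n",
              x$r2_at_0, x$max_dist, x$r2_at_1mb, x$mean_ld))
  invisible(x)
}

#' The three LD-decay scalars of a fit
#' @param fit an `ldd_fit`
#' @return named list `r2_at_0`, `r2_at_1mb`, `mean_ld`
#' @export
ld_metrics <- function(fit) {
  if (!inherits(fit, "ldd_fit")) .stopf("fit must be an ldd_fit")
  list(r2_at_0 = fit$r2_at_0, r2_at_1mb = fit$r2_at_1mb, mean_ld = fit$mean_ld)
}

#' Write an LD pair table in PLINK .ld-style columns
#' @param pairs pair table from [pairwise_ld()]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_ld_pairs <- function(pairs, path) {
  out <- data.frame(CHR_A = pairs$chrom, BP_A = pairs$pos_a, SNP_A = pairs$id_a,
                    CHR_B = pairs$chrom, BP_B = pairs$pos_b, SNP_B = pairs$id_b,
                    R2 = pairs$r2)
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
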