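#' Eigenstrat-style principal component analysis of genotypes
#'
#' Each marker column is centred by twice its sample alternate-allele
#' frequency and scaled by `sqrt(2 p (1 - p))`; markers monomorphic in the
#' analysed subset are skipped. Missing dosages are mean-filled after
#' standardization (i.e. set to zero), the standard eigenstrat convention;
#' alternatively complete the matrix first with [fill_major_allele()].
#' Coordinates are obtained by truncated singular value decomposition of the
#' standardized matrix, so each axis has zero-mean coordinates.
#'
#' @param gm a [genotype_matrix()]
#' @param n_components number of axes to retain
#' @return an object of class `pca_result`: `coordinates` (samples x
#'   components, rownames = sample ids), `eigenvalues`, `variance_explained`
#'   (fractions of the total variance over all axes, non-increasing) and
#'   `n_markers_used`.
#' @export
pca_eigenstrat <- function(gm, n_components = 5) {
  d <- gm$dosages
  if (nrow(d) < 2) .stopf("need at least 2 samples")
  p <- colMeans(d, na.rm = TRUE) / 2
  poly <- !is.na(p) & p > 0 & p < 1
  if (sum(poly) < n_components)
    .stopf("fewer polymorphic markers (%d) than components (%d)", sum(poly), n_components)
  x <- d[, poly, drop = FALSE]
  p <- p[poly]
  x <- sweep(x, 2, 2 * p)
  x <- sweep(x, 2, sqrt(2 * p * (1 - p)), "/")
  x[is.na(x)] <- 0
  sv <- svd(x, nu = min(dim(x)), nv = 0)
  k <- min(n_components, length(sv$d))
  coords <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k, k)
  rownames(coords) <- rownames(d)
  colnames(coords) <- paste0("PC", seq_len(k))
  structure(list(coordinates = coords,
                 eigenvalues = sv$d[seq_len(k)]^2 / max(nrow(d) - 1, 1),
                 variance_explained = sv$d[seq_len(k)]^2 / sum(sv$d^2),
                 n_markers_used = sum(poly)),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("eigenstrat PCA: %d samples, %d markers, %d axes\n",
              nrow(x$coordinates), x$n_markers_used, ncol(x$coordinates)))
  cat("  variance explained:",
      paste(sprintf("%.1f%%", 100 * x$variance_explained), collapse = " "), "\n")
  invisible(x)
}

#' Supervised admixture-proportion estimation
#'
#' Estimates, for every sample, its vector of ancestry proportions `q` on the
#' K-simplex given fixed reference allele frequencies for the K source
#' groups, by maximizing the binomial log-likelihood
#' \deqn{\sum_m d_m \log(q \cdot p_m) + (2 - d_m) \log(1 - q \cdot p_m)}
#' with multiplicative EM updates. The likelihood is non-decreasing across
#' iterations; iteration stops when the total log-likelihood gain falls
#' below `tol` or after `max_iter` iterations. Panel frequencies are clipped
#' to `[eps, 1 - eps]`. When the panels are indistinguishable the likelihood
#' is flat in `q`; this is detected and uniform rows are returned with a
#' warning.
#'
#' This covers the supervised workflow where group reference frequencies are
#' known (e.g. from labelled founders); externally estimated Q matrices can
#' be read with [read_qmatrix()] instead.
#'
#' @param gm a [genotype_matrix()]
#' @param panel_freqs markers x K matrix of reference alternate-allele
#'   frequencies (column names become cluster names).
#' @param eps clipping bound for panel frequencies.
#' @param max_iter,tol EM stopping rule.
#' @return a samples x K matrix of class `q_matrix` (rows sum to 1), with
#'   attributes `loglik` (final total), `loglik_trace` and `iterations`.
#' @export
supervised_admixture <- function(gm, panel_freqs, eps = 1e-3,
                                 max_iter = 2000, tol = 1e-8) {
  P <- as.matrix(panel_freqs)
  if (ncol(P) < 2) .stopf("need K >= 2 reference panels")
  if (nrow(P) != ncol(gm$dosages))
    .stopf("panel_freqs rows (%d) != markers (%d)", nrow(P), ncol(gm$dosages))
  K <- ncol(P)
  if (is.null(colnames(P))) colnames(P) <- paste0("cluster", seq_len(K))
  P <- pmin(pmax(P, eps), 1 - eps)
  G <- gm$dosages
  n <- nrow(G)

  if (max(apply(P, 1, function(r) diff(range(r)))) < 1e-10) {
    .warnf("reference panels are indistinguishable; returning uniform ancestry")
    Q <- matrix(1 / K, n, K, dimnames = list(rownames(G), colnames(P)))
    return(structure(Q, class = c("q_matrix", "matrix"),
                     loglik = NA_real_, loglik_trace = numeric(0), iterations = 0L))
  }

  obs <- !is.na(G)
  Gf <- G; Gf[!obs] <- 0L
  storage.mode(Gf) <- "double"
  Gc <- (2 - G); Gc[!obs] <- 0L
  storage.mode(Gc) <- "double"
  m_i <- rowSums(obs)

  Q <- matrix(1 / K, n, K)
  ll_trace <- numeric(0)
  ll_old <- -Inf
  iter <- 0L
  repeat {
    iter <- iter + 1L
    mu <- Q %*% t(P)                       # n x m expected alt frequency
    mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
    ll <- sum(Gf * log(mu) + Gc * log1p(-mu))
    ll_trace <- c(ll_trace, ll)
    if (iter >= max_iter || (ll - ll_old) < tol && iter > 1L) break
    ll_old <- ll
    A <- (Gf / mu) %*% P
    B <- (Gc / (1 - mu)) %*% (1 - P)
    Q <- Q * (A + B)
    denom <- 2 * m_i
    zero <- denom == 0
    Q[zero, ] <- 1
    Q <- Q / rowSums(Q)                    # exact simplex renormalization
  }
  dimnames(Q) <- list(rownames(G), colnames(P))
  structure(Q, class = c("q_matrix", "matrix"),
            loglik = ll_trace[length(ll_trace)], loglik_trace = ll_trace,
            iterations = iter)
}

#' Read / write an ancestry-proportion (Q) matrix
#'
#' The on-disk dialect is the ADMIXTURE `.Q` format: whitespace-delimited,
#' one row per sample, K columns. Rows whose sum deviates from 1 by more
#' than `1e-3` raise an error naming the row; smaller deviations are
#' renormalized.
#'
#' @param path file path
#' @param K expected number of clusters (checked when given)
#' @param sample_ids optional row names
#' @return a samples x K `q_matrix`
#' @export
read_qmatrix <- function(path, K = NULL, sample_ids = NULL) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  tab <- utils::read.table(path, header = FALSE)
  Q <- as.matrix(tab)
  if (!is.null(K) && ncol(Q) != K) .stopf("expected K = %d columns, found %d", K, ncol(Q))
  if (any(Q < 0 | Q > 1)) .stopf("Q entries must lie in [0, 1]")
  rs <- rowSums(Q)
  bad <- which(abs(rs - 1) > 1e-3)
  if (length(bad)) .stopf("row %d sums to %.4f (must be 1 within 1e-3)", bad[1], rs[bad[1]])
  Q <- Q / rs
  rownames(Q) <- sample_ids %||% sprintf("sample_%d", seq_len(nrow(Q)))
  colnames(Q) <- paste0("cluster", seq_len(ncol(Q)))
  structure(Q, class = c("q_matrix", "matrix"))
}

#' @rdname read_qmatrix
#' @param Q a Q matrix
#' @export
write_qmatrix <- function(Q, path) {
  utils::write.table(format(unclass(Q), digits = 17, scientific = FALSE, trim = TRUE),
                     path, sep = " ", row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Cluster maximum assignation probability (CMAP) and admixed classification
#'
#' CMAP is the largest entry of a sample's ancestry-proportion row; it ranges
#' from 1/K (equal assignation across clusters) to 1 (complete assignation).
#' Every sample is assigned to its argmax cluster regardless of the CMAP
#' value (ties broken towards the lowest cluster index, with a message), and
#' samples with CMAP strictly below `threshold` are additionally classified
#' as admixed.
#'
#' @param Q a samples x K ancestry matrix ([read_qmatrix()] /
#'   [supervised_admixture()])
#' @param threshold admixed classification threshold (strict `<`)
#' @return `data.frame` with `sample_id`, `cmap`, `assigned_cluster`
#'   (1-based index), `admixed`.
#' @export
cmap <- function(Q, threshold = 0.75) {
  Q <- as.matrix(Q)
  cm <- apply(Q, 1, max)
  ties <- rowSums(Q == cm) > 1
  if (any(ties)) message(sprintf("cmap: %d tie(s) broken towards the lowest cluster index",
                                 sum(ties)))
  data.frame(sample_id = rownames(Q) %||% sprintf("sample_%d", seq_len(nrow(Q))),
             cmap = cm,
             assigned_cluster = max.col(Q, ties.method = "first"),
             admixed = cm < threshold,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' BIC-over-K clustering diagnostic on PCA coordinates
#'
#' For each candidate number of clusters K, runs k-means on the retained
#' principal-component coordinates (best of `restarts` starts by
#' within-cluster sum of squares, WSS) and reports
#' `BIC = n log(WSS / n) + K log(n)`. A diagnostic of cluster support, not a
#' model-selection guarantee: strongly pedigree-structured germplasm may show
#' no interior minimum.
#'
#' @param pca a `pca_result` from [pca_eigenstrat()]
#' @param K_range candidate cluster counts
#' @param n_pcs number of leading axes used
#' @param restarts k-means restarts per K
#' @param seed integer seed (caller's RNG state restored afterwards)
#' @return `data.frame` with `K`, `WSS`, `BIC`.
#' @export
kmeans_bic <- function(pca, K_range = 1:10, n_pcs = 5, restarts = 10, seed = NULL) {
  X <- pca$coordinates[, seq_len(min(n_pcs, ncol(pca$coordinates))), drop = FALSE]
  n <- nrow(X)
  if (max(K_range) >= n) .stopf("K must be smaller than the number of samples")
  .with_seed(seed, {
    res <- lapply(K_range, function(k) {
      if (k == 1) {
        wss <- sum(scale(X, scale = FALSE)^2)
      } else {
        km <- stats::kmeans(X, centers = k, nstart = restarts, iter.max = 50)
        wss <- km$tot.withinss
      }
      data.frame(K = k, WSS = wss, BIC = n * log(max(wss, 1e-12) / n) + k * log(n))
    })
    do.call(rbind, res)
  })
}
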