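#' Filter cells and genes before program discovery
#'
#' Removes cells with fewer than `min_genes` detected genes or fewer than
#' `min_umis` total UMIs, then genes detected in fewer than `min_cells` of
#' the surviving cells.
#'
#' @param counts gene x cell matrix of non-negative integer counts.
#' @param min_genes,min_umis,min_cells filter thresholds (defaults
#'   200 / 200 / 10; boundary values are retained).
#' @return filtered counts with a `"filter_report"` attribute
#'   (cells/genes removed).
#' @export
filter_cells_genes <- function(counts, min_genes = 200, min_umis = 200,
                               min_cells = 10) {
  detected <- Matrix::colSums(counts > 0)
  umis <- Matrix::colSums(counts)
  keep_cells <- detected >= min_genes & umis >= min_umis
  sub <- counts[, keep_cells, drop = FALSE]
  keep_genes <- Matrix::rowSums(sub > 0) >= min_cells
  out <- sub[keep_genes, , drop = FALSE]
  if (ncol(out) == 0 || nrow(out) == 0) stop("no cells survive filters")
  attr(out, "filter_report") <- list(cells_removed = sum(!keep_cells),
                                     genes_removed = sum(!keep_genes))
  out
}

## one NMF restart by hierarchical alternating least squares (HALS) on
## X (cells x genes) ~ W (cells x k) H (k x genes); seeded uniform init
nmf_hals <- function(X, k, seed, max_iter = 300, tol = 1e-6) {
  set.seed(seed)
  n <- nrow(X); m <- ncol(X)
  scale0 <- sqrt(mean(X) / k)
  W <- matrix(stats::runif(n * k, 0, 2 * scale0), n, k)
  H <- matrix(stats::runif(k * m, 0, 2 * scale0), k, m)
  xnorm2 <- sum(X^2)
  err_prev <- Inf
  for (it in seq_len(max_iter)) {
    ## update W columns
    XHt <- X %*% t(H); HHt <- H %*% t(H)
    for (t in seq_len(k)) {
      denom <- HHt[t, t]
      if (denom <= 0) next
      wt <- W[, t] + (XHt[, t] - W %*% HHt[, t]) / denom
      W[, t] <- pmax(wt, 0)
    }
    ## update H rows
    WtX <- crossprod(W, X); WtW <- crossprod(W)
    for (t in seq_len(k)) {
      denom <- WtW[t, t]
      if (denom <= 0) next
      ht <- H[t, ] + (WtX[t, ] - WtW[t, ] %*% H) / denom
      H[t, ] <- pmax(ht, 0)
    }
    if (it %% 10 == 0 || it == max_iter) {
      err <- sum((X - W %*% H)^2) / xnorm2
      if (is.finite(err_prev) && err_prev - err < tol * max(err, 1e-12)) break
      err_prev <- err
    }
  }
  list(W = W, H = H)
}

## L2-normalise matrix rows; zero rows left untouched
l2_rows <- function(m) {
  nr <- sqrt(rowSums(m^2))
  m[nr > 0, ] <- m[nr > 0, , drop = FALSE] / nr[nr > 0]
  m
}

#' Consensus non-negative matrix factorisation of single-cell counts
#'
#' For each candidate `k`, runs `restarts` seeded NMF factorisations (HALS
#' updates) on the variance-normalised counts, pools the L2-normalised
#' component spectra, drops outlier components whose mean distance to
#' their nearest-neighbour components exceeds `outlier_distance`, clusters
#' the surviving components into `k` consensus groups by seeded k-means,
#' takes the component-wise median of each cluster as the consensus
#' spectrum, and refits per-cell usages by non-negative least squares.
#' Stability is the mean silhouette width of the component clustering;
#' the reconstruction error is the relative Frobenius error
#' `||X - U S||_F / ||X||_F`.
#'
#' @param counts gene x cell matrix of non-negative counts (already
#'   filtered; see [filter_cells_genes()]).
#' @param k_values candidate factorisation ranks (default `3:30`).
#' @param restarts NMF restarts per k (default 20).
#' @param outlier_distance component-outlier threshold on L2-normalised
#'   spectra (default 0.3).
#' @param seed integer seed; every restart and the clustering are seeded
#'   from it.
#' @param var_scale scale genes to unit variance before factorisation
#'   (default TRUE, the usual normalisation for program discovery;
#'   set FALSE to factorise raw counts).
#' @param max_iter HALS iterations per restart.
#' @return object of class `cnmf_fit`: `selection` (data frame k /
#'   stability / error), `k` (stability-maximising k), `spectra`
#'   (program x gene consensus spectra for the chosen k), `usages`
#'   (cell x program, rows normalised to sum 1), `results` (per-k list of
#'   spectra/usages/stability/error).
#' @export
cnmf_consensus <- function(counts, k_values = 3:30, restarts = 20,
                           outlier_distance = 0.3, seed = 1L,
                           var_scale = TRUE, max_iter = 300) {
  stopifnot(all(k_values >= 2), restarts >= 3)
  X <- t(as.matrix(counts))          # cells x genes
  if (var_scale) {
    sds <- apply(X, 2, stats::sd)
    sds[sds == 0] <- 1
    X <- sweep(X, 2, sds, "/")
  }
  xnorm <- sqrt(sum(X^2))
  results <- list()
  for (k in k_values) {
    comp <- vector("list", restarts)
    for (r in seq_len(restarts)) {
      fit <- nmf_hals(X, k, seed = seed + 1000L * k + r,
                      max_iter = max_iter)
      comp[[r]] <- l2_rows(fit$H)
    }
    spectra_all <- do.call(rbind, comp)
    nonzero <- rowSums(spectra_all) > 0
    spectra_all <- spectra_all[nonzero, , drop = FALSE]
    ## outlier components: far from their nearest neighbours
    d <- as.matrix(stats::dist(spectra_all))
    diag(d) <- Inf
    nn <- max(1L, restarts %/% 3L)
    mean_nn <- apply(d, 1, function(row) mean(sort(row)[seq_len(nn)]))
    keep <- mean_nn <= outlier_distance
    if (sum(keep) < k) keep <- rep(TRUE, nrow(spectra_all))
    spectra_kept <- spectra_all[keep, , drop = FALSE]
    set.seed(seed + k)
    km <- stats::kmeans(spectra_kept, centers = k, nstart = 10,
                        iter.max = 100)
    sil <- cluster::silhouette(km$cluster, stats::dist(spectra_kept))
    stability <- mean(sil[, "sil_width"])
    consensus <- t(vapply(seq_len(k), function(cl)
      apply(spectra_kept[km$cluster == cl, , drop = FALSE], 2,
            stats::median),
      numeric(ncol(spectra_kept))))
    consensus <- l2_rows(consensus)
    usages <- nnls_usages(X, consensus)
    err <- sqrt(sum((X - usages %*% consensus)^2)) / xnorm
    rownames(consensus) <- paste0("program_", seq_len(k))
    colnames(consensus) <- colnames(X)
    dimnames(usages) <- list(rownames(X), rownames(consensus))
    results[[as.character(k)]] <- list(
      k = k, spectra = consensus, usages = usage_normalize(usages),
      stability = stability, error = err)
  }
  selection <- data.frame(
    k = k_values,
    stability = vapply(results, `[[`, 0, "stability"),
    error = vapply(results, `[[`, 0, "error"), row.names = NULL)
  best <- results[[which.max(selection$stability)]]
  structure(list(selection = selection, k = best$k,
                 spectra = best$spectra, usages = best$usages,
                 results = results, var_scale = var_scale, seed = seed),
            class = "cnmf_fit")
}

## per-cell non-negative least squares against fixed spectra
nnls_usages <- function(X, spectra) {
  A <- t(spectra)                    # genes x k
  t(apply(X, 1, function(x) pracma::lsqnonneg(A, x)$x))
}

#' @export
print.cnmf_fit <- function(x, ...) {
  cat(sprintf("consensus NMF fit: chosen k = %d (stability %.3f, error %.4g)\n",
              x$k, x$results[[as.character(x$k)]]$stability,
              x$results[[as.character(x$k)]]$error))
  cat("selection report:\n")
  print(x$selection, row.names = FALSE)
  invisible(x)
}

#' @export
summary.cnmf_fit <- function(object, ...) {
  res <- object$results[[as.character(object$k)]]
  cat(sprintf("k = %d programs over %d genes, %d cells\n",
              object$k, ncol(res$spectra), nrow(res$usages)))
  invisible(object$selection)
}

#' @export
coef.cnmf_fit <- function(object, ...) object$spectra

#' @export
plot.cnmf_fit <- function(x, ...) {
  graphics::plot(x$selection$k, x$selection$stability, type = "b",
                 xlab = "k", ylab = "stability (mean silhouette)", ...)
  invisible(x)
}

#' Normalise program usages so each cell sums to 1
#'
#' @param usages non-negative cell x program matrix.
#' @return row-normalised matrix; all-zero rows are left zero and listed
#'   in the `"zero_rows"` attribute.
#' @export
usage_normalize <- function(usages) {
  if (any(usages < 0)) stop("usages must be non-negative")
  rs <- rowSums(usages)
  out <- usages
  out[rs > 0, ] <- usages[rs > 0, , drop = FALSE] / rs[rs > 0]
  attr(out, "zero_rows") <- rownames(usages)[rs == 0]
  out
}

#' Donor-level mean program scores
#'
#' Per donor, the mean normalised usage of each program across that
#' donor's cells, multiplied by a per-program orientation (+1/-1).  The
#' orientation mirrors the convention of flipping a program's sign so that
#' "more of the program" points the same way across analyses.
#'
#' @param usages cell x program matrix (rows normalised; see
#'   [usage_normalize()]).
#' @param cell_donor donor id of each cell (aligned with rows).
#' @param orientation +1/-1 per program (default all +1).
#' @return donor x program matrix of mean scores; donors with zero cells
#'   are absent and listed in the `"missing_donors"` attribute.
#' @export
donor_program_scores <- function(usages, cell_donor, orientation = NULL) {
  stopifnot(length(cell_donor) == nrow(usages))
  if (anyNA(cell_donor)) stop("every cell must be mapped to a donor")
  if (is.null(orientation)) orientation <- rep(1, ncol(usages))
  stopifnot(length(orientation) == ncol(usages),
            all(orientation %in% c(-1, 1)))
  donors <- sort(unique(cell_donor))
  m <- do.call(rbind, lapply(donors, function(d)
    colMeans(usages[cell_donor == d, , drop = FALSE])))
  m <- sweep(m, 2, orientation, "*")
  dimnames(m) <- list(donors, colnames(usages))
  m
}
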