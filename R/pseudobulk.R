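#' Pearson residual normalisation of UMI counts
#'
#' Variance-stabilises a gene x cell count matrix under a negative-binomial
#' error model: `r = (x - mu) / sqrt(mu + mu^2 / theta)` with
#' `mu_gc = depth_c * p_g`, where `p_g` is gene g's pooled proportion of
#' all UMIs and `depth_c` the cell's total.  Per-gene dispersions `theta_g`
#' are method-of-moments estimates pooled across cells and regularised by a
#' rolling-median smooth against the log mean; genes with pooled proportion
#' below `min_prop` inherit the global median theta.  Residuals are clipped
#' to `+/- sqrt(n_cells)`.
#'
#' @param counts gene x cell matrix of non-negative integer counts (dense
#'   or sparse); at least 2 cells.
#' @param theta optional fixed dispersion: a scalar (recycled) or per-gene
#'   vector; `Inf` gives Poisson residuals.  Default `NULL` estimates
#'   per-gene values.
#' @param clip residual clip bound; default `sqrt(ncol(counts))`.
#' @param min_prop pooled-proportion floor below which a gene inherits the
#'   global median theta.
#' @return dense gene x cell matrix of clipped Pearson residuals, with the
#'   theta vector used in attribute `"theta"`.
#' @export
pearson_residuals <- function(counts, theta = NULL, clip = NULL,
                              min_prop = 1e-4) {
  x <- as.matrix(counts)
  if (ncol(x) < 2) stop("need at least 2 cells")
  if (any(x < 0)) stop("counts must be non-negative")
  n_cells <- ncol(x)
  depth <- colSums(x)
  total <- sum(depth)
  p_g <- rowSums(x) / total
  mu <- outer(p_g, depth)
  if (is.null(theta)) {
    theta <- estimate_theta(x, mu, p_g, min_prop)
  } else {
    theta <- rep_len(theta, nrow(x))
  }
  denom <- sqrt(mu + mu^2 / theta)
  r <- (x - mu) / denom
  r[p_g == 0, ] <- 0  # all-zero genes: no information, residual 0
  if (is.null(clip)) clip <- sqrt(n_cells)
  r[r > clip] <- clip
  r[r < -clip] <- -clip
  dimnames(r) <- dimnames(x)
  attr(r, "theta") <- theta
  r
}

## pooled method-of-moments NB dispersion per gene, regularised by a
## rolling median of log theta along log mean expression
estimate_theta <- function(x, mu, p_g, min_prop) {
  excess <- rowSums((x - mu)^2 - mu)       # overdispersion evidence
  denom_t <- rowSums(mu^2)
  theta_raw <- ifelse(excess > 0 & denom_t > 0, denom_t / excess, Inf)
  theta_cap <- 1e6
  lt <- log(pmin(theta_raw, theta_cap))
  ord <- order(p_g)
  n <- length(lt)
  k <- min(101L, if (n %% 2L == 1L) n else n - 1L)  # odd window <= n
  sm <- lt
  if (length(lt) >= 3 && k >= 3) {
    sm[ord] <- stats::runmed(lt[ord], k, endrule = "median")
  }
  theta <- exp(sm)
  global <- stats::median(theta[p_g >= min_prop])
  if (!is.finite(global)) global <- theta_cap
  theta[p_g < min_prop] <- global
  theta[theta >= theta_cap] <- Inf
  unname(theta)
}

#' Aggregate per-cell values into per-cell-type gene x donor pseudobulk
#'
#' Sums each donor's cells within each cell type, producing one
#' `celltype_pseudobulk` object per type.  `mode` records whether the input
#' is raw counts (`"raw_sum"`) or Pearson residuals (`"residual_sum"`);
#' downstream stages check the tag (conformity QC needs raw sums, factor
#' analysis residual sums).
#'
#' @param values gene x cell matrix (counts or residuals).
#' @param cell_donor named character vector or vector aligned with columns:
#'   donor of each cell.
#' @param cell_type cell-type label of each cell, aligned likewise.
#' @param mode `"raw_sum"` or `"residual_sum"`.
#' @return named list of `celltype_pseudobulk` objects, each a list with
#'   `cell_type`, `matrix` (gene x donor), `mode`, `donor_umis` (raw mode),
#'   `n_cells` per donor, and `absent_donors` (donors with no cells of the
#'   type, relative to the full donor set).
#' @export
aggregate_pseudobulk <- function(values, cell_donor, cell_type,
                                 mode = c("raw_sum", "residual_sum")) {
  mode <- match.arg(mode)
  stopifnot(length(cell_donor) == ncol(values),
            length(cell_type) == ncol(values))
  bad <- is.na(cell_donor) | is.na(cell_type)
  if (any(bad))
    stop("unmapped cell barcode(s): ",
         paste(utils::head(colnames(values)[bad], 10), collapse = ", "))
  all_donors <- sort(unique(cell_donor))
  out <- list()
  for (ct in sort(unique(cell_type))) {
    sel <- cell_type == ct
    donors_here <- sort(unique(cell_donor[sel]))
    ind <- Matrix::sparseMatrix(
      i = seq_len(sum(sel)),
      j = match(cell_donor[sel], donors_here),
      x = 1, dims = c(sum(sel), length(donors_here)),
      dimnames = list(NULL, donors_here))
    m <- as.matrix(values[, sel, drop = FALSE] %*% ind)
    pb <- structure(list(
      cell_type = ct, matrix = m, mode = mode,
      donor_umis = if (mode == "raw_sum") colSums(m) else NULL,
      n_cells = as.vector(table(factor(cell_donor[sel], donors_here))),
      absent_donors = setdiff(all_donors, donors_here)),
      class = "celltype_pseudobulk")
    out[[ct]] <- pb
  }
  out
}

#' @export
print.celltype_pseudobulk <- function(x, ...) {
  cat(sprintf("pseudobulk [%s]: %s, %d genes x %d donors\n",
              x$mode, x$cell_type, nrow(x$matrix), ncol(x$matrix)))
  if (length(x$absent_donors))
    cat("  donors without cells of this type:",
        paste(x$absent_donors, collapse = ", "), "\n")
  invisible(x)
}
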