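#' Modified z-scores for robust outlier detection
#'
#' `M_i = 0.6745 * (x_i - median(x)) / MAD`, with MAD the (unscaled) median
#' absolute deviation.  The constant 0.6745 makes M comparable to an
#' ordinary z-score for Gaussian data, since the expected MAD of a standard
#' normal is 0.6745.
#'
#' @param scores numeric vector (per-donor conformity scores, typically).
#' @return numeric vector of modified z-scores, same names as input.
#' @export
modified_z <- function(scores) {
  med <- stats::median(scores)
  mad0 <- stats::median(abs(scores - med))
  if (mad0 == 0) stop("degenerate spread (MAD = 0)")
  0.6745 * (scores - med) / mad0
}

## shared conformity machinery: feature x donor matrix -> per-donor median
## pairwise Pearson correlation
conformity_from_matrix <- function(m, log_transform = TRUE) {
  if (ncol(m) < 3) stop("conformity undefined for fewer than 3 donors")
  v <- if (log_transform) log10(m + 1) else m
  cc <- stats::cor(v)
  if (anyNA(cc))
    stop("conformity undefined: some donor profiles have zero variance")
  x <- vapply(seq_len(ncol(cc)),
              function(i) stats::median(cc[-i, i]), 0)
  names(x) <- colnames(m)
  x
}

#' Donor conformity scores from raw pseudobulk expression
#'
#' For each cell type, donor columns are scaled to 100,000 UMIs, genes with
#' at least 10 UMIs per 100,000 in at least one donor are kept, and the
#' kept (log10-scaled) rows from all cell types are merged.  Each donor's
#' conformity score is the median of its pairwise Pearson correlations with
#' the other donors; aberrant donors show up as low-conformity outliers.
#'
#' @param pseudobulks list of `raw_sum` [aggregate_pseudobulk()] objects
#'   (one per cell type) sharing a donor set.
#' @param min_per_1e5 gene filter threshold (default 10 per 100,000).
#' @return object of class `conformity_report`: list with `scores` (x_i),
#'   `median`, `mad` (unscaled), `modified_z` (M_i), `n_features`.
#' @export
conformity_scores <- function(pseudobulks, min_per_1e5 = 10) {
  stopifnot(length(pseudobulks) >= 1)
  donors <- Reduce(intersect, lapply(pseudobulks, function(p) colnames(p$matrix)))
  if (length(donors) < 3) stop("conformity undefined for fewer than 3 donors")
  blocks <- lapply(pseudobulks, function(pb) {
    if (pb$mode != "raw_sum")
      stop("conformity_scores needs raw_sum pseudobulk, got ", pb$mode)
    m <- pb$matrix[, donors, drop = FALSE]
    scaled <- sweep(m, 2, pmax(colSums(m), 1), "/") * 1e5
    keep <- apply(scaled, 1, max) >= min_per_1e5
    out <- scaled[keep, , drop = FALSE]
    rownames(out) <- paste(rownames(out), pb$cell_type, sep = "_")
    out
  })
  merged <- do.call(rbind, blocks)
  x <- conformity_from_matrix(merged, log_transform = TRUE)
  new_conformity_report(x, n_features = nrow(merged))
}

#' Donor conformity scores from cell-type proportions
#'
#' The same conformity statistic as [conformity_scores()], computed on each
#' donor's vector of cell-type proportions instead of gene expression.
#'
#' @param cell_donor donor of each cell.
#' @param cell_type cell-type label of each cell.
#' @return a `conformity_report`.
#' @export
proportion_conformity <- function(cell_donor, cell_type) {
  tab <- table(cell_type, cell_donor)
  prop <- sweep(unclass(tab), 2, colSums(tab), "/")
  x <- conformity_from_matrix(prop, log_transform = FALSE)
  new_conformity_report(x, n_features = nrow(prop))
}

new_conformity_report <- function(x, n_features) {
  med <- stats::median(x)
  mad0 <- stats::median(abs(x - med))
  structure(list(scores = x, median = med, mad = mad0,
                 modified_z = if (mad0 > 0) 0.6745 * (x - med) / mad0
                              else rep(NA_real_, length(x)),
                 n_features = n_features),
            class = "conformity_report")
}

#' @export
print.conformity_report <- function(x, ...) {
  cat(sprintf("conformity over %d donors (%d features)\n",
              length(x$scores), x$n_features))
  cat(sprintf("  median %.4f, MAD %.4g; |modified z| range %.2f..%.2f\n",
              x$median, x$mad,
              min(abs(x$modified_z)), max(abs(x$modified_z))))
  invisible(x)
}

#' Flag aberrant donors for exclusion
#'
#' Union of three criteria: (1) fewer than `min_umis` total UMIs in any
#' cell type; (2) expression conformity |modified z| > `expr_z`; (3)
#' cell-type-proportion conformity |modified z| > `prop_z`.  Defaults
#' 1000 / 5 / 15.
#'
#' @param expr_report `conformity_report` from [conformity_scores()].
#' @param prop_report `conformity_report` from [proportion_conformity()].
#' @param umi_totals donor x cell-type matrix of total UMIs.
#' @param min_umis,expr_z,prop_z thresholds.
#' @return data frame (donor, criterion, statistic), zero rows when no
#'   donor is flagged.
#' @export
flag_outlier_donors <- function(expr_report, prop_report, umi_totals,
                                min_umis = 1000, expr_z = 5, prop_z = 15) {
  out <- list()
  if (!is.null(umi_totals)) {
    low <- apply(umi_totals, 1, min) < min_umis
    if (any(low))
      out[[length(out) + 1L]] <- data.frame(
        donor = rownames(umi_totals)[low], criterion = "low_umis",
        statistic = apply(umi_totals, 1, min)[low])
  }
  if (!is.null(expr_report)) {
    m <- expr_report$modified_z
    hit <- !is.na(m) & abs(m) > expr_z
    if (any(hit))
      out[[length(out) + 1L]] <- data.frame(
        donor = names(m)[hit], criterion = "expression_conformity",
        statistic = m[hit])
  }
  if (!is.null(prop_report)) {
    m <- prop_report$modified_z
    hit <- !is.na(m) & abs(m) > prop_z
    if (any(hit))
      out[[length(out) + 1L]] <- data.frame(
        donor = names(m)[hit], criterion = "proportion_conformity",
        statistic = m[hit])
  }
  if (length(out) == 0)
    return(data.frame(donor = character(0), criterion = character(0),
                      statistic = numeric(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
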