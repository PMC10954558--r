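#' Build the donor x (gene, cell type) factor-analysis input matrix
#'
#' Runs the standard pre-processing chain on a gene x cell count matrix:
#' per-cell-type Pearson residuals, residual-sum and raw-sum pseudobulk
#' aggregation, the per-type top-fraction expression filter, cell-type
#' suffixing and concatenation.
#'
#' @param counts gene x cell count matrix.
#' @param cell_donor donor id per cell.
#' @param cell_type cell-type label per cell.
#' @param top_fraction per-type fraction of genes kept (default 0.5).
#' @param theta optional fixed dispersion passed to [pearson_residuals()].
#' @return donor x feature matrix as from [concatenate_celltypes()], with
#'   the raw pseudobulk list in attribute `"raw_pseudobulk"`.
#' @export
build_factor_matrix <- function(counts, cell_donor, cell_type,
                                top_fraction = 0.5, theta = NULL) {
  res_list <- list(); raw_list <- list()
  for (ct in sort(unique(cell_type))) {
    sel <- cell_type == ct
    sub <- counts[, sel, drop = FALSE]
    pr <- pearson_residuals(sub, theta = theta)
    raw_list[[ct]] <- aggregate_pseudobulk(sub, cell_donor[sel],
                                           rep(ct, sum(sel)), "raw_sum")[[ct]]
    res_list[[ct]] <- aggregate_pseudobulk(pr, cell_donor[sel],
                                           rep(ct, sum(sel)),
                                           "residual_sum")[[ct]]
  }
  out <- concatenate_celltypes(res_list, raw_list, top_fraction)
  attr(out, "raw_pseudobulk") <- raw_list
  out
}

#' Benchmark scenario: cross-cell-type factor recovery
#'
#' The planted-factor recovery condition: 180 donors in 20-donor villages,
#' three cell types (astrocyte, glutamatergic, GABAergic), one strongly
#' planted cross-cell-type program whose donor scores decline with age and
#' with case status, score noise at half the structured score sd
#' (signal-to-noise 2 at the score level), and loadings strong enough that
#' the program is spectrally resolvable from 180 donors.
#'
#' @param n_donors number of donors (default 180).
#' @return a [village_config()].
#' @export
scenario_factor_recovery <- function(n_donors = 180) {
  village_config(
    n_donors = n_donors, village_size = 20,
    cell_types = c("astrocyte", "glutamatergic", "GABAergic"),
    celltype_weights = c(1.4, 1.2, 1),
    doublet_rate = 0,
    program = program_spec(loading_scale = 0.5, fraction_loaded = 0.2))
}

#' Benchmark scenario: donor outlier QC
#'
#' 40 donors in two 20-donor villages with 2 planted aberrant donors under
#' the default (subtle) program; no doublets, so pseudobulk can use true
#' donor labels directly.
#'
#' @return a [village_config()].
#' @export
scenario_outlier_qc <- function() {
  village_config(n_donors = 40, n_outliers = 2, doublet_rate = 0)
}

#' Run the donor-exclusion QC chain on a simulation
#'
#' Aggregates raw pseudobulk per cell type, computes expression and
#' cell-type-proportion conformity reports, and applies the three
#' exclusion criteria.
#'
#' @param counts gene x cell counts.
#' @param cell_donor,cell_type per-cell annotations.
#' @param ... thresholds passed to [flag_outlier_donors()].
#' @return list: `flags` (data frame), `expression` and `proportions`
#'   (conformity reports), `umi_totals`.
#' @export
run_donor_qc <- function(counts, cell_donor, cell_type, ...) {
  raw <- aggregate_pseudobulk(counts, cell_donor, cell_type, "raw_sum")
  expr_rep <- conformity_scores(raw)
  prop_rep <- proportion_conformity(cell_donor, cell_type)
  donors <- sort(unique(cell_donor))
  umis <- vapply(raw, function(p) {
    v <- rep(0, length(donors)); names(v) <- donors
    v[colnames(p$matrix)] <- p$donor_umis
    v
  }, numeric(length(donors)))
  flags <- flag_outlier_donors(expr_rep, prop_rep, umis, ...)
  list(flags = flags, expression = expr_rep, proportions = prop_rep,
       umi_totals = umis)
}
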