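## Per-UMI gene association rule: a UMI belongs to a single gene if at
## least one of its reads maps uniquely (high quality) to that gene; if
## all reads are low-quality multi-mappers, the UMI is associated with the
## union of the hit genes.  UMIs with unique reads to >1 distinct genes are
## chimeric and discarded.
umi_associations <- function(records) {
  stopifnot(all(c("cell_barcode", "umi", "gene_id", "mapq_class")
                %in% names(records)))
  if (nrow(records) == 0)
    return(data.frame(cell_barcode = character(0), umi = character(0),
                      genes = character(0), n_genes = integer(0),
                      chimeric = logical(0)))
  key <- paste(records$cell_barcode, records$umi, sep = "\r")
  is_unique <- records$mapq_class == "unique"
  assoc <- vapply(split(seq_len(nrow(records)), key), function(ix) {
    u <- unique(records$gene_id[ix][is_unique[ix]])
    if (length(u) == 1) return(u)
    if (length(u) > 1) return(NA_character_)  # chimeric
    paste(sort(unique(records$gene_id[ix])), collapse = "+")
  }, "")
  keys <- strsplit(names(assoc), "\r", fixed = TRUE)
  data.frame(
    cell_barcode = vapply(keys, `[`, "", 1),
    umi = vapply(keys, `[`, "", 2),
    genes = unname(assoc),
    n_genes = ifelse(is.na(assoc), NA_integer_,
                     lengths(strsplit(assoc, "+", fixed = TRUE))),
    chimeric = is.na(assoc),
    stringsAsFactors = FALSE)
}

#' Discover paralog gene families ("metagenes") from co-ambiguous UMIs
#'
#' High-homology genes (e.g. C4A/C4B) produce reads that map to several
#' gene models with low mapping quality, so their UMIs cannot be assigned
#' to a single gene.  A UMI is associated with one gene if at least one of
#' its reads maps uniquely; otherwise it is associated with the whole set
#' of multi-hit genes.  Gene sets that recur as the association set of many
#' UMIs, and account for nearly all ambiguous UMIs touching their members,
#' are reported as metagene families.
#'
#' Purity of a candidate set S = (UMIs whose association set equals S) /
#' (ambiguous UMIs whose association set intersects S).  Overlapping
#' candidates are resolved greedily by higher purity, then larger support,
#' then lexicographic member order.
#'
#' @param records data frame of read-to-gene hits: `cell_barcode`, `umi`,
#'   `gene_id`, `mapq_class` (`"unique"` or `"multi"`).
#' @param min_support minimum UMIs whose association set equals the family.
#' @param min_purity minimum purity (default 0.95).
#' @return list of families, each `list(member_genes, supporting_umis,
#'   purity)`, sorted by decreasing support; class `metagene_families`.
#' @export
discover_metagenes <- function(records, min_support = 50, min_purity = 0.95) {
  assoc <- umi_associations(records)
  assoc <- assoc[!assoc$chimeric, , drop = FALSE]
  amb <- assoc[assoc$n_genes >= 2, , drop = FALSE]
  out <- list()
  if (nrow(amb) > 0) {
    support <- table(amb$genes)
    cand <- names(support)[support >= min_support]
    members <- strsplit(cand, "+", fixed = TRUE)
    amb_sets <- strsplit(amb$genes, "+", fixed = TRUE)
    amb_genes <- rep(seq_along(amb_sets), lengths(amb_sets))
    gene_of_amb <- unlist(amb_sets)
    purity <- vapply(seq_along(cand), function(i) {
      touching <- unique(amb_genes[gene_of_amb %in% members[[i]]])
      as.numeric(support[cand[i]]) / length(touching)
    }, 0)
    keep <- purity >= min_purity
    cand <- cand[keep]; members <- members[keep]
    purity <- purity[keep]; supp <- as.numeric(support[cand])
    ## deterministic overlap resolution
    ord <- order(-purity, -supp, cand)
    used <- character(0)
    for (i in ord) {
      if (any(members[[i]] %in% used)) next
      used <- c(used, members[[i]])
      out[[length(out) + 1L]] <- list(member_genes = members[[i]],
                                      supporting_umis = supp[i],
                                      purity = purity[i])
    }
    out <- out[order(-vapply(out, `[[`, 0, "supporting_umis"))]
  }
  structure(out, class = "metagene_families")
}

#' @export
print.metagene_families <- function(x, ...) {
  cat(length(x), if (length(x) == 1) "metagene family" else "metagene families", "\n")
  for (f in x)
    cat(sprintf("  %s: %d UMIs, purity %.3f\n",
                paste(f$member_genes, collapse = "+"),
                f$supporting_umis, f$purity))
  invisible(x)
}

#' Count UMIs per gene and per metagene family
#'
#' Unambiguous UMIs count to their single gene.  Ambiguous UMIs whose
#' association set exactly equals a family count once to that family's
#' joint row.  Remaining ambiguous UMIs (strict subsets/supersets of a
#' family, or sets matching no family) go to a discarded-inconsistent
#' bucket rather than being fractionally allocated; every input UMI is
#' accounted for: `sum(genes) + sum(metagenes) + discarded + chimeric ==
#' total UMIs`.
#'
#' @param records as in [discover_metagenes()].
#' @param families a `metagene_families` list (or list of character
#'   vectors); members must be pairwise disjoint.
#' @return list with sparse matrices `gene_counts` (gene x cell),
#'   `metagene_counts` (family x cell, feature ids `"A+B"`),
#'   `discarded` (ambiguous UMIs not matching any family), `chimeric`,
#'   and `total_umis`.
#' @export
count_metagene_umis <- function(records, families = list()) {
  fam_members <- lapply(families, function(f)
    if (is.list(f)) f$member_genes else f)
  if (length(fam_members) > 1) {
    all_m <- unlist(fam_members)
    if (anyDuplicated(all_m)) stop("resolve overlaps first")
  }
  fam_ids <- vapply(fam_members, function(m) paste(sort(m), collapse = "+"), "")
  assoc <- umi_associations(records)
  cells <- sort(unique(assoc$cell_barcode))
  ci <- match(assoc$cell_barcode, cells)
  chimeric <- sum(assoc$chimeric)
  ok <- !assoc$chimeric
  uniq <- ok & assoc$n_genes == 1
  amb <- ok & assoc$n_genes >= 2
  genes <- sort(unique(assoc$genes[uniq]))
  gene_counts <- make_count_matrix(assoc$genes[uniq], ci[uniq], genes, cells)
  is_fam <- amb & assoc$genes %in% fam_ids
  metagene_counts <- make_count_matrix(assoc$genes[is_fam], ci[is_fam],
                                       fam_ids, cells)
  list(gene_counts = gene_counts,
       metagene_counts = metagene_counts,
       discarded = sum(amb & !assoc$genes %in% fam_ids),
       chimeric = chimeric,
       total_umis = nrow(assoc))
}

make_count_matrix <- function(feature, cell_idx, features, cells) {
  m <- Matrix::sparseMatrix(
    i = match(feature, features), j = cell_idx, x = 1,
    dims = c(length(features), length(cells)),
    dimnames = list(features, cells))
  methods::as(m, "CsparseMatrix")
}

#' Validate joint metagene counts against a collapsed single-copy oracle
#'
#' The reference check for joint family counting: re-quantify the same
#' cells against a reference in which the family is collapsed to a single
#' gene copy (so every UMI maps uniquely) and compare per-cell totals.
#'
#' @param joint_counts family x cell matrix from [count_metagene_umis()].
#' @param oracle_counts family x cell matrix of single-copy-reference
#'   counts with matching rownames and cell barcodes.
#' @return list: `concordant`, `total`, `fraction`, `discordant_cells`.
#' @export
validate_single_copy <- function(joint_counts, oracle_counts) {
  cells <- intersect(colnames(joint_counts), colnames(oracle_counts))
  if (length(cells) == 0) stop("no shared cell barcodes")
  fams <- intersect(rownames(joint_counts), rownames(oracle_counts))
  if (length(fams) == 0) stop("no shared family ids")
  a <- as.matrix(joint_counts[fams, cells, drop = FALSE])
  b <- as.matrix(oracle_counts[fams, cells, drop = FALSE])
  good <- colSums(a != b) == 0
  list(concordant = sum(good), total = length(cells),
       fraction = mean(good),
       discordant_cells = cells[!good])
}
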