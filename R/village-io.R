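#' Write a simulated village to disk
#'
#' Emits, per village batch, a Matrix Market counts matrix with companion
#' `barcodes.tsv` / `features.tsv`, plus village-wide genotype, SNP
#' observation and donor metadata TSVs and a ground-truth JSON (planted
#' outliers, doublet barcodes, program scores).  The layout round-trips
#' losslessly through [read_village()].
#'
#' @param sim a `village_sim` from [simulate_village()].
#' @param dir output directory.
#' @param overwrite allow writing into an existing non-empty directory.
#' @return `dir`, invisibly.
#' @export
write_village <- function(sim, dir, overwrite = FALSE) {
  stopifnot(inherits(sim, "village_sim"))
  if (dir.exists(dir) && length(dir(dir)) > 0 && !overwrite)
    stop("directory exists and is non-empty; pass overwrite = TRUE")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (v in sort(unique(sim$nuclei$village))) {
    bcs <- sim$nuclei$barcode[sim$nuclei$village == v]
    sub <- sim$counts[, bcs, drop = FALSE]
    base <- file.path(dir, sprintf("village%02d", v))
    Matrix::writeMM(methods::as(sub, "CsparseMatrix"),
                    paste0(base, "_counts.mtx"))
    writeLines(bcs, paste0(base, "_barcodes.tsv"))
    writeLines(rownames(sub), paste0(base, "_features.tsv"))
  }
  gt <- data.frame(
    snp_id = rep(colnames(sim$genotypes), each = nrow(sim$genotypes)),
    donor_id = rep(rownames(sim$genotypes), ncol(sim$genotypes)),
    dosage = as.vector(sim$genotypes))
  utils::write.table(gt, file.path(dir, "genotypes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$snp_obs, file.path(dir, "snp_observations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$nuclei, file.path(dir, "nuclei.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$donors, file.path(dir, "donors.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth <- list(
    outlier_donors = as.list(sim$outlier_truth),
    doublet_barcodes = sim$nuclei$barcode[sim$nuclei$is_doublet],
    program_scores = as.data.frame(sim$program_scores),
    seed = sim$seed)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a village directory written by [write_village()]
#'
#' @param dir directory produced by [write_village()].
#' @return list with `counts` (gene x nucleus sparse matrix, batches
#'   column-bound), `nuclei`, `donors`, `genotypes` (donor x SNP matrix),
#'   `snp_obs`, and `truth`.
#' @export
read_village <- function(dir) {
  mtx <- sort(list.files(dir, pattern = "_counts\\.mtx$", full.names = TRUE))
  if (length(mtx) == 0) stop("no counts matrices found in ", dir)
  mats <- lapply(mtx, function(f) {
    base <- sub("_counts\\.mtx$", "", f)
    m <- methods::as(Matrix::readMM(f), "CsparseMatrix")
    dimnames(m) <- list(readLines(paste0(base, "_features.tsv")),
                        readLines(paste0(base, "_barcodes.tsv")))
    m
  })
  counts <- do.call(cbind, mats)
  gt <- utils::read.table(file.path(dir, "genotypes.tsv"), header = TRUE,
                          sep = "\t", stringsAsFactors = FALSE)
  genotypes <- genotype_matrix(gt)
  list(counts = counts,
       nuclei = utils::read.table(file.path(dir, "nuclei.tsv"), header = TRUE,
                                  sep = "\t", stringsAsFactors = FALSE),
       donors = utils::read.table(file.path(dir, "donors.tsv"), header = TRUE,
                                  sep = "\t", stringsAsFactors = FALSE),
       genotypes = genotypes,
       snp_obs = utils::read.table(file.path(dir, "snp_observations.tsv"),
                                   header = TRUE, sep = "\t",
                                   stringsAsFactors = FALSE),
       truth = jsonlite::read_json(file.path(dir, "truth.json"),
                                   simplifyVector = TRUE))
}

## long (snp_id, donor_id, dosage) -> donor x SNP matrix
genotype_matrix <- function(gt) {
  stopifnot(all(c("snp_id", "donor_id", "dosage") %in% names(gt)))
  donors <- unique(gt$donor_id); snps <- unique(gt$snp_id)
  m <- matrix(NA_real_, length(donors), length(snps),
              dimnames = list(donors, snps))
  m[cbind(match(gt$donor_id, donors), match(gt$snp_id, snps))] <- gt$dosage
  if (anyNA(m)) stop("genotype table is not a complete donor x SNP grid")
  if (!all(m %in% c(0, 1, 2))) stop("dosages must be in {0, 1, 2}")
  m
}

#' Read donor genotypes from a 3-column TSV
#'
#' Expected columns: `snp_id`, `donor_id`, `dosage` (alt-allele dosage in
#' 0/1/2).
#'
#' @param path TSV file path.
#' @return donor x SNP dosage matrix.
#' @export
read_genotypes_tsv <- function(path) {
  genotype_matrix(utils::read.table(path, header = TRUE, sep = "\t",
                                    stringsAsFactors = FALSE))
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated `set<TAB>description<TAB>`
#' then gene ids.
#'
#' @param path GMT file path.
#' @return named list of character vectors; set descriptions in the
#'   `"description"` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3
  if (any(bad)) stop("malformed GMT line(s): ", paste(which(bad), collapse = ", "))
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[`, "", 1)
  attr(sets, "description") <- vapply(parts, `[`, "", 2)
  sets
}
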