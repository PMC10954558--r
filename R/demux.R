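#' Expected fraction of cross-donor doublets
#'
#' In a pooled village, a droplet doublet combines two nuclei drawn from
#' the donor pool.  If donors contribute nuclei with proportions `p`, the
#' probability that the two nuclei come from *distinct* donors is
#' `1 - sum(p^2)`; for 20 equally represented donors this is 0.95, which is
#' why most doublets in a village design are detectable from their mixed
#' SNP alleles.
#'
#' @param donor_proportions non-negative proportions summing to 1.
#' @param tol tolerance on the sum-to-one check.
#' @return scalar fraction in `[0, 1]`.
#' @export
expected_cross_donor_fraction <- function(donor_proportions, tol = 1e-8) {
  p <- donor_proportions
  if (length(p) == 0) stop("empty proportion vector")
  if (any(p < 0)) stop("proportions must be non-negative")
  if (abs(sum(p) - 1) > tol) stop("proportions must sum to 1")
  1 - sum(p^2)
}

## P(alt read | dosage g, error rate eps): linear error contamination,
## exact at homozygous dosages, unbiased at g = 1
p_alt_allele <- function(g, eps) (1 - 2 * eps) * g / 2 + eps

## collapse SNP observations to at most `cap` reads per SNP, then return
## per-donor log-likelihoods for a dosage matrix (possibly of pair mixtures)
snp_loglik <- function(obs, dosage, eps, cap = 1L) {
  if (nrow(obs) == 0) return(rep(0, nrow(dosage)))
  if (is.finite(cap)) {
    obs$count <- pmin(obs$count, cap)
  }
  idx <- match(obs$snp_id, colnames(dosage))
  if (anyNA(idx))
    stop("observed SNP(s) missing from genotype panel: ",
         paste(unique(obs$snp_id[is.na(idx)]), collapse = ", "))
  p <- p_alt_allele(dosage[, idx, drop = FALSE], eps)  # donors x obs
  is_alt <- obs$allele == "alt"
  ll <- log(p) %*% (obs$count * is_alt) +
    log1p(-p) %*% (obs$count * !is_alt)
  as.vector(ll)
}

#' Assign a nucleus to its donor of origin from transcribed-SNP alleles
#'
#' Computes, for every donor, the log-likelihood of the nucleus's allele
#' observations under that donor's genotype with a per-read error rate
#' `error_rate`, using `P(alt | dosage g) = (1 - 2*eps) * g/2 + eps`.
#' The best donor wins; the assignment is `"ambiguous"` when the margin to
#' the runner-up falls below `margin_threshold` (natural-log units) or the
#' nucleus carries no SNP evidence.
#'
#' @param obs data frame of observations for one nucleus: columns `snp_id`,
#'   `allele` (`"ref"`/`"alt"`), `count`; optionally `barcode`.
#' @param genotypes donor x SNP dosage matrix (0/1/2), donor ids as
#'   rownames.
#' @param error_rate per-read allele error rate, in (0, 0.5).
#' @param margin_threshold minimum log-likelihood margin for a confident
#'   singlet call (default 2 nats).
#' @param cap_per_snp maximum reads counted per SNP per nucleus (default 1;
#'   collapsing avoids pseudo-replication from PCR duplicates).
#' @return list of class `donor_assignment`: `barcode`, `loglik` (named
#'   per-donor vector), `best_donor`, `margin`, `status`, `best_pair`
#'   (`NULL` here; see [classify_doublet()]), `note`.
#' @export
assign_nucleus <- function(obs, genotypes, error_rate = 0.01,
                           margin_threshold = 2, cap_per_snp = 1L) {
  stopifnot(error_rate > 0, error_rate < 0.5)
  barcode <- if ("barcode" %in% names(obs) && nrow(obs) > 0)
    obs$barcode[1] else NA_character_
  if (nrow(obs) == 0) {
    return(structure(list(barcode = barcode,
                          loglik = stats::setNames(rep(0, nrow(genotypes)),
                                                   rownames(genotypes)),
                          best_donor = NA_character_, margin = 0,
                          status = "ambiguous", best_pair = NULL,
                          note = "no evidence"),
                     class = "donor_assignment"))
  }
  ll <- snp_loglik(obs, genotypes, error_rate, cap_per_snp)
  names(ll) <- rownames(genotypes)
  ord <- order(ll, decreasing = TRUE)
  margin <- if (length(ll) > 1) ll[ord[1]] - ll[ord[2]] else Inf
  structure(list(barcode = barcode, loglik = ll,
                 best_donor = names(ll)[ord[1]],
                 margin = unname(margin),
                 status = if (margin >= margin_threshold) "singlet" else "ambiguous",
                 best_pair = NULL, note = NULL),
            class = "donor_assignment")
}

#' Resolve singlet vs cross-donor doublet status for a nucleus
#'
#' Evaluates, in addition to every single-donor likelihood, the likelihood
#' of every unordered donor pair under a 50/50 mixture (mixture dosage
#' `(g1 + g2) / 2`).  The nucleus is called a doublet when the best pair
#' beats the best singlet by at least `doublet_margin` nats; otherwise it
#' is a singlet or, below `margin_threshold`, ambiguous.
#'
#' @inheritParams assign_nucleus
#' @param doublet_margin log-likelihood advantage a pair must have over the
#'   best singlet to call a doublet (default 5 nats).
#' @return a `donor_assignment`; for doublets `best_pair` holds the two
#'   donor ids and `status == "doublet"`.
#' @export
classify_doublet <- function(obs, genotypes, error_rate = 0.01,
                             doublet_margin = 5, margin_threshold = 2,
                             cap_per_snp = 1L) {
  base <- assign_nucleus(obs, genotypes, error_rate,
                         margin_threshold, cap_per_snp)
  if (nrow(obs) == 0 || nrow(genotypes) < 2) return(base)
  pairs <- utils::combn(nrow(genotypes), 2)
  mix <- (genotypes[pairs[1, ], , drop = FALSE] +
          genotypes[pairs[2, ], , drop = FALSE]) / 2
  rownames(mix) <- paste(rownames(genotypes)[pairs[1, ]],
                         rownames(genotypes)[pairs[2, ]], sep = "|")
  ll_pair <- snp_loglik(obs, mix, error_rate, cap_per_snp)
  best_pair_i <- which.max(ll_pair)
  best_single <- max(base$loglik)
  if (ll_pair[best_pair_i] - best_single >= doublet_margin) {
    base$status <- "doublet"
    base$best_pair <- rownames(genotypes)[pairs[, best_pair_i]]
    base$pair_loglik <- ll_pair[best_pair_i]
  }
  base
}

#' @export
print.donor_assignment <- function(x, ...) {
  cat(sprintf("nucleus %s: %s", x$barcode, x$status))
  if (x$status == "doublet")
    cat(sprintf(" (%s + %s)", x$best_pair[1], x$best_pair[2]))
  else if (!is.na(x$best_donor))
    cat(sprintf(" -> %s (margin %.2f nats)", x$best_donor, x$margin))
  if (!is.null(x$note)) cat(" [", x$note, "]", sep = "")
  cat("\n")
  invisible(x)
}

#' Demultiplex every nucleus in a simulation or observation table
#'
#' Convenience wrapper running [classify_doublet()] over all barcodes.
#'
#' @param snp_obs data frame with columns `barcode`, `snp_id`, `allele`,
#'   `count`.
#' @inheritParams classify_doublet
#' @return data frame: barcode, best_donor, status, margin, pair columns.
#' @export
demux_all <- function(snp_obs, genotypes, error_rate = 0.01,
                      doublet_margin = 5, margin_threshold = 2,
                      cap_per_snp = 1L) {
  split_obs <- split(snp_obs, snp_obs$barcode)
  res <- lapply(split_obs, classify_doublet, genotypes = genotypes,
                error_rate = error_rate, doublet_margin = doublet_margin,
                margin_threshold = margin_threshold,
                cap_per_snp = cap_per_snp)
  data.frame(
    barcode = names(res),
    best_donor = vapply(res, function(r) r$best_donor, ""),
    status = vapply(res, function(r) r$status, ""),
    margin = vapply(res, function(r) r$margin, 0),
    pair_1 = vapply(res, function(r)
      if (is.null(r$best_pair)) NA_character_ else r$best_pair[1], ""),
    pair_2 = vapply(res, function(r)
      if (is.null(r$best_pair)) NA_character_ else r$best_pair[2], ""),
    row.names = NULL, stringsAsFactors = FALSE)
}
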