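## Weighted Kolmogorov-Smirnov-like enrichment score for one set.
## `order_idx` sorts the metric decreasing; `w` = |metric|^p in that order.
## Returns ES (signed max deviation of the running sum) and the rank index
## of the extremum, for leading-edge extraction.
enrichment_score <- function(hit_pos, w, N) {
  nh <- length(hit_pos)
  if (nh == N)  # degenerate: every gene a hit, no misses to walk against
    return(list(es = 0, peak = NA_integer_, sign = 1L))
  hit_pos <- sort(hit_pos)
  wh <- w[hit_pos]
  nr <- sum(wh)
  if (nr == 0) wh <- rep(1 / nh, nh) else wh <- wh / nr
  miss_step <- 1 / (N - nh)
  cum_hit <- cumsum(wh)
  ## running sum immediately after hit j, and immediately before hit j
  after <- cum_hit - (hit_pos - seq_len(nh)) * miss_step
  before <- c(0, cum_hit[-nh]) - (hit_pos - seq_len(nh)) * miss_step
  i_max <- which.max(after); i_min <- which.min(before)
  if (after[i_max] >= -before[i_min]) {
    list(es = unname(after[i_max]), peak = hit_pos[i_max], sign = 1L)
  } else {
    list(es = unname(before[i_min]), peak = hit_pos[i_min], sign = -1L)
  }
}

#' Preranked gene-set enrichment analysis
#'
#' Genes are ranked by a real-valued metric (typically a factor's gene
#' loadings).  For each gene set, the enrichment score (ES) is the maximal
#' deviation of a running sum that increments at set members (weighted by
#' `|metric|^weight`, normalised within the set) and decrements uniformly
#' at non-members.  Significance comes from gene-label permutations:
#' `n_perm` random same-size sets drawn from the ranked universe.  NES is
#' the ES divided by the mean of same-sign null ES values; the permutation
#' p-value and the FDR q-value use the standard sign-stratified
#' normalisation (a Benjamini-Hochberg alternative on the permutation
#' p-values is available via `fdr_method = "BH"`).
#'
#' Ties in the metric keep their input order (stable sort).
#'
#' @param metric named numeric vector: ranking metric per gene.
#' @param sets named list of character vectors (e.g. from [read_gmt()]).
#' @param weight exponent on `|metric|` for hit increments (default 1).
#' @param n_perm number of permutations (default 10000).
#' @param min_size,max_size set-size filter after intersecting with the
#'   ranked universe (defaults 10 and 500); skipped sets are recorded in
#'   the `"skipped"` attribute.
#' @param seed integer seed for the permutation draws.
#' @param fdr_method `"signed"` (sign-stratified NES-ratio FDR) or `"BH"`.
#' @return data frame of class `gsea_result`: set, size, ES, NES, p-value,
#'   FDR q-value, leading-edge size and genes (comma separated).
#' @export
preranked_gsea <- function(metric, sets, weight = 1, n_perm = 10000,
                           min_size = 10, max_size = 500, seed = 1L,
                           fdr_method = c("signed", "BH")) {
  fdr_method <- match.arg(fdr_method)
  stopifnot(!is.null(names(metric)), all(is.finite(metric)))
  if (anyDuplicated(names(metric))) stop("duplicate gene ids in metric")
  ord <- order(metric, decreasing = TRUE)   # stable: ties keep input order
  genes <- names(metric)[ord]
  w <- abs(metric[ord])^weight
  N <- length(genes)
  sets_idx <- lapply(sets, function(s) which(genes %in% s))
  sizes <- lengths(sets_idx)
  keep <- sizes >= min_size & sizes <= max_size & sizes < N
  skipped <- names(sets)[!keep]
  sets_idx <- sets_idx[keep]
  if (length(sets_idx) == 0) {
    out <- data.frame(set = character(0), size = integer(0), ES = numeric(0),
                      NES = numeric(0), p_value = numeric(0),
                      fdr = numeric(0), n_leading_edge = integer(0),
                      leading_edge = character(0))
    class(out) <- c("gsea_result", "data.frame")
    attr(out, "skipped") <- skipped
    return(out)
  }
  obs <- lapply(sets_idx, enrichment_score, w = w, N = N)
  es <- vapply(obs, `[[`, 0, "es")
  set.seed(seed)
  ## one shared null per set size keeps the permutations affordable
  null_by_size <- list()
  for (nh in sort(unique(lengths(sets_idx)))) {
    null_by_size[[as.character(nh)]] <- vapply(seq_len(n_perm), function(i) {
      enrichment_score(sample.int(N, nh), w, N)$es
    }, 0)
  }
  p <- nes <- numeric(length(es))
  null_nes_pool <- list()
  for (i in seq_along(es)) {
    null <- null_by_size[[as.character(length(sets_idx[[i]]))]]
    if (es[i] >= 0) {
      pos <- null[null >= 0]
      p[i] <- (1 + sum(pos >= es[i])) / (1 + length(pos))
      nes[i] <- if (length(pos)) es[i] / mean(pos) else NA_real_
    } else {
      neg <- null[null < 0]
      p[i] <- (1 + sum(neg <= es[i])) / (1 + length(neg))
      nes[i] <- if (length(neg)) -es[i] / mean(neg) else NA_real_
    }
    norm_null <- ifelse(null >= 0,
                        null / mean(null[null >= 0]),
                        -null / mean(null[null < 0]))
    null_nes_pool[[i]] <- norm_null
  }
  fdr <- if (fdr_method == "BH") {
    stats::p.adjust(p, "BH")
  } else {
    all_null <- unlist(null_nes_pool)
    vapply(seq_along(nes), function(i) {
      if (is.na(nes[i])) return(NA_real_)
      if (nes[i] >= 0) {
        num <- mean(all_null[all_null >= 0] >= nes[i])
        den <- mean(nes[nes >= 0] >= nes[i])
      } else {
        num <- mean(all_null[all_null < 0] <= nes[i])
        den <- mean(nes[nes < 0] <= nes[i])
      }
      min(1, num / max(den, .Machine$double.eps))
    }, 0)
  }
  le <- lapply(seq_along(obs), function(i) {
    hp <- sort(sets_idx[[i]])
    if (obs[[i]]$es == 0) return(character(0))
    if (obs[[i]]$sign > 0) genes[hp[hp <= obs[[i]]$peak]]
    else genes[hp[hp >= obs[[i]]$peak]]
  })
  out <- data.frame(set = names(sets_idx), size = lengths(sets_idx),
                    ES = es, NES = nes, p_value = p, fdr = fdr,
                    n_leading_edge = lengths(le),
                    leading_edge = vapply(le, paste, "", collapse = ","),
                    row.names = NULL)
  class(out) <- c("gsea_result", "data.frame")
  attr(out, "skipped") <- skipped
  out
}

#' Enrichment score of one gene set against a ranked metric
#'
#' The ES statistic of [preranked_gsea()] for a single set, without
#' permutations: the signed maximal deviation of the weighted running sum.
#'
#' @inheritParams leading_edge
#' @return scalar ES in `[-1, 1]`.
#' @export
gsea_es <- function(set, metric, weight = 1) {
  ord <- order(metric, decreasing = TRUE)
  genes <- names(metric)[ord]
  w <- abs(metric[ord])^weight
  hp <- which(genes %in% set)
  if (length(hp) == 0) stop("set does not intersect the ranked universe")
  enrichment_score(hp, w, length(genes))$es
}

#' Leading-edge ("core") genes of an enrichment
#'
#' For a positive ES, the set members at or before the running-sum
#' maximum; for a negative ES, those at or after the minimum.  These are
#' the genes that drive the enrichment.
#'
#' @param set character vector of set member gene ids.
#' @param metric the named ranking metric used for the enrichment.
#' @param weight exponent on `|metric|` (default 1, as in
#'   [preranked_gsea()]).
#' @return character vector of leading-edge genes (possibly empty).
#' @export
leading_edge <- function(set, metric, weight = 1) {
  ord <- order(metric, decreasing = TRUE)
  genes <- names(metric)[ord]
  w <- abs(metric[ord])^weight
  hp <- which(genes %in% set)
  if (length(hp) == 0 || length(hp) == length(genes)) return(character(0))
  sc <- enrichment_score(hp, w, length(genes))
  if (sc$es == 0) return(character(0))
  hp <- sort(hp)
  if (sc$sign > 0) genes[hp[hp <= sc$peak]] else genes[hp[hp >= sc$peak]]
}
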