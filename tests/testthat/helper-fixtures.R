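# small fixture builders shared across test files

# tiny village for fast structural tests
tiny_config <- function(...) {
  defaults <- list(n_donors = 6, village_size = 6,
                   cell_types = c("astrocyte", "neuron"),
                   celltype_weights = c(1.2, 1),
                   n_genes = 50, nuclei_per_donor_type = 5,
                   mean_depth = 500, n_snps = 30, snps_per_nucleus = 20)
  do.call(village_config, utils::modifyList(defaults, list(...)))
}

# deterministic donor table for plant_programs tests
toy_donors <- function(n = 10, ages = seq(30, 80, length.out = n)) {
  data.frame(donor_id = sprintf("D%02d", seq_len(n)),
             age = ages,
             status = rep(c("case", "control"), length.out = n),
             stringsAsFactors = FALSE)
}

# an exactly factorizable non-negative matrix (genes x cells) with
# block-structured programs
exact_nmf_counts <- function(n_cells = 60, n_genes = 39, k = 3, seed = 1) {
  set.seed(seed)
  W <- matrix(0, n_cells, k)
  for (i in seq_len(n_cells)) W[i, ((i - 1) %% k) + 1] <- runif(1, 0.5, 1.5)
  H <- matrix(0, k, n_genes)
  blk <- n_genes %/% k
  for (j in seq_len(k))
    H[j, ((j - 1) * blk + 1):(j * blk)] <- runif(blk, 0.2, 1)
  X <- W %*% H
  dimnames(X) <- list(sprintf("c%03d", seq_len(n_cells)),
                      sprintf("g%03d", seq_len(n_genes)))
  list(counts = t(X), W = W, H = H)
}

# brute-force GSEA running sum: the independent oracle implementation
brute_force_es <- function(set, metric, weight = 1) {
  ord <- order(metric, decreasing = TRUE)
  genes <- names(metric)[ord]
  w <- abs(metric[ord])^weight
  hit <- genes %in% set
  nr <- sum(w[hit])
  running <- 0
  best_pos <- 0; best_neg <- 0
  p_miss <- 1 / sum(!hit)
  for (i in seq_along(genes)) {
    running <- running + if (hit[i]) w[i] / nr else -p_miss
    if (running > best_pos) best_pos <- running
    if (running < best_neg) best_neg <- running
  }
  # positive deviation wins exact-magnitude ties
  unname(if (best_pos >= -best_neg) best_pos else best_neg)
}

# exhaustive singlet log-likelihood for demux oracle checks
brute_force_loglik <- function(obs, genotypes, eps) {
  vapply(seq_len(nrow(genotypes)), function(d) {
    ll <- 0
    for (i in seq_len(nrow(obs))) {
      g <- genotypes[d, obs$snp_id[i]]
      p_alt <- (1 - 2 * eps) * g / 2 + eps
      p <- if (obs$allele[i] == "alt") p_alt else 1 - p_alt
      ll <- ll + min(obs$count[i], 1) * log(p)
    }
    ll
  }, 0)
}
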