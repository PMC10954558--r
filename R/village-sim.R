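#' Default configuration for a synthetic village simulation
#'
#' A "village" is a pooled snRNA-seq library in which nuclei from ~20 donors
#' are processed together and donors are resolved computationally from
#' transcribed SNPs.  `village_config()` collects every knob of the
#' generator; the defaults describe the study conditions the downstream
#' modules are designed for: villages of 20 donors, several cell types per
#' donor, negative-binomial UMI counts whose log-mean carries planted
#' cross-cell-type latent programs, cross-donor doublets, a common-SNP panel
#' for demultiplexing, and optional aberrant ("outlier") donors.
#'
#' @param n_donors number of donors across all villages.
#' @param village_size donors per pooled village (default 20).
#' @param cell_types character vector of cell-type labels; every donor
#'   contributes nuclei of every type.
#' @param n_genes size of the shared gene universe.
#' @param nuclei_per_donor_type expected singlet nuclei per donor per type
#'   (Poisson-varying, at least 1, scaled by `celltype_weights`).
#' @param celltype_weights relative abundance of each cell type (recycled
#'   over `cell_types`); cell types in real tissue differ in yield, which
#'   is what makes per-donor composition informative for QC.
#' @param mean_depth expected UMIs per nucleus (library-size lognormal
#'   variation with `depth_sdlog`).
#' @param depth_sdlog lognormal sd of per-nucleus depth.
#' @param theta negative-binomial size parameter (inverse dispersion);
#'   `Inf` gives Poisson counts.
#' @param doublet_rate probability that a droplet contains two nuclei,
#'   in `[0, 1)`.  The second nucleus is drawn uniformly from the same
#'   village, so with 20 equally represented donors about 95% of doublets
#'   combine two distinct donors.
#' @param n_snps number of independent SNPs on the genotyping panel.
#' @param maf_range range of the uniform minor-allele-frequency draw.
#' @param snps_per_nucleus transcribed SNPs observed per nucleus.
#' @param snp_error per-read allele error rate epsilon.
#' @param age_range donor age range (years), sampled uniformly.
#' @param program a `program_spec()` describing the planted latent programs.
#' @param donor_effect_sdlog sd of the lognormal idiosyncratic donor
#'   expression effect (per donor x gene, shared across cell types);
#'   models the biological inter-donor heterogeneity real cohorts carry.
#' @param n_outliers number of donors given an aberrant expression profile.
#' @param outlier_gene_fraction fraction of genes perturbed in an outlier
#'   donor.
#' @param outlier_sdlog sd of the lognormal multiplicative perturbation
#'   applied to those genes (profiles are renormalised so library size is
#'   unchanged).
#'
#' @return a named list of class `village_config`.
#' @seealso [simulate_village()], [program_spec()]
#' @export
village_config <- function(n_donors = 40,
                           village_size = 20,
                           cell_types = c("astrocyte", "endothelial",
                                          "GABAergic", "glutamatergic",
                                          "microglia", "oligodendrocyte",
                                          "polydendrocyte"),
                           n_genes = 1000,
                           nuclei_per_donor_type = 40,
                           celltype_weights = c(1.4, 0.6, 1, 1.2,
                                                0.7, 1.1, 0.6),
                           mean_depth = 20000,
                           depth_sdlog = 0.3,
                           theta = 10,
                           doublet_rate = 0.05,
                           n_snps = 200,
                           maf_range = c(0.1, 0.5),
                           snps_per_nucleus = 100,
                           snp_error = 0.01,
                           age_range = c(22, 97),
                           program = program_spec(),
                           donor_effect_sdlog = 0.15,
                           n_outliers = 0,
                           outlier_gene_fraction = 0.3,
                           outlier_sdlog = 1.0) {
  stopifnot(n_donors >= 1, village_size >= 1, n_genes >= 1,
            length(cell_types) >= 1)
  if (doublet_rate < 0 || doublet_rate >= 1)
    stop("doublet_rate must lie in [0, 1)")
  if (village_size > n_donors)
    stop("village_size larger than donor count")
  cfg <- list(
    n_donors = n_donors, village_size = village_size,
    cell_types = cell_types, n_genes = n_genes,
    nuclei_per_donor_type = nuclei_per_donor_type,
    celltype_weights = celltype_weights,
    mean_depth = mean_depth, depth_sdlog = depth_sdlog, theta = theta,
    doublet_rate = doublet_rate, n_snps = n_snps, maf_range = maf_range,
    snps_per_nucleus = snps_per_nucleus, snp_error = snp_error,
    age_range = age_range, program = program,
    donor_effect_sdlog = donor_effect_sdlog,
    n_outliers = n_outliers,
    outlier_gene_fraction = outlier_gene_fraction,
    outlier_sdlog = outlier_sdlog)
  class(cfg) <- "village_config"
  cfg
}

#' Specification of planted latent gene-expression programs
#'
#' Each planted program (latent factor) assigns a per-donor score that is
#' linear in age and case status plus Gaussian noise, and a sparse gene
#' loading vector per cell type.  A program may load on similar genes in
#' several cell types (a genuinely multicellular program) or on distinct
#' genes per type; the default single program emulates a factor whose donor
#' expression declines with age and with case status.
#'
#' The default program is subtle: its contribution to a donor's overall
#' expression profile is small next to the idiosyncratic donor
#' heterogeneity (`donor_effect_sdlog`), mirroring the small share of
#' inter-individual variation real transcriptome-wide factors carry.
#' Factor-recovery benchmarks use a strongly planted program
#' (`loading_scale = 0.5, fraction_loaded = 0.2`) so that the factor is
#' resolvable from 180 donors.
#'
#' @param n_factors number of planted programs (>= 1).
#' @param age_slope score units per year (scalar or length `n_factors`).
#' @param case_shift score units added for case donors.
#' @param score_noise_sd sd of the Gaussian score noise (>= 0).
#' @param fraction_loaded fraction of genes carrying a nonzero loading in
#'   each cell type.
#' @param loading_scale sd of the Gaussian loading values on loaded genes.
#' @param shared_loadings if `TRUE` the same gene subset (and values) is
#'   loaded in every cell type; if `FALSE` each cell type gets its own
#'   random subset.
#'
#' @return list of class `program_spec`.
#' @export
program_spec <- function(n_factors = 1,
                         age_slope = -0.02,
                         case_shift = -0.5,
                         score_noise_sd = 0.25,
                         fraction_loaded = 0.1,
                         loading_scale = 0.15,
                         shared_loadings = TRUE) {
  if (n_factors < 1) stop("empty program spec")
  if (any(score_noise_sd < 0)) stop("score_noise_sd must be >= 0")
  spec <- list(n_factors = n_factors,
               age_slope = rep_len(age_slope, n_factors),
               case_shift = rep_len(case_shift, n_factors),
               score_noise_sd = rep_len(score_noise_sd, n_factors),
               fraction_loaded = fraction_loaded,
               loading_scale = loading_scale,
               shared_loadings = shared_loadings)
  class(spec) <- "program_spec"
  spec
}

#' Plant per-donor program scores
#'
#' Fills in the score of every planted program for every donor:
#' `score = age_slope * (age - mean(age)) + case_shift * I(case) +
#' N(0, score_noise_sd)`.
#'
#' @param donors data frame with columns `donor_id`, `age`, `status`
#'   (`"case"`/`"control"`).
#' @param spec a [program_spec()].
#' @param seed integer seed; scores are deterministic given the seed.
#' @return `donors` with one extra numeric column `score_<k>` per program.
#' @export
plant_programs <- function(donors, spec, seed = 1L) {
  if (!inherits(spec, "program_spec")) spec <- do.call(program_spec, spec)
  stopifnot(is.data.frame(donors),
            all(c("donor_id", "age", "status") %in% names(donors)))
  set.seed(seed)
  n <- nrow(donors)
  case <- as.numeric(donors$status == "case")
  age_c <- donors$age - mean(donors$age)
  for (k in seq_len(spec$n_factors)) {
    donors[[paste0("score_", k)]] <-
      spec$age_slope[k] * age_c + spec$case_shift[k] * case +
      stats::rnorm(n, 0, spec$score_noise_sd[k])
  }
  donors
}

score_matrix <- function(donors, n_factors) {
  as.matrix(donors[paste0("score_", seq_len(n_factors))])
}

## NB sampler that degrades gracefully to Poisson at theta = Inf
rnb <- function(n, mu, theta) {
  if (is.infinite(theta)) stats::rpois(n, mu) else stats::rnbinom(n, mu = mu, size = theta)
}

#' Simulate a pooled-donor ("village") snRNA-seq experiment
#'
#' Generates the full ground truth the downstream modules are tested
#' against: donors with ages, sex, case-control status, SNP genotypes and
#' planted program scores; sparse gene-loading vectors per cell type;
#' per-nucleus UMI counts drawn from a negative binomial whose log-mean is
#' `baseline(gene, cell type) + sum_k score_k(donor) * loading_k(gene, cell
#' type)`; droplet doublets that mix two donors' expected profiles 50/50 and
#' pool their SNP evidence; per-nucleus transcribed-SNP allele observations
#' with read error; and optional aberrant donors whose expected profile is
#' multiplicatively perturbed on a fraction of genes (renormalised, so
#' library size is preserved and only the expression *pattern* is unusual).
#'
#' @param config a [village_config()].
#' @param seed integer seed; the simulation is fully reproducible given
#'   `config` and `seed`.
#' @return an object of class `village_sim`: a list with elements
#'   `donors` (data frame incl. planted scores), `genotypes` (donor x SNP
#'   dosage matrix in 0/1/2), `maf`, `loadings` (gene x cell type x factor
#'   array), `baseline` (gene x cell type expected proportions),
#'   `nuclei` (data frame: barcode, donor, donor2, cell_type, village,
#'   is_doublet, depth), `counts` (sparse gene x nucleus dgCMatrix),
#'   `snp_obs` (data frame: barcode, snp_id, allele, count),
#'   `outlier_truth` (donor ids), and `config`.
#' @export
simulate_village <- function(config = village_config(), seed = 1L) {
  cfg <- config
  if (!inherits(cfg, "village_config")) cfg <- do.call(village_config, cfg)
  set.seed(seed)
  D <- cfg$n_donors; G <- cfg$n_genes
  types <- cfg$cell_types; Tn <- length(types)
  spec <- cfg$program; K <- spec$n_factors

  donors <- data.frame(
    donor_id = sprintf("D%03d", seq_len(D)),
    age = stats::runif(D, cfg$age_range[1], cfg$age_range[2]),
    sex = sample(c("F", "M"), D, replace = TRUE),
    status = rep_len(c("control", "case"), D)[sample.int(D)],
    village = rep(seq_len(ceiling(D / cfg$village_size)),
                  each = cfg$village_size)[seq_len(D)],
    stringsAsFactors = FALSE)

  ## genotype panel: independent common SNPs
  maf <- stats::runif(cfg$n_snps, cfg$maf_range[1], cfg$maf_range[2])
  genotypes <- matrix(stats::rbinom(D * cfg$n_snps, 2, rep(maf, each = D)),
                      nrow = D,
                      dimnames = list(donors$donor_id,
                                      sprintf("snp%04d", seq_len(cfg$n_snps))))

  donors <- plant_programs(donors, spec, seed = seed + 1L)
  scores <- score_matrix(donors, K)

  ## per-cell-type baseline abundances and sparse program loadings
  gene_ids <- sprintf("G%04d", seq_len(G))
  baseline <- matrix(stats::rgamma(G * Tn, shape = 0.7), G, Tn,
                     dimnames = list(gene_ids, types))
  baseline <- sweep(baseline, 2, colSums(baseline), "/")
  loadings <- array(0, dim = c(G, Tn, K),
                    dimnames = list(gene_ids, types, paste0("factor_", 1:K)))
  n_loaded <- max(1L, round(spec$fraction_loaded * G))
  for (k in seq_len(K)) {
    shared_idx <- sample.int(G, n_loaded)
    shared_val <- stats::rnorm(n_loaded, 0, spec$loading_scale)
    for (t in seq_len(Tn)) {
      if (spec$shared_loadings) {
        loadings[shared_idx, t, k] <- shared_val
      } else {
        idx <- sample.int(G, n_loaded)
        loadings[idx, t, k] <- stats::rnorm(n_loaded, 0, spec$loading_scale)
      }
    }
  }

  ## idiosyncratic donor expression heterogeneity: a mild lognormal
  ## multiplicative effect per donor x gene, shared across cell types
  ## (genetic background, post-mortem interval and the like)
  perturb <- matrix(exp(stats::rnorm(G * D, 0, cfg$donor_effect_sdlog)), G, D)
  ## aberrant donors: a much stronger perturbation on a gene subset
  outlier_ids <- character(0)
  if (cfg$n_outliers > 0) {
    out_idx <- sample.int(D, cfg$n_outliers)
    outlier_ids <- donors$donor_id[out_idx]
    n_pert <- max(1L, round(cfg$outlier_gene_fraction * G))
    for (d in out_idx) {
      gi <- sample.int(G, n_pert)
      perturb[gi, d] <- perturb[gi, d] *
        exp(stats::rnorm(n_pert, 0, cfg$outlier_sdlog))
    }
  }

  ## expected per-gene proportions for each (donor, type): baseline shifted
  ## on the log scale by planted program effects, perturbed for outliers,
  ## renormalised to a proportion vector
  profile <- function(d, t) {
    L_t <- matrix(loadings[, t, ], G, K)
    eta <- log(baseline[, t]) +
      as.vector(L_t %*% scores[d, ]) +
      log(perturb[, d])
    p <- exp(eta)
    p / sum(p)
  }
  prof <- array(0, dim = c(G, D, Tn))
  for (t in seq_len(Tn)) for (d in seq_len(D)) prof[, d, t] <- profile(d, t)

  ## nuclei: Poisson-varying singlet yield per donor x type (at least 1,
  ## so every donor contributes nuclei of every type), plus village doublets
  wts <- rep_len(cfg$celltype_weights, Tn)
  n_dt <- matrix(pmax(1L, stats::rpois(
    D * Tn, cfg$nuclei_per_donor_type * rep(wts, each = D))), D, Tn)
  n_sing <- sum(n_dt)
  sing <- data.frame(
    donor = rep(rep(seq_len(D), Tn), as.vector(n_dt)),
    cell_type = rep(rep(types, each = D), as.vector(n_dt)),
    stringsAsFactors = FALSE)
  is_dbl <- stats::runif(n_sing) < cfg$doublet_rate
  ## a doublet droplet captures a second nucleus from the same village
  donor2 <- rep(NA_integer_, n_sing)
  if (any(is_dbl)) {
    for (i in which(is_dbl)) {
      vill <- donors$village[sing$donor[i]]
      pool <- which(donors$village == vill)
      donor2[i] <- pool[sample.int(length(pool), 1)]
    }
  }
  nuclei <- data.frame(
    barcode = sprintf("BC%06d", seq_len(n_sing)),
    donor = donors$donor_id[sing$donor],
    donor2 = ifelse(is_dbl, donors$donor_id[donor2], NA_character_),
    cell_type = sing$cell_type,
    village = donors$village[sing$donor],
    is_doublet = is_dbl,
    stringsAsFactors = FALSE)
  nuclei$depth <- cfg$mean_depth *
    exp(stats::rnorm(n_sing, -cfg$depth_sdlog^2 / 2, cfg$depth_sdlog))

  ## counts: NB draws around depth x mixture profile
  ti <- match(nuclei$cell_type, types)
  di <- match(nuclei$donor, donors$donor_id)
  d2i <- match(nuclei$donor2, donors$donor_id)
  counts_list <- vector("list", n_sing)
  for (i in seq_len(n_sing)) {
    p <- prof[, di[i], ti[i]]
    dep <- nuclei$depth[i]
    if (is_dbl[i]) {  # two nuclei worth of content, 50/50 expected mixture
      p <- (p + prof[, d2i[i], ti[i]]) / 2
      dep <- 2 * dep
    }
    counts_list[[i]] <- rnb(G, dep * p, cfg$theta)
  }
  counts <- Matrix::Matrix(
    matrix(unlist(counts_list), nrow = G,
           dimnames = list(gene_ids, nuclei$barcode)),
    sparse = TRUE)

  ## transcribed-SNP allele observations (one read per sampled SNP)
  eps <- cfg$snp_error
  n_obs <- min(cfg$snps_per_nucleus, cfg$n_snps)
  obs_snp <- matrix(0L, n_obs, n_sing)
  obs_alt <- matrix(FALSE, n_obs, n_sing)
  for (i in seq_len(n_sing)) {
    s_idx <- sample.int(cfg$n_snps, n_obs)
    g <- genotypes[di[i], s_idx]
    if (is_dbl[i]) g <- (g + genotypes[d2i[i], s_idx]) / 2
    p_alt <- (1 - 2 * eps) * g / 2 + eps
    obs_snp[, i] <- s_idx
    obs_alt[, i] <- stats::runif(n_obs) < p_alt
  }
  snp_obs <- data.frame(
    barcode = rep(nuclei$barcode, each = n_obs),
    snp_id = colnames(genotypes)[as.vector(obs_snp)],
    allele = ifelse(as.vector(obs_alt), "alt", "ref"),
    count = 1L,
    stringsAsFactors = FALSE)

  structure(list(
    donors = donors, genotypes = genotypes, maf = maf,
    loadings = loadings, baseline = baseline,
    nuclei = nuclei, counts = counts, snp_obs = snp_obs,
    outlier_truth = outlier_ids, program_scores = scores,
    metagene_truth = NULL, config = cfg, seed = seed),
    class = "village_sim")
}

#' @export
print.village_sim <- function(x, ...) {
  cat("Synthetic village simulation\n")
  cat(sprintf("  %d donors in %d village(s); %d cell types; %d genes\n",
              nrow(x$donors), length(unique(x$donors$village)),
              length(x$config$cell_types), nrow(x$counts)))
  cat(sprintf("  %d nuclei (%d doublets); %d SNPs on panel\n",
              nrow(x$nuclei), sum(x$nuclei$is_doublet), ncol(x$genotypes)))
  if (length(x$outlier_truth))
    cat("  planted outlier donors:", paste(x$outlier_truth, collapse = ", "), "\n")
  invisible(x)
}

#' Simulate UMI read-to-gene hit records with planted paralog families
#'
#' Emulates the read-level evidence from which high-homology gene families
#' ("metagenes", e.g. C4A/C4B) are discovered.  UMIs from genes inside a
#' planted family produce low-quality multi-hits to every family member,
#' except for a small fraction (`unique_rate`) that retain one
#' uniquely-mapping high-quality read; UMIs from all other genes map
#' uniquely.
#'
#' @param n_cells number of cells.
#' @param families list of character vectors (each length >= 2) of paralog
#'   gene ids to plant.
#' @param n_plain_genes number of additional unambiguous genes.
#' @param mean_umis expected UMIs per gene per cell (Poisson).
#' @param unique_rate fraction of family-gene UMIs that map uniquely to
#'   their true member gene.
#' @param seed integer seed.
#' @return list with `records` (data frame: cell_barcode, umi, gene_id,
#'   mapq_class in `"unique"`/`"multi"`), `truth` (list: families,
#'   per-cell true family totals `family_totals` suitable as a collapsed
#'   single-copy oracle, and per-gene true totals).
#' @export
simulate_umi_records <- function(n_cells = 50,
                                 families = list(c("C4A", "C4B"),
                                                 c("SERF1A", "SERF1B", "SERF2")),
                                 n_plain_genes = 10,
                                 mean_umis = 3,
                                 unique_rate = 0.005,
                                 seed = 1L) {
  set.seed(seed)
  stopifnot(all(lengths(families) >= 2))
  plain <- sprintf("PG%03d", seq_len(n_plain_genes))
  fam_genes <- unlist(families)
  if (anyDuplicated(c(fam_genes, plain))) stop("gene ids must be distinct")
  cells <- sprintf("CELL%04d", seq_len(n_cells))
  rows <- list(); umi_counter <- 0L
  fam_totals <- matrix(0L, length(families), n_cells,
                       dimnames = list(vapply(families, paste, "", collapse = "+"),
                                       cells))
  gene_totals <- matrix(0L, length(fam_genes) + n_plain_genes, n_cells,
                        dimnames = list(c(fam_genes, plain), cells))
  for (ci in seq_len(n_cells)) {
    for (fi in seq_along(families)) {
      fam <- families[[fi]]
      for (g in fam) {
        n_umi <- stats::rpois(1, mean_umis)
        gene_totals[g, ci] <- gene_totals[g, ci] + n_umi
        fam_totals[fi, ci] <- fam_totals[fi, ci] + n_umi
        if (n_umi == 0) next
        uniq <- stats::runif(n_umi) < unique_rate
        for (u in seq_len(n_umi)) {
          umi_counter <- umi_counter + 1L
          id <- sprintf("UMI%07d", umi_counter)
          if (uniq[u]) {
            rows[[length(rows) + 1L]] <- data.frame(
              cell_barcode = cells[ci], umi = id, gene_id = g,
              mapq_class = "unique", stringsAsFactors = FALSE)
          }
          # low-quality hits to every family member
          rows[[length(rows) + 1L]] <- data.frame(
            cell_barcode = cells[ci], umi = id, gene_id = fam,
            mapq_class = "multi", stringsAsFactors = FALSE)
        }
      }
    }
    for (g in plain) {
      n_umi <- stats::rpois(1, mean_umis)
      gene_totals[g, ci] <- gene_totals[g, ci] + n_umi
      if (n_umi == 0) next
      ids <- sprintf("UMI%07d", umi_counter + seq_len(n_umi))
      umi_counter <- umi_counter + n_umi
      rows[[length(rows) + 1L]] <- data.frame(
        cell_barcode = cells[ci], umi = ids, gene_id = g,
        mapq_class = "unique", stringsAsFactors = FALSE)
    }
  }
  records <- do.call(rbind, rows)
  rownames(records) <- NULL
  list(records = records,
       truth = list(families = families,
                    family_totals = fam_totals,
                    gene_totals = gene_totals))
}
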