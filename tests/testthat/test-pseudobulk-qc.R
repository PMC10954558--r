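test_that("Pearson residuals behave at the closed-form limits", {
  # identical counts across equal-depth cells: mean model exact, residual 0
  counts <- matrix(5L, nrow = 3, ncol = 8,
                   dimnames = list(paste0("g", 1:3), paste0("c", 1:8)))
  r <- pearson_residuals(counts, theta = Inf)
  expect_true(all(abs(r) < 1e-12))

  # theta -> Inf reduces to the Poisson residual (x - mu)/sqrt(mu)
  set.seed(3)
  x <- matrix(rpois(200, 10), 10, 20)
  depth <- colSums(x); p_g <- rowSums(x) / sum(x)
  mu <- outer(p_g, depth)
  r2 <- pearson_residuals(x, theta = Inf, clip = Inf)
  expect_equal(unname(as.matrix(r2)), (x - mu) / sqrt(mu),
               tolerance = 1e-12, ignore_attr = TRUE)

  # all-zero gene: residual row all zeros, no division error
  x0 <- rbind(x, 0)
  expect_true(all(pearson_residuals(x0, theta = Inf)[11, ] == 0))
})

test_that("residual variance is near 1 for NB counts at estimated theta", {
  set.seed(11)
  n_genes <- 200; n_cells <- 400; theta_true <- 5
  mu_g <- exp(rnorm(n_genes, log(8), 1))
  x <- matrix(rnbinom(n_genes * n_cells, mu = mu_g, size = theta_true),
              n_genes, n_cells)
  r <- pearson_residuals(x)
  v <- apply(r, 1, var)
  expect_gte(mean(v >= 0.5 & v <= 2), 0.95)
})

test_that("pseudobulk aggregation is additive and mode-tagged", {
  set.seed(2)
  x <- matrix(rpois(60, 5), 6, 10,
              dimnames = list(paste0("g", 1:6), paste0("c", 1:10)))
  donor <- rep(c("d1", "d2"), each = 5)
  type <- rep("astro", 10)
  pb <- aggregate_pseudobulk(x, donor, type, "raw_sum")
  expect_length(pb, 1)
  m <- pb[["astro"]]$matrix
  # splitting into donors and summing back equals the whole-matrix sum
  expect_equal(rowSums(m), rowSums(x))
  expect_equal(m[, "d1"], rowSums(x[, 1:5]))
  # one donor, one cell: pseudobulk equals that cell
  pb1 <- aggregate_pseudobulk(x[, 1, drop = FALSE], "d9", "astro", "raw_sum")
  expect_equal(pb1[["astro"]]$matrix[, "d9"], x[, 1])
  expect_error(aggregate_pseudobulk(x, c(donor[-1], NA), type, "raw_sum"),
               "unmapped")
})

test_that("modified z-scores follow the 0.6745 MAD formula", {
  x <- c(0.90, 0.91, 0.92, 0.93, 0.94, 0.50)
  m <- modified_z(x)
  med <- median(x)                      # 0.915
  mad0 <- median(abs(x - med))          # 0.015
  expect_equal(m[6], 0.6745 * (0.50 - med) / mad0)
  expect_equal(m[6], -18.66116667, tolerance = 1e-8)
  # a score at the median maps to 0; at median + MAD maps to 0.6745
  y <- c(1, 2, 3, 4, 5)      # median 3, unscaled MAD 1
  my <- modified_z(y)
  expect_equal(my[3], 0)
  expect_equal(my[4], 0.6745)
  expect_error(modified_z(rep(1, 5)), "degenerate")
})

test_that("conformity scores mark a shuffled donor lowest", {
  set.seed(6)
  base <- exp(rnorm(150, 3, 1))
  m <- vapply(1:8, function(i) rpois(150, base), numeric(150))
  dimnames(m) <- list(paste0("g", 1:150), paste0("d", 1:8))
  m[, 8] <- sample(m[, 8])    # destroy donor 8's gene correspondence
  pb <- list(structure(list(cell_type = "astro", matrix = m,
                            mode = "raw_sum", donor_umis = colSums(m)),
                       class = "celltype_pseudobulk"))
  rep <- conformity_scores(pb)
  expect_identical(names(which.min(rep$scores)), "d8")
  expect_true(all(rep$scores >= -1 & rep$scores <= 1))
  # invariant to donor column order
  pb2 <- pb; pb2[[1]]$matrix <- m[, 8:1]
  rep2 <- conformity_scores(pb2)
  expect_equal(rep$scores[names(rep2$scores)], rep2$scores)
  expect_error(conformity_scores(list(structure(list(cell_type = "a",
    matrix = m[, 1:2], mode = "raw_sum"), class = "celltype_pseudobulk"))),
    "fewer than 3 donors")
})

test_that("the gene filter keeps exactly genes with >= 10 per 100,000", {
  # columns already sum to 100,000, so scaled values equal raw values:
  # g2 peaks at 9 per 1e5 (dropped), g4 at exactly 10 (kept)
  m <- cbind(d1 = c(12, 9, 99879, 100), d2 = c(15, 8, 99967, 10),
             d3 = c(11, 7, 99973, 9))
  rownames(m) <- paste0("g", 1:4)
  stopifnot(all(colSums(m) == 1e5))
  pb <- list(structure(list(cell_type = "t", matrix = m, mode = "raw_sum",
                            donor_umis = colSums(m)),
                       class = "celltype_pseudobulk"))
  cr <- conformity_scores(pb, min_per_1e5 = 10)
  expect_equal(cr$n_features, 3)   # g2 alone fails the threshold
})

test_that("flag_outlier_donors applies the three thresholds correctly", {
  mk_report <- function(m) {
    structure(list(scores = NULL, median = 0, mad = 1, modified_z = m),
              class = "conformity_report")
  }
  donors <- paste0("d", 1:4)
  expr <- mk_report(setNames(c(0, -5.1, 0, 0), donors))
  prop <- mk_report(setNames(c(0, 0, -10, 0), donors))
  umis <- matrix(5000, 4, 2, dimnames = list(donors, c("t1", "t2")))
  fl <- flag_outlier_donors(expr, prop, umis)
  # |M| = 5.1 on expression excluded; |M| = 10 on proportions is not (> 15)
  expect_identical(fl$donor, "d2")
  expect_identical(fl$criterion, "expression_conformity")
  # low-UMI rule at the 1,000 threshold
  umis["d4", "t2"] <- 999
  fl2 <- flag_outlier_donors(expr, prop, umis)
  expect_setequal(fl2$donor, c("d2", "d4"))
  expect_true("low_umis" %in% fl2$criterion)
  # homogeneous donors: nothing flagged
  none <- flag_outlier_donors(mk_report(setNames(rep(0, 4), donors)),
                              mk_report(setNames(rep(0, 4), donors)),
                              matrix(5000, 4, 2,
                                     dimnames = list(donors, c("t1", "t2"))))
  expect_equal(nrow(none), 0)
})

test_that("planted aberrant donors are flagged without false positives", {
  hits <- 0; planted <- 0; fps <- 0
  for (seed in 1:3) {
    sim <- simulate_village(scenario_outlier_qc(), seed = seed)
    qc <- run_donor_qc(sim$counts, sim$nuclei$donor, sim$nuclei$cell_type)
    flagged <- unique(qc$flags$donor)
    hits <- hits + sum(flagged %in% sim$outlier_truth)
    fps <- fps + sum(!flagged %in% sim$outlier_truth)
    planted <- planted + length(sim$outlier_truth)
  }
  expect_equal(fps, 0)
  expect_gte(hits / planted, 0.95)
})
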