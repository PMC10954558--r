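test_that("cell and gene filters apply their thresholds at the boundary", {
  set.seed(1)
  counts <- matrix(1L, nrow = 250, ncol = 5,
                   dimnames = list(paste0("g", 1:250), paste0("c", 1:5)))
  # cell 1: 199 detected genes (fails); cell 2: 200 genes but 199 UMIs
  counts[200:250, 1] <- 0L
  counts[201:250, 2] <- 0L; counts[1, 2] <- 0L
  f <- filter_cells_genes(counts, min_genes = 200, min_umis = 200,
                          min_cells = 2)
  expect_false("c1" %in% colnames(f))
  expect_false("c2" %in% colnames(f))
  expect_true(all(c("c3", "c4", "c5") %in% colnames(f)))
  # a gene detected in exactly min_cells surviving cells is retained
  counts2 <- matrix(2L, 300, 12,
                    dimnames = list(paste0("g", 1:300), paste0("c", 1:12)))
  counts2["g300", ] <- 0L; counts2["g300", 1:10] <- 1L
  f2 <- filter_cells_genes(counts2, min_cells = 10)
  expect_true("g300" %in% rownames(f2))
  # all-pass input is returned unchanged
  expect_equal(dim(filter_cells_genes(counts2, min_genes = 1,
                                      min_umis = 1, min_cells = 1)),
               dim(counts2))
  expect_error(filter_cells_genes(counts2 * 0L), "no cells survive")
})

test_that("an exactly factorizable matrix is reconstructed at the true k", {
  fx <- exact_nmf_counts(n_cells = 60, n_genes = 39, k = 3, seed = 2)
  fit <- cnmf_consensus(fx$counts, k_values = 2:4, restarts = 8,
                        seed = 6, var_scale = FALSE)
  sel <- fit$selection
  expect_equal(fit$k, 3)
  expect_lt(sel$error[sel$k == 3], 1e-6)
  expect_gt(sel$stability[sel$k == 3], 0.95)
})

test_that("planted spectra are recovered up to permutation", {
  fx <- exact_nmf_counts(n_cells = 80, n_genes = 45, k = 3, seed = 5)
  # moderate Poisson noise around the planted structure
  set.seed(5)
  noisy <- matrix(rpois(length(fx$counts), as.matrix(fx$counts) * 20),
                  nrow(fx$counts), dimnames = dimnames(fx$counts))
  fit <- cnmf_consensus(noisy, k_values = 3, restarts = 8, seed = 9,
                        var_scale = FALSE)
  H_true <- fx$H / sqrt(rowSums(fx$H^2))
  cosine <- fit$spectra %*% t(H_true)   # consensus spectra are L2-normalised
  # optimal one-to-one assignment via greedy on 3x3 is exact enough here
  best <- apply(cosine, 1, max)
  expect_true(all(best >= 0.95))
  expect_equal(length(unique(apply(cosine, 1, which.max))), 3)
})

test_that("row-shuffled null data destroys stability", {
  fx <- exact_nmf_counts(n_cells = 60, n_genes = 39, k = 3, seed = 7)
  set.seed(3)
  noisy <- matrix(rpois(length(fx$counts), as.matrix(fx$counts) * 20),
                  nrow(fx$counts), dimnames = dimnames(fx$counts))
  shuffled <- t(apply(noisy, 1, sample))
  dimnames(shuffled) <- dimnames(noisy)
  fit_real <- cnmf_consensus(noisy, k_values = 3, restarts = 6, seed = 2,
                             var_scale = FALSE)
  fit_null <- cnmf_consensus(shuffled, k_values = 3, restarts = 6, seed = 2,
                             var_scale = FALSE)
  expect_gt(fit_real$selection$stability, fit_null$selection$stability)
})

test_that("usage normalisation is idempotent and row-stochastic", {
  expect_equal(usage_normalize(matrix(c(2, 2), 1)), matrix(c(0.5, 0.5), 1),
               ignore_attr = TRUE)
  set.seed(4)
  u <- matrix(rexp(50), 10, 5)
  n1 <- usage_normalize(u)
  expect_equal(usage_normalize(n1), n1, ignore_attr = TRUE)
  expect_true(all(abs(rowSums(n1) - 1) < 1e-12))
  # zero rows flagged, left zero
  u0 <- rbind(u, 0)
  rownames(u0) <- paste0("c", 1:11)
  n0 <- usage_normalize(u0)
  expect_identical(attr(n0, "zero_rows"), "c11")
  expect_true(all(n0[11, ] == 0))
  expect_error(usage_normalize(-u), "non-negative")
})

test_that("donor program scores average usages and obey orientation", {
  u <- rbind(c(0.2, 0.8), c(0.4, 0.6))
  colnames(u) <- c("p1", "p2")
  m <- donor_program_scores(u, c("d1", "d1"))
  expect_equal(unname(m["d1", ]), c(0.3, 0.7))
  m2 <- donor_program_scores(u, c("d1", "d1"), orientation = c(1, -1))
  expect_equal(unname(m2["d1", ]), c(0.3, -0.7))
  expect_error(donor_program_scores(u, c("d1", NA)), "mapped")
})

test_that("donor means commute with subsampling in expectation", {
  set.seed(31)
  n_cells <- 400
  u <- usage_normalize(matrix(rexp(n_cells * 3), n_cells, 3))
  donors <- sample(paste0("d", 1:4), n_cells, TRUE)
  full <- donor_program_scores(u, donors)
  sub_means <- replicate(60, {
    idx <- sample(n_cells, n_cells / 2)
    donor_program_scores(u[idx, , drop = FALSE], donors[idx])[rownames(full), ]
  })
  expect_equal(apply(sub_means, 1:2, mean), full, tolerance = 0.02)
})

test_that("an age-declining program shows up in donor scores", {
  # planted program: usage of program 1 declines with donor age
  set.seed(55)
  donors <- sprintf("d%02d", 1:30)
  ages <- seq(25, 95, length.out = 30)
  cells_per <- 25
  cell_donor <- rep(donors, each = cells_per)
  cell_age <- rep(ages, each = cells_per)
  w1 <- pmax(0.05, 0.9 - 0.008 * cell_age + rnorm(length(cell_age), 0, 0.1))
  u <- cbind(w1, 1 - w1)
  colnames(u) <- c("p1", "p2")
  scores <- donor_program_scores(usage_normalize(u), cell_donor)
  res <- rank_correlation(scores[donors, "p1"], ages)
  expect_lt(res$estimate, 0)
  expect_lt(res$p_value, 0.05)
})
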