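test_that("plant_programs implements the linear score model", {
  donors <- toy_donors(10)
  # degenerate spec: everyone shares the baseline score
  spec <- program_spec(age_slope = 0, case_shift = 0, score_noise_sd = 0)
  d <- plant_programs(donors, spec, seed = 1)
  expect_equal(d$score_1, rep(0, 10))

  # two donors aged 30 and 80, slope -0.02/yr, no noise: difference -1.0
  d2 <- plant_programs(toy_donors(2, ages = c(30, 80)),
                       program_spec(age_slope = -0.02, case_shift = 0,
                                    score_noise_sd = 0), seed = 1)
  expect_equal(d2$score_1[2] - d2$score_1[1], -1.0)

  expect_error(program_spec(n_factors = 0), "empty program spec")
})

test_that("OLS on planted scores recovers the generating age slope", {
  set.seed(10)
  donors <- toy_donors(100, ages = runif(100, 25, 95))
  spec <- program_spec(age_slope = -0.02, case_shift = 0,
                       score_noise_sd = 0.3)
  d <- plant_programs(donors, spec, seed = 99)
  slope <- coef(lm(score_1 ~ age, d))["age"]
  expect_lt(abs(slope - (-0.02)), 0.005)
})

test_that("simulation structure honours its contracts", {
  sim <- simulate_village(tiny_config(doublet_rate = 0), seed = 3)
  expect_true(all(is.na(sim$nuclei$donor2)))     # no doublets at rate 0
  expect_false(any(sim$nuclei$is_doublet))
  expect_true(all(sim$counts@x >= 0))
  expect_true(all(sim$genotypes %in% 0:2))
  # every donor contributes nuclei of every cell type
  tab <- table(sim$nuclei$donor, sim$nuclei$cell_type)
  expect_true(all(tab > 0))
  expect_error(village_config(doublet_rate = 1), "doublet_rate")
  expect_error(village_config(n_donors = 5, village_size = 20),
               "village_size")
})

test_that("identical config and seed reproduce the simulation exactly", {
  a <- simulate_village(tiny_config(), seed = 7)
  b <- simulate_village(tiny_config(), seed = 7)
  expect_identical(a$counts, b$counts)
  expect_identical(a$snp_obs, b$snp_obs)
  expect_identical(a$donors, b$donors)
})

test_that("Poisson limit with no loadings matches the baseline means", {
  cfg <- tiny_config(theta = Inf, doublet_rate = 0, depth_sdlog = 0,
                     donor_effect_sdlog = 0,
                     nuclei_per_donor_type = 120, mean_depth = 300,
                     program = program_spec(age_slope = 0, case_shift = 0,
                                            score_noise_sd = 0,
                                            loading_scale = 0))
  sim <- simulate_village(cfg, seed = 5)
  for (ct in cfg$cell_types) {
    sel <- sim$nuclei$cell_type == ct
    emp <- Matrix::rowMeans(sim$counts[, sel])
    expected <- 300 * sim$baseline[, ct]
    # Monte-Carlo tolerance: 6 standard errors of the Poisson mean
    se <- sqrt(expected / sum(sel))
    expect_true(all(abs(emp - expected) < 6 * pmax(se, 1e-3)))
  }
})

test_that("about 95% of simulated village doublets are cross-donor", {
  cfg <- village_config(n_donors = 20, village_size = 20,
                        cell_types = "nucleus", celltype_weights = 1,
                        n_genes = 2, nuclei_per_donor_type = 1000,
                        mean_depth = 10, n_snps = 2, snps_per_nucleus = 1,
                        doublet_rate = 0.5, theta = Inf)
  sim <- simulate_village(cfg, seed = 9)
  dbl <- sim$nuclei[sim$nuclei$is_doublet, ]
  expect_gt(nrow(dbl), 5000)
  frac <- mean(dbl$donor != dbl$donor2)
  se <- sqrt(0.95 * 0.05 / nrow(dbl))
  expect_lt(abs(frac - 0.95), 3 * se)
})

test_that("centered noiseless score matrix has the planted rank", {
  # noiseless scores are linear in (age, case): two independent factor
  # patterns give exactly rank 2, and a third pattern cannot add rank
  spec <- program_spec(n_factors = 2, age_slope = c(-0.02, 0.01),
                       case_shift = c(-0.5, 0.3), score_noise_sd = 0)
  set.seed(2)
  d <- plant_programs(toy_donors(30, ages = runif(30, 22, 97)), spec, seed = 2)
  Sc <- scale(as.matrix(d[paste0("score_", 1:2)]), scale = FALSE)
  expect_equal(qr(Sc)$rank, 2)
  spec3 <- program_spec(n_factors = 3, age_slope = c(-0.02, 0.01, 0),
                        case_shift = c(-0.5, 0, 0.3), score_noise_sd = 0)
  d3 <- plant_programs(toy_donors(30, ages = runif(30, 22, 97)), spec3,
                       seed = 2)
  Sc3 <- scale(as.matrix(d3[paste0("score_", 1:3)]), scale = FALSE)
  expect_equal(qr(Sc3)$rank, 2)
  # with noise the full factor dimension is realised
  spec_n <- program_spec(n_factors = 3, age_slope = c(-0.02, 0.01, 0),
                         case_shift = c(-0.5, 0, 0.3), score_noise_sd = 0.1)
  dn <- plant_programs(toy_donors(30, ages = runif(30, 22, 97)), spec_n,
                       seed = 3)
  expect_equal(qr(scale(as.matrix(dn[paste0("score_", 1:3)]),
                        scale = FALSE))$rank, 3)
})

test_that("village round-trips losslessly through write and read", {
  sim <- simulate_village(tiny_config(n_outliers = 1), seed = 21)
  dir <- withr::local_tempdir()
  write_village(sim, dir, overwrite = TRUE)
  back <- read_village(dir)
  expect_equal(as.matrix(back$counts[rownames(sim$counts), colnames(sim$counts)]),
               as.matrix(sim$counts))
  expect_equal(sum(back$counts), sum(sim$counts))  # conservation
  expect_equal(back$genotypes[rownames(sim$genotypes), colnames(sim$genotypes)],
               sim$genotypes, tolerance = 0, ignore_attr = FALSE)
  expect_identical(sort(unlist(back$truth$outlier_donors)),
                   sort(sim$outlier_truth))
  # features file: one row per cell-type-agnostic gene id
  feats <- readLines(file.path(dir, "village01_features.tsv"))
  expect_identical(feats, rownames(sim$counts))
  # refuse to clobber a non-empty directory
  expect_error(write_village(sim, dir), "overwrite")
})
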