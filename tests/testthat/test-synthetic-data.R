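# generator self-checks: every generator is a pure function of (params, seed)
# and its realized moments match the configured parameters

test_that("genotype panel reproduces configured LD and frequencies", {
  # independence when rho = 0
  p0 <- simulate_genotype_panel(2000, 40, block_size = 4, rho = 0, seed = 1)
  cc <- cor(p0$dosage)
  expect_lt(mean(abs(cc[upper.tri(cc)])), 0.05)

  # strong LD: adjacent pairs in 2-variant blocks reach r2 > 0.5 on average
  p9 <- simulate_genotype_panel(2000, 60, block_size = 2,
                                maf_range = c(0.2, 0.5), rho = 0.9, seed = 2)
  r2 <- sapply(seq(1, 59, 2), function(j)
    cor(p9$dosage[, j], p9$dosage[, j + 1])^2)
  expect_gt(mean(r2), 0.5)

  # allele frequency calibration
  pm <- simulate_genotype_panel(2000, 20, block_size = 4,
                                maf_range = c(0.3, 0.3), rho = 0.5, seed = 3)
  expect_true(all(abs(colMeans(pm$dosage) / 2 - 0.3) < 0.03))
  af <- colMeans(p9$dosage) / 2
  expect_true(all(af > 0 & af < 1))

  # adjacent dosage correlation matches the configured autoregressive rho
  pr <- simulate_genotype_panel(4000, 50, block_size = 5,
                                maf_range = c(0.25, 0.35), rho = 0.6, seed = 4)
  adj <- sapply(which(diff(pr$block) == 0), function(j)
    cor(pr$dosage[, j], pr$dosage[, j + 1]))
  expect_equal(mean(adj), 0.6, tolerance = 0.05)

  # determinism and argument validation
  expect_identical(simulate_genotype_panel(50, 10, seed = 9)$dosage,
                   simulate_genotype_panel(50, 10, seed = 9)$dosage)
  expect_error(simulate_genotype_panel(0, 10), "positive")
  expect_error(simulate_genotype_panel(10, 5, maf_range = c(0.2, 0.7)),
               "maf_range")
  expect_error(simulate_genotype_panel(10, 5, rho = 1), "rho")
})

test_that("cohort generator calibrates heritability and case fraction", {
  sc <- simulation_scenario(n_exposure = 20000, n_outcome = 4000, m = 100,
                            j_causal = 30, h2x = 0.05, seed = 7)
  px <- simulate_genotype_panel(20000, 100, seed = 11)
  py <- simulate_genotype_panel(4000, 100, seed = 12)
  py$maf <- px$maf; py$a1 <- px$a1; py$a2 <- px$a2
  co <- simulate_mr_cohorts(px, py, sc)
  g <- as.vector(px$dosage[, co$truth$causal] %*% co$truth$beta)
  expect_equal(var(g) / var(co$exposure), 0.05, tolerance = 0.01)
  expect_equal(mean(co$outcome), 0.34, tolerance = 0.02)
  # ground truth carried alongside, disjoint samples
  expect_length(co$truth$causal, 30)
  expect_identical(co$truth$theta, sc$theta)
  expect_error(simulate_mr_cohorts(px, px, sc), "sample sizes")
  expect_error(simulation_scenario(case_fraction = 1.2), "fraction")
  expect_error(simulation_scenario(j_causal = 200, m = 100), "j_causal")
})

test_that("null cohorts give nominal IVW type-I error downstream", {
  reps <- 500
  rej <- 0
  for (r in seq_len(reps)) {
    sc <- simulation_scenario(n_exposure = 3000, n_outcome = 3000, m = 30,
                              j_causal = 20, theta = 0, h2x = 0.2,
                              case_fraction = 0.34, seed = r)
    px <- simulate_genotype_panel(3000, 30, block_size = 1, rho = 0,
                                  seed = 2 * r + 1)
    py <- simulate_genotype_panel(3000, 30, block_size = 1, rho = 0,
                                  seed = 2 * r + 2)
    py$maf <- px$maf; py$a1 <- px$a1; py$a2 <- px$a2
    co <- simulate_mr_cohorts(px, py, sc)
    ex <- run_gwas(px, co$exposure)
    ou <- run_gwas(py, co$outcome)  # OLS on 0/1 is a valid null scan
    h <- harmonize_pair(ex[ex$SNP %in% co$truth$causal, ], ou)
    rej <- rej + (mr_ivw(h)$p < 0.05)
  }
  expect_gte(rej / reps, 0.02)
  expect_lte(rej / reps, 0.10)
})

test_that("summary-level generator is exact when noiseless and consistent otherwise", {
  s0 <- simulate_summary_mr(20, theta = 0.7, se_x = 0, se_y = 0, seed = 1)
  expect_equal(s0$beta_y / s0$beta_x, rep(0.7, 20), tolerance = 1e-9)

  s <- simulate_summary_mr(150, theta = 0.3, seed = 5)
  iv <- mr_ivw(s)
  expect_lt(abs(iv$theta - 0.3), 3 * iv$se)

  # directional pleiotropy surfaces in the Egger intercept
  sd <- simulate_summary_mr(150, theta = 0.3, prop_invalid = 1,
                            alpha_mean = 0.05, alpha_sd = 0.01,
                            balanced = FALSE, seed = 6)
  e <- mr_egger(sd)
  expect_lt(abs(e$intercept - 0.05), 3 * e$intercept_se)
  expect_identical(simulate_summary_mr(10, 0.1, seed = 3)$beta_y,
                   simulate_summary_mr(10, 0.1, seed = 3)$beta_y)
})

test_that("blow generator and QC round-trip configured exclusion fractions", {
  b <- simulate_blows(5000, one_blow_frac = 0.04, discordant_frac = 0.06,
                      seed = 1)
  qc <- qc_spirometry(b)
  expect_lt(abs(mean(!qc$pass_fev1) - 0.10), 0.02)
  # clean series with >= 2 blows all pass; all-one-blow keeps none
  b0 <- simulate_blows(300, one_blow_frac = 0, discordant_frac = 0, seed = 2)
  expect_true(all(qc_spirometry(b0)$pass_fev1))
  b1 <- simulate_blows(100, one_blow_frac = 1, discordant_frac = 0, seed = 3)
  expect_false(any(qc_spirometry(b1)$pass_fev1))
})

test_that("polygenic pair generator matches its null and LD-inflation model", {
  pg0 <- simulate_polygenic_pair(20000, 20000, 2000, 0, 0, 0, seed = 4)
  expect_equal(mean(pg0$z1^2), 1, tolerance = 0.08)

  # rg = 0, no overlap: cross-product regression slope near 0
  pg <- simulate_polygenic_pair(20000, 20000, 4000, 0.2, 0.2, 0, seed = 5)
  slope <- coef(lm(I(pg$z1 * pg$z2) ~ pg$ld))[2]
  rho_g <- slope * 4000 / 20000
  expect_lt(abs(rho_g), 0.05)

  # chi2 grows with the LD score as configured
  pg2 <- simulate_polygenic_pair(20000, 20000, 5000, 0.3, 0.3, 0.5, seed = 6)
  fit <- coef(lm(I(pg2$z1^2) ~ pg2$ld))
  expect_lt(abs(unname(fit[2]) * 5000 / 20000 - 0.3), 0.06)
  expect_identical(simulate_polygenic_pair(100, 100, 50, .1, .1, .5, seed = 2),
                   simulate_polygenic_pair(100, 100, 50, .1, .1, .5, seed = 2))
  expect_error(simulate_polygenic_pair(100, 100, 50, .1, .1, 1.5), "rg")
})
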