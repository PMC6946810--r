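# stage 1: spirometry QC, phenotype derivation, variant QC, association
# scan, clumping, two-stage selection, instrument strength

test_that("blow reproducibility rule follows the 0.15 L tolerance", {
  expect_false(qc_blow_series(2.0)$pass)                 # single blow
  q <- qc_blow_series(c(2.0, 2.1, 2.2))
  expect_true(q$pass)                                    # 2.1 within 0.15
  expect_equal(q$best, 2.2)
  expect_equal(q$n_retained, 1L)
  expect_false(qc_blow_series(c(1.5, 1.8))$pass)         # 0.3 > 0.15
  expect_error(qc_blow_series(numeric(0)), "empty")
  expect_error(qc_blow_series(c(2, -1)), "positive")
})

test_that("phenotype derivation z-standardizes and flags obstruction", {
  ph <- derive_phenotypes(c(2, 3.5, 2.8), c(4, 4.1, 3.6))
  expect_equal(ph$ratio[1], 0.5)
  expect_true(ph$copd[1])                                # 0.5 < 0.70
  expect_false(ph$copd[2])                               # 3.5/4.1 = 0.85
  expect_equal(mean(ph$fev1_z), 0, tolerance = 1e-10)
  expect_equal(sd(ph$fev1_z), 1, tolerance = 1e-10)
  expect_error(derive_phenotypes(c(2, 2), c(3, 3)), "zero variance")
  expect_error(derive_phenotypes(c(2, 3), c(-1, 3)), "positive")
  expect_error(derive_phenotypes(c(4, 3), c(3.5, 4)), "ratio")
})

test_that("HWE exact test matches the full-enumeration oracle", {
  expect_equal(hwe_exact_p(25, 50, 25), 1)               # exact proportions
  expect_lt(hwe_exact_p(50, 0, 50), 1e-5)                # no heterozygotes
  # oracle equivalence over a grid of genotype counts up to n = 200
  cases <- expand.grid(aa = c(0, 3, 10, 40, 80), ab = c(0, 5, 25, 60, 100),
                       bb = c(0, 2, 12, 35))
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    if (sum(cs) == 0) next
    expect_equal(hwe_exact_p(cs$aa, cs$ab, cs$bb),
                 hwe_oracle(cs$aa, cs$ab, cs$bb), tolerance = 1e-9,
                 info = paste(cs, collapse = "/"))
  }
})

test_that("variant QC removes HWE, call-rate and MAF failures", {
  p <- simulate_genotype_panel(200, 4, block_size = 1, rho = 0, seed = 1)
  # plant failures: col 1 no hets, col 2 rare, col 3 poorly called
  p$dosage[, 1] <- rep(c(0, 2), each = 100)
  p$dosage[, 2] <- c(rep(1, 1), rep(0, 199))             # MAF 0.0025
  p$dosage[, 3] <- p$dosage[, 3] + 0.25                  # off hard-call grid
  qc <- variant_qc(p)
  expect_identical(unname(qc$table$fail[1]), "hwe")
  expect_identical(unname(qc$table$fail[2]), "maf")
  expect_identical(unname(qc$table$fail[3]), "call_rate")
  expect_identical(qc$keep, p$snp[4])
  expect_identical(qc$info_filter, "skipped")
})

test_that("association scan recovers planted effects with calibrated nulls", {
  # noiseless single-variant regression
  p <- simulate_genotype_panel(500, 1, block_size = 1, rho = 0, seed = 2)
  y <- 0.5 * p$dosage[, 1] + rnorm(500, sd = 1e-8)
  expect_equal(run_gwas(p, y)$BETA, 0.5, tolerance = 1e-6)

  # null scan: lambda_GC near 1 and uniform p (Kolmogorov-Smirnov)
  pn <- simulate_genotype_panel(500, 1000, block_size = 1, rho = 0, seed = 3)
  set.seed(4); y0 <- rnorm(500)
  st <- run_gwas(pn, y0)
  expect_gt(attr(st, "lambda_gc"), 0.8)
  expect_lt(attr(st, "lambda_gc"), 1.2)
  expect_gt(suppressWarnings(ks.test(st$P, "punif"))$p.value, 0.01)

  # duplicated covariate column -> rank-deficiency error
  cv <- cbind(rep(1, 500), rep(1, 500))
  expect_error(run_gwas(pn, y0, covariates = cv), "rank-deficient")
})

test_that("clumping matches the hand example and the brute-force oracle", {
  p <- simulate_genotype_panel(4000, 3, block_size = 2,
                               maf_range = c(0.3, 0.3), rho = 0.9, seed = 2)
  expect_gt(panel_r2(p, "rs00001", "rs00002")[1], 0.05)
  st <- make_stats(p$snp, p = c(1e-10, 1e-9, 1e-8), pos = p$pos)
  expect_identical(clump(st, p), c("rs00001", "rs00003"))

  # mutually independent variants are all kept
  pi <- simulate_genotype_panel(3000, 8, block_size = 1, rho = 0, seed = 5)
  sti <- make_stats(pi$snp, p = runif(8, 1e-9, 1e-6), pos = pi$pos)
  expect_setequal(clump(sti, pi), pi$snp)

  # identical variants with tied p: exactly one kept (position tie-break)
  pd <- simulate_genotype_panel(1000, 2, block_size = 2,
                                maf_range = c(0.4, 0.4), rho = 0.999, seed = 6)
  pd$dosage[, 2] <- pd$dosage[, 1]
  std <- make_stats(pd$snp, p = c(1e-8, 1e-8), pos = pd$pos)
  expect_identical(clump(std, pd), "rs00001")

  # order invariance + oracle equivalence on 50 variants
  p50 <- simulate_genotype_panel(2000, 50, block_size = 5, rho = 0.8, seed = 7)
  set.seed(8)
  s50 <- make_stats(p50$snp, p = runif(50, 1e-12, 1e-4), pos = p50$pos)
  shuffled <- s50[sample.int(50), ]
  expect_identical(clump(s50, p50), clump(shuffled, p50))
  expect_identical(clump(s50, p50), clump_oracle(s50, p50))
  # every discarded variant is tagged by a retained index
  kept <- clump(s50, p50)
  dropped <- setdiff(s50$SNP, kept)
  r2 <- panel_r2(p50, dropped, kept)
  expect_true(all(apply(r2, 1, max) >= 0.05))
  expect_error(clump(make_stats("absent", p = 0.5), p50), "absent")
})

test_that("two-stage selection enforces thresholds and sign agreement", {
  p <- simulate_genotype_panel(1000, 3, block_size = 1, rho = 0, seed = 9)
  disc <- make_stats(p$snp, p = c(1e-9, 1e-9, 1e-7), beta = c(0.1, 0.1, 0.1),
                     pos = p$pos)
  repl <- make_stats(p$snp, p = c(0.01, 0.01, 1e-9),
                     beta = c(0.08, -0.05, 0.1), pos = p$pos)
  sel <- select_instruments(disc, repl, p)
  # v1 selected; v2 rejected (sign flip); v3 rejected (discovery 1e-7)
  expect_identical(sel$SNP, "rs00001")
  expect_identical(attr(sel, "weights_stage"), "discovery")
  expect_equal(sel$BETA, sel$BETA_DISC)
  selr <- select_instruments(disc, repl, p, weights = "replication")
  expect_equal(selr$BETA, selr$BETA_REPL)

  # monotonicity: tightening either threshold never adds instruments
  p20 <- simulate_genotype_panel(2000, 20, block_size = 1, rho = 0, seed = 10)
  set.seed(11)
  d20 <- make_stats(p20$snp, p = 10^runif(20, -12, -4),
                    beta = rnorm(20, 0.1, 0.02), pos = p20$pos)
  r20 <- make_stats(p20$snp, p = 10^runif(20, -6, 0),
                    beta = rnorm(20, 0.1, 0.05), pos = p20$pos)
  base <- select_instruments(d20, r20, p20)$SNP
  tighter_d <- select_instruments(d20, r20, p20, p_discovery = 5e-10)$SNP
  tighter_r <- select_instruments(d20, r20, p20, p_replication = 0.01)$SNP
  expect_true(all(tighter_d %in% base))
  expect_true(all(tighter_r %in% base))
  expect_error(select_instruments(d20, r20[-1, ], p20), "replication")
})

test_that("instrument strength follows the z-based closed form", {
  st <- instrument_strength(z = 10, n = 10000)
  expect_equal(st$r2_per_variant, 100 / 10098, tolerance = 1e-12)
  expect_equal(st$F, (100 / 10098) * 9998 / ((1 - 100 / 10098) * 1),
               tolerance = 1e-12)
  expect_equal(instrument_strength(z = 0, n = 100)$F, 0)
  st2 <- instrument_strength(z = rep(sqrt(0.01 * 9998 / 0.99), 2), n = 10000)
  expect_equal(st2$R2, 0.02, tolerance = 1e-9)
  expect_equal(st2$F, 0.02 * 9997 / (0.98 * 2), tolerance = 1e-6)
  expect_error(instrument_strength(z = rep(1, 10), n = 11), "exceed")
})

test_that("causal variants with adequate variance explained are recovered", {
  sc <- simulation_scenario(n_exposure = 50000, n_outcome = 1000, m = 60,
                            j_causal = 25, h2x = 0.25, seed = 21)
  px <- simulate_genotype_panel(50000, 60, block_size = 1, rho = 0, seed = 22)
  py <- simulate_genotype_panel(1000, 60, block_size = 1, rho = 0, seed = 23)
  py$maf <- px$maf; py$a1 <- px$a1; py$a2 <- px$a2
  co <- simulate_mr_cohorts(px, py, sc)
  st <- run_gwas(px, co$exposure)
  hits <- clump(st[st$P < 5e-8, ], px)
  freq <- colMeans(px$dosage[, co$truth$causal]) / 2
  r2_true <- co$truth$beta^2 * 2 * freq * (1 - freq)
  strong <- co$truth$causal[r2_true >= 0.001]
  expect_gte(mean(strong %in% hits), 0.9)
})
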