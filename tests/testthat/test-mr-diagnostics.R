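# stage 4: heterogeneity, outliers, NOME, directionality, screening, power

test_that("modified-weight Q matches hand arithmetic and the grid argmin", {
  # all ratios equal -> Q = 0, p = 1
  s0 <- make_hset(beta_x = c(1, 2, 4), beta_y = c(0.3, 0.6, 1.2),
                  se_x = 0.01, se_y = 0.1)
  q0 <- cochran_q_modified(s0)
  expect_equal(q0$Q, 0, tolerance = 1e-10)
  expect_equal(q0$p, 1)

  # the two-row IVW example with se_x ~ 0 reduces to first-order Q
  s <- make_hset(beta_x = c(1, 1), beta_y = c(0.3, 0.5), se_y = 0.1)
  q <- cochran_q_modified(s)
  expect_equal(q$Q, 2.0, tolerance = 1e-6)
  expect_equal(q$p, pchisq(2, 1, lower.tail = FALSE), tolerance = 1e-6)
  expect_equal(q$theta, 0.4, tolerance = 1e-6)
  expect_equal(sum(q$Qj), q$Q)

  # minimizer equals a dense grid search to 1e-5
  sg <- simulate_summary_mr(30, 0.2, se_x = 0.05, se_y = 0.08, seed = 8)
  qg <- cochran_q_modified(sg)
  d <- sg[is.na(sg$excluded), ]
  grid <- seq(qg$theta - 0.05, qg$theta + 0.05, length.out = 20001)
  qfun <- function(t) sum((d$beta_y / d$beta_x - t)^2 /
                            (d$se_y^2 / d$beta_x^2 + t^2 * d$se_x^2 / d$beta_x^2))
  qvals <- vapply(grid, qfun, numeric(1))
  expect_lt(abs(grid[which.min(qvals)] - qg$theta), 1e-5)
  expect_lte(min(qvals), qg$Q + 1e-10)
})

test_that("outlier filtering removes planted outliers and only those", {
  # homogeneous set: nothing removed
  s0 <- simulate_summary_mr(30, 0.3, seed = 3)
  f0 <- filter_outliers(make_hset(s0$beta_x, 0.3 * s0$beta_x,
                                  se_x = s0$se_x, se_y = s0$se_y))
  expect_identical(nrow(f0$removed), 0L)

  # one ratio planted 10 SD off among 30 clean: exactly that one removed
  s <- simulate_summary_mr(30, 0.3, seed = 3)
  s$beta_y[5] <- s$beta_y[5] + 10 * s$se_y[5]
  f <- filter_outliers(s)
  expect_identical(f$removed$snp, "snp0005")
  expect_identical(f$set$excluded[5], "q_outlier")

  # global Q p-value never decreases across removal rounds
  sh <- simulate_summary_mr(40, 0.3, prop_invalid = 0.2, alpha_sd = 0.3,
                            seed = 9)
  ps <- cochran_q_modified(sh)$p
  fh <- filter_outliers(sh)
  expect_gt(nrow(fh$removed), 0)
  work <- sh
  for (r in seq_len(nrow(fh$removed))) {
    work$excluded[work$snp == fh$removed$snp[r]] <- "q_outlier"
    pnew <- cochran_q_modified(work)$p
    expect_gte(pnew, ps - 1e-12)
    ps <- pnew
  }

  # false-removal control on clean data: <= 1 removal per 30 instruments
  removals <- vapply(1:300, function(r) {
    nrow(filter_outliers(simulate_summary_mr(30, 0.3, seed = 5000 + r))$removed)
  }, numeric(1))
  expect_lte(mean(removals), 1)
})

test_that("I2_GX quantifies exposure-effect dispersion", {
  s0 <- make_hset(beta_x = c(1, 1, 1), beta_y = c(0.1, 0.2, 0.3),
                  se_x = 0.1, se_y = 0.1)
  expect_equal(i2_gx(s0)$I2_GX, 0)
  s <- make_hset(beta_x = c(1, 2, 3), beta_y = c(0.1, 0.2, 0.3),
                 se_x = 0.1, se_y = 0.1)
  n <- i2_gx(s)
  expect_equal(n$Q_GX, 200, tolerance = 1e-10)
  expect_equal(n$I2_GX, 0.99, tolerance = 1e-10)
  sp <- make_hset(beta_x = c(1, 2, 3), beta_y = c(0.1, 0.2, 0.3),
                  se_x = 1e-6, se_y = 0.1)
  expect_gt(i2_gx(sp)$I2_GX, 0.999999)
})

test_that("Steiger orients causal direction and flags reversals", {
  s <- make_hset(beta_x = rep(0.5, 10), beta_y = rep(0.01, 10),
                 se_x = 0.02, se_y = 0.02)
  st <- mr_steiger(s, 20000, 20000)
  expect_true(st$direction)
  expect_false(st$indeterminate)
  expect_length(st$failing, 0)
  # symmetric effects: indeterminate
  se <- make_hset(beta_x = rep(0.2, 5), beta_y = rep(0.2, 5),
                  se_x = 0.02, se_y = 0.02)
  expect_true(mr_steiger(se, 20000, 20000)$indeterminate)
  expect_error(mr_steiger(s, 2, 20000), "exceed")
  # reverse-causal simulation: direction FALSE in >= 95% of replicates
  ok <- 0
  set.seed(1)
  for (r in 1:200) {
    f <- simulate_summary_mr(50, 0, seed = r)
    rev <- harmonized_set(data.frame(
      snp = f$snp, beta_x = f$beta_y + rnorm(50, 0, 0.01), se_x = f$se_y,
      beta_y = f$beta_x, se_y = f$se_x))
    ok <- ok + (!mr_steiger(rev, 20000, 20000)$direction)
  }
  expect_gte(ok / 200, 0.95)
})

test_that("confounder screen applies both thresholds and records gaps", {
  instr <- data.frame(SNP = c("v1", "v2", "v3", "v4"))
  conf <- make_stats(c("v1", "v2", "v3"), p = c(1e-9, 1e-6, 0.01))
  sc <- confounder_screen(instr, list(smoking = conf))
  expect_identical(sc$flags$flagged_strict, c(TRUE, FALSE, FALSE))
  expect_identical(sc$flags$flagged_suggestive, c(TRUE, TRUE, FALSE))
  expect_identical(sc$unscreened$snp, "v4")
  h <- make_hset(beta_x = rep(1, 4), beta_y = rep(0.3, 4), se_x = 0.01,
                 snp = c("v1", "v2", "v3", "v4"))
  h2 <- apply_confounder_screen(h, sc)
  expect_identical(h2$excluded,
                   c("confounder_associated", "confounder_associated",
                     NA, NA))
})

test_that("analytic power matches the closed form and is monotone", {
  expect_equal(mr_power_binary(1e5, 0.3, 0.03, 1), pnorm(-qnorm(0.975)))
  # the study-scale claims: > 80% at OR 1.25 with R2 3.13% / 5.83%;
  # never smokers at OR 1.40 (R2 4.21%) and 1.60 (R2 2.06%)
  expect_gt(mr_power_binary(85716, 29266 / 85716, 0.0313, 1.25), 0.80)
  expect_gt(mr_power_binary(85716, 29266 / 85716, 0.0583, 1.25), 0.80)
  expect_gte(mr_power_binary(9859, 2355 / 9859, 0.0421, 1.40), 0.80)
  expect_gte(mr_power_binary(9859, 2355 / 9859, 0.0206, 1.60), 0.80)
  # monotone non-decreasing in N, R2, |log OR| over random grids
  set.seed(2)
  for (i in 1:50) {
    n <- sample(1e3:1e5, 1); k <- runif(1, 0.1, 0.9)
    r2 <- runif(1, 0.005, 0.2); or <- exp(runif(1, -1, 1))
    p0 <- mr_power_binary(n, k, r2, or)
    expect_gte(mr_power_binary(n * 2, k, r2, or), p0)
    expect_gte(mr_power_binary(n, k, r2 * 1.5, or), p0)
    expect_gte(mr_power_binary(n, k, r2, exp(1.2 * log(or))), p0)
    expect_gte(p0, 0.025 - 1e-12)
  }
  # inverse: minimum detectable OR reproduces the target power
  or80 <- mr_min_detectable_or(9859, 2355 / 9859, 0.0421, power = 0.80)
  expect_equal(mr_power_binary(9859, 2355 / 9859, 0.0421, or80), 0.80,
               tolerance = 1e-6)
  expect_error(mr_min_detectable_or(1e4, 0.3, 0.03, power = 0.01),
               "target power")
})
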