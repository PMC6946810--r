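# stage 3: the five causal-effect estimators and multivariable MR

test_that("Wald ratio is the direct per-variant ratio", {
  w <- wald_ratio(0.5, 0.02, 0.2, 0.05)
  expect_equal(w$theta, 0.4)
  expect_equal(w$se, 0.1)
  expect_equal(wald_ratio(0.5, 0.02, 0, 0.05)$theta, 0)
  expect_equal(wald_ratio(-0.5, 0.02, 0.2, 0.05)$theta, -0.4)
  expect_error(wald_ratio(0, 0.02, 0.2, 0.05), "nonzero")
})

test_that("IVW matches hand arithmetic with multiplicative RE inflation", {
  s <- make_hset(beta_x = c(1, 1), beta_y = c(0.3, 0.5), se_y = 0.1)
  fe <- mr_ivw(s, random_effects = FALSE)
  re <- mr_ivw(s)
  expect_equal(fe$theta, 0.4, tolerance = 1e-12)
  expect_equal(fe$se, sqrt(0.005), tolerance = 1e-12)
  expect_equal(re$Q, 2.0, tolerance = 1e-12)
  expect_equal(re$se, 0.1, tolerance = 1e-12)
  # no inflation when all ratios agree
  s0 <- make_hset(beta_x = c(1, 2), beta_y = c(0.4, 0.8), se_y = 0.1)
  expect_equal(mr_ivw(s0)$se, mr_ivw(s0, random_effects = FALSE)$se)
  # single instrument falls back to the Wald ratio
  s1 <- make_hset(beta_x = 0.5, beta_y = 0.2, se_x = 0.02, se_y = 0.05)
  expect_equal(mr_ivw(s1)$theta, 0.4)
  expect_equal(mr_ivw(s1)$se, 0.1)
})

test_that("maximum likelihood agrees with IVW in the NOME limit and is exact when noiseless", {
  s <- simulate_summary_mr(60, 0.3, se_x = 1e-9, seed = 5)
  expect_equal(mr_maximum_likelihood(s)$theta,
               mr_ivw(s, random_effects = FALSE)$theta, tolerance = 1e-6)
  s0 <- simulate_summary_mr(20, 0.7, se_x = 0, se_y = 0, seed = 1)
  expect_equal(mr_maximum_likelihood(s0)$theta, 0.7, tolerance = 1e-6)
})

test_that("maximum likelihood recovers theta with bias no worse than IVW", {
  reps <- 200
  bias_ml <- numeric(reps); bias_ivw <- numeric(reps)
  last <- NULL
  for (r in seq_len(reps)) {
    s <- simulate_summary_mr(150, 0.3, se_x = 0.03, seed = 400 + r)
    ml <- mr_maximum_likelihood(s)
    bias_ml[r] <- ml$theta - 0.3
    bias_ivw[r] <- mr_ivw(s)$theta - 0.3
    last <- ml
  }
  expect_lt(abs(last$theta - 0.3), 3 * last$se)
  expect_lte(abs(mean(bias_ml)), abs(mean(bias_ivw)))
})

test_that("weighted median interpolates the cumulative weight midpoints", {
  s3 <- make_hset(beta_x = c(1, 1, 1), beta_y = c(0.2, 0.4, 0.6),
                  se_x = 0.01, se_y = 0.1)
  expect_equal(mr_weighted_median(s3, n_boot = 50)$theta, 0.4)
  # two equal weights: interpolation midway between the ratios
  s2 <- make_hset(beta_x = c(1, 1, 1e-6), beta_y = c(0.2, 0.4, 1e-7),
                  se_x = 0.01, se_y = 0.1)
  expect_equal(mr_weighted_median(s2, n_boot = 50)$theta, 0.3,
               tolerance = 1e-3)
  # dominant weight mass pins the estimate to that instrument's ratio
  sd <- make_hset(beta_x = c(10, 0.01, 0.01), beta_y = c(5, 0.009, 0.001),
                  se_x = 0.01, se_y = 0.1)
  expect_equal(mr_weighted_median(sd, n_boot = 50)$theta, 0.5,
               tolerance = 1e-3)
  # bootstrap SE is seeded and reproducible
  s <- simulate_summary_mr(30, 0.3, seed = 2)
  expect_identical(mr_weighted_median(s, n_boot = 200)$se,
                   mr_weighted_median(s, n_boot = 200)$se)
  expect_error(mr_weighted_median(make_hset(1, 1)), "at least 3")
})

test_that("Egger regression separates slope from directional pleiotropy", {
  bx <- seq(0.05, 0.3, length.out = 10)
  s <- make_hset(beta_x = bx, beta_y = 0.1 + 0.3 * bx, se_y = 0.05)
  e <- mr_egger(s)
  expect_equal(e$intercept, 0.1, tolerance = 1e-9)
  expect_equal(e$theta, 0.3, tolerance = 1e-9)
  expect_equal(e$Q, 0, tolerance = 1e-12)
  # constrained intercept reduces to fixed-effect IVW
  sn <- simulate_summary_mr(50, 0.3, seed = 3)
  expect_equal(mr_egger(sn, fix_intercept = TRUE)$theta,
               mr_ivw(sn, random_effects = FALSE)$theta, tolerance = 1e-9)
  expect_error(mr_egger(make_hset(c(1, 1, 1), c(1, 1, 1))), "unidentified")
  # directional pleiotropy: intercept rejected in most replicates
  rej <- 0
  for (r in 1:200) {
    sd <- simulate_summary_mr(150, 0.3, prop_invalid = 1, alpha_mean = 0.05,
                              alpha_sd = 0.05, balanced = FALSE, seed = r)
    rej <- rej + (mr_egger(sd)$intercept_p < 0.05)
  }
  expect_gt(rej / 200, 0.5)
})

test_that("RAPS matches IVW in its limiting case and resists gross outliers", {
  s <- simulate_summary_mr(60, 0.3, se_x = 1e-9, seed = 5)
  expect_equal(mr_raps(s, loss = "squared", overdispersion = FALSE)$theta,
               mr_ivw(s, random_effects = FALSE)$theta, tolerance = 1e-4)
  better <- 0
  for (r in 1:200) {
    s <- simulate_summary_mr(50, 0.3, seed = r)
    s$beta_y[1] <- s$beta_x[1] * 10
    ra <- suppressWarnings(mr_raps(s))
    better <- better +
      (abs(ra$theta - 0.3) < abs(mr_ivw(s)$theta - 0.3))
  }
  expect_gte(better / 200, 0.8)
})

test_that("RAPS confidence intervals are calibrated under balanced pleiotropy", {
  cover <- 0
  for (r in 1:300) {
    s <- simulate_summary_mr(100, 0.3, prop_invalid = 0.3, alpha_sd = 0.02,
                             balanced = TRUE, seed = r)
    ra <- suppressWarnings(mr_raps(s))
    cover <- cover + (ra$ci[1] <= 0.3 && 0.3 <= ra$ci[2])
  }
  expect_gte(cover / 300, 0.90)
  expect_lte(cover / 300, 0.98)
})

test_that("multivariable MR solves exact systems and reduces to IVW", {
  bx <- cbind(x1 = c(1, 2, 3, 4, 5), x2 = c(2, 1, 4, 3, 6))
  by <- 0.3 * bx[, 1] - 0.2 * bx[, 2]
  mv <- mr_mvmr(bx, by, rep(0.1, 5))
  expect_equal(mv$theta, c(0.3, -0.2), tolerance = 1e-10)
  s <- simulate_summary_mr(40, 0.25, seed = 6)
  mv1 <- mr_mvmr(cbind(x = s$beta_x), s$beta_y, s$se_y)
  iv <- mr_ivw(s)
  expect_equal(mv1$theta, iv$theta, tolerance = 1e-12)
  expect_equal(mv1$se, iv$se, tolerance = 1e-12)
  expect_error(mr_mvmr(cbind(bx[, 1], bx[, 1]), by, rep(0.1, 5)),
               "rank deficient")
})

test_that("estimators share scale and sign equivariance and agree when valid", {
  s <- simulate_summary_mr(150, 0.3, seed = 11)
  base <- mr_estimate_all(s, wm_boot = 200)
  # scale: beta_x * c scales every estimate by 1/c
  sc <- s; sc$beta_x <- s$beta_x * 2; sc$se_x <- s$se_x * 2
  scaled <- mr_estimate_all(sc, wm_boot = 200)
  expect_equal(scaled$theta, base$theta / 2, tolerance = 1e-6)
  # sign: flipping one variant's orientation changes nothing
  sf <- s; sf$beta_x[7] <- -s$beta_x[7]; sf$beta_y[7] <- -s$beta_y[7]
  flipped <- mr_estimate_all(sf, wm_boot = 200)
  expect_equal(flipped$theta, base$theta, tolerance = 1e-9)
  # with all instruments valid the five estimators agree within 2 joint SE
  for (i in seq_len(nrow(base))) for (j in seq_len(nrow(base))) {
    expect_lt(abs(base$theta[i] - base$theta[j]),
              2 * sqrt(base$se[i]^2 + base$se[j]^2))
  }
  # RE SE never below FE SE; Egger CI at least as wide as IVW's
  expect_gte(mr_ivw(s)$se, mr_ivw(s, random_effects = FALSE)$se)
  expect_gte(diff(mr_egger(s)$ci), diff(mr_ivw(s)$ci))
})
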