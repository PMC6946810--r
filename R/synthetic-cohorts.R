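#' Define a simulation scenario for two-sample MR cohorts
#'
#' Bundles and validates the generative parameters behind a two-sample MR
#' simulation: a polygenic continuous exposure with configurable heritability,
#' a binary outcome generated on the log-odds (logistic) scale with a target
#' case fraction, confounding through a shared covariate, and a configurable
#' fraction of invalid (horizontally pleiotropic) instruments with direct
#' outcome effects.
#'
#' The logistic (rather than liability-threshold) outcome model is used so
#' that the causal ground truth `theta` is exact on the log-odds scale, i.e.
#' `exp(theta)` is the true odds ratio per exposure unit.
#'
#' @param n_exposure,n_outcome individuals in the (disjoint) exposure and
#'   outcome samples.
#' @param m variants in the shared variant map.
#' @param j_causal number of causal variants (`<= m`).
#' @param theta causal effect of the exposure on the outcome log-odds, per
#'   exposure unit.
#' @param h2x fraction of exposure variance explained by the causal variants.
#' @param prop_invalid fraction of causal variants with direct (pleiotropic)
#'   outcome effects.
#' @param alpha_mean mean direct effect of invalid instruments (ignored when
#'   `balanced = TRUE`).
#' @param alpha_sd standard deviation of direct effects.
#' @param balanced if `TRUE`, direct effects are zero-mean ("balanced
#'   horizontal pleiotropy", the InSIDE-compatible case).
#' @param confounder_exposure,confounder_outcome effects of a standard-normal
#'   shared confounder on exposure and outcome log-odds.
#' @param case_fraction target expected case fraction `K` in (0, 1).
#' @param seed integer seed; the scenario seed fully determines all draws.
#' @return a validated list of class `simulation_scenario`.
#' @export
simulation_scenario <- function(n_exposure = 20000, n_outcome = 20000,
                                m = 200, j_causal = 40, theta = 0,
                                h2x = 0.15, prop_invalid = 0,
                                alpha_mean = 0, alpha_sd = 0.05,
                                balanced = TRUE,
                                confounder_exposure = 0.3,
                                confounder_outcome = 0.3,
                                case_fraction = 0.34, seed = 1) {
  sc <- list(n_exposure = assert_scalar_count(n_exposure, "n_exposure"),
             n_outcome = assert_scalar_count(n_outcome, "n_outcome"),
             m = assert_scalar_count(m, "m"),
             j_causal = assert_scalar_count(j_causal, "j_causal"),
             theta = theta,
             h2x = assert_fraction(h2x, "h2x", open = c(TRUE, TRUE)),
             prop_invalid = assert_fraction(prop_invalid, "prop_invalid"),
             alpha_mean = alpha_mean, alpha_sd = alpha_sd,
             balanced = isTRUE(balanced),
             confounder_exposure = confounder_exposure,
             confounder_outcome = confounder_outcome,
             case_fraction = assert_fraction(case_fraction, "case_fraction",
                                             open = c(TRUE, TRUE)),
             seed = as.integer(seed))
  if (sc$j_causal > sc$m) stop("j_causal must not exceed m")
  class(sc) <- "simulation_scenario"
  sc
}

# solve the logistic intercept so that the mean case probability hits K,
# by bisection to +/- 0.001
solve_logistic_intercept <- function(linear_predictor, K, tol = 0.001) {
  f <- function(a) mean(stats::plogis(a + linear_predictor)) - K
  lo <- -30; hi <- 30
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (abs(f(mid)) <= tol / 10) break
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  mid
}

#' Simulate disjoint exposure and outcome cohorts for two-sample MR
#'
#' Given two genotype panels sharing a variant map (same `m`, ids, and
#' frequencies by construction) and a [simulation_scenario()], generates a
#' continuous exposure in the first panel's sample and a binary outcome in
#' the second. The exposure is a genetic score plus confounder plus noise,
#' with the noise variance solved so that the genetic score explains exactly
#' `h2x` of the exposure variance in expectation. The outcome follows a
#' logistic model whose intercept is solved numerically so that the expected
#' case fraction equals `case_fraction` (to within 0.001). A configured
#' fraction of causal variants additionally receives direct outcome effects
#' (zero-mean when `balanced`).
#'
#' Ground-truth labels (causal variant ids, validity flags, true `theta`)
#' are returned alongside and are never consumed by inference code.
#'
#' @param panel_exposure,panel_outcome `genotype_panel` objects with a common
#'   variant map.
#' @param scenario a [simulation_scenario()].
#' @return list with `exposure` (vector), `confounder_exposure`, `outcome`
#'   (0/1 vector), `confounder_outcome`, and `truth` (causal ids, per-variant
#'   effects, validity flags, theta, intercept).
#' @export
simulate_mr_cohorts <- function(panel_exposure, panel_outcome, scenario) {
  stopifnot(inherits(panel_exposure, "genotype_panel"),
            inherits(panel_outcome, "genotype_panel"),
            inherits(scenario, "simulation_scenario"))
  if (!identical(panel_exposure$snp, panel_outcome$snp))
    stop("the two panels must share the variant map")
  if (panel_exposure$n != scenario$n_exposure ||
      panel_outcome$n != scenario$n_outcome)
    stop("panel sizes must match the scenario sample sizes")
  sc <- scenario
  if (sc$j_causal < 1) stop("scenario has no causal variants")

  with_seed(sc$seed, {
    causal <- sort(sample.int(sc$m, sc$j_causal))
    b <- stats::rnorm(sc$j_causal)

    # scale the per-variant effects so the genetic score has variance h2x and
    # the exposure unit variance (an SD-standardized phenotype, so theta is
    # per 1-SD of exposure)
    gx_raw <- as.vector(panel_exposure$dosage[, causal, drop = FALSE] %*% b)
    b <- b * sqrt(sc$h2x / stats::var(gx_raw))
    gx <- gx_raw * sqrt(sc$h2x / stats::var(gx_raw))
    ve <- 1 - sc$h2x - sc$confounder_exposure^2
    if (ve <= 0)
      stop("confounder effect too large for the requested h2x")
    cx <- stats::rnorm(sc$n_exposure)
    x <- gx + sc$confounder_exposure * cx +
      stats::rnorm(sc$n_exposure, sd = sqrt(ve))

    # outcome sample: same genetic architecture, fresh noise and confounder
    gy <- as.vector(panel_outcome$dosage[, causal, drop = FALSE] %*% b)
    vey <- 1 - sc$h2x - sc$confounder_outcome^2
    if (vey <= 0) stop("confounder effect too large for the requested h2x")
    cy <- stats::rnorm(sc$n_outcome)
    xy <- gy + sc$confounder_outcome * cy +
      stats::rnorm(sc$n_outcome, sd = sqrt(vey))

    n_invalid <- round(sc$prop_invalid * sc$j_causal)
    invalid <- if (n_invalid > 0) sort(sample(causal, n_invalid)) else integer(0)
    alpha <- numeric(length(invalid))
    if (n_invalid > 0) {
      mu <- if (sc$balanced) 0 else sc$alpha_mean
      alpha <- stats::rnorm(n_invalid, mean = mu, sd = sc$alpha_sd)
    }
    eta <- sc$theta * xy + sc$confounder_outcome * cy
    if (n_invalid > 0)
      eta <- eta + as.vector(panel_outcome$dosage[, invalid, drop = FALSE] %*% alpha)
    a0 <- solve_logistic_intercept(eta, sc$case_fraction)
    y <- stats::rbinom(sc$n_outcome, 1L, stats::plogis(a0 + eta))

    list(exposure = x, confounder_exposure = cx,
         outcome = y, confounder_outcome = cy,
         truth = list(causal = panel_exposure$snp[causal], beta = b,
                      invalid = panel_exposure$snp[invalid], alpha = alpha,
                      theta = sc$theta, intercept = a0,
                      h2x = sc$h2x, case_fraction = sc$case_fraction))
  })
}

#' Simulate spirometry blow series
#'
#' Emulates repeated spirometry blows per individual: each person has a best
#' (maximum) blow for FEV1 and FVC, additional blows that fall within the
#' 0.15 L reproducibility tolerance, and configurable fractions of
#' individuals who either completed only one blow or whose repeat blows are
#' all discordant (more than 0.15 L below the best), both of which are
#' excluded by [qc_spirometry()].
#'
#' @param n individuals.
#' @param one_blow_frac fraction completing a single blow.
#' @param discordant_frac fraction whose non-best blows all differ from the
#'   best by more than 0.15 L.
#' @param max_extra_blows additional blows beyond the first two (uniform).
#' @param seed integer seed.
#' @return data.frame with columns `id`, `blow`, `fev1`, `fvc` (litres), one
#'   row per blow; the true status of each individual (`"single"`,
#'   `"discordant"`, `"concordant"`) is attached as attribute `truth`.
#' @export
simulate_blows <- function(n, one_blow_frac = 0.01, discordant_frac = 0.05,
                           max_extra_blows = 1, seed = 1) {
  n <- assert_scalar_count(n, "n")
  assert_fraction(one_blow_frac, "one_blow_frac")
  assert_fraction(discordant_frac, "discordant_frac")
  if (one_blow_frac + discordant_frac > 1)
    stop("one_blow_frac + discordant_frac must not exceed 1")
  with_seed(seed, {
    status <- sample(c("single", "discordant", "concordant"), n, replace = TRUE,
                     prob = c(one_blow_frac, discordant_frac,
                              1 - one_blow_frac - discordant_frac))
    fev1_best <- pmax(stats::rnorm(n, 3.0, 0.5), 0.8)
    ratio <- stats::runif(n, 0.55, 0.92)
    fvc_best <- fev1_best / ratio

    rows <- vector("list", n)
    for (i in seq_len(n)) {
      nb <- if (status[i] == "single") 1L
            else 2L + sample.int(max_extra_blows + 1L, 1L) - 1L
      delta <- numeric(nb)        # shortfall of each blow from the best
      if (nb > 1L) {
        delta[-1] <- if (status[i] == "discordant")
          0.15 + stats::runif(nb - 1L, 0.05, 0.6)
        else stats::runif(nb - 1L, 0, 0.12)
      }
      rows[[i]] <- data.frame(id = i, blow = seq_len(nb),
                              fev1 = fev1_best[i] - delta,
                              fvc = fvc_best[i] - delta)
    }
    out <- do.call(rbind, rows)
    attr(out, "truth") <- status
    out
  })
}
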