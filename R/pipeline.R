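#' Declarative configuration for an end-to-end pipeline run
#'
#' Collects every stage's parameters in one validated list. Thresholds
#' default to the study conventions used throughout the package: two-stage
#' selection at discovery P < 5e-8 and replication P < 0.05 with sign
#' agreement, LD clumping at r2 < 0.05 in a 10,000 kb window, palindrome
#' inferability at MAF 0.42, proxy LD r2 > 0.90, heterogeneity outlier
#' filtering at the Bonferroni-per-variant level 0.05/J, and confounder
#' screens at 5e-8 / 1e-5. One seed per stage is derived from `seed` by
#' fixed offsets. The config round-trips losslessly through
#' [write_pipeline_config()] / [read_pipeline_config()].
#'
#' @param scenario a [simulation_scenario()] describing the synthetic study.
#' @param seed master seed; per-stage seeds are `seed + offset`.
#' @param split_discovery fraction of the exposure cohort used for
#'   discovery (default 0.70, remainder replication).
#' @param p_discovery,p_replication,r2_threshold,window_kb,palindrome_maf,proxy_r2,q_alpha,screen_thresholds
#'   stage thresholds (see above).
#' @param estimators methods passed to [mr_estimate_all()].
#' @param rescale_mode reporting scale (see [rescale_units()]).
#' @param outlier_filtering apply heterogeneity outlier filtering before the
#'   post-filtering estimates (default `TRUE`).
#' @param run_ldsc also run the summary-level heritability / genetic
#'   correlation stage (default `TRUE`).
#' @param block_size,maf_range,rho genotype panel structure.
#' @param power_or odds-ratio alternatives for the power table.
#' @return a validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(scenario = simulation_scenario(),
                            seed = 1,
                            split_discovery = 0.70,
                            p_discovery = 5e-8, p_replication = 0.05,
                            r2_threshold = 0.05, window_kb = 10000,
                            palindrome_maf = 0.42, proxy_r2 = 0.90,
                            q_alpha = 0.05,
                            screen_thresholds = c(5e-8, 1e-5),
                            estimators = c("ivw", "ml", "wm", "egger",
                                           "raps"),
                            rescale_mode = "impairment",
                            outlier_filtering = TRUE,
                            run_ldsc = TRUE,
                            block_size = 10, maf_range = c(0.1, 0.5),
                            rho = 0.6,
                            power_or = c(1.25, 1.4, 1.6)) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  assert_fraction(split_discovery, "split_discovery", open = c(TRUE, TRUE))
  cfg <- list(scenario = scenario, seed = as.integer(seed),
              split_discovery = split_discovery,
              p_discovery = p_discovery, p_replication = p_replication,
              r2_threshold = r2_threshold, window_kb = window_kb,
              palindrome_maf = palindrome_maf, proxy_r2 = proxy_r2,
              q_alpha = q_alpha, screen_thresholds = screen_thresholds,
              estimators = estimators, rescale_mode = rescale_mode,
              outlier_filtering = isTRUE(outlier_filtering),
              run_ldsc = isTRUE(run_ldsc),
              block_size = block_size, maf_range = maf_range, rho = rho,
              power_or = power_or)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Write / read a pipeline config as JSON
#' @param config a [pipeline_config()].
#' @param path file path.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  x <- unclass(config)
  x$scenario <- unclass(x$scenario)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  sc <- do.call(simulation_scenario, x$scenario)
  x$scenario <- NULL
  do.call(pipeline_config, c(list(scenario = sc), x))
}

# fixed per-stage seed offsets from the master seed
stage_seed <- function(config, stage) {
  offsets <- c(panel_exposure = 101L, panel_outcome = 202L, cohorts = 303L,
               split = 404L, ldsc = 505L)
  config$seed + offsets[[stage]]
}

#' Run the full synthetic two-sample MR pipeline
#'
#' Orchestrates every stage from one config: simulate genotype panels and
#' disjoint cohorts; split the exposure cohort into discovery/replication;
#' run the exposure association scans and two-stage instrument selection
#' with LD clumping; run the binary outcome scan (logistic, log-odds scale);
#' harmonize, rescale, and estimate with all configured estimators;
#' recompute after heterogeneity outlier filtering; produce heterogeneity /
#' NOME / Steiger / instrument-strength / power diagnostics; optionally run
#' the summary-level heritability and genetic-correlation stage. Outputs
#' are written as TSV/JSON under `out_dir` together with a plain-text log
#' echoing parameters and in/out counts per stage; runs are deterministic
#' given the config (two runs produce byte-identical numeric outputs).
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed); `NULL` skips
#'   writing.
#' @return (invisibly) a list with `instruments`, `harmonized`, `estimates`
#'   (pre/post filtering), `diagnostics`, `power`, `ldsc`, `counts`, and
#'   `log`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  sc <- config$scenario
  log_lines <- character(0)
  say <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
    invisible(line)
  }
  say("pipeline seed: %d", config$seed)
  say("scenario: n_exposure=%d n_outcome=%d m=%d J=%d theta=%.4f h2x=%.3f K=%.3f prop_invalid=%.2f",
      sc$n_exposure, sc$n_outcome, sc$m, sc$j_causal, sc$theta, sc$h2x,
      sc$case_fraction, sc$prop_invalid)

  panel_x <- simulate_genotype_panel(sc$n_exposure, sc$m,
                                     block_size = config$block_size,
                                     maf_range = config$maf_range,
                                     rho = config$rho,
                                     seed = stage_seed(config, "panel_exposure"))
  panel_y <- simulate_genotype_panel(sc$n_outcome, sc$m,
                                     block_size = config$block_size,
                                     maf_range = config$maf_range,
                                     rho = config$rho,
                                     seed = stage_seed(config, "panel_outcome"))
  # the outcome panel must share the exposure panel's variant map
  panel_y$maf <- panel_x$maf
  panel_y$a1 <- panel_x$a1; panel_y$a2 <- panel_x$a2
  cohorts <- simulate_mr_cohorts(panel_x, panel_y,
                                 within_scenario_seed(sc, stage_seed(config, "cohorts")))
  say("cohorts simulated: case fraction %.3f (target %.3f)",
      mean(cohorts$outcome), sc$case_fraction)

  # 70/30 split of the exposure cohort by seeded random assignment
  disc_idx <- with_seed(stage_seed(config, "split"), {
    sample.int(sc$n_exposure, round(config$split_discovery * sc$n_exposure))
  })
  repl_idx <- setdiff(seq_len(sc$n_exposure), disc_idx)
  sub_panel <- function(panel, idx) {
    p <- panel; p$dosage <- panel$dosage[idx, , drop = FALSE]
    p$n <- length(idx); p
  }
  disc_stats <- run_gwas(sub_panel(panel_x, disc_idx),
                         cohorts$exposure[disc_idx])
  repl_stats <- run_gwas(sub_panel(panel_x, repl_idx),
                         cohorts$exposure[repl_idx])
  say("exposure scans: discovery n=%d (lambda_GC %.3f), replication n=%d",
      length(disc_idx), attr(disc_stats, "lambda_gc"), length(repl_idx))

  instruments <- select_instruments(disc_stats, repl_stats, panel_x,
                                    p_discovery = config$p_discovery,
                                    p_replication = config$p_replication,
                                    r2_threshold = config$r2_threshold,
                                    window_kb = config$window_kb)
  say("instruments selected: %d (disc P<%g, repl P<%g, r2<%g/%g kb)",
      nrow(instruments), config$p_discovery, config$p_replication,
      config$r2_threshold, config$window_kb)
  if (nrow(instruments) < 3)
    stop("fewer than 3 instruments selected; enlarge the scenario")

  outcome_stats <- run_gwas_binary(panel_y, cohorts$outcome)
  hset <- harmonize_pair(instruments, outcome_stats,
                         palindrome_maf = config$palindrome_maf,
                         exposure_name = "exposure",
                         outcome_name = "outcome")
  if (config$rescale_mode != "per_sd")
    hset <- rescale_units(hset, config$rescale_mode)
  n_excl <- sum(!is.na(hset$excluded))
  say("harmonized: %d variants (%d excluded: %s)", nrow(hset), n_excl,
      paste(names(exclusion_counts(hset)),
            as.integer(exclusion_counts(hset)), collapse = ", ") )

  estimates_full <- mr_estimate_all(hset, config$estimators)
  estimates_full$stage <- "all instruments"
  filt <- NULL
  estimates <- estimates_full
  if (config$outlier_filtering) {
    filt <- filter_outliers(hset, q_alpha = config$q_alpha)
    est_f <- mr_estimate_all(filt$set, config$estimators)
    est_f$stage <- "outliers removed"
    estimates <- rbind(estimates_full, est_f)
    say("outlier filtering: %d removed over %d rounds", nrow(filt$removed),
        max(c(0L, filt$removed$round)))
  }

  het <- cochran_q_modified(hset)
  nome <- i2_gx(hset)
  steig <- mr_steiger(hset, n_exposure = sc$n_exposure,
                      n_outcome = sc$n_outcome)
  strength <- instrument_strength(instruments)
  say("diagnostics: Q=%.2f (p=%.3g), I2_GX=%.3f, Steiger direction %s, R2=%.4f, F=%.1f",
      het$Q, het$p, nome$I2_GX, steig$direction, strength$R2, strength$F)

  power_tab <- do.call(rbind, lapply(config$power_or, function(orv)
    data.frame(or = orv,
               power = mr_power_binary(sc$n_outcome, sc$case_fraction,
                                       strength$R2, orv))))

  ldsc_res <- NULL
  if (config$run_ldsc) {
    pg <- simulate_polygenic_pair(sc$n_exposure, sc$n_outcome, 5000,
                                  h2_1 = 0.16, h2_2 = 0.10, rg = 0.12,
                                  seed = stage_seed(config, "ldsc"))
    h2 <- ldsc_h2(pg$z1, pg$n1, pg$ld, pg$m)
    rg <- ldsc_rg(pg$z1, pg$z2, pg$n1, pg$n2, pg$ld, pg$m)
    ldsc_res <- list(h2 = h2, rg = rg)
    say("ldsc stage: h2=%.3f (SE %.3f), rg=%.3f (SE %.3f)",
        h2$h2, h2$se, rg$rg, rg$se)
  }

  counts <- list(
    instruments_selected = nrow(instruments),
    harmonized_usable = sum(is.na(hset$excluded)),
    harmonized_excluded = n_excl,
    outliers_removed = if (is.null(filt)) 0L else nrow(filt$removed))
  # conservation: selected = usable + excluded; filtered = usable - removed
  stopifnot(counts$instruments_selected ==
              counts$harmonized_usable + counts$harmonized_excluded)

  result <- list(instruments = instruments, harmonized = hset,
                 estimates = estimates,
                 diagnostics = list(heterogeneity = het, nome = nome,
                                    steiger = steig, strength = strength,
                                    outliers = filt),
                 power = power_tab, ldsc = ldsc_res, counts = counts,
                 log = log_lines, config = config)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(as.data.frame(instruments),
                       file.path(out_dir, "instruments.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(as.data.frame(hset),
                       file.path(out_dir, "harmonized.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(estimates, file.path(out_dir, "estimates.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(power_tab, file.path(out_dir, "power.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    diag_tab <- data.frame(
      Q = het$Q, Q_df = het$df, Q_p = het$p, phi = het$phi,
      I2_GX = nome$I2_GX, steiger_direction = steig$direction,
      steiger_p = steig$p, R2 = strength$R2, F_stat = strength$F,
      outliers_removed = counts$outliers_removed)
    utils::write.table(diag_tab, file.path(out_dir, "diagnostics.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(ldsc_res)) {
      ld_tab <- data.frame(
        h2 = ldsc_res$h2$h2, h2_se = ldsc_res$h2$se,
        h2_intercept = ldsc_res$h2$intercept,
        rg = ldsc_res$rg$rg, rg_se = ldsc_res$rg$se, rg_p = ldsc_res$rg$p)
      utils::write.table(ld_tab, file.path(out_dir, "ldsc.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    jsonlite::write_json(counts, file.path(out_dir, "counts.json"),
                         auto_unbox = TRUE, digits = NA)
    writeLines(log_lines, file.path(out_dir, "pipeline.log"))
    write_pipeline_config(config, file.path(out_dir, "config.json"))
  }
  invisible(result)
}

# replace the scenario seed with a stage-derived one (keeps everything else)
within_scenario_seed <- function(scenario, seed) {
  scenario$seed <- as.integer(seed)
  scenario
}
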