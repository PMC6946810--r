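#' Gene-level causal effect from eQTL instruments
#'
#' Estimates the effect of a gene's expression on the outcome using its
#' eQTLs as instruments: genes with a single eQTL use the Wald ratio; genes
#' with multiple eQTLs are first LD-pruned to independent variants
#' (`r^2 < r2_threshold`, greedy by eQTL p-value) and combined by IVW
#' (fixed effects by default; set `random_effects = TRUE` for the
#' multiplicative random-effects variant).
#'
#' @param set a [harmonized_set()] of eQTL (expression, exposure side) and
#'   outcome effects for one gene.
#' @param gene gene identifier.
#' @param panel optional `genotype_panel` for LD pruning; omitted means the
#'   eQTLs are already independent.
#' @param r2_threshold LD pruning threshold among eQTLs (default 0.05).
#' @param random_effects IVW random-effects flag (default fixed).
#' @return data.frame row: `gene`, `n_eqtl`, `method`, `theta`, `se`, `or`,
#'   `or_lower`, `or_upper`, `p`.
#' @export
gene_effect <- function(set, gene = "gene", panel = NULL, r2_threshold = 0.05,
                        random_effects = FALSE) {
  d <- hm_data(set, 1L, "gene_effect")
  if (!is.null(panel) && nrow(d) > 1) {
    ord <- order(2 * stats::pnorm(-abs(d$beta_x / d$se_x)))
    keep <- character(0)
    for (s in d$snp[ord]) {
      if (!length(keep) ||
          all(panel_r2(panel, s, keep) < r2_threshold)) keep <- c(keep, s)
    }
    d <- d[d$snp %in% keep, , drop = FALSE]
  }
  fit <- if (nrow(d) == 1L) {
    wald_ratio(d$beta_x, d$se_x, d$beta_y, d$se_y)
  } else {
    mr_ivw(harmonized_set(d), random_effects = random_effects)
  }
  data.frame(gene = gene, n_eqtl = nrow(d), method = fit$method,
             theta = fit$theta, se = fit$se, or = fit$or,
             or_lower = fit$or_ci[1], or_upper = fit$or_ci[2], p = fit$p,
             stringsAsFactors = FALSE)
}

#' Gene-level effects across many genes with a Bonferroni threshold
#'
#' Runs [gene_effect()] per gene and flags genes significant at
#' `0.05 / n_genes`, the Bonferroni level computed from the number of genes
#' actually tested.
#'
#' @param sets named list of per-gene [harmonized_set()]s.
#' @param panel,r2_threshold,random_effects see [gene_effect()].
#' @return data.frame with one row per gene plus a `significant` column;
#'   the threshold used is attached as attribute `bonferroni`.
#' @export
gene_effects <- function(sets, panel = NULL, r2_threshold = 0.05,
                         random_effects = FALSE) {
  stopifnot(is.list(sets), length(sets) >= 1)
  nm <- names(sets) %||% paste0("gene", seq_along(sets))
  out <- do.call(rbind, lapply(seq_along(sets), function(i)
    gene_effect(sets[[i]], nm[i], panel, r2_threshold, random_effects)))
  thr <- 0.05 / nrow(out)
  out$significant <- out$p < thr
  attr(out, "bonferroni") <- thr
  out
}

#' Classify direction consistency of a gene's expression effects
#'
#' A gene is `"consistent"` with mediation through pulmonary impairment when
#' the allele-aligned effects of expression on lung function and on cancer
#' risk point in opposite directions (increased expression -> impaired
#' function and increased risk, or conversely); `"inconsistent"` when they
#' point the same way; `"indeterminate"` when either association fails its
#' significance threshold. Jointly flipping the coded allele flips both
#' signs and leaves the label unchanged.
#'
#' @param beta_function effect of expression-increasing allele on the
#'   function phenotype.
#' @param beta_cancer effect of the same allele on cancer risk (log-odds).
#' @param p_function,p_cancer association p-values.
#' @param p_threshold significance required to call a direction (default
#'   0.05).
#' @return `"consistent"`, `"inconsistent"`, or `"indeterminate"`.
#' @export
classify_consistency <- function(beta_function, beta_cancer,
                                 p_function = 0, p_cancer = 0,
                                 p_threshold = 0.05) {
  if (is.na(beta_function) || is.na(beta_cancer) ||
      p_function > p_threshold || p_cancer > p_threshold ||
      beta_function == 0 || beta_cancer == 0) return("indeterminate")
  if (sign(beta_function) * sign(beta_cancer) < 0) "consistent" else
    "inconsistent"
}

#' Synthetic per-gene eQTL fixture generator
#'
#' Builds per-gene harmonized eQTL/outcome sets with a known gene-level
#' effect, for documentation and tests: each gene gets `n_eqtl` independent
#' eQTLs with expression effects drawn around `beta_eqtl`, and outcome
#' effects `theta_gene * beta + noise`.
#'
#' @param n_genes number of genes.
#' @param theta range (length-2) of true gene-level effects, drawn uniformly.
#' @param n_eqtl eQTLs per gene (recycled).
#' @param beta_eqtl mean expression effect per allele.
#' @param se_y outcome effect SE.
#' @param seed integer seed.
#' @return named list of [harmonized_set()]s with `truth` attributes.
#' @export
simulate_eqtl_sets <- function(n_genes = 10, theta = c(-0.3, 0.3),
                               n_eqtl = c(1, 2, 3), beta_eqtl = 0.4,
                               se_y = 0.03, seed = 1) {
  with_seed(seed, {
    out <- lapply(seq_len(n_genes), function(i) {
      k <- n_eqtl[(i - 1) %% length(n_eqtl) + 1]
      th <- stats::runif(1, theta[1], theta[2])
      bx <- stats::rnorm(k, beta_eqtl, 0.05)
      set <- harmonized_set(
        data.frame(snp = sprintf("g%02d_eqtl%d", i, seq_len(k)),
                   beta_x = bx, se_x = 0.02,
                   beta_y = th * bx + stats::rnorm(k, 0, se_y), se_y = se_y,
                   stringsAsFactors = FALSE),
        exposure = sprintf("expression of gene%02d", i),
        outcome = "disease risk")
      attr(set, "truth") <- list(theta = th)
      set
    })
    names(out) <- sprintf("gene%02d", seq_len(n_genes))
    out
  })
}
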