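ALLELE_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

is_palindromic <- function(a1, a2) {
  !is.na(a1) & !is.na(a2) & ALLELE_COMPLEMENT[a1] == a2
}

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns the outcome effects to the exposure's effect allele, variant by
#' variant: when the outcome's allele labels are swapped the outcome beta is
#' sign-flipped (and its frequency mirrored); when the outcome is reported on
#' the opposite strand its alleles are complemented before matching. Variants
#' whose allele sets cannot be reconciled (e.g. A/G vs A/C) raise an error.
#' Multi-allelic records are excluded. Palindromic (A/T, C/G) variants, whose
#' strand cannot be resolved from allele labels, are retained only when the
#' minor allele frequency is at most `palindrome_maf` in *both* studies and
#' the allele frequencies are concordant (same minor-allele side) after
#' orientation; otherwise they are excluded with a machine-readable reason.
#'
#' @param exposure an `instrument_set` or [sumstats()]-like table for the
#'   exposure (columns `SNP`, `A1`, `A2`, `EAF`, `BETA`, `SE`).
#' @param outcome a [sumstats()]-like table for the outcome.
#' @param palindrome_maf inferability threshold for palindromic variants
#'   (default 0.42).
#' @param exposure_name,outcome_name,scale labels for the resulting set
#'   (scale defaults to the exposure attribute when present).
#' @return a [harmonized_set()]; excluded rows carry their reason and are
#'   ignored by estimators. Use [exclusion_counts()] for the report.
#' @export
harmonize_pair <- function(exposure, outcome, palindrome_maf = 0.42,
                           exposure_name = NULL, outcome_name = "outcome",
                           scale = NULL) {
  stopifnot(is.data.frame(exposure), is.data.frame(outcome))
  exposure_name <- exposure_name %||% attr(exposure, "trait") %||% "exposure"
  scale <- scale %||% attr(exposure, "scale") %||% "per_sd"
  shared <- intersect(exposure$SNP, outcome$SNP)
  if (length(shared) == 0) stop("no shared variant ids")
  ex <- exposure[match(shared, exposure$SNP), , drop = FALSE]
  ou <- outcome[match(shared, outcome$SNP), , drop = FALSE]

  n <- length(shared)
  beta_y <- ou$BETA; se_y <- ou$SE; eaf_y <- ou$EAF
  reason <- rep(NA_character_, n)
  bases <- names(ALLELE_COMPLEMENT)

  for (i in seq_len(n)) {
    ea1 <- ex$A1[i]; ea2 <- ex$A2[i]; oa1 <- ou$A1[i]; oa2 <- ou$A2[i]
    if (!all(c(ea1, ea2, oa1, oa2) %in% bases) || ea1 == ea2 || oa1 == oa2 ||
        sum(exposure$SNP == shared[i]) > 1 || sum(outcome$SNP == shared[i]) > 1) {
      reason[i] <- "multi_allelic"
      next
    }
    flip <- NA
    if (oa1 == ea1 && oa2 == ea2) flip <- FALSE
    else if (oa1 == ea2 && oa2 == ea1) flip <- TRUE
    else {
      ca1 <- unname(ALLELE_COMPLEMENT[oa1]); ca2 <- unname(ALLELE_COMPLEMENT[oa2])
      if (ca1 == ea1 && ca2 == ea2) flip <- FALSE
      else if (ca1 == ea2 && ca2 == ea1) flip <- TRUE
      else stop(sprintf("irreconcilable allele sets for %s: %s/%s vs %s/%s",
                        shared[i], ea1, ea2, oa1, oa2))
    }
    if (flip) {
      beta_y[i] <- -beta_y[i]
      if (!is.na(eaf_y[i])) eaf_y[i] <- 1 - eaf_y[i]
    }
    if (is_palindromic(ea1, ea2)) {
      maf_x <- min(ex$EAF[i], 1 - ex$EAF[i])
      maf_y <- min(eaf_y[i], 1 - eaf_y[i])
      if (is.na(maf_x) || is.na(maf_y) ||
          maf_x > palindrome_maf || maf_y > palindrome_maf) {
        reason[i] <- "palindromic_intermediate_maf"
      } else if ((ex$EAF[i] < 0.5) != (eaf_y[i] < 0.5)) {
        reason[i] <- "palindromic_freq_discordant"
      }
    }
  }

  harmonized_set(
    data.frame(snp = shared,
               chr = ex$CHR %||% rep(NA_integer_, n),
               pos = ex$POS %||% rep(NA_integer_, n),
               a1 = ex$A1, a2 = ex$A2,
               beta_x = ex$BETA, se_x = ex$SE,
               beta_y = beta_y, se_y = se_y,
               eaf_x = ex$EAF, eaf_y = eaf_y,
               excluded = reason, stringsAsFactors = FALSE),
    exposure = exposure_name, outcome = outcome_name, scale = scale)
}

#' Find an LD proxy for a variant missing from the outcome study
#'
#' Returns the panel variant with the highest LD to the missing variant among
#' those available in the outcome table, provided `r^2 > r2_threshold`
#' (default 0.90) within the window; ties are broken by smaller position.
#'
#' @param snp_id missing variant id (must be in the panel).
#' @param panel `genotype_panel` used as the LD reference.
#' @param available_ids variant ids present in the outcome table.
#' @param r2_threshold minimum (exclusive) proxy LD.
#' @param window_kb search window around the missing variant.
#' @return list with `proxy` and `r2`, or `NULL` when no proxy qualifies.
#' @export
find_proxy <- function(snp_id, panel, available_ids, r2_threshold = 0.90,
                       window_kb = 10000) {
  stopifnot(inherits(panel, "genotype_panel"))
  i <- match(snp_id, panel$snp)
  if (is.na(i)) stop("variant absent from panel: ", snp_id)
  cand <- which(panel$snp %in% setdiff(available_ids, snp_id) &
                  panel$chr == panel$chr[i] &
                  abs(panel$pos - panel$pos[i]) <= window_kb * 1000)
  if (length(cand) == 0) return(NULL)
  r2 <- as.vector(stats::cor(panel$dosage[, i],
                             panel$dosage[, cand, drop = FALSE])^2)
  ok <- r2 > r2_threshold
  if (!any(ok)) return(NULL)
  cand <- cand[ok]; r2 <- r2[ok]
  best <- order(-r2, panel$pos[cand])[1]
  list(proxy = panel$snp[cand[best]], r2 = r2[best])
}

#' Rescale a harmonized set to the reporting conventions
#'
#' Three modes: `"per_sd"` is the identity for z-scored exposures;
#' `"per_10pct_ratio"` re-expresses causal effects per 0.1-unit (10%) change
#' of a ratio phenotype measured in natural 0-1 units, by multiplying the
#' exposure effects (and their SEs) by 10 so that downstream `theta` is one
#' tenth of the per-unit effect; `"impairment"` orients every variant so the
#' effect allele *decreases* the exposure (all `beta_x >= 0` on the
#' impairment scale), jointly flipping the outcome effect -- applying it
#' twice returns the identical set.
#'
#' @param set a [harmonized_set()].
#' @param mode one of `"per_sd"`, `"per_10pct_ratio"`, `"impairment"`.
#' @return the rescaled `harmonized_set` (scale / sign-convention attributes
#'   updated).
#' @export
rescale_units <- function(set, mode = c("per_sd", "per_10pct_ratio",
                                        "impairment")) {
  stopifnot(inherits(set, "harmonized_set"))
  mode <- match.arg(mode)
  if (mode == "per_sd") return(set)
  if (mode == "per_10pct_ratio") {
    set$beta_x <- set$beta_x * 10
    set$se_x <- set$se_x * 10
    attr(set, "scale") <- "per_10pct_ratio"
    return(set)
  }
  # impairment: orient every variant to the exposure-*decreasing* allele and
  # report beta_x as the (positive) effect on impairment, flipping beta_y for
  # the variants whose orientation changed; already-oriented sets are
  # returned unchanged, so applying the mode twice yields the identical set
  if (identical(attr(set, "sign_convention"), "impairment")) return(set)
  flip <- set$beta_x > 0        # allele currently increases the exposure
  set$beta_y <- ifelse(flip, -set$beta_y, set$beta_y)
  a1_new <- ifelse(flip, set$a2, set$a1)
  set$a2 <- ifelse(flip, set$a1, set$a2)
  set$a1 <- a1_new
  set$eaf_x <- ifelse(flip, 1 - set$eaf_x, set$eaf_x)
  set$eaf_y <- ifelse(flip, 1 - set$eaf_y, set$eaf_y)
  set$beta_x <- abs(set$beta_x) # magnitude of the impairment effect
  attr(set, "sign_convention") <- "impairment"
  set
}
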