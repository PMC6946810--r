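#' Greedy LD clumping of association results
#'
#' Standard clumping: take the variant with the smallest p-value as an index,
#' discard all remaining variants on the same chromosome within the window
#' whose LD with the index is `r^2 >= r2_threshold`, and repeat until no
#' variants remain. Ties in p are broken by position, then id, so the output
#' is invariant to input row order.
#'
#' @param stats a [sumstats()] table (or data.frame with `SNP`, `CHR`, `POS`,
#'   `P`).
#' @param panel a `genotype_panel` covering the stats variants (LD reference).
#' @param r2_threshold LD pruning threshold (default 0.05).
#' @param window_kb clumping window in kb, applied as +/- around the index
#'   (default 10,000 kb).
#' @return character vector of index variant ids, in selection order.
#' @export
clump <- function(stats, panel, r2_threshold = 0.05, window_kb = 10000) {
  stopifnot(is.data.frame(stats), inherits(panel, "genotype_panel"))
  miss <- setdiff(stats$SNP, panel$snp)
  if (length(miss)) stop("variant(s) absent from panel: ",
                         paste(utils::head(miss, 5), collapse = ", "))
  ord <- order(stats$P, stats$POS, stats$SNP)
  s <- stats[ord, , drop = FALSE]
  active <- rep(TRUE, nrow(s))
  index <- character(0)
  win <- window_kb * 1000
  while (any(active)) {
    i <- which(active)[1]
    index <- c(index, s$SNP[i])
    active[i] <- FALSE
    cand <- which(active & s$CHR == s$CHR[i] & abs(s$POS - s$POS[i]) <= win)
    if (length(cand)) {
      r2 <- as.vector(stats::cor(panel$dosage[, s$SNP[i]],
                                 panel$dosage[, s$SNP[cand], drop = FALSE])^2)
      active[cand[r2 >= r2_threshold]] <- FALSE
    }
  }
  index
}

#' Two-stage instrument selection
#'
#' Selects genetic instruments from a discovery and a replication association
#' scan over shared variants: discovery hits at `p_discovery` (default
#' 5e-8) are LD-clumped (`r^2 < r2_threshold` within `window_kb`), and the
#' surviving index variants are retained only if they replicate at
#' `p_replication` (default 0.05) with a consistent direction of effect.
#'
#' Instrument weights default to the discovery-stage effects; replication is
#' used only for filtering, avoiding winner's-curse double-dipping. Set
#' `weights = "replication"` to weight by the replication effects instead
#' (which are free of selection bias but noisier).
#'
#' @param discovery,replication [sumstats()] tables indexed by shared ids.
#' @param panel LD reference `genotype_panel`.
#' @param p_discovery,p_replication selection thresholds.
#' @param r2_threshold,window_kb clumping parameters (see [clump()]).
#' @param weights `"discovery"` (default) or `"replication"`.
#' @param trait,scale labels carried into downstream metadata.
#' @return an `instrument_set`: data.frame of selected variants with both
#'   stages' effects plus the chosen working `BETA`/`SE`/`P`, and attributes
#'   recording thresholds, the weighting stage, and the trait/scale labels.
#' @export
select_instruments <- function(discovery, replication, panel,
                               p_discovery = 5e-8, p_replication = 0.05,
                               r2_threshold = 0.05, window_kb = 10000,
                               weights = c("discovery", "replication"),
                               trait = "exposure", scale = "per_sd") {
  weights <- match.arg(weights)
  hits <- discovery[discovery$P < p_discovery, , drop = FALSE]
  if (nrow(hits) == 0) {
    sel <- hits
  } else {
    idx <- clump(hits, panel, r2_threshold, window_kb)
    sel <- hits[match(idx, hits$SNP), , drop = FALSE]
  }
  miss <- setdiff(sel$SNP, replication$SNP)
  if (length(miss)) stop("variant(s) missing from replication table: ",
                         paste(utils::head(miss, 5), collapse = ", "))
  rep_rows <- replication[match(sel$SNP, replication$SNP), , drop = FALSE]
  keep <- rep_rows$P < p_replication &
    sign(rep_rows$BETA) == sign(sel$BETA) & rep_rows$BETA != 0
  sel <- sel[keep, , drop = FALSE]
  rep_rows <- rep_rows[keep, , drop = FALSE]
  out <- data.frame(
    SNP = sel$SNP, CHR = sel$CHR, POS = sel$POS, A1 = sel$A1, A2 = sel$A2,
    EAF = sel$EAF,
    BETA_DISC = sel$BETA, SE_DISC = sel$SE, P_DISC = sel$P, N_DISC = sel$N,
    BETA_REPL = rep_rows$BETA, SE_REPL = rep_rows$SE, P_REPL = rep_rows$P,
    N_REPL = rep_rows$N, stringsAsFactors = FALSE)
  out$BETA <- if (weights == "discovery") out$BETA_DISC else out$BETA_REPL
  out$SE <- if (weights == "discovery") out$SE_DISC else out$SE_REPL
  out$P <- if (weights == "discovery") out$P_DISC else out$P_REPL
  structure(out, class = c("instrument_set", "data.frame"),
            trait = trait, scale = scale, weights_stage = weights,
            p_discovery = p_discovery, p_replication = p_replication,
            r2_threshold = r2_threshold, window_kb = window_kb)
}

#' Instrument strength: variance explained and F-statistic
#'
#' Per-variant variance explained is approximated from an *independent*
#' (replication) sample as `r2_j = z_j^2 / (z_j^2 + n - 2)`; the set-level
#' `R^2` is their sum, and the F-statistic is
#' `F = R^2 (n - 1 - J) / ((1 - R^2) J)`.
#'
#' @param z per-variant z-statistics from the independent sample, or an
#'   `instrument_set` (whose replication z-scores and sample size are used).
#' @param n sample size of the independent sample (taken from the set when
#'   an `instrument_set` is supplied).
#' @return list with `r2_per_variant`, `R2`, `F`, `J`, `n`.
#' @examples
#' instrument_strength(z = 10, n = 10000)   # r2 ~ 0.0099, F ~ 99
#' @export
instrument_strength <- function(z, n = NULL) {
  if (inherits(z, "instrument_set")) {
    set <- z
    z <- set$BETA_REPL / set$SE_REPL
    n <- n %||% max(set$N_REPL)
  }
  if (is.null(n)) stop("`n` is required")
  J <- length(z)
  if (n <= J + 1) stop("n must exceed J + 1")
  r2j <- z^2 / (z^2 + n - 2)
  R2 <- sum(r2j)
  list(r2_per_variant = r2j, R2 = R2,
       F = R2 * (n - 1 - J) / ((1 - R2) * J), J = J, n = n)
}

#' Serialize an instrument set as TSV plus a JSON sidecar
#'
#' @param set an `instrument_set`.
#' @param path TSV path; a `.json` sidecar with the selection metadata
#'   (trait, scale, thresholds, weighting stage) is written alongside.
#' @export
write_instruments <- function(set, path) {
  stopifnot(inherits(set, "instrument_set"))
  utils::write.table(as.data.frame(set), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  meta <- attributes(set)[c("trait", "scale", "weights_stage", "p_discovery",
                            "p_replication", "r2_threshold", "window_kb")]
  jsonlite::write_json(meta, paste0(sub("\\.tsv$", "", path), ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
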