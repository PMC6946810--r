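#' Reproducibility QC for a single blow series
#'
#' Applies the standard spirometry reproducibility rule: individuals who only
#' completed one blow are excluded (reproducibility cannot be assessed); the
#' best measure is the maximum blow; non-best blows differing from the best
#' by more than 0.15 L are dropped as non-reproducible; the series passes if
#' at least one non-best blow is retained.
#'
#' @param volumes numeric vector of blow volumes (litres), all positive.
#' @param tolerance reproducibility tolerance in litres (default 0.15).
#' @return list with `pass`, `best`, `n_retained` (retained non-best blows).
#' @export
qc_blow_series <- function(volumes, tolerance = 0.15) {
  if (length(volumes) == 0) stop("empty blow series")
  if (any(!is.finite(volumes)) || any(volumes <= 0))
    stop("blow volumes must be positive")
  best <- max(volumes)
  if (length(volumes) == 1L)
    return(list(pass = FALSE, best = best, n_retained = 0L))
  others <- volumes[-which.max(volumes)]
  kept <- others[best - others <= tolerance]
  list(pass = length(kept) >= 1L, best = best, n_retained = length(kept))
}

#' Spirometry QC over a blow-series collection
#'
#' Applies [qc_blow_series()] per individual and per measure (FEV1 and FVC)
#' to the long-format blow table produced by [simulate_blows()].
#'
#' @param blows data.frame with columns `id`, `fev1`, `fvc` (one row per blow).
#' @param tolerance litres; see [qc_blow_series()].
#' @return data.frame with one row per individual: `id`, `n_blows`,
#'   `best_fev1`, `pass_fev1`, `best_fvc`, `pass_fvc`.
#' @export
qc_spirometry <- function(blows, tolerance = 0.15) {
  stopifnot(is.data.frame(blows), all(c("id", "fev1", "fvc") %in% names(blows)))
  if (nrow(blows) == 0) stop("empty blow series")
  ids <- unique(blows$id)
  res <- lapply(ids, function(i) {
    rows <- blows[blows$id == i, , drop = FALSE]
    q1 <- qc_blow_series(rows$fev1, tolerance)
    q2 <- qc_blow_series(rows$fvc, tolerance)
    data.frame(id = i, n_blows = nrow(rows),
               best_fev1 = q1$best, pass_fev1 = q1$pass,
               best_fvc = q2$best, pass_fvc = q2$pass)
  })
  do.call(rbind, res)
}

#' Derive analysis phenotypes from best spirometry measures
#'
#' Converts best FEV1 and FVC to standardized z-scores (mean 0, SD 1 over the
#' analysis sample), computes the untransformed FEV1/FVC ratio (bounded by 0
#' and 1), and flags airflow obstruction (COPD) as ratio < 0.70.
#'
#' @param best_fev1,best_fvc numeric vectors (litres), QC already applied.
#' @return data.frame with `fev1`, `fvc`, `fev1_z`, `fvc_z`, `ratio`, `copd`.
#' @examples
#' derive_phenotypes(c(2, 3), c(4, 3.8))
#' @export
derive_phenotypes <- function(best_fev1, best_fvc) {
  if (length(best_fev1) != length(best_fvc)) stop("length mismatch")
  if (any(best_fvc <= 0)) stop("FVC must be positive")
  if (any(best_fev1 <= 0)) stop("FEV1 must be positive")
  ratio <- best_fev1 / best_fvc
  if (any(ratio > 1 + 1e-12)) stop("FEV1/FVC ratio must lie in (0, 1]")
  zs <- function(v, name) {
    s <- stats::sd(v)
    if (length(v) < 2 || !is.finite(s) || s == 0)
      stop(sprintf("cannot z-standardize `%s`: zero variance", name))
    (v - mean(v)) / s
  }
  data.frame(fev1 = best_fev1, fvc = best_fvc,
             fev1_z = zs(best_fev1, "best_fev1"),
             fvc_z = zs(best_fvc, "best_fvc"),
             ratio = ratio, copd = ratio < 0.70)
}
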