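#' Construct a harmonized exposure/outcome effect set
#'
#' The lingua franca of the estimation stage: one row per variant with the
#' exposure effect (`beta_x`, `se_x`), the outcome effect on the same effect
#' allele (`beta_y`, `se_y`, log-odds for binary outcomes), allele labels and
#' frequencies, optional proxy metadata, and an optional machine-readable
#' exclusion reason. Rows with a non-`NA` `excluded` reason are retained for
#' reporting but ignored by estimators.
#'
#' @param data data.frame with at least `snp`, `beta_x`, `se_x`, `beta_y`,
#'   `se_y`; optional `a1`, `a2`, `eaf_x`, `eaf_y`, `chr`, `pos`, `proxy_of`,
#'   `proxy_r2`, `excluded`.
#' @param exposure,outcome trait names.
#' @param scale scale label for the exposure (e.g. `"per_sd"`,
#'   `"per_unit_ratio"`, `"per_10pct_ratio"`).
#' @param sign_convention `"trait-increasing"` or `"impairment"` (effects
#'   oriented to the exposure-decreasing allele).
#' @return object of class `harmonized_set` (a data.frame with attributes).
#' @export
harmonized_set <- function(data, exposure = "exposure", outcome = "outcome",
                           scale = "per_sd",
                           sign_convention = "trait-increasing") {
  need <- c("snp", "beta_x", "se_x", "beta_y", "se_y")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  for (col in c("a1", "a2")) if (is.null(data[[col]])) data[[col]] <- NA_character_
  for (col in c("eaf_x", "eaf_y", "proxy_r2")) if (is.null(data[[col]])) data[[col]] <- NA_real_
  if (is.null(data$proxy_of)) data$proxy_of <- NA_character_
  if (is.null(data$excluded)) data$excluded <- NA_character_
  ok <- is.na(data$excluded)
  if (any(data$se_x[ok] <= 0, na.rm = TRUE) || any(data$se_y[ok] < 0, na.rm = TRUE))
    stop("standard errors must be positive")
  structure(as.data.frame(data, stringsAsFactors = FALSE),
            exposure = exposure, outcome = outcome, scale = scale,
            sign_convention = sign_convention,
            class = c("harmonized_set", "data.frame"))
}

# rows usable for estimation (not excluded), with a minimum-count check
hm_data <- function(set, min_j = 1L, caller = "estimator") {
  if (!inherits(set, "harmonized_set")) {
    if (is.data.frame(set)) set <- harmonized_set(set) else
      stop("expected a harmonized_set")
  }
  d <- set[is.na(set$excluded), , drop = FALSE]
  if (nrow(d) < min_j)
    stop(sprintf("%s requires at least %d usable instruments (have %d)",
                 caller, min_j, nrow(d)))
  d
}

#' Count excluded variants by reason
#' @param set a `harmonized_set`.
#' @return named integer vector of exclusion reasons (possibly empty).
#' @export
exclusion_counts <- function(set) {
  stopifnot(inherits(set, "harmonized_set"))
  table(set$excluded[!is.na(set$excluded)])
}

#' @export
print.harmonized_set <- function(x, ...) {
  kept <- sum(is.na(x$excluded))
  cat(sprintf("harmonized_set: %s -> %s (%s scale), %d variants (%d usable, %d excluded)\n",
              attr(x, "exposure"), attr(x, "outcome"), attr(x, "scale"),
              nrow(x), kept, nrow(x) - kept))
  NextMethod()
}
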