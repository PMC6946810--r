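#' Assemble and validate a GWAS summary-statistics table
#'
#' The per-variant association record used throughout the pipeline. Columns
#' follow the common tab-delimited exchange convention: `SNP`, `CHR`, `POS`
#' (1-based bp), `A1` (effect allele), `A2` (other allele), `EAF`
#' (effect-allele frequency), `BETA` (per-allele effect in trait units),
#' `SE`, `P`, `N`.
#'
#' @param data data.frame carrying the columns above.
#' @return the validated data.frame with class `sumstats`.
#' @export
sumstats <- function(data) {
  need <- c("SNP", "CHR", "POS", "A1", "A2", "EAF", "BETA", "SE", "P", "N")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  data <- as.data.frame(data, stringsAsFactors = FALSE)[, need]
  if (any(!is.na(data$SE) & data$SE <= 0)) stop("SE must be > 0")
  if (any(!is.na(data$P) & (data$P <= 0 | data$P > 1))) stop("P must lie in (0, 1]")
  if (any(!is.na(data$EAF) & (data$EAF <= 0 | data$EAF >= 1)))
    stop("EAF must lie in (0, 1)")
  class(data) <- c("sumstats", "data.frame")
  data
}

#' Read / write tab-delimited summary statistics
#'
#' @param path file path.
#' @return `read_sumstats` returns a validated `sumstats` data.frame.
#' @export
read_sumstats <- function(path) {
  sumstats(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' @rdname read_sumstats
#' @param stats a `sumstats` table (or coercible data.frame).
#' @export
write_sumstats <- function(stats, path) {
  stats <- sumstats(stats)
  utils::write.table(stats, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
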