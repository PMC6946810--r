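#' Simulate a genotype dosage panel with block LD structure
#'
#' Generates an individuals-by-variants dosage matrix under Hardy-Weinberg
#' equilibrium with linkage disequilibrium (LD) confined to fixed-size blocks.
#' Within a block, adjacent variants follow an autoregressive correlation
#' structure: the dosage correlation between neighbours is calibrated to
#' `rho` by generating two independent latent Gaussian haplotypes per
#' individual and thresholding them at the allele-frequency quantile
#' (a Gaussian copula). The latent adjacent correlation is chosen by
#' inverting the tetrachoric relation so that the *observed* dosage
#' correlation matches `rho`; when allele frequencies of a pair differ the
#' attainable correlation is bounded above (Frechet bounds) and the latent
#' correlation is capped.
#'
#' Variants in different blocks are independent. Positions are evenly spaced
#' (default 50 kb) on one chromosome so that a block always falls well inside
#' a 10,000 kb clumping window.
#'
#' @param n number of individuals.
#' @param m number of variants.
#' @param block_size variants per LD block.
#' @param maf_range length-2 numeric, minor allele frequencies are drawn
#'   uniformly from this interval; must lie within (0, 0.5].
#' @param rho target adjacent-variant dosage correlation within a block,
#'   `|rho| < 1`.
#' @param seed integer seed; the panel is a pure function of the arguments.
#' @param chromosome chromosome label for all variants.
#' @param spacing_bp base pairs between adjacent variants (positions are
#'   1-based).
#' @return an object of class `genotype_panel`: a list with `snp`, `chr`,
#'   `pos`, `a1`, `a2`, `maf` (target frequencies), `block`, and `dosage`
#'   (an `n` x `m` matrix with values in 0..2, columns named by variant id).
#' @examples
#' p <- simulate_genotype_panel(200, 20, block_size = 5, rho = 0.8, seed = 1)
#' dim(p$dosage)
#' @export
simulate_genotype_panel <- function(n, m, block_size = 10,
                                    maf_range = c(0.05, 0.5), rho = 0.8,
                                    seed = 1, chromosome = 1L,
                                    spacing_bp = 50000) {
  n <- assert_scalar_count(n, "n")
  m <- assert_scalar_count(m, "m")
  block_size <- assert_scalar_count(block_size, "block_size")
  if (length(maf_range) != 2L || any(!is.finite(maf_range)) ||
      maf_range[1] > maf_range[2] || maf_range[1] <= 0 || maf_range[2] > 0.5)
    stop("`maf_range` must be an interval within (0, 0.5]")
  if (!is.finite(rho) || abs(rho) >= 1) stop("|rho| must be < 1")

  with_seed(seed, {
    maf <- stats::runif(m, maf_range[1], maf_range[2])
    block <- rep(seq_len(ceiling(m / block_size)), each = block_size)[seq_len(m)]
    q <- stats::qnorm(maf)

    # latent adjacent correlation per within-block pair (entry j links j-1, j)
    rho_lat <- numeric(m)
    if (abs(rho) > 0) {
      for (j in seq_len(m)[-1]) {
        if (block[j] == block[j - 1L])
          rho_lat[j] <- latent_cor_for_target(rho, maf[j - 1L], maf[j])
      }
    }

    draw_haplotype <- function() {
      w <- matrix(stats::rnorm(n * m), n, m)
      z <- w
      for (j in seq_len(m)[-1]) {
        r <- rho_lat[j]
        if (block[j] == block[j - 1L] && r != 0)
          z[, j] <- r * z[, j - 1L] + sqrt(1 - r^2) * w[, j]
      }
      z < rep(q, each = n)
    }
    dosage <- draw_haplotype() + draw_haplotype()
    storage.mode(dosage) <- "double"

    # guard against monomorphic columns at small n: redraw independently
    mono <- which(apply(dosage, 2, function(g) var(g) == 0))
    for (j in mono) dosage[, j] <- stats::rbinom(n, 2L, maf[j])

    bases <- c("A", "C", "G", "T")
    a1 <- sample(bases, m, replace = TRUE)
    a2 <- vapply(a1, function(b) sample(setdiff(bases, b), 1L), character(1))

    snp <- sprintf("rs%05d", seq_len(m))
    colnames(dosage) <- snp
    structure(
      list(snp = snp, chr = rep(as.integer(chromosome), m),
           pos = as.integer(seq_len(m)) * as.integer(spacing_bp),
           a1 = a1, a2 = unname(a2), maf = maf, block = block,
           dosage = dosage, n = n, m = m, rho = rho, seed = seed),
      class = "genotype_panel")
  })
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("genotype_panel: %d individuals x %d variants, %d LD blocks (rho = %.2f)\n",
              x$n, x$m, length(unique(x$block)), x$rho))
  invisible(x)
}

#' Pairwise LD (r-squared) between panel variants
#'
#' @param panel a `genotype_panel`.
#' @param ids1,ids2 variant ids (columns of the dosage matrix).
#' @return matrix of squared Pearson correlations between dosages.
#' @export
panel_r2 <- function(panel, ids1, ids2 = ids1) {
  stopifnot(inherits(panel, "genotype_panel"))
  miss <- setdiff(c(ids1, ids2), panel$snp)
  if (length(miss)) stop("variant(s) absent from panel: ", paste(miss, collapse = ", "))
  stats::cor(panel$dosage[, ids1, drop = FALSE],
             panel$dosage[, ids2, drop = FALSE])^2
}
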