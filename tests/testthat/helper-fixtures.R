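# shared test fixtures, all built in code

# minimal sumstats data.frame
make_stats <- function(snp, p, beta = 1, se = 0.1, chr = 1,
                       pos = seq_along(snp) * 1000, a1 = "A", a2 = "G",
                       eaf = 0.3, n = 1000) {
  sumstats(data.frame(SNP = snp, CHR = chr, POS = pos, A1 = a1, A2 = a2,
                      EAF = eaf, BETA = beta, SE = se, P = p, N = n,
                      stringsAsFactors = FALSE))
}

# harmonized set straight from effect vectors
make_hset <- function(beta_x, beta_y, se_x = 1e-12, se_y = 0.1,
                      snp = sprintf("s%03d", seq_along(beta_x))) {
  harmonized_set(data.frame(snp = snp, beta_x = beta_x, se_x = se_x,
                            beta_y = beta_y, se_y = se_y,
                            stringsAsFactors = FALSE))
}

# independent HWE exact-test oracle: direct enumeration of every
# heterozygote class with log-factorial probabilities (no recurrence)
hwe_oracle <- function(n_hom1, n_het, n_hom2) {
  n <- n_hom1 + n_het + n_hom2
  na <- 2 * n_hom1 + n_het
  nb <- 2 * n_hom2 + n_het
  hets <- seq(min(na, nb) %% 2, min(na, nb), by = 2)
  logp <- sapply(hets, function(h) {
    ha <- (na - h) / 2; hb <- (nb - h) / 2
    lfactorial(n) - lfactorial(ha) - lfactorial(h) - lfactorial(hb) +
      h * log(2) + lfactorial(na) + lfactorial(nb) - lfactorial(2 * n)
  })
  p <- exp(logp - max(logp)); p <- p / sum(p)
  obs <- p[match(n_het, hets)]
  min(1, sum(p[p <= obs * (1 + 1e-10)]))
}

# brute-force clumping oracle: greedy over the full r2 matrix
clump_oracle <- function(stats, panel, r2 = 0.05, window_kb = 10000) {
  ord <- order(stats$P, stats$POS, stats$SNP)
  s <- stats[ord, ]
  R2 <- panel_r2(panel, s$SNP)
  active <- rep(TRUE, nrow(s))
  keep <- character(0)
  while (any(active)) {
    i <- which(active)[1]
    keep <- c(keep, s$SNP[i])
    active[i] <- FALSE
    near <- abs(s$POS - s$POS[i]) <= window_kb * 1000 & s$CHR == s$CHR[i]
    active[active & near & R2[i, ] >= r2] <- FALSE
  }
  keep
}
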