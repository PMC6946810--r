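# internal helpers shared across modules

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the random-number generator seeded at `seed`, restoring
#' the caller's RNG state afterwards so that library calls never perturb a
#' user's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# standard bivariate normal CDF P(Z1 < a, Z2 < b) with correlation rho,
# by conditioning on Z1 and integrating (adequate for |a|,|b| <= 8)
pbvnorm <- function(a, b, rho) {
  if (abs(rho) < 1e-12) return(stats::pnorm(a) * stats::pnorm(b))
  if (abs(rho) > 1 - 1e-9) {
    if (rho > 0) return(stats::pnorm(min(a, b)))
    return(max(0, stats::pnorm(a) - stats::pnorm(-b)))
  }
  s <- sqrt(1 - rho^2)
  f <- function(z) stats::pnorm((b - rho * z) / s) * stats::dnorm(z)
  stats::integrate(f, -9, a, rel.tol = 1e-9, abs.tol = 1e-12)$value
}

# correlation of two binary indicators 1{Z1 < qnorm(p1)}, 1{Z2 < qnorm(p2)}
# induced by latent correlation rho
binary_cor_from_latent <- function(rho, p1, p2) {
  (pbvnorm(stats::qnorm(p1), stats::qnorm(p2), rho) - p1 * p2) /
    sqrt(p1 * (1 - p1) * p2 * (1 - p2))
}

# invert the tetrachoric relation: latent correlation that yields a target
# binary correlation for margins (p1, p2); capped at +/-0.9999 because the
# attainable binary correlation is bounded by the Frechet limits
latent_cor_for_target <- function(target, p1, p2) {
  if (abs(target) < 1e-12) return(0)
  cap <- 0.9999
  hi <- binary_cor_from_latent(cap, p1, p2)
  lo <- binary_cor_from_latent(-cap, p1, p2)
  if (target >= hi) return(cap)
  if (target <= lo) return(-cap)
  stats::uniroot(function(r) binary_cor_from_latent(r, p1, p2) - target,
                 lower = -cap, upper = cap, tol = 1e-6)$root
}

assert_scalar_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 || x != floor(x))
    stop(sprintf("`%s` must be a positive integer", name), call. = FALSE)
  as.integer(x)
}

assert_fraction <- function(x, name, open = c(FALSE, FALSE)) {
  lo_ok <- if (open[1]) x > 0 else x >= 0
  hi_ok <- if (open[2]) x < 1 else x <= 1
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || !lo_ok || !hi_ok)
    stop(sprintf("`%s` must be a fraction in %s0, 1%s", name,
                 if (open[1]) "(" else "[", if (open[2]) ")" else "]"),
         call. = FALSE)
  as.numeric(x)
}
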