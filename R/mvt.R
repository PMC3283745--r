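# Multivariate t / normal box probabilities with a fixed integration seed.
#
# Genz-Bretz quasi-Monte-Carlo integration consumes R's RNG stream; to make
# every p-value and quantile reproducible (and independent of how many
# probabilities a simulation has already computed), each call runs under a
# fixed seed and restores the caller's RNG state afterwards.

mvt_seed <- function() getOption("moirank.mvt_seed", 20120221L)

with_preserved_rng <- function(code) {
  ge <- globalenv()
  had <- exists(".Random.seed", envir = ge, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = ge, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = ge)
    else if (exists(".Random.seed", envir = ge, inherits = FALSE)) {
      rm(".Random.seed", envir = ge)
    }
  }, add = TRUE)
  force(code)
}

# P(lower <= T <= upper) for central multivariate t(df, corr); df = Inf gives
# the multivariate normal. df is rounded to an integer (required by the
# integration routine); singular correlation matrices are supported (the
# contrast correlation always is singular: three statistics, two degrees of
# freedom in the effect vector). Integration precision is configurable via
# options(moirank.mvt_abseps = ...); the default 1e-4 matches the precision
# the procedure reports.
mvt_prob <- function(lower, upper, corr, df = Inf,
                     abseps = getOption("moirank.mvt_abseps", 1e-4)) {
  alg <- mvtnorm::GenzBretz(abseps = abseps, maxpts = 50000L)
  with_preserved_rng({
    set.seed(mvt_seed())
    p <- if (is.finite(df)) {
      mvtnorm::pmvt(lower = lower, upper = upper,
                    df = max(1L, as.integer(round(df))),
                    corr = corr, algorithm = alg)
    } else {
      mvtnorm::pmvnorm(lower = lower, upper = upper, corr = corr,
                       algorithm = alg)
    }
    min(1, max(0, as.numeric(p)))
  })
}

#' Equicoordinate quantile of a central multivariate t distribution
#'
#' The smallest z with P(max_q |T_q| <= z) = 1 - alpha (two-sided) or
#' P(max_q T_q <= z) = 1 - alpha (one-sided) under a central multivariate
#' t(df, corr); `df = Inf` uses the multivariate normal. This is the common
#' critical value of the max-T multiple contrast test and of the
#' simultaneous confidence intervals.
#'
#' @param corr Correlation matrix of the test statistics (symmetric, unit
#'   diagonal; may be singular, e.g. perfectly correlated contrasts).
#' @param df Degrees of freedom; `Inf` for the normal approximation.
#' @param alpha Familywise level in (0, 1).
#' @param two_sided Use the two-sided (absolute-value) form; default TRUE.
#' @param tol Root-finding tolerance on z.
#' @return A single quantile z.
#' @details The quantile is found by bracketed root search: the marginal
#'   quantile (attained under perfect correlation) is a lower bound and the
#'   Bonferroni quantile an upper bound, so about ten box-probability
#'   evaluations suffice. Probabilities use deterministic-seeded
#'   quasi-Monte-Carlo integration, making the quantile reproducible to the
#'   stated tolerance.
#' @examples
#' equicoordinate_quantile(diag(3), df = Inf, alpha = 0.05) # ~2.3877
#' @export
equicoordinate_quantile <- function(corr, df = Inf, alpha = 0.05,
                                    two_sided = TRUE, tol = 1e-4) {
  corr <- as.matrix(corr)
  k <- nrow(corr)
  if (!isTRUE(all.equal(diag(corr), rep(1, k), tolerance = 1e-8)) ||
      any(abs(corr) > 1 + 1e-8) || any(abs(corr - t(corr)) > 1e-8)) {
    stop("invalid correlation matrix", call. = FALSE)
  }
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  qfun <- if (is.finite(df)) {
    function(p) stats::qt(p, df = max(1, round(df)))
  } else {
    stats::qnorm
  }
  prob <- function(z) {
    lo <- if (two_sided) rep(-z, k) else rep(-Inf, k)
    mvt_prob(lo, rep(z, k), corr = corr, df = df)
  }
  side <- if (two_sided) 2 else 1
  lower <- qfun(1 - alpha / side)          # perfect-correlation limit
  upper <- qfun(1 - alpha / (side * k))    # Bonferroni bound
  f <- function(z) prob(z) - (1 - alpha)
  stats::uniroot(f, lower = lower - 1e-3, upper = upper + 1e-3,
                 extendInt = "upX", tol = tol)$root
}

# Max-T adjusted p-value for an observed statistic t_obs (two-sided):
# 1 - P(max_r |T_r| <= |t_obs|).
mvt_adjusted_p <- function(t_obs, corr, df = Inf) {
  t_obs <- abs(t_obs)
  if (t_obs == 0) return(1)
  k <- nrow(corr)
  1 - mvt_prob(rep(-t_obs, k), rep(t_obs, k), corr = corr, df = df)
}
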