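#' Two-locus haplotype frequencies under linkage disequilibrium
#'
#' Frequencies of the four haplotypes formed by the risk allele at the trait
#' locus (frequency `q1`) and at the genotyped marker (frequency `q2`) with
#' linkage-disequilibrium coefficient `delta` (deviation of the risk-risk
#' haplotype frequency from the product `q1 * q2`).
#'
#' @param q1,q2 Risk-allele frequencies in (0, 1).
#' @param delta LD coefficient; must lie in
#'   \[max(-q1 q2, -(1-q1)(1-q2)), min(q1 (1-q2), (1-q1) q2)\].
#' @return Named numeric vector of the four haplotype frequencies
#'   (risk/risk, risk/other, other/risk, other/other); non-negative,
#'   summing to 1.
#' @examples
#' haplotype_frequencies(0.3, 0.3, 0)     # independence products
#' haplotype_frequencies(0.3, 0.3, 0.09)  # 0.18 0.12 0.12 0.58
#' @export
haplotype_frequencies <- function(q1, q2, delta) {
  if (any(c(q1, q2) <= 0) || any(c(q1, q2) >= 1)) {
    stop("allele frequencies must lie in (0, 1)", call. = FALSE)
  }
  lo <- max(-q1 * q2, -(1 - q1) * (1 - q2))
  hi <- min(q1 * (1 - q2), (1 - q1) * q2)
  if (delta < lo - 1e-12 || delta > hi + 1e-12) {
    stop(sprintf("delta = %g outside the feasible interval [%g, %g] for q1 = %g, q2 = %g",
                 delta, lo, hi, q1, q2), call. = FALSE)
  }
  h <- c(rr = q1 * q2 + delta,
         rR = q1 * (1 - q2) - delta,
         Rr = (1 - q1) * q2 - delta,
         RR = (1 - q1) * (1 - q2) + delta)
  pmax(h, 0) / sum(pmax(h, 0))
}

#' Maximum feasible LD coefficient
#'
#' @param q1,q2 Risk-allele frequencies.
#' @return `min(q1 (1 - q2), (1 - q1) q2)`, the upper end of the feasible
#'   `delta` interval (positive LD).
#' @export
delta_max <- function(q1, q2) min(q1 * (1 - q2), (1 - q1) * q2)

#' Simulation scenario for the genotype-phenotype study
#'
#' Bundles the parameters of one simulation condition: a quantitative trait
#' controlled by an unobserved trait locus, tested at a genotyped marker in
#' LD with it.
#'
#' @param N Number of subjects.
#' @param q1 Risk-allele frequency at the trait locus.
#' @param q2 Allele frequency at the marker.
#' @param delta LD coefficient between the two loci.
#' @param h2 Fraction of phenotypic variance explained by the trait locus,
#'   in \[0, 1); `h2 = 0` yields the global null (type-I error studies).
#' @param mode Mode of inheritance at the trait locus: `"additive"`,
#'   `"dominant"` or `"recessive"`.
#' @param dist Trait distribution: `"normal"` or `"lognormal"` (the
#'   log-normal trait is a strictly increasing transform of the normal one,
#'   generated from the same draws).
#' @param sigma2 Residual variance (default 1).
#' @param reps Number of simulation replicates.
#' @param seed RNG seed for [run_study()].
#' @return A `moi_scenario` object (validated list).
#' @export
moi_scenario <- function(N, q1, q2, delta, h2 = 0,
                         mode = c("additive", "dominant", "recessive"),
                         dist = c("normal", "lognormal"),
                         sigma2 = 1, reps = 1000L, seed = 1L) {
  mode <- match.arg(mode)
  dist <- match.arg(dist)
  haplotype_frequencies(q1, q2, delta)  # validates q1, q2, delta
  if (h2 < 0 || h2 >= 1) stop("h2 must lie in [0, 1)", call. = FALSE)
  if (sigma2 <= 0) stop("sigma2 must be positive", call. = FALSE)
  structure(list(N = as.integer(N), q1 = q1, q2 = q2, delta = delta,
                 h2 = h2, mode = mode, dist = dist, sigma2 = sigma2,
                 reps = as.integer(reps), seed = as.integer(seed)),
            class = "moi_scenario")
}

#' @export
print.moi_scenario <- function(x, ...) {
  cat(sprintf("<moi_scenario> N = %d, q1 = %g, q2 = %g, delta = %g, h2 = %g,\n  mode = %s, dist = %s, sigma2 = %g, reps = %d, seed = %d\n",
              x$N, x$q1, x$q2, x$delta, x$h2, x$mode, x$dist, x$sigma2,
              x$reps, x$seed))
  invisible(x)
}

#' Draw genotypes at the trait locus and the marker
#'
#' Each subject receives two haplotypes drawn independently from the
#' four-cell haplotype distribution (random mating, so marker genotypes
#' follow Hardy-Weinberg proportions of `q2`); the genotype at each locus
#' is the number of risk-allele copies carried.
#'
#' @param scenario A [moi_scenario()] (or any list with `N`, `q1`, `q2`,
#'   `delta`).
#' @return List with integer vectors `trait` and `marker`, each in
#'   \{0, 1, 2\}. Uses the current RNG stream.
#' @export
draw_genotypes <- function(scenario) {
  h <- haplotype_frequencies(scenario$q1, scenario$q2, scenario$delta)
  hap <- sample.int(4L, size = 2L * scenario$N, replace = TRUE, prob = h)
  hap <- matrix(hap, ncol = 2L)
  # haplotypes 1, 2 carry the risk allele at the trait locus; 1, 3 at the marker
  list(trait = rowSums(hap <= 2L),
       marker = rowSums(hap == 1L | hap == 3L))
}

#' Genotypic values for a given mode of inheritance and variance explained
#'
#' Returns the means (mu_aa, mu_aA, mu_AA) of the trait given the genotype
#' at the trait locus: additive (0, a, 2a), dominant (0, a, a), recessive
#' (0, 0, a), with `a` scaled so that the genetic variance under
#' Hardy-Weinberg frequencies at `q1` explains the fraction `h2` of the
#' total variance: Vg / (Vg + sigma2) = h2.
#'
#' @param mode `"additive"`, `"dominant"` or `"recessive"`.
#' @param h2 Variance explained, in \[0, 1).
#' @param q1 Risk-allele frequency at the trait locus.
#' @param sigma2 Residual variance.
#' @return Numeric length-3 vector of genotypic means.
#' @examples
#' genotypic_values("additive", 0.5, 0.5, 1) # 0, sqrt(2), 2 sqrt(2)
#' @export
genotypic_values <- function(mode = c("additive", "dominant", "recessive"),
                             h2, q1, sigma2 = 1) {
  mode <- match.arg(mode)
  if (h2 < 0 || h2 >= 1) stop("h2 must lie in [0, 1)", call. = FALSE)
  if (h2 == 0) return(c(0, 0, 0))
  f <- c((1 - q1)^2, 2 * q1 * (1 - q1), q1^2)  # HWE genotype frequencies
  pattern <- switch(mode,
                    additive  = c(0, 1, 2),
                    dominant  = c(0, 1, 1),
                    recessive = c(0, 0, 1))
  vg1 <- sum(f * pattern^2) - sum(f * pattern)^2  # genetic variance at a = 1
  a <- sqrt(h2 * sigma2 / ((1 - h2) * vg1))
  a * pattern
}

#' Draw phenotypes from genotypic values
#'
#' Normal traits are Y = mu_g + e with e ~ N(0, sigma2). Log-normal traits
#' apply the quantile-transform X = Q_LN(Phi(Y)) with Phi the standard
#' normal CDF and Q_LN the standard log-normal quantile function -- a
#' strictly increasing transform of Y, so all rank-based results coincide
#' with the normal case by construction while parametric procedures face a
#' skewed, variance-heterogeneous trait.
#'
#' @param trait_genotypes Integer vector in \{0, 1, 2\} (trait locus).
#' @param values Genotypic means from [genotypic_values()].
#' @param dist `"normal"` or `"lognormal"`.
#' @param sigma2 Residual variance.
#' @return Numeric trait vector. Uses the current RNG stream.
#' @export
draw_phenotypes <- function(trait_genotypes, values,
                            dist = c("normal", "lognormal"), sigma2 = 1) {
  dist <- match.arg(dist)
  y <- values[trait_genotypes + 1L] +
    stats::rnorm(length(trait_genotypes), sd = sqrt(sigma2))
  if (dist == "lognormal") stats::qlnorm(stats::pnorm(y)) else y
}
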