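#' Mid-ranks of a numeric vector
#'
#' Ranks with ties replaced by the average of the spanned ranks; this is the
#' ranking implied by the normalized (mid) empirical distribution function
#' F(x) = (#\{< x\} + 1/2 #\{= x\}) / n, which the whole package uses so that
#' ordered-categorical scores and detection-limit spikes need no continuity
#' correction.
#'
#' @param x Numeric vector, finite, non-empty.
#' @return Numeric vector of mid-ranks; their sum is always m(m+1)/2.
#' @examples
#' midranks(c(10, 20, 20, 30)) # 1, 2.5, 2.5, 4
#' @export
midranks <- function(x) {
  if (length(x) == 0L) stop("empty vector has no ranks", call. = FALSE)
  if (!is.numeric(x) || !all(is.finite(x))) {
    stop("mid-ranks require finite numeric values", call. = FALSE)
  }
  rank(x, ties.method = "average")
}

# Normalized EDF of `sample` evaluated at `at`:
# F(x) = (#{sample < x} + 1/2 #{sample = x}) / length(sample).
# Uses the mid-rank identity F(at_k) = (R_pooled - R_within) / n, valid under
# ties, which keeps the evaluation O((n+m) log(n+m)).
edf_at <- function(sample, at) {
  n <- length(sample)
  m <- length(at)
  pooled <- midranks(c(sample, at))[n + seq_len(m)]
  within <- midranks(at)
  (pooled - within) / n
}

#' Placements of one sample within another
#'
#' Evaluates the normalized empirical distribution function of `sample_j` at
#' every observation of `sample_i`, i.e. the relative position of each
#' `sample_i` value within group j. Placements are the building blocks of
#' two-sample relative effects and of the covariance estimator.
#'
#' @param sample_i,sample_j Non-empty numeric vectors.
#' @return Numeric vector of length `length(sample_i)` with values in
#'   \[0, 1\].
#' @examples
#' pairwise_placements(c(1, 3), c(2, 4)) # 0, 0.5
#' @export
pairwise_placements <- function(sample_i, sample_j) {
  if (length(sample_i) == 0L || length(sample_j) == 0L) {
    stop("placements need two non-empty samples", call. = FALSE)
  }
  edf_at(sample_j, sample_i)
}

#' Two-sample relative effect
#'
#' Estimates w_ij = P(X_i < X_j) + 1/2 P(X_i = X_j), the probability that a
#' random observation from group i is smaller than one from group j, counting
#' ties half. Equals the Mann-Whitney U statistic (with 1/2 for ties) divided
#' by n_i * n_j, and satisfies w_ij + w_ji = 1.
#'
#' @param sample_i,sample_j Non-empty numeric vectors.
#' @return A single number in \[0, 1\].
#' @examples
#' pairwise_effect(c(1, 2), c(3, 4)) # 1: complete separation
#' pairwise_effect(c(1, 1), c(1, 2)) # 0.75
#' @export
pairwise_effect <- function(sample_i, sample_j) {
  mean(pairwise_placements(sample_j, sample_i))
}

#' Pseudo-ranks of a grouped sample
#'
#' Ranks computed against the unweighted mean distribution
#' G = (F1 + F2 + F3)/3 rather than the pooled sample:
#' psi_ik = 1/2 + N * G(X_ik). In a balanced design (n1 = n2 = n3) they
#' coincide exactly with the usual global mid-ranks; under unbalance they
#' remove the implicit sample-size weighting of global ranks.
#'
#' @param grouped A [grouped_sample()].
#' @return Numeric vector of length N, in the order of the flattened groups
#'   (group 1 first).
#' @export
pseudo_ranks <- function(grouped) {
  gs <- as_grouped_sample(grouped)
  flat <- gs_flatten(gs)
  G <- rowMeans(vapply(gs$groups, edf_at, numeric(gs$N), at = flat$values))
  0.5 + gs$N * G
}

#' Unweighted relative effects of the three genotype groups
#'
#' Estimates p_i = P(Z < X_i) + 1/2 P(Z = X_i) where Z is drawn from the
#' unweighted mean distribution G = (F1 + F2 + F3)/3: a rank-based effect
#' measure for each genotype group against the "average" genotype. The
#' estimates always satisfy p1 + p2 + p3 = 3/2 and are invariant under
#' strictly increasing transformations of the trait.
#'
#' @param grouped A [grouped_sample()].
#' @return An object of class `rel_effects`: list with `p_hat` (length-3
#'   effect vector), `w_hat` (3x3 matrix of two-sample effects, diagonal
#'   1/2), `pseudo_ranks`, `n`, `N`. Covariance slots (`V_hat`,
#'   `group_contrib`) are filled by [effect_covariance()].
#' @examples
#' gs <- as_grouped_sample(list(c(1, 2), c(3, 4), c(5, 6)))
#' estimate_effects(gs)$p_hat # 1/6, 1/2, 5/6
#' @export
estimate_effects <- function(grouped) {
  gs <- as_grouped_sample(grouped)
  psi <- pseudo_ranks(gs)
  grp <- rep.int(seq_len(3L), gs$n)
  p_hat <- as.numeric(tapply(psi, grp, mean) - 0.5) / gs$N

  w_hat <- diag(3) * 0.5
  for (i in 1:2) {
    for (j in (i + 1):3) {
      w <- pairwise_effect(gs$groups[[i]], gs$groups[[j]])
      w_hat[i, j] <- w
      w_hat[j, i] <- 1 - w
    }
  }
  structure(
    list(p_hat = p_hat, w_hat = w_hat, pseudo_ranks = psi,
         V_hat = NULL, group_contrib = NULL, n = gs$n, N = gs$N),
    class = "rel_effects"
  )
}

#' @export
print.rel_effects <- function(x, digits = 4, ...) {
  cat("<rel_effects> p_hat = (", paste(round(x$p_hat, digits), collapse = ", "),
      ")  N =", x$N, "\n")
  if (!is.null(x$V_hat)) {
    cat("  V_hat (covariance of sqrt(N)(p_hat - p)):\n")
    print(round(x$V_hat, digits))
  }
  invisible(x)
}

#' Covariance of the relative-effect estimator
#'
#' Estimates V_N = Cov(sqrt(N) (p_hat - p)) through the asymptotic influence
#' decomposition of the pseudo-rank estimator: for subject k of group g the
#' influence on effect m is
#' \deqn{u^{(m)}_{gk} = \frac{1}{3}\sum_{j \ne m} (F_j(X_{mk}) - w_{jm})
#'   \quad (g = m), \qquad
#'   u^{(m)}_{gk} = -\frac{1}{3} (F_m(X_{gk}) - w_{mg}) \quad (g \ne m),}
#' with all distribution functions in their normalized (mid) version, and
#' \deqn{\hat V_N[m, m'] = N \sum_g \frac{1}{n_g (n_g - 1)}
#'   \sum_k u^{(m)}_{gk} u^{(m')}_{gk}.}
#' The construction is tie-robust and reduces to the standard Brunner-type
#' two-sample variance estimator. Because p1 + p2 + p3 is constant, every
#' row of V_N sums to zero.
#'
#' @param grouped A [grouped_sample()].
#' @param effects The [estimate_effects()] result for the same sample; if
#'   missing it is computed.
#' @return The `rel_effects` object with `V_hat` (3x3, positive
#'   semidefinite) and `group_contrib` (list of three 3x3 per-group
#'   contributions summing to `V_hat`) filled in.
#' @export
effect_covariance <- function(grouped, effects = NULL) {
  gs <- as_grouped_sample(grouped)
  if (any(gs$n < 2L)) {
    stop("variance not estimable: every genotype group needs at least 2 observations (n = ",
         paste(gs$n, collapse = ", "), ")", call. = FALSE)
  }
  if (is.null(effects)) effects <- estimate_effects(gs)
  stopifnot(inherits(effects, "rel_effects"), effects$N == gs$N)
  n <- gs$n
  w <- effects$w_hat

  # placements[[g]][[j]] = F_j evaluated at the observations of group g
  placements <- lapply(1:3, function(g) {
    lapply(1:3, function(j) edf_at(gs$groups[[j]], gs$groups[[g]]))
  })

  contrib <- vector("list", 3L)
  for (g in 1:3) {
    U <- matrix(0, nrow = n[g], ncol = 3L)
    for (m in 1:3) {
      if (m == g) {
        acc <- 0
        for (j in setdiff(1:3, m)) acc <- acc + placements[[m]][[j]] - w[j, m]
        U[, m] <- acc / 3
      } else {
        U[, m] <- -(placements[[g]][[m]] - w[m, g]) / 3
      }
    }
    contrib[[g]] <- gs$N * crossprod(U) / (n[g] * (n[g] - 1))
  }
  V <- contrib[[1]] + contrib[[2]] + contrib[[3]]
  effects$V_hat <- (V + t(V)) / 2
  effects$group_contrib <- contrib
  effects
}
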