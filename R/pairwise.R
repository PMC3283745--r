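#' Pairwise-ranking genetic effects
#'
#' The pairwise variant expresses the three genetic effects as linear
#' combinations of two-sample relative effects w_ij = P(X_i < X_j) +
#' 1/2 P(X_i = X_j), each estimated from pairwise mid-ranks only:
#' \describe{
#'   \item{dominant}{pooled \{aa, aA\} vs AA:
#'     (n1 w_13 + n2 w_23) / (n1 + n2).}
#'   \item{additive}{w_13 (aa vs AA).}
#'   \item{recessive}{aa vs pooled \{aA, AA\}:
#'     (n2 w_12 + n3 w_13) / (n2 + n3).}
#' }
#' The null value of every effect is 1/2 (no association). The pooled
#' effects are combined with sample-size weights, matching pooling of the
#' observations into a combined sample. Unlike the global-ranking effects,
#' pairwise effects can be intransitive; see [transitivity_check()].
#'
#' @param grouped A [grouped_sample()].
#' @return List with `w` (3x3 two-sample effect matrix, `w[i, j]` = w_ij),
#'   `pi` (named length-3 vector: dominant, additive, recessive), `n`, `N`.
#' @export
pairwise_genetic_effects <- function(grouped) {
  gs <- as_grouped_sample(grouped)
  n <- gs$n
  w <- diag(3) * 0.5
  for (i in 1:2) {
    for (j in (i + 1):3) {
      wij <- pairwise_effect(gs$groups[[i]], gs$groups[[j]])
      w[i, j] <- wij
      w[j, i] <- 1 - wij
    }
  }
  pi_hat <- c(
    dominant  = (n[1] * w[1, 3] + n[2] * w[2, 3]) / (n[1] + n[2]),
    additive  = w[1, 3],
    recessive = (n[2] * w[1, 2] + n[3] * w[1, 3]) / (n[2] + n[3])
  )
  list(w = w, pi = pi_hat, n = n, N = gs$N)
}

# coefficient matrix over the ordered pairs (1,2), (1,3), (2,3) defining
# each reported effect as sum of a_p * w_pair
pairwise_coefficients <- function(type, n) {
  switch(type,
    marcus = rbind(
      dominant  = c(0, n[1] / (n[1] + n[2]), n[2] / (n[1] + n[2])),
      additive  = c(0, 1, 0),
      recessive = c(n[2] / (n[2] + n[3]), n[3] / (n[2] + n[3]), 0)
    ),
    `all-pairs` = rbind(`2-1` = c(1, 0, 0),
                        `3-1` = c(0, 1, 0),
                        `3-2` = c(0, 0, 1))
  )
}

# Covariance of sqrt(N) (pi_hat - pi) via the influence decomposition of the
# two-sample effects, restricted to pairwise empirical distributions.
pairwise_covariance <- function(gs, w, A) {
  n <- gs$n
  if (any(n < 2L)) {
    stop("variance not estimable: every genotype group needs at least 2 observations",
         call. = FALSE)
  }
  pairs <- list(c(1L, 2L), c(1L, 3L), c(2L, 3L))
  placements <- lapply(1:3, function(g) {
    lapply(1:3, function(j) {
      if (j == g) NULL else edf_at(gs$groups[[j]], gs$groups[[g]])
    })
  })
  k <- nrow(A)
  contrib <- vector("list", 3L)
  for (g in 1:3) {
    U <- matrix(0, nrow = n[g], ncol = k)
    for (p in seq_along(pairs)) {
      i <- pairs[[p]][1]; j <- pairs[[p]][2]
      infl <- if (g == j) {
        placements[[j]][[i]] - w[i, j]
      } else if (g == i) {
        -(placements[[i]][[j]] - w[j, i])
      } else {
        NULL
      }
      if (!is.null(infl)) {
        for (q in seq_len(k)) {
          if (A[q, p] != 0) U[, q] <- U[, q] + A[q, p] * infl
        }
      }
    }
    contrib[[g]] <- gs$N * crossprod(U) / (n[g] * (n[g] - 1))
  }
  V <- contrib[[1]] + contrib[[2]] + contrib[[3]]
  list(V = (V + t(V)) / 2, contrib = contrib)
}

#' Detect intransitive pairwise effects
#'
#' Pairwise relative effects can form a cycle (group 1 tends to beat 2,
#' 2 beats 3, 3 beats 1), a configuration with no global ordering and hence
#' potentially paradoxical test results; the global-ranking variant is
#' recommended when this occurs. A cycle is flagged when w_12 - 1/2,
#' w_23 - 1/2 and w_31 - 1/2 all share a strict sign.
#'
#' @param w 3x3 matrix of two-sample effects with `w[i, j] + w[j, i] = 1`.
#' @return List with logical `flag` and an `explanation` string.
#' @export
transitivity_check <- function(w) {
  stopifnot(is.matrix(w), all(dim(w) == 3))
  if (max(abs(w + t(w) - 1)) > 1e-8) {
    stop("invalid pairwise effect matrix: w_ij + w_ji must equal 1", call. = FALSE)
  }
  s <- c(w[1, 2], w[2, 3], w[3, 1]) - 0.5
  flag <- all(s > 0) || all(s < 0)
  explanation <- if (flag) {
    sprintf(paste0("intransitive pairwise effects (cycle w12 = %.3f, ",
                   "w23 = %.3f, w31 = %.3f); the global-ranking variant ",
                   "is recommended"), w[1, 2], w[2, 3], w[3, 1])
  } else {
    "no intransitivity detected"
  }
  list(flag = flag, explanation = explanation)
}

# pairwise-ranking variant of moi_test(); called via moi_test(ranking = "pairwise")
pairwise_moi_test <- function(gs, contrasts, alpha, approx, interval,
                              flip_sign = FALSE) {
  pe <- pairwise_genetic_effects(gs)
  A <- pairwise_coefficients(contrasts, gs$n)
  pi_hat <- as.numeric(A %*% c(pe$w[1, 2], pe$w[1, 3], pe$w[2, 3]))
  cov <- pairwise_covariance(gs, pe$w, A)
  eff <- list(p_hat = pi_hat, V_hat = cov$V, group_contrib = cov$contrib,
              n = gs$n, N = gs$N)
  delta <- pi_hat - 0.5
  if (flip_sign) delta <- -delta
  res <- mct_engine(delta, diag(nrow(A)), eff, alpha, approx, interval,
                    labels = rownames(A), null_value = 0.5)
  structure(
    c(res,
      list(effects = pe, contrast_spec = A, contrast_type = contrasts,
           ranking = "pairwise", alpha = alpha, approx = approx,
           interval = interval, n = gs$n, N = gs$N,
           intransitive = transitivity_check(pe$w))),
    class = "moi_test"
  )
}
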