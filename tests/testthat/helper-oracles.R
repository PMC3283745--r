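# Independent brute-force oracles. These deliberately use naive double
# loops over observation pairs so that they share no code with the
# rank-based implementation they check.

oracle_two_sample_effect <- function(xi, xj) {
  acc <- 0
  for (a in xi) {
    for (b in xj) acc <- acc + (a < b) + 0.5 * (a == b)
  }
  acc / (length(xi) * length(xj))
}

oracle_edf <- function(sample, x) {
  (sum(sample < x) + 0.5 * sum(sample == x)) / length(sample)
}

# unweighted relative effects p_i = mean over X_ik of G(X_ik),
# G = (F1 + F2 + F3) / 3, evaluated pointwise
oracle_effects <- function(groups) {
  G <- function(x) mean(vapply(groups, oracle_edf, numeric(1), x = x))
  vapply(groups, function(g) mean(vapply(g, G, numeric(1))), numeric(1))
}

# random three-group sample; with ties = TRUE values are discretized so
# mid-rank handling is exercised
random_groups <- function(max_n = 30, ties = FALSE) {
  n <- sample(2:max_n, 3, replace = TRUE)
  lapply(n, function(m) {
    x <- stats::rnorm(m)
    if (ties) round(x * 2) / 2 else x
  })
}
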