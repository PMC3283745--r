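test_that("midranks average over ties and reject bad input", {
  expect_equal(midranks(c(10, 20, 20, 30)), c(1, 2.5, 2.5, 4))
  expect_equal(midranks(c(5, 5, 5)), c(2, 2, 2))
  expect_equal(midranks(c(3, 1, 2)), c(3, 1, 2))
  expect_equal(sum(midranks(rnorm(17))), 17 * 18 / 2)
  expect_error(midranks(numeric(0)), "empty")
  expect_error(midranks(c(1, NA)), "finite")
  expect_error(midranks(c(1, Inf)), "finite")
})

test_that("placements evaluate the normalized EDF of the other sample", {
  expect_equal(pairwise_placements(c(1, 2), c(3, 4)), c(0, 0))
  expect_equal(pairwise_placements(c(3, 4), c(1, 2)), c(1, 1))
  expect_equal(pairwise_placements(c(1, 3), c(2, 4)), c(0, 0.5))
  expect_error(pairwise_placements(numeric(0), 1), "non-empty")
  # matches the brute-force EDF definition, including under heavy ties
  set.seed(4)
  for (i in 1:20) {
    xi <- round(rnorm(sample(2:15, 1)), 1)
    xj <- round(rnorm(sample(2:15, 1)), 1)
    expect_equal(pairwise_placements(xi, xj),
                 vapply(xi, oracle_edf, numeric(1), sample = xj))
  }
})

test_that("two-sample effect equals the scaled Mann-Whitney statistic", {
  expect_equal(pairwise_effect(c(1, 2), c(3, 4)), 1)
  expect_equal(pairwise_effect(c(2, 7, 1), c(2, 7, 1)), 0.5)
  expect_equal(pairwise_effect(c(1, 1), c(1, 2)), 0.75)
  set.seed(11)
  for (i in 1:30) {
    g <- random_groups(ties = i %% 2 == 0)
    w <- pairwise_effect(g[[1]], g[[2]])
    expect_equal(w, oracle_two_sample_effect(g[[1]], g[[2]]))
    expect_equal(w + pairwise_effect(g[[2]], g[[1]]), 1)
  }
})

test_that("pseudo-ranks reduce to global mid-ranks in balanced designs", {
  expect_equal(pseudo_ranks(list(c(1, 2), c(3, 4), c(5, 6))), 1:6)
  expect_equal(pseudo_ranks(list(c(2, 2), c(2, 2), c(2, 2))), rep(3.5, 6))
  # unbalanced: hand-evaluated G at each point
  expect_equal(pseudo_ranks(list(c(1, 2, 3), 4, c(5, 6))),
               c(0.5 + 6 * c(1/18, 3/18, 5/18, 9/18, 13.5/18, 16.5/18)))
  set.seed(5)
  for (i in 1:10) {
    x <- round(rnorm(30), 1)
    g <- split(x, rep(1:3, each = 10))
    expect_equal(pseudo_ranks(g), midranks(unlist(g, use.names = FALSE)))
  }
})

test_that("relative effects sum to 3/2 and match hand values", {
  e <- estimate_effects(list(c(1, 2), c(3, 4), c(5, 6)))
  expect_equal(e$p_hat, c(1/6, 1/2, 5/6))
  expect_equal(estimate_effects(list(c(1, 5), c(1, 5), c(1, 5)))$p_hat,
               rep(0.5, 3))
  expect_equal(estimate_effects(list(c(1, 2, 3), 4, c(5, 6)))$p_hat,
               c(1/6, 1/2, 5/6))
  set.seed(6)
  for (i in 1:25) {
    g <- random_groups(ties = i %% 3 == 0)
    e <- estimate_effects(g)
    expect_equal(sum(e$p_hat), 1.5)
    expect_true(all(e$p_hat >= 0 & e$p_hat <= 1))
    # p_i is also the mean of the two-sample effects against all groups
    for (m in 1:3) {
      expect_equal(e$p_hat[m], mean(e$w_hat[, m]))
    }
    expect_equal(e$w_hat + t(e$w_hat), matrix(1, 3, 3))
  }
})

test_that("effect covariance is PSD, additive over groups, and null on constants", {
  gs <- as_grouped_sample(list(c(3, 3, 3), c(3, 3), c(3, 3, 3)))
  e <- effect_covariance(gs)
  expect_equal(e$V_hat, matrix(0, 3, 3))

  expect_error(effect_covariance(as_grouped_sample(list(c(1, 2, 3), 4, c(5, 6)))),
               "variance not estimable")

  set.seed(9)
  for (i in 1:15) {
    g <- random_groups(ties = i %% 2 == 0)
    e <- effect_covariance(as_grouped_sample(g))
    expect_equal(e$V_hat, t(e$V_hat))
    expect_true(min(eigen(e$V_hat, symmetric = TRUE,
                          only.values = TRUE)$values) > -1e-10)
    expect_equal(Reduce(`+`, e$group_contrib), e$V_hat)
    # p1 + p2 + p3 constant => rows of the covariance sum to zero
    expect_equal(rowSums(e$V_hat), c(0, 0, 0))
  }
})

test_that("effects are invariant under increasing transforms and reflected by decreasing ones", {
  set.seed(13)
  g <- random_groups(ties = TRUE)
  e <- effect_covariance(as_grouped_sample(g))
  up <- effect_covariance(as_grouped_sample(lapply(g, function(x) exp(x) + 1)))
  expect_identical(e$p_hat, up$p_hat)
  expect_identical(e$w_hat, up$w_hat)
  expect_identical(e$V_hat, up$V_hat)

  down <- estimate_effects(as_grouped_sample(lapply(g, function(x) -2 * x)))
  expect_equal(down$p_hat, 1 - e$p_hat)
  expect_equal(down$w_hat[upper.tri(diag(3))],
               (1 - e$w_hat)[upper.tri(diag(3))])
})
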