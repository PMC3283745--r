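test_that("haplotype frequencies are valid and match arithmetic", {
  expect_equal(unname(haplotype_frequencies(0.3, 0.3, 0)),
               c(0.09, 0.21, 0.21, 0.49))
  expect_equal(unname(haplotype_frequencies(0.5, 0.5, 0.25)),
               c(0.5, 0, 0, 0.5))
  expect_equal(unname(haplotype_frequencies(0.3, 0.3, 0.09)),
               c(0.18, 0.12, 0.12, 0.58))
  expect_error(haplotype_frequencies(0.3, 0.3, 0.5), "feasible interval")
  expect_error(haplotype_frequencies(0, 0.3, 0), "\\(0, 1\\)")
  set.seed(91)
  for (i in 1:20) {
    q <- runif(2, 0.05, 0.95)
    d <- runif(1, max(-q[1] * q[2], -(1 - q[1]) * (1 - q[2])),
               delta_max(q[1], q[2]))
    h <- haplotype_frequencies(q[1], q[2], d)
    expect_true(all(h >= 0))
    expect_equal(sum(h), 1)
  }
})

test_that("genotype draws follow the LD model and HWE", {
  sc <- moi_scenario(N = 5000, q1 = 0.3, q2 = 0.3,
                     delta = delta_max(0.3, 0.3), seed = 1)
  set.seed(1)
  g <- draw_genotypes(sc)
  expect_identical(g$trait, g$marker)  # maximal LD with q1 = q2

  set.seed(2)
  g0 <- draw_genotypes(moi_scenario(N = 10000, q1 = 0.4, q2 = 0.3, delta = 0))
  expect_lt(abs(cor(g0$trait, g0$marker)), 0.05)

  set.seed(3)
  gh <- draw_genotypes(moi_scenario(N = 100000, q1 = 0.5, q2 = 0.3, delta = 0))
  freq <- tabulate(gh$marker + 1L, 3) / 100000
  expect_true(max(abs(freq - c(0.49, 0.42, 0.09))) < 0.01)
})

test_that("genotypic values solve the variance-explained equation", {
  expect_equal(genotypic_values("additive", 0, 0.3), c(0, 0, 0))
  expect_equal(genotypic_values("dominant", 0, 0.3), c(0, 0, 0))
  a <- genotypic_values("additive", 0.5, 0.5, 1)
  expect_equal(a, sqrt(2) * c(0, 1, 2))
  d <- genotypic_values("dominant", 0.5, 0.5, 1)
  expect_equal(d[2], sqrt(1 / (0.75 * 0.25)), tolerance = 1e-12)
  expect_equal(d[2], d[3])
  r <- genotypic_values("recessive", 0.2, 0.3, 2)
  f <- c(0.49, 0.42, 0.09)
  vg <- sum(f * r^2) - sum(f * r)^2
  expect_equal(vg / (vg + 2), 0.2)
  expect_error(genotypic_values("additive", 1, 0.3), "h2")
})

test_that("phenotype generation respects the distribution and the transform", {
  set.seed(4)
  x <- draw_phenotypes(rep(0L, 100000), c(0, 0, 0), dist = "lognormal")
  ks <- suppressWarnings(ks.test(x, plnorm))
  expect_lt(unname(ks$statistic), 0.01)

  # same underlying normals: identical ranks, hence identical decisions
  set.seed(5)
  y <- draw_phenotypes(rep(0:2, each = 10), c(0, 1, 2), dist = "normal")
  set.seed(5)
  z <- draw_phenotypes(rep(0:2, each = 10), c(0, 1, 2), dist = "lognormal")
  expect_identical(midranks(y), midranks(z))

  # dominant mixture: carrier fraction matches 1 - (1 - q1)^2 under HWE
  set.seed(6)
  sc <- moi_scenario(N = 50000, q1 = 0.3, q2 = 0.3, delta = delta_max(0.3, 0.3),
                     h2 = 0.5, mode = "dominant")
  g <- draw_genotypes(sc)
  v <- genotypic_values("dominant", 0.5, 0.3)
  yy <- draw_phenotypes(g$trait, v, "normal")
  carrier <- mean(yy > v[2] / 2)  # split point between the two modes
  expect_equal(carrier, 1 - 0.7^2, tolerance = 0.05)
})

test_that("comparator tests match hand computations", {
  gs <- as_grouped_sample(list(c(1, 2), c(3, 4), c(5, 6)))
  kw <- comparator_test(gs, "kw")
  expect_equal(kw$p,
               unname(stats::kruskal.test(1:6, rep(1:3, each = 2))$p.value))
  # hand value of the Kruskal-Wallis statistic for this layout: 12/42 * 16
  expect_equal(unname(stats::kruskal.test(1:6, rep(1:3, each = 2))$statistic),
               12 / 42 * 16)

  flat <- as_grouped_sample(list(c(1, 3), c(2, 2), c(3, 1)))
  tr <- comparator_test(flat, "trend_reg")
  fit <- lm(c(1, 3, 2, 2, 3, 1) ~ rep(0:2, each = 2))
  expect_equal(abs(unname(coef(fit)[2])), 0)
  expect_gt(tr$p, 0.99)
  av <- comparator_test(flat, "anova")
  expect_gt(av$p, 0.99)

  expect_error(comparator_test(gs, "nope"), "arg")
})

test_that("the pooled parametric max-T test matches an independent construction", {
  set.seed(7)
  g <- lapply(c(8, 12, 10), rnorm, mean = 0.3)
  res <- moirank:::param_mct(as_grouped_sample(g), "all-pairs", pooled = TRUE)
  n <- vapply(g, length, integer(1))
  m <- vapply(g, mean, numeric(1))
  sp2 <- sum((n - 1) * vapply(g, var, numeric(1))) / (sum(n) - 3)
  C <- rbind(c(-1, 1, 0), c(-1, 0, 1), c(0, -1, 1))
  t_ref <- drop(C %*% m) / sqrt(sp2 * drop(C^2 %*% (1 / n)))
  expect_equal(unname(res$statistic), t_ref)
  # adjusted p bounded between the marginal and Bonferroni p-values
  p_marg <- 2 * (1 - pt(abs(t_ref), df = sum(n) - 3))
  expect_true(all(res$p_adj >= p_marg - 5e-4))
  expect_true(all(res$p_adj <= pmin(1, 3 * p_marg) + 5e-4))
})

test_that("the study harness is reproducible and self-consistent", {
  sc <- moi_scenario(N = 60, q1 = 0.4, q2 = 0.4, delta = delta_max(0.4, 0.4) / 2,
                     h2 = 0, reps = 400, seed = 99)
  r1 <- run_study(sc, methods = c("dummy", "kw"))
  r2 <- run_study(sc, methods = c("dummy", "kw"))
  expect_identical(r1, r2)
  # dummy method: rate within 3 MC s.e. of alpha
  dummy <- r1[r1$method == "dummy", ]
  expect_lt(abs(dummy$rate - 0.05), 3 * sqrt(0.05 * 0.95 / 400) + 1e-9)
  expect_equal(dummy$mc_se, sqrt(dummy$rate * (1 - dummy$rate) / 400))
  expect_error(run_study(sc, methods = "telepathy"), "unknown method")
  expect_s3_class(ggplot2::autoplot(r1), "ggplot")
})
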