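fake_effects <- function(V, n = c(10, 10, 10)) {
  structure(list(p_hat = c(0.5, 0.5, 0.5), V_hat = V,
                 group_contrib = NULL, n = n, N = sum(n)),
            class = "rel_effects")
}

test_that("studentization reproduces the geometric contrast correlation", {
  spec <- contrast_marcus(10, 10, 10)
  st <- studentize(c(0, 0, 0), spec, fake_effects(diag(3)), 30)
  expect_equal(st$statistic, c(0, 0, 0))
  # with V = I the correlation is the cosine between contrast rows
  expect_equal(st$corr[1, 2], 1.5 / sqrt(1.5 * 2), tolerance = 1e-12)
  expect_false(any(st$degenerate))
  expect_error(studentize(c(0, 0, 0), spec,
                          fake_effects(diag(c(1, 1, -1))), 30),
               "positive semidefinite")
})

test_that("Satterthwaite df matches closed forms and is scale free", {
  spec <- contrast_marcus(11, 11, 11)
  contrib_eq <- list(diag(3), diag(3), diag(3))
  nu <- satterthwaite_df(spec, contrib_eq, c(11, 11, 11))
  expect_equal(as.numeric(nu), 30)  # 3 (n - 1) under equal contributions

  zero <- matrix(0, 3, 3)
  nu1 <- satterthwaite_df(spec, list(diag(3), zero, zero), c(11, 5, 7))
  expect_equal(as.numeric(nu1), 10)  # dominated by one group: n_g - 1

  nu_scaled <- satterthwaite_df(spec, lapply(contrib_eq, `*`, 7), c(11, 11, 11))
  expect_equal(as.numeric(nu_scaled), as.numeric(nu))

  nu0 <- satterthwaite_df(spec, list(zero, zero, zero), c(11, 11, 11))
  expect_true(is.infinite(nu0))
  expect_true(attr(nu0, "degenerate"))
})

test_that("equicoordinate quantile is monotone in alpha and rejects bad input", {
  R <- diag(3) + 0.4 - diag(0.4, 3)
  z05 <- equicoordinate_quantile(R, df = 20, alpha = 0.05)
  z01 <- equicoordinate_quantile(R, df = 20, alpha = 0.01)
  expect_gt(z01, z05)
  expect_error(equicoordinate_quantile(matrix(2, 3, 3)), "correlation")
  expect_error(equicoordinate_quantile(diag(3), alpha = 1.2), "alpha")
  # repeated calls are bit-identical (fixed integration seed)
  expect_identical(z05, equicoordinate_quantile(R, df = 20, alpha = 0.05))
})

test_that("simultaneous intervals: Fisher stays in range, plain may not", {
  f <- simultaneous_ci(0, se = 0.2, z = 1, method = "fisher")
  expect_equal(c(f$lower, f$upper), c(-tanh(0.2), tanh(0.2)))

  d <- simultaneous_ci(0.4, se = 0, z = 2, method = "fisher")
  expect_equal(c(d$lower, d$upper), c(0.4, 0.4))

  p <- simultaneous_ci(0.9, se = 0.15, z = 2, method = "plain")
  expect_gt(p$upper, 1)
  f2 <- simultaneous_ci(0.9, se = 0.15, z = 2, method = "fisher")
  expect_lt(f2$upper, 1)
  expect_gt(f2$lower, -1)
})

test_that("max-T adjusted p-values reduce to the Sidak form under independence", {
  for (t_obs in c(0.5, 1.5, 2.5)) {
    p <- moirank:::mvt_adjusted_p(t_obs, diag(3), df = Inf)
    expect_equal(p, 1 - (2 * pnorm(t_obs) - 1)^3, tolerance = 5e-4)
  }
})

test_that("adjusted p-values are never below the marginal t p-values", {
  set.seed(21)
  for (i in 1:10) {
    g <- random_groups(max_n = 20, ties = i %% 2 == 0)
    fit <- moi_test(as_grouped_sample(g), interval = "plain")
    marginal <- 2 * (1 - pt(abs(fit$table$statistic), df = fit$df))
    expect_true(all(fit$table$p_adj >= marginal - 5e-4))
  }
})

test_that("the full test holds its level on exchangeable null data", {
  set.seed(31)
  rej <- replicate(300, {
    gs <- as_grouped_sample(split(rnorm(45), rep(1:3, each = 15)))
    moirank:::np_global_p(effect_covariance(gs)) < 0.05
  })
  expect_gt(mean(rej), 0.01)
  expect_lt(mean(rej), 0.10)
})

test_that("degenerate separation yields finite output with flagged contrasts", {
  fit <- moi_test(as_grouped_sample(list(c(1, 2), c(3, 4), c(1000, 1001))))
  expect_true(all(is.finite(fit$table$estimate)))
  expect_true(all(is.finite(fit$table$lower)))
  expect_true(all(is.finite(fit$table$upper)))
  # complete separation kills all placement variability: everything degenerate
  expect_true(all(fit$table$degenerate))
  expect_equal(fit$table$p_adj, rep(1, 3))
  expect_false(fit$global_reject)
})

test_that("test decisions and intervals agree on a quick random sweep", {
  set.seed(41)
  withr::with_options(list(moirank.mvt_abseps = 1e-3), {
    for (i in 1:25) {
      g <- random_groups(max_n = 15, ties = i %% 2 == 0)
      for (interval in c("plain", "fisher")) {
        fit <- moi_test(as_grouped_sample(g), interval = interval)
        excl <- fit$table$lower > 0 | fit$table$upper < 0
        expect_identical(excl, fit$table$p_adj < fit$alpha)
      }
    }
  })
})

test_that("statistics are invariant under trait rescaling", {
  set.seed(51)
  g <- random_groups(max_n = 15)
  f1 <- moi_test(as_grouped_sample(g))
  f2 <- moi_test(as_grouped_sample(lapply(g, `*`, 2)))
  expect_identical(f1$table$statistic, f2$table$statistic)
  expect_identical(f1$table$p_adj, f2$table$p_adj)
})

test_that("tidy, glance and autoplot expose the result", {
  d <- generate_fixture("additive", n = 45, seed = 3)
  fit <- moi_test(d)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("contrast", "estimate", "conf.low", "conf.high",
                     "statistic", "p.value", "degenerate"))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1L)
  expect_equal(gl$p.value, min(td$p.value))
  expect_s3_class(ggplot2::autoplot(fit), "ggplot")
})
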