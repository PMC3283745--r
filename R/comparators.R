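# Comparator tests for the simulation study. Each returns the p-value of
# its global test; standard procedures are delegated to base R, the
# parametric multiple contrast tests (pooled-variance Bretz type and
# heteroscedastic Satterthwaite Hasler type) are built on the same
# multivariate-t machinery as the nonparametric tests.

#' Comparator association tests on a grouped sample
#'
#' Global tests used as benchmarks in the simulation study:
#' \describe{
#'   \item{kw}{tie-corrected Kruskal-Wallis test ([stats::kruskal.test()]).}
#'   \item{anova}{one-way ANOVA F test (equal variances).}
#'   \item{trend_reg}{two-sided t test on the slope of trait on genotype
#'     scores 0/1/2 (the usual additive linear-regression scan).}
#'   \item{mctp_param_homo}{parametric max-T multiple contrast test on
#'     group means with pooled variance, multivariate t with N - 3 df.}
#'   \item{mctp_param_hetero}{heteroscedastic parametric max-T test with
#'     per-group variances and per-contrast Satterthwaite df.}
#' }
#'
#' @param grouped A [grouped_sample()].
#' @param method One of the method names above.
#' @param alpha Level for the rejection flag.
#' @param contrasts Contrast family for the parametric max-T tests
#'   (`"marcus"` or `"all-pairs"`).
#' @return List with `p` (global p-value), `reject`, `method`.
#' @export
comparator_test <- function(grouped,
                            method = c("kw", "anova", "trend_reg",
                                       "mctp_param_homo", "mctp_param_hetero"),
                            alpha = 0.05,
                            contrasts = c("marcus", "all-pairs")) {
  method <- match.arg(method)
  contrasts <- match.arg(contrasts)
  gs <- as_grouped_sample(grouped)
  flat <- gs_flatten(gs)
  p <- switch(method,
    kw = stats::kruskal.test(flat$values, factor(flat$group))$p.value,
    anova = stats::oneway.test(values ~ group,
                               data = data.frame(values = flat$values,
                                                 group = factor(flat$group)),
                               var.equal = TRUE)$p.value,
    trend_reg = {
      score <- flat$group - 1
      fit <- stats::lm(flat$values ~ score)
      stats::coef(summary(fit))["score", "Pr(>|t|)"]
    },
    mctp_param_homo = param_mct(gs, contrasts, pooled = TRUE)$p_global,
    mctp_param_hetero = param_mct(gs, contrasts, pooled = FALSE)$p_global
  )
  list(p = as.numeric(p), reject = as.numeric(p) < alpha, method = method)
}

# Parametric multiple contrast test on group means.
# pooled = TRUE: common variance, df = N - 3 (Bretz type).
# pooled = FALSE: group variances, per-contrast Satterthwaite df (Hasler type).
param_mct <- function(gs, contrasts = "marcus", pooled = TRUE) {
  n <- gs$n
  N <- gs$N
  m <- vapply(gs$groups, mean, numeric(1))
  s2 <- vapply(gs$groups, stats::var, numeric(1))
  spec <- switch(contrasts,
                 marcus = contrast_marcus(n[1], n[2], n[3]),
                 `all-pairs` = contrast_all_pairs())
  C <- spec$matrix
  est <- drop(C %*% m)
  if (pooled) {
    sp2 <- sum((n - 1) * s2) / (N - 3)
    D <- diag(sp2 / n)
    df_each <- rep(N - 3, nrow(C))
  } else {
    D <- diag(s2 / n)
    df_each <- apply(C, 1, function(cq) {
      lam <- cq^2 * s2 / n
      sum(lam)^2 / sum(lam^2 / (n - 1))
    })
  }
  CDC <- C %*% D %*% t(C)
  se <- sqrt(pmax(diag(CDC), 0))
  degen <- se < 1e-12
  tt <- ifelse(degen, 0, est / ifelse(degen, 1, se))
  corr <- contrast_correlation(CDC, degen)
  p_each <- vapply(seq_along(tt), function(q) {
    if (degen[q]) 1 else mvt_adjusted_p(tt[q], corr, df = df_each[q])
  }, numeric(1))
  list(estimate = est, se = se, statistic = tt, corr = corr,
       df = df_each, p_adj = p_each, p_global = min(p_each),
       labels = spec$labels)
}
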