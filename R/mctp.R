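#' Studentized contrast statistics and their correlation
#'
#' Forms the max-T ingredients for a set of contrasts of relative effects:
#' standard errors se_q = sqrt(c_q' V c_q / N), statistics T_q =
#' delta_q / se_q, and the estimated correlation matrix of the T vector.
#' Contrasts whose variance falls below `1e-12` are flagged degenerate and
#' reported with T = 0 (a total tie carries no evidence against the null).
#'
#' @param delta_hat Numeric vector of contrast effects (one per contrast row).
#' @param spec A `moi_contrasts` object.
#' @param estimate A `rel_effects` object with `V_hat` filled
#'   ([effect_covariance()]).
#' @param N Total sample size.
#' @return List with `statistic`, `se`, `corr`, and logical `degenerate`.
#' @export
studentize <- function(delta_hat, spec, estimate, N) {
  C <- if (inherits(spec, "moi_contrasts")) spec$matrix else spec
  V <- estimate$V_hat
  if (is.null(V)) stop("covariance not available; run effect_covariance() first", call. = FALSE)
  ev <- eigen((V + t(V)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(1, abs(ev))) {
    stop("covariance estimate is not positive semidefinite", call. = FALSE)
  }
  CVC <- C %*% V %*% t(C)
  var_q <- unname(pmax(diag(CVC), 0)) / N
  degenerate <- var_q < 1e-12
  se <- sqrt(var_q)
  stat <- ifelse(degenerate, 0, delta_hat / ifelse(degenerate, 1, se))
  corr <- contrast_correlation(CVC, degenerate)
  list(statistic = as.numeric(stat), se = as.numeric(se), corr = corr,
       degenerate = degenerate)
}

# correlation of the contrast statistics; degenerate contrasts are carried
# as uncorrelated coordinates so the max-T integral stays well defined
contrast_correlation <- function(CVC, degenerate) {
  k <- nrow(CVC)
  d <- sqrt(pmax(diag(CVC), 0))
  corr <- diag(k)
  for (q in seq_len(k - 1)) {
    for (r in (q + 1):k) {
      if (!degenerate[q] && !degenerate[r]) {
        rho <- CVC[q, r] / (d[q] * d[r])
        corr[q, r] <- corr[r, q] <- max(-1, min(1, rho))
      }
    }
  }
  corr
}

#' Welch-Satterthwaite degrees of freedom for contrast statistics
#'
#' Approximates the df of each studentized contrast from the per-group
#' contributions to its variance, lambda_gq = c_q' contrib_g c_q:
#' nu_q = (sum_g lambda_gq)^2 / sum_g lambda_gq^2 / (n_g - 1).
#' The returned common df is the minimum over non-degenerate contrasts
#' (conservative single-quantile construction), floored at 2. With equal
#' contributions across three groups of size n it reduces to 3(n - 1).
#'
#' @param spec A `moi_contrasts` object.
#' @param group_contrib List of per-group covariance contributions from
#'   [effect_covariance()].
#' @param n Group sizes.
#' @return The common df (scalar); `Inf` with attribute `degenerate = TRUE`
#'   when every contrast variance vanishes. Per-contrast values are in
#'   attribute `per_contrast`.
#' @export
satterthwaite_df <- function(spec, group_contrib, n) {
  C <- if (inherits(spec, "moi_contrasts")) spec$matrix else spec
  k <- nrow(C)
  nu <- numeric(k)
  for (q in seq_len(k)) {
    cq <- C[q, ]
    lambda <- vapply(group_contrib, function(B) drop(cq %*% B %*% cq), numeric(1))
    lambda <- pmax(lambda, 0)
    tot <- sum(lambda)
    nu[q] <- if (tot < 1e-14) Inf else tot^2 / sum(lambda^2 / (n - 1))
  }
  if (all(is.infinite(nu))) {
    return(structure(Inf, degenerate = TRUE, per_contrast = nu))
  }
  structure(max(2, min(nu[is.finite(nu)])), degenerate = FALSE, per_contrast = nu)
}

#' Simultaneous confidence intervals for contrast effects
#'
#' Plain intervals delta +/- z * se may leave the admissible range of a
#' relative-effect difference; Fisher (atanh) intervals
#' tanh(atanh(delta) +/- z * se / (1 - delta^2)) are range preserving in
#' (-1, 1) and agree with the plain intervals to first order as se -> 0.
#'
#' @param delta_hat Contrast effects.
#' @param se Standard errors.
#' @param z Equicoordinate quantile (> 0).
#' @param method `"plain"` or `"fisher"`.
#' @return A tibble with columns `lower`, `upper`.
#' @export
simultaneous_ci <- function(delta_hat, se, z,
                            method = c("plain", "fisher")) {
  method <- match.arg(method)
  stopifnot(z > 0, length(delta_hat) == length(se))
  if (method == "plain") {
    lower <- delta_hat - z * se
    upper <- delta_hat + z * se
  } else {
    d <- delta_hat
    if (any(abs(d) >= 1)) {
      warning("effect at the boundary; clamped for the Fisher transform")
      d <- pmin(pmax(d, -(1 - 1e-12)), 1 - 1e-12)
    }
    half <- z * se / (1 - d^2)
    lower <- tanh(atanh(d) - half)
    upper <- tanh(atanh(d) + half)
  }
  tibble::tibble(lower = lower, upper = upper)
}

# Shared inferential engine for the global-ranking and pairwise variants.
# `delta` is the contrast effect relative to its null value; statistics and
# adjusted p-values are formed on the same scale as the requested interval so
# that CI-vs-null and p-vs-alpha decisions are compatible by construction.
mct_engine <- function(delta, Cmat, effects, alpha, approx, interval,
                       labels, null_value = 0) {
  delta <- unname(delta)
  N <- effects$N
  st <- studentize(delta, Cmat, effects, N)
  df <- if (approx == "t") {
    satterthwaite_df(Cmat, effects$group_contrib, effects$n)
  } else {
    Inf
  }
  d <- pmin(pmax(delta, -(1 - 1e-12)), 1 - 1e-12)
  if (interval == "fisher") {
    stat <- ifelse(st$degenerate, 0,
                   atanh(d) * (1 - d^2) / ifelse(st$degenerate, 1, st$se))
  } else {
    stat <- st$statistic
  }
  z <- equicoordinate_quantile(st$corr, df = as.numeric(df), alpha = alpha)
  ci <- simultaneous_ci(delta, st$se, z, method = interval)
  ci$lower[st$degenerate] <- delta[st$degenerate]
  ci$upper[st$degenerate] <- delta[st$degenerate]
  p_adj <- vapply(stat, mvt_adjusted_p, numeric(1),
                  corr = st$corr, df = as.numeric(df))
  p_adj[st$degenerate] <- 1

  tab <- tibble::tibble(
    contrast = labels,
    estimate = delta + null_value,
    se = st$se,
    statistic = stat,
    lower = ci$lower + null_value,
    upper = ci$upper + null_value,
    p_adj = p_adj,
    degenerate = st$degenerate
  )
  list(table = tab, corr = st$corr, df = as.numeric(df), quantile = z,
       p_global = min(p_adj), global_reject = min(p_adj) < alpha,
       null_value = null_value)
}

#' Nonparametric multiple contrast test for mode of inheritance
#'
#' The main entry point: tests association between a di-allelic genotype and
#' a quantitative trait with a max-T multiple contrast test on rank-based
#' relative effects. With Marcus-type contrasts, the dominant, additive and
#' recessive modes of inheritance are tested simultaneously, with
#' simultaneous confidence intervals for the three genetic effects and
#' compatible adjusted p-values; all-pairs contrasts give a rank-based
#' alternative to the Kruskal-Wallis heterogeneity test that localizes the
#' signal. The procedure assumes neither normality nor equal variances and
#' is invariant under strictly increasing transformations of the trait.
#'
#' @param data A data frame (see [grouped_sample()]) or a `grouped_sample`.
#' @param trait,genotype Bare column names when `data` is a data frame.
#' @param contrasts `"marcus"` (dominant/additive/recessive, default) or
#'   `"all-pairs"`.
#' @param ranking `"global"` (pseudo-rank unweighted relative effects,
#'   default and recommended) or `"pairwise"` (two-sample relative effects;
#'   can be intransitive, see [transitivity_check()]).
#' @param alpha Familywise error level (default 0.05).
#' @param approx `"t"` (multivariate t with Welch-Satterthwaite df, default;
#'   recommended for small samples) or `"normal"`.
#' @param interval `"fisher"` (range-preserving, default) or `"plain"`.
#'   Test statistics and adjusted p-values are computed on the same scale
#'   as the interval, so interval and test decisions always agree.
#' @param flip_sign Flip the reporting orientation of the contrasts.
#' @return An object of class `moi_test`; see [tidy.moi_test()],
#'   [glance.moi_test()], [autoplot.moi_test()]. Key fields: `table`
#'   (per-contrast tibble with estimate, simultaneous CI, adjusted p),
#'   `p_global` (minimum adjusted p), `global_reject`.
#' @examples
#' d <- generate_fixture("additive", n = 60, seed = 1)
#' fit <- moi_test(d)
#' fit
#' generics::tidy(fit)
#' @export
moi_test <- function(data, trait = trait, genotype = genotype,
                     contrasts = c("marcus", "all-pairs"),
                     ranking = c("global", "pairwise"),
                     alpha = 0.05,
                     approx = c("t", "normal"),
                     interval = c("fisher", "plain"),
                     flip_sign = FALSE) {
  contrasts <- match.arg(contrasts)
  ranking <- match.arg(ranking)
  approx <- match.arg(approx)
  interval <- match.arg(interval)
  gs <- if (inherits(data, "grouped_sample")) data else {
    grouped_sample(data, {{ trait }}, {{ genotype }})
  }

  if (ranking == "pairwise") {
    return(pairwise_moi_test(gs, contrasts = contrasts, alpha = alpha,
                             approx = approx, interval = interval,
                             flip_sign = flip_sign))
  }

  eff <- effect_covariance(gs)
  spec <- switch(contrasts,
                 marcus = contrast_marcus(gs$n[1], gs$n[2], gs$n[3]),
                 `all-pairs` = contrast_all_pairs())
  Cm <- spec
  if (flip_sign) Cm$matrix <- -Cm$matrix
  delta <- apply_contrasts(Cm, eff$p_hat)
  res <- mct_engine(delta, Cm, eff, alpha, approx, interval,
                    labels = spec$labels, null_value = 0)

  structure(
    c(res,
      list(effects = eff, contrast_spec = Cm, contrast_type = contrasts,
           ranking = ranking, alpha = alpha, approx = approx,
           interval = interval, n = gs$n, N = gs$N)),
    class = "moi_test"
  )
}

#' @export
print.moi_test <- function(x, digits = 4, ...) {
  cat("Nonparametric multiple contrast test (",
      x$contrast_type, " contrasts, ", x$ranking, " ranking)\n", sep = "")
  cat("N =", x$N, " n = (", paste(x$n, collapse = ", "), ")",
      " alpha =", x$alpha,
      " approx =", x$approx, "(df =",
      if (is.finite(x$df)) round(x$df, 2) else "Inf", ")",
      " interval =", x$interval, "\n")
  if (x$ranking == "global") {
    cat("Relative effects p_hat: (",
        paste(round(x$effects$p_hat, digits), collapse = ", "), ")\n")
  }
  tab <- as.data.frame(x$table)
  tab$estimate <- round(tab$estimate, digits)
  tab$lower <- round(tab$lower, digits)
  tab$upper <- round(tab$upper, digits)
  tab$statistic <- round(tab$statistic, digits)
  tab$p_adj <- signif(tab$p_adj, 3)
  print(tab[, c("contrast", "estimate", "lower", "upper", "statistic", "p_adj")],
        row.names = FALSE)
  cat("Equicoordinate quantile:", round(x$quantile, digits),
      " global p =", signif(x$p_global, 3),
      if (x$global_reject) " -> reject global null\n" else " -> no global rejection\n")
  if (!is.null(x$intransitive) && isTRUE(x$intransitive$flag)) {
    cat("Warning:", x$intransitive$explanation, "\n")
  }
  invisible(x)
}

#' Tidy a `moi_test` into one row per contrast
#'
#' @param x A `moi_test` object.
#' @param ... Unused.
#' @return A tibble with columns `contrast`, `estimate`, `conf.low`,
#'   `conf.high`, `statistic`, `p.value` (max-T adjusted) and `degenerate`.
#' @method tidy moi_test
#' @export
#' @importFrom generics tidy
tidy.moi_test <- function(x, ...) {
  dplyr::transmute(x$table,
                   contrast = .data$contrast,
                   estimate = .data$estimate,
                   conf.low = .data$lower,
                   conf.high = .data$upper,
                   statistic = .data$statistic,
                   p.value = .data$p_adj,
                   degenerate = .data$degenerate)
}

#' One-row summary of a `moi_test`
#'
#' @param x A `moi_test` object.
#' @param ... Unused.
#' @return A one-row tibble: sample sizes, df, equicoordinate quantile,
#'   global p-value (minimum adjusted p) and global decision.
#' @method glance moi_test
#' @export
#' @importFrom generics glance
glance.moi_test <- function(x, ...) {
  tibble::tibble(
    N = x$N, n1 = x$n[1], n2 = x$n[2], n3 = x$n[3],
    contrasts = x$contrast_type, ranking = x$ranking,
    approx = x$approx, interval = x$interval,
    df = x$df, quantile = x$quantile, alpha = x$alpha,
    p.value = x$p_global, global_reject = x$global_reject
  )
}
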