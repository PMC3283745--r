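# Type-I error / power harness reproducing the design of the simulation
# study: genotypes from the two-locus LD model, phenotypes from the
# variance-explained model, tests applied to the marker genotype groups.

np_global_p <- function(eff, contrasts = "marcus", approx = "t",
                        scale = "plain") {
  spec <- switch(contrasts,
                 marcus = contrast_marcus(eff$n[1], eff$n[2], eff$n[3]),
                 `all-pairs` = contrast_all_pairs())
  delta <- apply_contrasts(spec, eff$p_hat)
  st <- studentize(delta, spec, eff, eff$N)
  df <- if (approx == "t") {
    as.numeric(satterthwaite_df(spec, eff$group_contrib, eff$n))
  } else {
    Inf
  }
  if (scale == "fisher") {
    d <- pmin(pmax(delta, -(1 - 1e-12)), 1 - 1e-12)
    stat <- ifelse(st$degenerate, 0,
                   atanh(d) * (1 - d^2) / ifelse(st$degenerate, 1, st$se))
  } else {
    stat <- st$statistic
  }
  if (all(st$degenerate)) return(1)
  mvt_adjusted_p(max(abs(stat)), st$corr, df = df)
}

np_pairwise_global_p <- function(gs, contrasts = "marcus", approx = "t",
                                 scale = "plain") {
  pe <- pairwise_genetic_effects(gs)
  A <- pairwise_coefficients(contrasts, gs$n)
  pi_hat <- as.numeric(A %*% c(pe$w[1, 2], pe$w[1, 3], pe$w[2, 3]))
  cov <- pairwise_covariance(gs, pe$w, A)
  eff <- list(p_hat = pi_hat, V_hat = cov$V, group_contrib = cov$contrib,
              n = gs$n, N = gs$N)
  delta <- pi_hat - 0.5
  st <- studentize(delta, diag(nrow(A)), eff, gs$N)
  df <- if (approx == "t") {
    as.numeric(satterthwaite_df(diag(nrow(A)), cov$contrib, gs$n))
  } else {
    Inf
  }
  if (scale == "fisher") {
    d <- pmin(pmax(delta, -(1 - 1e-12)), 1 - 1e-12)
    stat <- ifelse(st$degenerate, 0,
                   atanh(d) * (1 - d^2) / ifelse(st$degenerate, 1, st$se))
  } else {
    stat <- st$statistic
  }
  if (all(st$degenerate)) return(1)
  mvt_adjusted_p(max(abs(stat)), st$corr, df = df)
}

parse_method <- function(m) {
  parts <- strsplit(m, ":", fixed = TRUE)[[1]]
  base <- parts[1]
  ctr <- if (length(parts) > 1) parts[2] else "marcus"
  ctr <- sub("all_pairs", "all-pairs", ctr, fixed = TRUE)
  known <- c("np", "np_fisher", "np_pairwise", "kw", "anova", "trend_reg",
             "param_homo", "param_hetero", "dummy")
  if (!base %in% known) {
    stop("unknown method '", m, "'; known bases: ",
         paste(known, collapse = ", "), call. = FALSE)
  }
  list(base = base, contrasts = ctr, id = m)
}

#' Run a type-I error or power study
#'
#' For each replicate, draws genotypes at the trait locus and the marker
#' from the two-locus LD model, generates phenotypes under the scenario's
#' mode of inheritance and variance explained, groups subjects by the
#' *marker* genotype, and applies each requested global test at level
#' `alpha`. With `h2 = 0` the rejection rate estimates the type-I error,
#' otherwise power. Replicates in which a marker genotype class has fewer
#' than 2 subjects (common under low marker allele frequency) are redrawn
#' and counted in `redraws`, keeping the rejection-rate denominator
#' interpretable while recording the unbalance pathology.
#'
#' Method identifiers combine a base with an optional contrast family,
#' e.g. `"np:marcus"` (nonparametric max-T, plain scale), `"np_fisher:marcus"`,
#' `"np_pairwise:marcus"`, `"np:all_pairs"`, `"param_homo:marcus"` (pooled
#' variance), `"param_hetero:all_pairs"`, plus `"kw"`, `"anova"`,
#' `"trend_reg"` and the harness self-test `"dummy"` (rejects with
#' probability `alpha`).
#'
#' @param scenario A [moi_scenario()]; its `seed` makes the study fully
#'   reproducible and, for a fixed seed, normal and log-normal runs share
#'   the same underlying draws so their rank-test decisions can be compared
#'   replicate by replicate.
#' @param methods Character vector of method identifiers.
#' @param alpha Nominal level.
#' @param keep_reps Attach the replicate-level rejection indicators as
#'   attribute `"indicators"` (reps x methods matrix).
#' @return A tibble of class `moi_study`: one row per method with
#'   `rejections`, `rate`, `mc_se` = sqrt(rate (1 - rate) / reps),
#'   `redraws`, and the scenario parameters.
#' @export
run_study <- function(scenario, methods = c("np:marcus", "kw"),
                      alpha = 0.05, keep_reps = FALSE) {
  stopifnot(inherits(scenario, "moi_scenario"))
  if (scenario$reps < 100L) stop("need at least 100 replicates", call. = FALSE)
  specs <- lapply(methods, parse_method)
  values <- genotypic_values(scenario$mode, scenario$h2, scenario$q1,
                             scenario$sigma2)
  need_np <- any(vapply(specs, function(s) s$base %in% c("np", "np_fisher"),
                        logical(1)))
  reject <- matrix(FALSE, nrow = scenario$reps, ncol = length(methods),
                   dimnames = list(NULL, methods))
  redraws <- 0L

  set.seed(scenario$seed)
  for (r in seq_len(scenario$reps)) {
    attempts <- 0L
    repeat {
      g <- draw_genotypes(scenario)
      counts <- tabulate(g$marker + 1L, nbins = 3L)
      if (all(counts >= 2L)) break
      redraws <- redraws + 1L
      attempts <- attempts + 1L
      if (attempts > 10000L) {
        stop("marker genotype classes persistently below size 2; scenario infeasible",
             call. = FALSE)
      }
    }
    y <- draw_phenotypes(g$trait, values, scenario$dist, scenario$sigma2)
    gs <- as_grouped_sample(split(y, factor(g$marker, levels = 0:2)))
    eff <- if (need_np) effect_covariance(gs) else NULL

    for (j in seq_along(specs)) {
      s <- specs[[j]]
      reject[r, j] <- switch(s$base,
        np = np_global_p(eff, s$contrasts) < alpha,
        np_fisher = np_global_p(eff, s$contrasts, scale = "fisher") < alpha,
        np_pairwise = np_pairwise_global_p(gs, s$contrasts) < alpha,
        kw = ,
        anova = ,
        trend_reg = comparator_test(gs, s$base, alpha)$reject,
        param_homo = comparator_test(gs, "mctp_param_homo", alpha,
                                     contrasts = s$contrasts)$reject,
        param_hetero = comparator_test(gs, "mctp_param_hetero", alpha,
                                       contrasts = s$contrasts)$reject,
        dummy = stats::runif(1) < alpha
      )
    }
  }

  out <- tibble::tibble(
    method = methods,
    reps = scenario$reps,
    rejections = colSums(reject),
    rate = colMeans(reject),
    mc_se = sqrt(colMeans(reject) * (1 - colMeans(reject)) / scenario$reps),
    redraws = redraws,
    N = scenario$N, q1 = scenario$q1, q2 = scenario$q2,
    delta = scenario$delta, h2 = scenario$h2, mode = scenario$mode,
    dist = scenario$dist, alpha = alpha, seed = scenario$seed
  )
  class(out) <- c("moi_study", class(out))
  if (keep_reps) attr(out, "indicators") <- reject
  out
}
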