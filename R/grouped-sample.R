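#' Group a phenotype-genotype table by risk-allele count
#'
#' Splits one quantitative trait into the three genotype groups of a
#' di-allelic marker, ordered by the number of risk-allele copies
#' (0 = homozygous non-risk, 1 = heterozygous, 2 = homozygous risk).
#' All estimation in the package operates on this container.
#'
#' @param data A data frame with one row per subject, or a list of three
#'   numeric vectors already ordered by risk-allele count (passed to
#'   [as_grouped_sample()]).
#' @param trait Bare column name of the quantitative trait (default `trait`).
#' @param genotype Bare column name of the genotype, coded 0/1/2 risk-allele
#'   copies (default `genotype`).
#'
#' @return An object of class `grouped_sample`: a list with elements
#'   `groups` (list of three numeric vectors), `n` (group sizes) and `N`
#'   (total sample size).
#'
#' @details Ties among trait values are permitted and handled downstream by
#'   mid-ranks, so ordered-categorical scores and detection-limit data
#'   (all censored values set to one shared constant) are valid inputs.
#'   Effect estimation works with any non-empty groups; testing requires at
#'   least two subjects per genotype class, otherwise the within-group
#'   variance of the effect estimator is not estimable
#'   ([effect_covariance()] errors).
#'
#' @examples
#' d <- tibble::tibble(trait = c(1, 2, 3, 4, 5, 6),
#'                     genotype = c(0, 0, 1, 1, 2, 2))
#' grouped_sample(d)
#' @export
grouped_sample <- function(data, trait = trait, genotype = genotype) {
  if (is.list(data) && !is.data.frame(data)) {
    return(as_grouped_sample(data))
  }
  stopifnot(is.data.frame(data))
  tr <- dplyr::pull(data, {{ trait }})
  gt <- dplyr::pull(data, {{ genotype }})
  if (is.factor(gt)) gt <- as.integer(gt) - 1L
  if (!is.numeric(gt) || !all(gt %in% c(0, 1, 2))) {
    stop("`genotype` must be coded as 0, 1 or 2 risk-allele copies", call. = FALSE)
  }
  as_grouped_sample(split(as.numeric(tr), factor(gt, levels = 0:2)))
}

#' Coerce a list of three value vectors to a grouped sample
#'
#' @param groups List of three numeric vectors ordered by risk-allele count.
#' @return A `grouped_sample` object.
#' @export
as_grouped_sample <- function(groups) {
  if (inherits(groups, "grouped_sample")) return(groups)
  if (!is.list(groups) || length(groups) != 3L) {
    stop("a grouped sample needs exactly 3 genotype groups", call. = FALSE)
  }
  groups <- lapply(groups, as.numeric)
  n <- vapply(groups, length, integer(1))
  if (any(n < 1L)) {
    stop("every genotype group needs at least 1 observation (n = ",
         paste(n, collapse = ", "), ")", call. = FALSE)
  }
  if (!all(vapply(groups, function(x) all(is.finite(x)), logical(1)))) {
    stop("trait values must be finite", call. = FALSE)
  }
  structure(
    list(groups = unname(groups), n = unname(n), N = sum(n)),
    class = "grouped_sample"
  )
}

#' @export
print.grouped_sample <- function(x, ...) {
  cat("<grouped_sample> N =", x$N, " n = (", paste(x$n, collapse = ", "), ")\n")
  invisible(x)
}

# pooled trait vector with group index, in group order
gs_flatten <- function(gs) {
  list(values = unlist(gs$groups, use.names = FALSE),
       group = rep.int(seq_len(3L), gs$n))
}
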