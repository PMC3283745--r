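#' Marcus-type genetic contrast matrix
#'
#' Builds the three contrasts that are sensitive to exactly one basic mode
#' of inheritance each, comparing pooled relative effects of genotype
#' groups (aa, aA, AA ordered by risk-allele count):
#' \describe{
#'   \item{dominant}{pooled \{aA, AA\} vs aa: (-1, n2/(n2+n3), n3/(n2+n3));
#'     under dominance F2 = F3, so their effects are pooled with
#'     sample-size weights.}
#'   \item{additive}{AA vs aa: (-1, 0, 1).}
#'   \item{recessive}{AA vs pooled \{aa, aA\}:
#'     (-n1/(n1+n2), -n2/(n1+n2), 1).}
#' }
#' In a balanced design the matrix reduces to rows (-1, .5, .5), (-1, 0, 1),
#' (-.5, -.5, 1). Rows are oriented so a positive contrast means higher
#' trait values with more risk-allele copies.
#'
#' @param n1,n2,n3 Genotype group sizes (all >= 1).
#' @return A `moi_contrasts` object: list with `matrix` (3x3, rows summing
#'   to 0), `labels`, and the `weights` (group sizes) used.
#' @examples
#' contrast_marcus(10, 20, 30)$matrix
#' @export
contrast_marcus <- function(n1, n2, n3) {
  n <- c(n1, n2, n3)
  if (any(n < 1)) stop("group sizes must be >= 1 to form Marcus contrasts", call. = FALSE)
  m <- rbind(
    dominant  = c(-1, n2 / (n2 + n3), n3 / (n2 + n3)),
    additive  = c(-1, 0, 1),
    recessive = c(-n1 / (n1 + n2), -n2 / (n1 + n2), 1)
  )
  new_contrasts(m, weights = n)
}

#' All-pairs (Tukey-type) contrast matrix
#'
#' The three pairwise comparisons 2-1, 3-1, 3-2 among the genotype groups;
#' sensitive against any heterogeneity rather than a specific mode of
#' inheritance, and the rank-based counterpart of a Tukey all-pairs test.
#'
#' @return A `moi_contrasts` object.
#' @export
contrast_all_pairs <- function() {
  m <- rbind(`2-1` = c(-1, 1, 0),
             `3-1` = c(-1, 0, 1),
             `3-2` = c(0, -1, 1))
  new_contrasts(m, weights = NULL)
}

new_contrasts <- function(m, weights) {
  stopifnot(is.matrix(m), ncol(m) == 3L)
  if (any(abs(rowSums(m)) > 1e-12)) stop("contrast rows must sum to 0", call. = FALSE)
  if (any(apply(m, 1, function(r) all(r == 0)))) {
    stop("all-zero contrast row", call. = FALSE)
  }
  structure(list(matrix = m, labels = rownames(m), weights = weights),
            class = "moi_contrasts")
}

#' @export
print.moi_contrasts <- function(x, ...) {
  cat("<moi_contrasts>\n")
  print(round(x$matrix, 4))
  invisible(x)
}

#' Apply a contrast matrix to a relative-effect vector
#'
#' @param spec A `moi_contrasts` object (or bare matrix with 3 columns).
#' @param p_hat Numeric length-3 vector of relative effects.
#' @param flip_sign Flip the reporting orientation (multiply all contrasts
#'   by -1); two-sided inference is unaffected.
#' @return Named numeric vector of contrast effects, each in \[-1, 1\].
#' @export
apply_contrasts <- function(spec, p_hat, flip_sign = FALSE) {
  m <- if (inherits(spec, "moi_contrasts")) spec$matrix else spec
  if (!is.numeric(p_hat) || length(p_hat) != ncol(m)) {
    stop("effect vector length does not match the contrast matrix", call. = FALSE)
  }
  out <- drop(m %*% p_hat)
  if (flip_sign) out <- -out
  out
}
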