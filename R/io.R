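#' Read a phenotype-genotype dataset
#'
#' Reads a TSV with columns `id`, `trait`, `genotype` (genotype coded as
#' 0/1/2 risk-allele copies or as allele-pair strings such as `"AG"` or
#' `"A/G"`), or extracts a single biallelic SNP from a VCF combined with a
#' phenotype TSV keyed by sample id. Rows with missing trait or genotype
#' are dropped and counted (no imputation). Detection-limit phenotypes may
#' be encoded by fixing all censored values to one shared constant; the
#' resulting ties are handled by mid-ranks downstream.
#'
#' @param path TSV file, or VCF file when `format = "vcf"`.
#' @param format `"tsv"` (default) or `"vcf"`.
#' @param risk_allele Which allele to count. For allele-string genotypes a
#'   literal allele (e.g. `"A"`); for 0/1/2 codings and VCF mode, `"ALT"`
#'   (default) or `"REF"` to flip the orientation.
#' @param pheno Phenotype TSV (columns `id`, `trait`) for VCF mode.
#' @param snp_id SNP identifier (VCF `ID` column) for VCF mode.
#' @return List with `data` (tibble: `id`, `trait`, `genotype`), `grouped`
#'   (a [grouped_sample()]) and `dropped` (number of removed rows).
#' @export
read_moi_data <- function(path, format = c("tsv", "vcf"),
                          risk_allele = "ALT", pheno = NULL, snp_id = NULL) {
  format <- match.arg(format)
  d <- if (format == "tsv") {
    read_trait_tsv(path, risk_allele)
  } else {
    read_vcf_snp(path, pheno, snp_id, risk_allele)
  }
  n0 <- nrow(d)
  d <- dplyr::filter(d, is.finite(.data$trait), !is.na(.data$genotype))
  dropped <- n0 - nrow(d)
  if (dropped > 0) message(dropped, " row(s) with missing trait or genotype dropped")
  present <- sort(unique(d$genotype))
  if (length(present) < 3L) {
    stop("fewer than 3 genotype classes present (found: ",
         paste(present, collapse = ", "), ")", call. = FALSE)
  }
  counts <- table(d$genotype)
  if (any(counts < 2L)) {
    stop("every genotype class needs at least 2 subjects for testing (n = ",
         paste(as.integer(counts), collapse = ", "), ")", call. = FALSE)
  }
  list(data = d, grouped = grouped_sample(d), dropped = dropped)
}

read_trait_tsv <- function(path, risk_allele) {
  d <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(.default = readr::col_character()))
  need <- c("id", "trait", "genotype")
  if (!all(need %in% names(d))) {
    stop("TSV must have columns id, trait, genotype", call. = FALSE)
  }
  trait <- suppressWarnings(as.numeric(d$trait))
  gt_raw <- d$genotype
  numeric_like <- grepl("^[012]$", gt_raw) | is.na(gt_raw)
  gt <- if (all(numeric_like)) {
    as.integer(gt_raw)
  } else {
    code_allele_strings(gt_raw, risk_allele)
  }
  tibble::tibble(id = d$id, trait = trait, genotype = gt)
}

code_allele_strings <- function(gt_raw, risk_allele) {
  if (is.null(risk_allele) || risk_allele %in% c("ALT", "REF")) {
    stop("allele-string genotypes need an explicit risk_allele (e.g. \"A\")",
         call. = FALSE)
  }
  alleles <- strsplit(gsub("[/|]", "", gt_raw), "")
  bad <- !vapply(alleles, length, integer(1)) %in% c(0L, 2L)
  if (any(bad, na.rm = TRUE)) {
    stop("genotype strings must contain exactly two alleles", call. = FALSE)
  }
  seen <- unique(unlist(alleles))
  seen <- seen[!is.na(seen)]
  if (!risk_allele %in% seen) {
    stop("risk allele '", risk_allele, "' not observed; alleles present: ",
         paste(seen, collapse = ", "), call. = FALSE)
  }
  if (length(seen) > 2L) {
    stop("more than two alleles present (", paste(seen, collapse = ", "),
         "); marker is not di-allelic", call. = FALSE)
  }
  vapply(alleles, function(a) {
    if (length(a) == 0L) NA_integer_ else sum(a == risk_allele)
  }, integer(1))
}

read_vcf_snp <- function(path, pheno, snp_id, risk_allele = "ALT") {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("VCF input requires the vcfR package", call. = FALSE)
  }
  if (is.null(pheno) || is.null(snp_id)) {
    stop("VCF mode needs `pheno` (phenotype TSV) and `snp_id`", call. = FALSE)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  ids <- vcfR::getID(v)
  row <- which(ids == snp_id)
  if (length(row) != 1L) {
    stop("SNP '", snp_id, "' not found (or not unique) in VCF", call. = FALSE)
  }
  gt <- vcfR::extract.gt(v, element = "GT")[row, ]
  counts <- vapply(strsplit(gt, "[/|]"), function(a) {
    if (anyNA(a) || any(a == ".")) return(NA_integer_)
    sum(a == "1")
  }, integer(1))
  if (identical(risk_allele, "REF")) counts <- 2L - counts
  ph <- readr::read_tsv(pheno, show_col_types = FALSE)
  if (!all(c("id", "trait") %in% names(ph))) {
    stop("phenotype TSV must have columns id, trait", call. = FALSE)
  }
  tibble::tibble(id = names(counts), genotype = unname(counts)) |>
    dplyr::inner_join(dplyr::mutate(ph, id = as.character(.data$id)), by = "id") |>
    dplyr::select("id", "trait", "genotype")
}

#' Write a test result to TSV or JSON
#'
#' TSV output has one row per contrast (model label, effect estimate,
#' simultaneous interval, adjusted p-value) followed by `#`-prefixed footer
#' lines with the global decision; JSON output serializes the full result
#' and round-trips through [read_moi_results()].
#'
#' @param result A `moi_test` object.
#' @param path Output file.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_moi_results <- function(result, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  stopifnot(inherits(result, "moi_test"))
  if (format == "tsv") {
    tab <- result$table
    lines <- c(
      "model\testimate\tlower\tupper\tadj_p",
      sprintf("%s\t%.6g\t%.6g\t%.6g\t%.6g",
              tab$contrast, tab$estimate, tab$lower, tab$upper, tab$p_adj),
      sprintf("# global_reject\t%s", result$global_reject),
      sprintf("# global_p\t%.6g", result$p_global),
      sprintf("# alpha\t%g", result$alpha),
      sprintf("# quantile\t%.6g", result$quantile),
      sprintf("# df\t%.6g", result$df)
    )
    writeLines(lines, path)
  } else {
    x <- unclass(result)
    x$effects <- NULL  # per-observation slots are not part of the report
    x$contrast_spec <- NULL
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns")
  }
  invisible(path)
}

#' Read back a JSON result written by [write_moi_results()]
#'
#' @param path JSON file.
#' @return A `moi_test` object (without the per-observation effect slots).
#' @export
read_moi_results <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$table <- tibble::as_tibble(x$table)
  x$corr <- matrix(unlist(x$corr), nrow = nrow(x$table))
  structure(x, class = "moi_test")
}

#' Generate a deterministic synthetic phenotype-genotype fixture
#'
#' Produces datasets emulating the qualitative regimes of genotype-trait
#' data: `"null"` (three identical standard-normal groups), `"dominant"` /
#' `"additive"` / `"recessive"` (unit shifts following the mode of
#' inheritance, with groups 2 and 3, none, or groups 1 and 2 sharing a
#' generating distribution), `"tied"` (ordered-categorical trait with at
#' most 5 distinct values), and `"unbalanced"` (group sizes following
#' Hardy-Weinberg proportions of a rare allele, minimum class size 2).
#'
#' @param kind One of `"null"`, `"dominant"`, `"additive"`, `"recessive"`,
#'   `"tied"`, `"unbalanced"`.
#' @param n Total number of subjects (split across the three classes).
#' @param seed RNG seed; identical arguments give identical data.
#' @param path Optional TSV output path.
#' @return A tibble (`id`, `trait`, `genotype`), invisibly written to
#'   `path` when given.
#' @export
generate_fixture <- function(kind = c("null", "dominant", "additive",
                                      "recessive", "tied", "unbalanced"),
                             n = 60, seed = 1, path = NULL) {
  kind <- match.arg(kind)
  n <- as.integer(n)
  sizes <- if (kind == "unbalanced") {
    s <- round(n * c(0.81, 0.18, 0.01))
    s <- pmax(s, 2L)
    s[1] <- n - s[2] - s[3]
    s
  } else {
    s <- rep(n %/% 3L, 3L)
    s[seq_len(n %% 3L)] <- s[seq_len(n %% 3L)] + 1L
    s
  }
  if (any(sizes < 2L)) stop("need at least 2 subjects per class", call. = FALSE)
  shift <- switch(kind,
                  null = c(0, 0, 0),
                  dominant = c(0, 1, 1),
                  additive = c(0, 0.5, 1),
                  recessive = c(0, 0, 1),
                  tied = c(0, 0, 0),
                  unbalanced = c(0, 0, 0))
  old_seed <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  trait <- if (kind == "tied") {
    sample(1:4, sum(sizes), replace = TRUE, prob = c(0.4, 0.3, 0.2, 0.1))
  } else {
    stats::rnorm(sum(sizes)) + rep(shift, sizes)
  }
  d <- tibble::tibble(
    id = sprintf("S%03d", seq_len(sum(sizes))),
    trait = trait,
    genotype = rep(0:2, sizes)
  )
  if (!is.null(path)) {
    readr::write_tsv(d, path)
  }
  d
}

#' Parse a flat key-value scenario file
#'
#' One scenario per stanza; stanzas are separated by blank lines, each line
#' `key = value` with the [moi_scenario()] fields (`N`, `q1`, `q2`,
#' `delta`, `h2`, `mode`, `dist`, `sigma2`, `reps`, `seed`). `delta` may be
#' given as `dmax` or `dmax/2`.
#'
#' @param path Scenario file.
#' @return List of [moi_scenario()] objects.
#' @export
read_scenarios <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[!grepl("^#", lines)]
  stanza_id <- cumsum(lines == "")
  stanzas <- split(lines[lines != ""], stanza_id[lines != ""])
  lapply(unname(stanzas), function(s) {
    kv <- strsplit(s, "=", fixed = TRUE)
    keys <- trimws(vapply(kv, `[`, character(1), 1))
    vals <- trimws(vapply(kv, `[`, character(1), 2))
    names(vals) <- keys
    num <- function(k, default = NULL) {
      if (k %in% keys) as.numeric(vals[[k]]) else default
    }
    q1 <- num("q1"); q2 <- num("q2")
    delta_raw <- if ("delta" %in% keys) vals[["delta"]] else "0"
    delta <- switch(delta_raw,
                    dmax = delta_max(q1, q2),
                    `dmax/2` = delta_max(q1, q2) / 2,
                    as.numeric(delta_raw))
    moi_scenario(N = num("N"), q1 = q1, q2 = q2, delta = delta,
                 h2 = num("h2", 0),
                 mode = if ("mode" %in% keys) vals[["mode"]] else "additive",
                 dist = if ("dist" %in% keys) vals[["dist"]] else "normal",
                 sigma2 = num("sigma2", 1),
                 reps = num("reps", 1000), seed = num("seed", 1))
  })
}
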