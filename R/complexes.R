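# Complex-level co-expression: median pairwise member correlation,
# variability (1 - median R), stable/variable quartile classes, paralog
# content, per-subunit medians, and the random-complex permutation null.

all_pairwise_R <- function(v, members, min_obs) {
  combs <- combn(members, 2)
  apply(combs, 2, function(pr) {
    pair_correlation(v[pr[1], ], v[pr[2], ], min_obs = min_obs)$R
  })
}

#' Median pairwise co-expression per protein complex
#'
#' For every complex with at least `min_members` members quantified in the
#' dataset, all pairwise Pearson correlations between quantified members are
#' computed and summarised by their median; complex variability is
#' `1 - median_R`. A pairwise correlation enters the median only when it is
#' defined under the `min_obs` rule, and a complex is scored only when at
#' least half of its `choose(min_members, 2)` pairs have a defined R.
#'
#' @param dataset An [expression_dataset()].
#' @param catalog Named list: complex id -> member gene ids.
#' @param min_members Minimum quantified members (default 5).
#' @param min_obs Minimum pairwise-complete samples per correlation.
#' @return A tibble: `complex_id`, `n_members`, `n_quantified`,
#'   `n_pairs_defined`, `median_R`, `variability`.
#' @export
complex_coexpression <- function(dataset, catalog, min_members = 5,
                                 min_obs = 5) {
  stopifnot(inherits(dataset, "expression_dataset"))
  if (!length(catalog)) abort("Empty complex catalog.")
  v <- dataset$values
  min_defined <- ceiling(choose(min_members, 2) / 2)
  purrr::imap(catalog, function(members, id) {
    quant <- intersect(members, rownames(v))
    if (length(quant) < min_members) return(NULL)
    rs <- all_pairwise_R(v, quant, min_obs)
    rs <- rs[!is.na(rs)]
    if (length(rs) < min_defined) return(NULL)
    tibble(complex_id = id, n_members = length(members),
           n_quantified = length(quant), n_pairs_defined = length(rs),
           median_R = median(rs), variability = 1 - median(rs))
  }) %>%
    purrr::compact() %>%
    bind_rows()
}

#' Classify complexes as stable, variable or intermediate
#'
#' The top quartile of the observed `median_R` distribution is labelled
#' stable, the bottom quartile variable, the rest intermediate. Boundary
#' ties go to intermediate (strict inequalities against the quartile
#' values), which keeps class sizes conservative when the distribution is
#' degenerate.
#'
#' @param summaries Output of [complex_coexpression()].
#' @return `summaries` with an added `stability_class` column.
#' @export
classify_complex_stability <- function(summaries) {
  ok <- !is.na(summaries$median_R)
  if (sum(ok) < 4) {
    warn("Fewer than 4 complexes with defined median_R; all intermediate.")
    summaries$stability_class <- if_else(ok, "intermediate", NA_character_)
    return(summaries)
  }
  qs <- quantile(summaries$median_R[ok], c(0.25, 0.75))
  summaries$stability_class <- dplyr::case_when(
    !ok ~ NA_character_,
    summaries$median_R > qs[2] ~ "stable",
    summaries$median_R < qs[1] ~ "variable",
    TRUE ~ "intermediate"
  )
  summaries
}

#' Paralog content of a complex
#'
#' Fraction of complex members that have at least one paralog — either
#' anywhere in the genome (`scope = "genome"`, using precomputed flags) or
#' within the same complex (`scope = "same_complex"`, requiring a pair
#' table).
#'
#' @param members Character vector of member genes.
#' @param has_paralog Named logical vector covering `members`
#'   (see [flag_has_paralog()]); required for `scope = "genome"`.
#' @param scope `"genome"` or `"same_complex"`.
#' @param pairs Canonical pair table; required for `scope = "same_complex"`.
#' @return A fraction in \[0, 1\].
#' @export
paralog_content <- function(members, has_paralog = NULL,
                            scope = c("genome", "same_complex"),
                            pairs = NULL) {
  scope <- match.arg(scope)
  if (!length(members)) abort("Empty complex.")
  if (scope == "genome") {
    if (is.null(has_paralog)) abort("`has_paralog` flags required.")
    if (!all(members %in% names(has_paralog))) {
      abort("`has_paralog` must cover all members.")
    }
    return(mean(has_paralog[members]))
  }
  if (is.null(pairs)) abort("`pairs` required for scope = \"same_complex\".")
  flagged <- vapply(members, function(g) {
    partners <- c(pairs$gene_b[pairs$gene_a == g],
                  pairs$gene_a[pairs$gene_b == g])
    any(partners %in% members)
  }, logical(1))
  mean(flagged)
}

#' Correlation between complex variability and paralog content
#'
#' Tests whether complexes containing more paralog-bearing members are more
#' variable in member co-expression. Optionally excludes heterodimers
#' (complexes of size 2) and complexes composed entirely of paralogs, the
#' robustness variant.
#'
#' @param summaries Output of [complex_coexpression()] with an added
#'   `paralog_content` column (see [paralog_content()]).
#' @param exclude_dimers Drop complexes with `n_members == 2`.
#' @param exclude_all_paralog Drop complexes with `paralog_content == 1`.
#' @return An object of class `cv_relation` with the Pearson estimate,
#'   two-sided p-value and the data used; see [tidy.cv_relation()].
#' @export
content_variability_relation <- function(summaries, exclude_dimers = FALSE,
                                         exclude_all_paralog = FALSE) {
  d <- summaries %>% filter(!is.na(.data$variability),
                            !is.na(.data$paralog_content))
  if (exclude_dimers) d <- filter(d, .data$n_members > 2)
  if (exclude_all_paralog) d <- filter(d, .data$paralog_content < 1)
  if (nrow(d) < 3 || sd(d$paralog_content) == 0 || sd(d$variability) == 0) {
    out <- list(estimate = NA_real_, p_value = NA_real_, n = nrow(d), data = d)
    class(out) <- "cv_relation"
    return(out)
  }
  ct <- cor.test(d$paralog_content, d$variability)
  out <- list(estimate = unname(ct$estimate), p_value = ct$p.value,
              n = nrow(d), data = d)
  class(out) <- "cv_relation"
  out
}

#' @export
print.cv_relation <- function(x, ...) {
  cat("Complex variability vs paralog content\n")
  cat(sprintf("  Pearson R = %.3f, p = %.3g, n = %d complexes\n",
              x$estimate, x$p_value, x$n))
  invisible(x)
}

#' Tidiers for `cv_relation` objects
#'
#' @param x A `cv_relation` from [content_variability_relation()].
#' @param ... Unused.
#' @return `tidy()` returns a one-row tibble with `estimate` and `p.value`;
#'   `glance()` adds `n`.
#' @exportS3Method generics::tidy
tidy.cv_relation <- function(x, ...) {
  tibble(estimate = x$estimate, p.value = x$p_value)
}

#' @rdname tidy.cv_relation
#' @exportS3Method generics::glance
glance.cv_relation <- function(x, ...) {
  tibble(estimate = x$estimate, p.value = x$p_value, n = x$n)
}

#' Per-subunit median correlation with complex co-members
#'
#' For each quantified member of each retained complex, the median Pearson
#' correlation with all the other quantified members. Low values flag
#' subunits whose expression detaches from the rest of the complex.
#'
#' @inheritParams complex_coexpression
#' @param exclude_paralog_partner When `TRUE` and `pairs` is supplied, a
#'   subunit's own paralog partners are removed from its "other members".
#' @param pairs Optional canonical pair table (only used by the exclusion).
#' @return A tibble: `complex_id`, `gene`, `n_others`, `median_R`.
#' @export
subunit_median_correlation <- function(dataset, catalog, min_members = 5,
                                       min_obs = 5,
                                       exclude_paralog_partner = FALSE,
                                       pairs = NULL) {
  stopifnot(inherits(dataset, "expression_dataset"))
  v <- dataset$values
  purrr::imap(catalog, function(members, id) {
    quant <- intersect(members, rownames(v))
    if (length(quant) < min_members) return(NULL)
    purrr::map(quant, function(g) {
      others <- setdiff(quant, g)
      if (exclude_paralog_partner && !is.null(pairs)) {
        partners <- c(pairs$gene_b[pairs$gene_a == g],
                      pairs$gene_a[pairs$gene_b == g])
        others <- setdiff(others, partners)
      }
      rs <- vapply(others, function(o) {
        pair_correlation(v[g, ], v[o, ], min_obs = min_obs)$R
      }, numeric(1))
      rs <- rs[!is.na(rs)]
      tibble(complex_id = id, gene = g, n_others = length(rs),
             median_R = if (length(rs)) median(rs) else NA_real_)
    }) %>% bind_rows()
  }) %>%
    purrr::compact() %>%
    bind_rows()
}

#' Null distribution of complex co-expression from random complexes
#'
#' Replicates the real catalog's size spectrum with pseudo-complexes whose
#' members are drawn at random (without replacement within a complex) from
#' the dataset's quantified genes, and scores them exactly as
#' [complex_coexpression()] does. Comparing real and null `median_R`
#' distributions shows how much member co-expression exceeds chance.
#'
#' @inheritParams complex_coexpression
#' @param n_reps Number of randomized catalogs.
#' @param seed Integer seed.
#' @return A tibble of null summaries with an added `rep` column.
#' @export
random_complex_null <- function(dataset, catalog, n_reps = 10,
                                min_members = 5, min_obs = 5, seed = 1L) {
  stopifnot(inherits(dataset, "expression_dataset"))
  genes <- rownames(dataset$values)
  sizes <- vapply(catalog, function(m) length(intersect(m, genes)),
                  integer(1))
  sizes <- sizes[sizes >= min_members]
  if (!length(sizes)) abort("No complex passes `min_members` in the data.")
  if (max(sizes) > length(genes)) {
    abort("Dataset has fewer genes than the largest complex.")
  }
  withr::local_seed(seed)
  purrr::map(seq_len(n_reps), function(r) {
    pseudo <- lapply(sizes, function(s) sample(genes, s))
    names(pseudo) <- paste0("null_", names(sizes), "_rep", r)
    complex_coexpression(dataset, pseudo, min_members = min_members,
                         min_obs = min_obs) %>%
      mutate(rep = r)
  }) %>% bind_rows()
}
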