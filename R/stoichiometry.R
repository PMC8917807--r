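# Stoichiometric stability of complex subunits: per-subunit median
# fold-change distance to co-members, scored against an empirical null of
# randomly assembled complexes of equal size.

#' Log2 fold changes relative to the first condition
#'
#' Averages log2 quantities over replicates within each condition and
#' subtracts the first (reference) condition, yielding one log2 fold change
#' per gene per non-reference condition.
#'
#' @param dataset An [expression_dataset()] on log2 scale.
#' @param ref Reference condition label; defaults to the first condition in
#'   the metadata.
#' @return A numeric matrix, genes x comparisons, with comparison names
#'   `"<condition>_vs_<ref>"`.
#' @export
fold_change_matrix <- function(dataset, ref = NULL) {
  stopifnot(inherits(dataset, "expression_dataset"))
  if (dataset$scale != "log2") {
    abort("`fold_change_matrix()` expects a log2-scale dataset.")
  }
  conds <- unique(dataset$meta$condition)
  if (is.null(ref)) ref <- conds[1]
  if (!ref %in% conds) abort("Unknown reference condition.")
  cond_means <- vapply(conds, function(cc) {
    cols <- dataset$meta$sample[dataset$meta$condition == cc]
    rowMeans(dataset$values[, cols, drop = FALSE], na.rm = TRUE)
  }, numeric(nrow(dataset$values)))
  cond_means[is.nan(cond_means)] <- NA_real_
  others <- setdiff(conds, ref)
  fc <- cond_means[, others, drop = FALSE] - cond_means[, ref]
  colnames(fc) <- paste0(others, "_vs_", ref)
  fc
}

#' Median Euclidean fold-change distance of a subunit to its co-members
#'
#' The Euclidean distance between the subunit's fold-change vector and each
#' co-member's vector (the absolute difference when a single comparison is
#' analyzed), summarised by the median.
#'
#' @param subunit_fc Numeric vector of log2 fold changes.
#' @param member_fcs Matrix of co-member fold changes (rows = members,
#'   columns aligned with `subunit_fc`), or a numeric vector for a single
#'   co-member.
#' @return The median distance (non-negative).
#' @export
median_fc_distance <- function(subunit_fc, member_fcs) {
  if (is.null(dim(member_fcs))) {
    if (length(member_fcs) != length(subunit_fc)) {
      abort("Fold-change vectors must be aligned on the same comparisons.")
    }
    member_fcs <- matrix(member_fcs, ncol = length(subunit_fc))
  }
  if (!nrow(member_fcs)) abort("Need at least one co-member.")
  if (ncol(member_fcs) != length(subunit_fc)) {
    abort("Fold-change vectors must be aligned on the same comparisons.")
  }
  d <- sqrt(rowSums(sweep(member_fcs, 2, subunit_fc)^2))
  median(d)
}

#' Add-one smoothed empirical probability
#'
#' `p = (#\{null < observed\} + 1) / (n_null + 1)` (or `<=` when
#' `strict = FALSE`): the probability of observing a smaller value under
#' the empirical null, smoothed so that p is never 0 and its minimum
#' `1/(n_null + 1)` is attained only when no null value is strictly
#' smaller.
#'
#' @param null Numeric vector of null draws.
#' @param observed Observed statistic.
#' @param strict Use strict `<` (default) or `<=`.
#' @return The empirical probability in `(0, 1]`.
#' @export
empirical_p <- function(null, observed, strict = TRUE) {
  hits <- if (strict) sum(null < observed) else sum(null <= observed)
  (hits + 1) / (length(null) + 1)
}

# shared empirical null: median distance of a random subunit to (size-1)
# random co-members, per complex size class
null_distances <- function(fc, size, n_null) {
  n_genes <- nrow(fc)
  vapply(seq_len(n_null), function(i) {
    idx <- sample.int(n_genes, size)
    median_fc_distance(fc[idx[1], ], fc[idx[-1], , drop = FALSE])
  }, numeric(1))
}

#' Stoichiometric stability of complex subunits against a permutation null
#'
#' For each condition comparison and each complex with at least
#' `min_members` quantified members, computes every subunit's median
#' fold-change distance to its co-members and converts it to an empirical
#' probability of observing a lower distance among subunits of randomly
#' assembled complexes of the same size (members drawn from all quantified
#' genes). Low p means the subunit moves with its complex — stoichiometric
#' stability; high p flags variable subunits.
#'
#' The empirical p uses add-one smoothing,
#' `p = (#\{null < observed\} + 1) / (n_null + 1)`, so the smallest
#' attainable value `1/(n_null + 1)` is reached only when no null draw is
#' strictly smaller (e.g. a zero-distance subunit). One null of `n_null`
#' draws is shared per complex-size class within each comparison; set
#' `per_subunit_null = TRUE` to draw a fresh null per subunit.
#'
#' @param dataset A log2-scale [expression_dataset()].
#' @param catalog Named list of complex member vectors.
#' @param n_null Null draws per size class (default 2500).
#' @param min_members Minimum quantified members per complex (default 5).
#' @param seed Integer seed.
#' @param strict Use strict `<` in the null comparison (default `TRUE`); the
#'   `<=` variant is available for sensitivity analysis.
#' @param per_subunit_null Draw an independent null per subunit.
#' @param ref Reference condition for fold changes.
#' @return A tibble: `gene`, `complex_id`, `comparison`, `median_distance`,
#'   `p`, `n_null`.
#' @export
subunit_stability <- function(dataset, catalog, n_null = 2500,
                              min_members = 5, seed = 1L, strict = TRUE,
                              per_subunit_null = FALSE, ref = NULL) {
  fc_all <- fold_change_matrix(dataset, ref = ref)
  withr::local_seed(seed)
  out <- purrr::map(colnames(fc_all), function(comparison) {
    fc <- fc_all[, comparison, drop = FALSE]
    fc <- fc[!is.na(fc[, 1]), , drop = FALSE]
    quant_catalog <- lapply(catalog, function(m) intersect(m, rownames(fc)))
    quant_catalog <- quant_catalog[lengths(quant_catalog) >= min_members]
    if (!length(quant_catalog)) return(NULL)
    sizes <- sort(unique(lengths(quant_catalog)))
    if (max(sizes) > nrow(fc)) {
      abort("Too few quantified genes to assemble pseudo-complexes.")
    }
    nulls <- if (!per_subunit_null) {
      setNames(lapply(sizes, function(s) null_distances(fc, s, n_null)),
               as.character(sizes))
    } else NULL
    purrr::imap(quant_catalog, function(members, id) {
      size <- length(members)
      purrr::map(members, function(g) {
        obs <- median_fc_distance(fc[g, ],
                                  fc[setdiff(members, g), , drop = FALSE])
        null <- if (per_subunit_null) null_distances(fc, size, n_null)
                else nulls[[as.character(size)]]
        tibble(gene = g, complex_id = id, comparison = comparison,
               median_distance = obs,
               p = empirical_p(null, obs, strict = strict),
               n_null = n_null)
      }) %>% bind_rows()
    }) %>% bind_rows()
  })
  bind_rows(purrr::compact(out))
}

#' Complex-level co-expression score from subunit stability p-values
#'
#' Summarises [subunit_stability()] to one score per complex and
#' comparison: `1 - median(member p)`. Scores near 1 mean the complex's
#' subunits change stoichiometry coherently.
#'
#' @param stability Output of [subunit_stability()].
#' @param fun Summary across members (default [stats::median]).
#' @return A tibble: `complex_id`, `comparison`, `n_members`, `score`.
#' @export
complex_stability_score <- function(stability, fun = stats::median) {
  stability %>%
    group_by(.data$complex_id, .data$comparison) %>%
    summarise(n_members = dplyr::n(), score = 1 - fun(.data$p),
              .groups = "drop")
}
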