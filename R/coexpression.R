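# Pairwise co-expression of paralog pairs: correlation, divergence
# classification, coefficient of variation, random-pair nulls, identity
# bins, and the protein-vs-transcript delta score.

#' Pearson correlation of two abundance series
#'
#' Computed on pairwise-complete observations. The correlation is undefined
#' (returned as `NA`) when fewer than `min_obs` complete observations remain
#' or when either series is constant over them; a constant series has no
#' defined Pearson correlation and reporting 0 would silently inflate the
#' divergent class.
#'
#' @param x,y Numeric vectors aligned on the same samples.
#' @param min_obs Minimum number of pairwise-complete observations
#'   (default 5, the "identified in at least five time points/tissues" rule).
#' @return A list with `R` (correlation or `NA`) and `n_obs`.
#' @export
pair_correlation <- function(x, y, min_obs = 5) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  ok <- complete.cases(x, y)
  n_obs <- sum(ok)
  if (n_obs < min_obs) return(list(R = NA_real_, n_obs = n_obs))
  xo <- x[ok]; yo <- y[ok]
  if (sd(xo) == 0 || sd(yo) == 0) return(list(R = NA_real_, n_obs = n_obs))
  list(R = cor(xo, yo), n_obs = n_obs)
}

#' Classify a paralog pair as co-regulated or divergent
#'
#' A pair is divergent when its expression correlation is zero or negative
#' (R <= 0) and co-regulated when R > 0.
#'
#' @param R Pearson correlation(s), possibly `NA`.
#' @return Character vector: `"co-regulated"`, `"divergent"`, or `NA`.
#' @export
classify_divergence <- function(R) {
  if_else(is.na(R), NA_character_,
          if_else(R > 0, "co-regulated", "divergent"))
}

#' Coefficient of variation of a linear-scale abundance series
#'
#' CV = sample sd / mean over observed values. Undefined when fewer than
#' `min_obs` observations or when the mean is zero.
#'
#' @param x Non-negative abundances on the linear scale.
#' @param min_obs Minimum observation count (default 5).
#' @return CV, or `NA` when undefined.
#' @export
coefficient_of_variation <- function(x, min_obs = 5) {
  if (any(x < 0, na.rm = TRUE)) abort("Linear abundances must be >= 0.")
  xo <- x[!is.na(x)]
  if (length(xo) < min_obs) return(NA_real_)
  m <- mean(xo)
  if (m == 0) return(NA_real_)
  sd(xo) / m
}

#' Co-expression records for a paralog pair list
#'
#' Computes, for every canonical pair, the Pearson correlation of the two
#' genes' abundance profiles across the dataset's samples, classifies the
#' pair as co-regulated (R > 0) or divergent (R <= 0), and optionally flags
#' pairs whose two members sit in the same protein complex.
#'
#' @param dataset An [expression_dataset()]. Correlations are computed on
#'   the dataset's scale as loaded.
#' @param pairs Canonical pair table from [canonicalize_pairs()].
#' @param catalog Optional complex catalog (named list of member vectors)
#'   used to fill `same_complex`.
#' @param min_obs Minimum pairwise-complete observations per pair.
#' @return A tibble with columns `gene_a`, `gene_b`, `mean_identity`,
#'   `layer`, `R`, `n_obs`, `category`, `same_complex`.
#' @export
pair_coexpression <- function(dataset, pairs, catalog = NULL, min_obs = 5) {
  stopifnot(inherits(dataset, "expression_dataset"))
  pairs <- as_tibble(pairs)
  v <- dataset$values
  present <- pairs$gene_a %in% rownames(v) & pairs$gene_b %in% rownames(v)
  pairs <- pairs[present, ]
  layer <- paste(unique(dataset$meta$layer), collapse = "+")
  res <- purrr::map2(pairs$gene_a, pairs$gene_b, function(a, b) {
    pair_correlation(v[a, ], v[b, ], min_obs = min_obs)
  })
  same_complex <- rep(NA, nrow(pairs))
  if (!is.null(catalog)) {
    same_complex <- purrr::map2_lgl(pairs$gene_a, pairs$gene_b, function(a, b) {
      any(vapply(catalog, function(m) a %in% m && b %in% m, logical(1)))
    })
  }
  tibble(
    gene_a = pairs$gene_a,
    gene_b = pairs$gene_b,
    mean_identity = if ("mean_identity" %in% names(pairs))
      pairs$mean_identity else NA_real_,
    layer = layer,
    R = purrr::map_dbl(res, "R"),
    n_obs = purrr::map_int(res, ~ as.integer(.x$n_obs)),
    category = classify_divergence(purrr::map_dbl(res, "R")),
    same_complex = same_complex
  )
}

#' Estimate the divergent fraction from co-expression records
#'
#' Fraction of pairs with defined R that classify as divergent (R <= 0).
#'
#' @param records Output of [pair_coexpression()].
#' @return A single proportion.
#' @export
divergent_fraction <- function(records) {
  defined <- records$category[!is.na(records$category)]
  if (!length(defined)) return(NA_real_)
  mean(defined == "divergent")
}

#' Null distribution of correlations for random gene pairs
#'
#' Samples `n_draws` pairs of distinct genes uniformly from the dataset,
#' ignoring paralogy, and computes each pair's correlation exactly as
#' [pair_correlation()] does. This is the dashed-line reference null used
#' to judge whether paralog pairs correlate more (or less) than arbitrary
#' gene pairs.
#'
#' @param dataset An `expression_dataset`.
#' @param n_draws Number of random pairs (default 10000).
#' @param min_obs Passed to [pair_correlation()].
#' @param seed Integer seed.
#' @return A tibble with columns `gene_a`, `gene_b`, `R`, `n_obs`.
#' @export
random_pair_null <- function(dataset, n_draws = 10000, min_obs = 5,
                             seed = 1L) {
  stopifnot(inherits(dataset, "expression_dataset"))
  v <- dataset$values
  genes <- rownames(v)
  if (length(genes) < 2) abort("Need at least 2 genes for a random-pair null.")
  withr::local_seed(seed)
  ia <- sample.int(length(genes), n_draws, replace = TRUE)
  ib <- sample.int(length(genes) - 1L, n_draws, replace = TRUE)
  ib <- ifelse(ib >= ia, ib + 1L, ib)  # distinct second index, uniform
  res <- purrr::map2(ia, ib, function(a, b) {
    pair_correlation(v[a, ], v[b, ], min_obs = min_obs)
  })
  tibble(
    gene_a = genes[ia], gene_b = genes[ib],
    R = purrr::map_dbl(res, "R"),
    n_obs = purrr::map_int(res, ~ as.integer(.x$n_obs))
  )
}

#' Compare same-complex and other pairs within sequence-identity bins
#'
#' Pairs are binned by mean reciprocal sequence identity into left-closed
#' intervals `[edge_i, edge_{i+1})` (the last bin is closed on both sides).
#' Within each bin the correlation distributions of same-complex pairs and
#' all other pairs are compared with a two-sided Wilcoxon rank-sum test.
#'
#' @param records Output of [pair_coexpression()] with `same_complex` filled.
#' @param bin_edges Increasing identity percentages (default
#'   `c(0, 25, 50, 75, 100)`).
#' @return A tibble per bin: counts, median R per group, `p` (NA when either
#'   side has fewer than 2 observations, reported as untestable).
#' @export
identity_bin_compare <- function(records, bin_edges = c(0, 25, 50, 75, 100)) {
  if (is.unsorted(bin_edges, strictly = TRUE)) {
    abort("`bin_edges` must be strictly increasing.")
  }
  rec <- records %>%
    filter(!is.na(.data$R), !is.na(.data$mean_identity),
           !is.na(.data$same_complex))
  # left-closed bins [edge, next); the top bin also includes its right edge
  rec$bin <- cut(rec$mean_identity, breaks = bin_edges, right = FALSE,
                 include.lowest = TRUE)
  rec %>%
    filter(!is.na(.data$bin)) %>%
    group_by(.data$bin) %>%
    summarise(
      n_same_complex = sum(.data$same_complex),
      n_other = sum(!.data$same_complex),
      median_R_same_complex = median(.data$R[.data$same_complex]),
      median_R_other = median(.data$R[!.data$same_complex]),
      p = if (sum(.data$same_complex) >= 2 && sum(!.data$same_complex) >= 2) {
        suppressWarnings(wilcox.test(.data$R[.data$same_complex],
                                     .data$R[!.data$same_complex])$p.value)
      } else NA_real_,
      .groups = "drop"
    )
}

#' Delta score: protein minus transcript co-expression per pair
#'
#' For each paralog pair quantified at both layers, the delta score is
#' `R_protein - R_rna`. Positive values mean the pair is more co-expressed
#' at the protein level; negative values flag pairs that diverge post-
#' transcriptionally.
#'
#' @param records_rna,records_protein Outputs of [pair_coexpression()] on
#'   the two layers.
#' @return A tibble with `gene_a`, `gene_b`, `R_rna`, `R_protein`, `delta`.
#'   Pairs missing a defined R at either layer are omitted.
#' @export
transcript_protein_delta <- function(records_rna, records_protein) {
  rna <- records_rna %>%
    filter(!is.na(.data$R)) %>%
    select("gene_a", "gene_b", R_rna = "R")
  prot <- records_protein %>%
    filter(!is.na(.data$R)) %>%
    select("gene_a", "gene_b", R_protein = "R")
  inner_join(rna, prot, by = c("gene_a", "gene_b")) %>%
    mutate(delta = .data$R_protein - .data$R_rna)
}
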