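# Cross-species conserved paralog substitution: per-replicate log2 paralog
# ratios, moderated ratio-change tests, orthogroup aggregation, Fisher's
# combined probability, and the sign-consistency filter.

#' Per-sample log2 paralog ratios
#'
#' For every canonical pair and every sample where both genes are
#' quantified, the log2 ratio `log2(quantity_a) - log2(quantity_b)`.
#' Working in ratio space makes the signature independent of global
#' per-sample abundance shifts.
#'
#' @param dataset A log2-scale [expression_dataset()].
#' @param pairs Canonical pair table.
#' @return A tibble: `pair_id`, `gene_a`, `gene_b`, `sample`, `condition`,
#'   `replicate`, `species`, `ratio`. Samples where either gene is missing
#'   are omitted.
#' @export
ratio_profiles <- function(dataset, pairs) {
  stopifnot(inherits(dataset, "expression_dataset"))
  if (dataset$scale != "log2") abort("`ratio_profiles()` expects log2 data.")
  v <- dataset$values
  pairs <- pairs[pairs$gene_a %in% rownames(v) &
                 pairs$gene_b %in% rownames(v), ]
  if (!nrow(pairs)) return(tibble())
  ratio <- v[pairs$gene_a, , drop = FALSE] - v[pairs$gene_b, , drop = FALSE]
  out <- tibble(
    pair_id = rep(paste(pairs$gene_a, pairs$gene_b, sep = "|"),
                  times = ncol(v)),
    gene_a = rep(pairs$gene_a, times = ncol(v)),
    gene_b = rep(pairs$gene_b, times = ncol(v)),
    sample = rep(colnames(v), each = nrow(pairs)),
    ratio = as.vector(ratio)
  )
  out %>%
    left_join(dataset$meta, by = "sample") %>%
    filter(!is.na(.data$ratio)) %>%
    select("pair_id", "gene_a", "gene_b", "sample", "condition",
           "replicate", "species", "ratio")
}

#' Method-of-moments prior for the moderated variance
#'
#' Fits a scaled inverse chi-square prior to an ensemble of per-pair
#' residual variances by matching the first two moments of the implied
#' F distribution of `s^2 / s0^2`. Returns prior degrees of freedom `d0`
#' (possibly `Inf` when the variances are no more dispersed than sampling
#' alone explains) and prior variance `s0^2`.
#'
#' @param s2 Vector of residual variances.
#' @param df Residual degrees of freedom (single value or vector; the
#'   median is used when they differ).
#' @return A list with `d0` and `s0_sq`.
#' @export
estimate_var_prior <- function(s2, df) {
  s2 <- s2[is.finite(s2) & s2 > 0]
  if (length(s2) < 2) return(list(d0 = Inf, s0_sq = mean(s2)))
  d <- median(df)
  m <- mean(s2)
  r <- var(s2) / m^2
  # Var(F)/E(F)^2 = 2 (d + d0 - 2) / (d (d0 - 4)); solve for d0
  if (r * d <= 2) return(list(d0 = Inf, s0_sq = m))
  d0 <- (4 * r * d + 2 * d - 4) / (r * d - 2)
  if (!is.finite(d0) || d0 > 1e6) return(list(d0 = Inf, s0_sq = m))
  d0 <- max(d0, 2.5)  # numerical guard: keep the prior mean defined
  list(d0 = d0, s0_sq = m * (d0 - 2) / d0)
}

#' Moderated test of paralog ratio changes against the first time point
#'
#' For each pair and each condition, tests whether the mean log2 paralog
#' ratio differs from the reference (first) condition. Per-pair variances
#' are shrunk toward a common prior estimated from the whole ensemble of
#' pairs by the method of moments: the posterior variance is
#' `s2_post = (d0 * s0^2 + d * s^2) / (d0 + d)` and the moderated t has
#' `d0 + d` degrees of freedom. Setting `d0 = 0` recovers the ordinary
#' pooled two-sample t exactly.
#'
#' @param profiles Output of [ratio_profiles()].
#' @param ref Reference condition (default: first condition seen).
#' @param d0 Prior degrees of freedom: `NULL` to estimate (default), a
#'   number to fix (0 disables moderation), or `Inf` for full pooling.
#' @param paired Treat replicates with matching labels as paired and test
#'   the per-replicate ratio differences (one-sample); default unpaired.
#' @return A tibble: `pair_id`, `gene_a`, `gene_b`, `species`, `comparison`,
#'   `delta` (difference of mean log2 ratios), `t`, `df`, `p`, `adj_p`
#'   (BH within comparison). Untestable pair/comparison combinations
#'   (fewer than 2 ratios in a condition) are reported with `NA` statistics.
#' @export
ratio_change_test <- function(profiles, ref = NULL, d0 = NULL,
                              paired = FALSE) {
  if (!nrow(profiles)) return(tibble())
  conds <- unique(profiles$condition)
  if (is.null(ref)) ref <- conds[1]
  comparisons <- setdiff(conds, ref)
  species <- unique(profiles$species)
  out <- purrr::map(comparisons, function(cc) {
    sub <- profiles %>% filter(.data$condition %in% c(ref, cc))
    per_pair <- sub %>%
      group_by(.data$pair_id, .data$gene_a, .data$gene_b, .data$species) %>%
      summarise(stat = list(ratio_change_stat(
        .data$ratio[.data$condition == cc],
        .data$ratio[.data$condition == ref],
        .data$replicate[.data$condition == cc],
        .data$replicate[.data$condition == ref],
        paired = paired)), .groups = "drop") %>%
      tidyr::unnest_wider("stat")
    prior <- if (is.null(d0)) {
      estimate_var_prior(per_pair$s2, per_pair$df_resid)
    } else if (d0 == 0) {
      list(d0 = 0, s0_sq = 0)
    } else {
      list(d0 = d0, s0_sq = estimate_var_prior(per_pair$s2,
                                               per_pair$df_resid)$s0_sq)
    }
    per_pair %>%
      mutate(
        s2_post = moderated_s2(.data$s2, .data$df_resid,
                               prior$d0, prior$s0_sq),
        df = .data$df_resid + prior$d0,
        t = .data$delta / sqrt(.data$s2_post * .data$se_factor),
        p = 2 * pt(-abs(.data$t), .data$df),
        comparison = paste0(cc, "_vs_", ref)
      ) %>%
      mutate(adj_p = p.adjust(.data$p, method = "BH")) %>%
      select("pair_id", "gene_a", "gene_b", "species", "comparison",
             "delta", "s2", "df_resid", "t", "df", "p", "adj_p")
  })
  bind_rows(out)
}

ratio_change_stat <- function(rt, r0, rep_t, rep_0, paired = FALSE) {
  if (paired) {
    common <- intersect(rep_t, rep_0)
    d <- rt[match(common, rep_t)] - r0[match(common, rep_0)]
    d <- d[!is.na(d)]
    if (length(d) < 2) {
      return(list(delta = if (length(d)) mean(d) else NA_real_,
                  s2 = NA_real_, df_resid = NA_real_, se_factor = NA_real_))
    }
    return(list(delta = mean(d), s2 = var(d), df_resid = length(d) - 1,
                se_factor = 1 / length(d)))
  }
  rt <- rt[!is.na(rt)]; r0 <- r0[!is.na(r0)]
  if (length(rt) < 2 || length(r0) < 2) {
    return(list(delta = if (length(rt) && length(r0)) mean(rt) - mean(r0)
                        else NA_real_,
                s2 = NA_real_, df_resid = NA_real_, se_factor = NA_real_))
  }
  n1 <- length(rt); n0 <- length(r0)
  s2 <- ((n1 - 1) * var(rt) + (n0 - 1) * var(r0)) / (n1 + n0 - 2)
  list(delta = mean(rt) - mean(r0), s2 = s2, df_resid = n1 + n0 - 2,
       se_factor = 1 / n1 + 1 / n0)
}

moderated_s2 <- function(s2, df, d0, s0_sq) {
  if (d0 == 0) return(s2)
  if (is.infinite(d0)) return(rep(s0_sq, length(s2)))
  (d0 * s0_sq + df * s2) / (d0 + df)
}

#' Ratio-change tables for a panel of datasets
#'
#' Convenience wrapper running [ratio_profiles()] and [ratio_change_test()]
#' over a list of datasets (e.g. one per species or per species-comparison
#' batch, as produced by [simulate_multispecies_proteomes()]) and binding
#' the results. The pair table for each dataset is looked up by the
#' dataset's species label.
#'
#' @param datasets Named list of log2 [expression_dataset()]s.
#' @param pairs Named list of canonical pair tables, keyed by species.
#' @param ... Passed to [ratio_change_test()].
#' @return The row-bound ratio-change tibble across all datasets.
#' @export
multispecies_ratio_changes <- function(datasets, pairs, ...) {
  bind_rows(lapply(datasets, function(d) {
    sp <- d$meta$species[1]
    if (!sp %in% names(pairs)) {
      abort(paste0("No pair table for species \"", sp, "\"."))
    }
    ratio_change_test(ratio_profiles(d, pairs[[sp]]), ...)
  }))
}

#' Aggregate gene-pair ratio changes to orthogroup pairs
#'
#' Maps each gene of each pair to its orthogroup (per species), keeps only
#' pairs where both genes map, orients each orthogroup pair canonically
#' (lexicographically smaller orthogroup first, negating `delta` on flips),
#' and, when several gene pairs land on the same orthogroup pair in the
#' same species and comparison, takes the arithmetic mean of both the
#' deltas and the p-values.
#'
#' @param changes Output of [ratio_change_test()] (rows may span species).
#' @param map Orthogroup map tibble (`gene`, `species`, `orthogroup`).
#' @return A tibble: `og_a`, `og_b`, `species`, `comparison`, `delta`, `p`,
#'   `n_gene_pairs`.
#' @export
aggregate_to_orthogroups <- function(changes, map) {
  map <- validate_orthogroup_map(map)
  joined <- changes %>%
    inner_join(map %>% rename(gene_a = "gene", og_a = "orthogroup"),
               by = c("gene_a", "species")) %>%
    inner_join(map %>% rename(gene_b = "gene", og_b = "orthogroup"),
               by = c("gene_b", "species")) %>%
    filter(.data$og_a != .data$og_b)
  flipped <- joined$og_a > joined$og_b
  joined <- joined %>%
    mutate(
      delta = if_else(flipped, -.data$delta, .data$delta),
      og_first = if_else(flipped, .data$og_b, .data$og_a),
      og_second = if_else(flipped, .data$og_a, .data$og_b)
    ) %>%
    select(-"og_a", -"og_b") %>%
    rename(og_a = "og_first", og_b = "og_second")
  joined %>%
    group_by(.data$og_a, .data$og_b, .data$species, .data$comparison) %>%
    summarise(delta = mean(.data$delta), p = mean(.data$p),
              n_gene_pairs = dplyr::n(), .groups = "drop")
}

#' Fisher's combined probability test
#'
#' Combines independent p-values into one:
#' `X2 = -2 * sum(log(p))` is referred to a chi-square distribution with
#' `2k` degrees of freedom.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @return The combined p-value.
#' @export
fisher_combine <- function(p) {
  if (!length(p)) abort("Need at least one p-value.")
  if (any(is.na(p)) || any(p <= 0) || any(p > 1)) {
    abort("All p-values must lie in (0, 1].")
  }
  x2 <- -2 * sum(log(p))
  pchisq(x2, df = 2 * length(p), lower.tail = FALSE)
}

#' Conserved paralog-substitution signature across species
#'
#' An orthogroup pair is called conserved when (i) it is quantified in all
#' species, (ii) its ratio changes share the same sign in at least
#' `min_consistent` of the quantified comparisons, and (iii) its Fisher-
#' combined p-value, Benjamini-Hochberg-adjusted across all orthogroup
#' pairs, is at most `alpha`.
#'
#' Each pair is first oriented so that the sum of its deltas across
#' quantified comparisons is positive (positive ratios prioritized); sign
#' consistency then counts strictly positive deltas, with exact zeros
#' counted as inconsistent. The count is invariant to the input
#' orientation of the pair.
#'
#' @param og_changes Output of [aggregate_to_orthogroups()] pooled over
#'   species.
#' @param n_species Number of species required (default: number of distinct
#'   species present in `og_changes`).
#' @param min_consistent Minimum sign-consistent comparisons (default 5).
#' @param n_comparisons Total canonical comparison slots (default 7);
#'   recorded for reporting, the rule itself counts quantified comparisons.
#' @param alpha Threshold on the BH-adjusted combined p (default 0.05).
#' @return A `conserved_pairs` tibble: `og_a`, `og_b`, `n_species_present`,
#'   `n_comparisons_quantified`, `n_sign_consistent`, `combined_p`,
#'   `adj_combined_p`, `conserved`, plus a `deltas` attribute holding the
#'   pair-by-comparison delta matrix (oriented), with `NA` for
#'   unquantified slots.
#' @export
conserved_signature <- function(og_changes, n_species = NULL,
                                min_consistent = 5, n_comparisons = 7,
                                alpha = 0.05) {
  if (is.null(n_species)) n_species <- dplyr::n_distinct(og_changes$species)
  oriented <- og_changes %>%
    group_by(.data$og_a, .data$og_b) %>%
    mutate(delta = if (sum(.data$delta, na.rm = TRUE) < 0)
      -.data$delta else .data$delta) %>%
    ungroup()
  summary <- oriented %>%
    group_by(.data$og_a, .data$og_b) %>%
    summarise(
      n_species_present = dplyr::n_distinct(.data$species),
      n_comparisons_quantified = dplyr::n_distinct(.data$comparison),
      n_sign_consistent = sum(.data$delta > 0),
      combined_p = fisher_combine(pmax(.data$p, 1e-300)),
      .groups = "drop"
    ) %>%
    mutate(
      adj_combined_p = p.adjust(.data$combined_p, method = "BH"),
      conserved = .data$n_species_present >= n_species &
        .data$n_sign_consistent >= min_consistent &
        .data$adj_combined_p <= alpha
    )
  wide <- oriented %>%
    mutate(pair = paste(.data$og_a, .data$og_b, sep = "|")) %>%
    select("pair", "comparison", "delta") %>%
    tidyr::pivot_wider(names_from = "comparison", values_from = "delta")
  attr(summary, "deltas") <- wide
  attr(summary, "params") <- list(n_species = n_species,
                                  min_consistent = min_consistent,
                                  n_comparisons = n_comparisons,
                                  alpha = alpha)
  class(summary) <- c("conserved_pairs", class(summary))
  summary
}

#' Tidiers for conserved-signature results
#'
#' @param x A `conserved_pairs` object.
#' @param ... Unused.
#' @return `tidy()` returns the per-pair tibble; `glance()` a one-row
#'   summary of pair counts and the decision parameters.
#' @exportS3Method generics::tidy
tidy.conserved_pairs <- function(x, ...) {
  as_tibble(unclass(x))
}

#' @rdname tidy.conserved_pairs
#' @exportS3Method generics::glance
glance.conserved_pairs <- function(x, ...) {
  p <- attr(x, "params")
  tibble(n_pairs = nrow(x), n_conserved = sum(x$conserved),
         n_all_species = sum(x$n_species_present >= p$n_species),
         min_consistent = p$min_consistent, alpha = p$alpha)
}

#' PCA of orthogroup ratio differences across comparisons
#'
#' Principal component analysis of the complete-case pair-by-comparison
#' delta matrix, with comparisons as observations: comparisons from the
#' same species should cluster when species structure dominates the
#' paralog-ratio changes.
#'
#' @param deltas Wide tibble (`pair` column plus one column per comparison),
#'   e.g. the `deltas` attribute of [conserved_signature()].
#' @return A list of class `ratio_pca`: `scores` (tibble: comparison,
#'   PC coordinates), `sdev`, `var_explained`.
#' @export
ratio_pca <- function(deltas) {
  m <- as.matrix(deltas[setdiff(names(deltas), "pair")])
  rownames(m) <- deltas$pair
  m <- m[complete.cases(m), , drop = FALSE]
  if (nrow(m) < 2) abort("Need at least 2 complete-case pairs for PCA.")
  pc <- prcomp(t(m), center = TRUE, scale. = FALSE)
  scores <- as_tibble(pc$x, rownames = "comparison")
  out <- list(scores = scores, sdev = pc$sdev,
              var_explained = pc$sdev^2 / sum(pc$sdev^2))
  class(out) <- "ratio_pca"
  out
}

#' @export
print.ratio_pca <- function(x, ...) {
  cat("<ratio_pca> ", nrow(x$scores), " comparisons; variance explained: ",
      paste(sprintf("%.1f%%", 100 * head(x$var_explained, 3)),
            collapse = ", "), " ...\n", sep = "")
  invisible(x)
}
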