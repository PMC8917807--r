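# Differential abundance, paralog pair concordance, degradation-class
# analysis, TMT PSM filtering/summarization, and the ranked fold-change KS
# comparison.

#' Differential abundance between two conditions
#'
#' Computes per-gene log2 fold changes (mean log2 in condition B minus mean
#' log2 in condition A) with a two-sided Welch t test and Benjamini-Hochberg
#' adjustment. A gene is significant when `|log2_fc| > fc_threshold`
#' (strictly) and `adj_p < p_threshold`. Precomputed DE tables from any
#' upstream pipeline can be used instead wherever a `de` argument is
#' accepted downstream; this function is the package's internal route.
#'
#' @param dataset A log2-scale [expression_dataset()].
#' @param condition_a,condition_b Condition labels (fold change is B vs A).
#' @param fc_threshold Absolute log2 fold-change threshold (default 0.58,
#'   i.e. ~1.5-fold); the comparison is strict (`>`).
#' @param p_threshold Adjusted p threshold (default 0.05).
#' @return A tibble: `gene`, `comparison`, `log2_fc`, `t`, `p`, `adj_p`,
#'   `significant`.
#' @export
de_table <- function(dataset, condition_a, condition_b,
                     fc_threshold = 0.58, p_threshold = 0.05) {
  stopifnot(inherits(dataset, "expression_dataset"))
  if (dataset$scale != "log2") abort("`de_table()` expects log2 data.")
  conds <- unique(dataset$meta$condition)
  if (!condition_a %in% conds || !condition_b %in% conds) {
    abort("Unknown condition label.")
  }
  cols_a <- dataset$meta$sample[dataset$meta$condition == condition_a]
  cols_b <- dataset$meta$sample[dataset$meta$condition == condition_b]
  if (length(cols_a) < 2 || length(cols_b) < 2) {
    abort("Need at least 2 replicates per condition for the internal test.")
  }
  va <- dataset$values[, cols_a, drop = FALSE]
  vb <- dataset$values[, cols_b, drop = FALSE]
  res <- purrr::map(rownames(va), function(g) {
    a <- na.omit(va[g, ]); b <- na.omit(vb[g, ])
    if (length(a) < 2 || length(b) < 2 || (sd(a) == 0 && sd(b) == 0)) {
      fc <- if (length(a) && length(b)) mean(b) - mean(a) else NA_real_
      return(tibble(gene = g, log2_fc = fc, t = NA_real_, p = NA_real_))
    }
    tt <- t.test(b, a)
    tibble(gene = g, log2_fc = mean(b) - mean(a),
           t = unname(tt$statistic), p = tt$p.value)
  }) %>% bind_rows()
  res %>%
    mutate(comparison = paste0(condition_b, "_vs_", condition_a),
           adj_p = p.adjust(.data$p, method = "BH"),
           significant = !is.na(.data$adj_p) &
             abs(.data$log2_fc) > fc_threshold &
             .data$adj_p < p_threshold) %>%
    select("gene", "comparison", "log2_fc", "t", "p", "adj_p", "significant")
}

#' Concordant vs opposite regulation of paralog pairs
#'
#' Among paralog pairs whose two members are both significantly
#' differentially abundant in a comparison, classifies each pair as
#' concordant (same fold-change sign) or opposite (different sign). Pairs
#' with an exactly zero fold change are excluded with a warning.
#'
#' @param de A DE table with columns `gene`, `log2_fc`, `significant`
#'   (e.g. from [de_table()] or a precomputed upstream table).
#' @param pairs Canonical pair table.
#' @return A tibble: `gene_a`, `gene_b`, `fc_a`, `fc_b`, `class`.
#' @export
pair_concordance <- function(de, pairs) {
  sig <- de %>% filter(.data$significant)
  tab <- pairs %>%
    inner_join(sig %>% select("gene", fc_a = "log2_fc"),
               by = c(gene_a = "gene")) %>%
    inner_join(sig %>% select("gene", fc_b = "log2_fc"),
               by = c(gene_b = "gene"))
  zero <- tab$fc_a == 0 | tab$fc_b == 0
  if (any(zero)) {
    warn(sprintf("%d pair(s) with a zero fold change excluded.", sum(zero)))
    tab <- tab[!zero, ]
  }
  tab %>%
    mutate(class = if_else(sign(.data$fc_a) == sign(.data$fc_b),
                           "concordant", "opposite")) %>%
    select("gene_a", "gene_b", "fc_a", "fc_b", "class")
}

#' Degradation-class analysis of paralog pairs
#'
#' Two linked questions about protein degradation kinetics (NED,
#' non-exponentially degraded, vs ED, exponentially degraded):
#' (1) are NED proteins enriched among complex members (one Fisher exact
#' test on the 2x2 of NED status vs complex membership), and (2) do paralog
#' pairs containing at least one NED member show lower protein-vs-transcript
#' delta scores than pairs where both members are ED (two-sided Wilcoxon
#' rank-sum on the delta distributions)?
#'
#' @param deltas Output of [transcript_protein_delta()].
#' @param classes Named character vector gene -> `"NED"` or `"ED"`.
#' @param complex_members Character vector of genes that belong to at least
#'   one complex (used for the enrichment test); genes to include as the
#'   universe are those named in `classes`.
#' @param alternative Alternative for the Wilcoxon test on delta
#'   (default two-sided).
#' @return A list with `enrichment` (tibble: 2x2 counts, `odds_ratio`, `p`)
#'   and `delta_comparison` (tibble: group sizes, medians, `p`; `NA` p when
#'   a group is empty, reported as untestable).
#' @export
degradation_class_analysis <- function(deltas, classes, complex_members,
                                       alternative = "two.sided") {
  genes <- names(classes)
  is_ned <- classes[genes] == "NED"
  in_complex <- genes %in% complex_members
  tab <- table(factor(is_ned, levels = c(TRUE, FALSE)),
               factor(in_complex, levels = c(TRUE, FALSE)))
  ft <- fisher.test(tab)
  enrichment <- tibble(
    ned_in_complex = tab[1, 1], ned_outside = tab[1, 2],
    ed_in_complex = tab[2, 1], ed_outside = tab[2, 2],
    odds_ratio = unname(ft$estimate), p = ft$p.value
  )
  pair_has_ned <- (classes[deltas$gene_a] == "NED") |
    (classes[deltas$gene_b] == "NED")
  pair_has_ned <- unname(pair_has_ned)
  d_ned <- deltas$delta[pair_has_ned %in% TRUE]
  d_ed <- deltas$delta[pair_has_ned %in% FALSE]
  p_delta <- if (length(d_ned) && length(d_ed)) {
    wilcox.test(d_ned, d_ed, alternative = alternative)$p.value
  } else NA_real_
  delta_comparison <- tibble(
    n_ned_pairs = length(d_ned), n_ed_pairs = length(d_ed),
    median_delta_ned = if (length(d_ned)) median(d_ned) else NA_real_,
    median_delta_ed = if (length(d_ed)) median(d_ed) else NA_real_,
    p = p_delta
  )
  list(enrichment = enrichment, delta_comparison = delta_comparison)
}

#' Filter a TMT PSM table
#'
#' Discards PSMs mapping to reverse or contaminant hits, PSMs with a search
#' score below `score_min`, and PSMs whose reporter intensities fall below
#' `intensity_floor` in all channels, in that order.
#'
#' @param psms PSM tibble with columns `psm_id`, `protein`, `peptide`,
#'   `is_reverse`, `is_contaminant`, `score`, and 10 channel columns
#'   `channel_1` .. `channel_10`.
#' @param score_min Minimum search score (default 15; strict `<` discards).
#' @param intensity_floor Reporter-intensity floor (default 1e3); a PSM is
#'   discarded only when every channel is below it.
#' @return The retained rows of `psms`.
#' @export
psm_filter <- function(psms, score_min = 15, intensity_floor = 1e3) {
  ch <- grep("^channel_", names(psms), value = TRUE)
  if (length(ch) != 10) abort("Expected 10 reporter channel columns.")
  keep <- !psms$is_reverse & !psms$is_contaminant &
    psms$score >= score_min &
    apply(as.matrix(psms[ch]), 1, function(x) any(x >= intensity_floor,
                                                  na.rm = TRUE))
  psms[keep, ]
}

#' Summarize filtered PSMs into protein group quantities
#'
#' After [psm_filter()], retained reporter intensities are log2-transformed
#' and median-normalized per channel (subtracting each channel's median log2
#' intensity), peptides with any missing channel value are dropped, protein
#' groups with fewer than `min_unique_peptides` unique peptides are dropped,
#' and the remaining PSMs are summarized per protein by the channel-wise
#' median.
#'
#' @inheritParams psm_filter
#' @param min_unique_peptides Minimum unique peptides per protein
#'   (default 2).
#' @return A numeric matrix, proteins x 10 channels, of log2 quantities.
#' @export
psm_summarize <- function(psms, score_min = 15, intensity_floor = 1e3,
                          min_unique_peptides = 2) {
  kept <- psm_filter(psms, score_min, intensity_floor)
  ch <- grep("^channel_", names(kept), value = TRUE)
  inten <- log2(as.matrix(kept[ch]))
  inten[!is.finite(inten)] <- NA_real_
  # completeness: only peptides with no missing values across all channels
  complete <- rowSums(is.na(inten)) == 0
  kept <- kept[complete, ]
  inten <- inten[complete, , drop = FALSE]
  if (!nrow(kept)) return(matrix(numeric(0), 0, length(ch),
                                 dimnames = list(NULL, ch)))
  inten <- sweep(inten, 2, apply(inten, 2, median))
  pep_counts <- kept %>%
    distinct(.data$protein, .data$peptide) %>%
    count(.data$protein)
  keep_prot <- pep_counts$protein[pep_counts$n >= min_unique_peptides]
  keep_prot <- sort(keep_prot)
  out <- t(vapply(keep_prot, function(pr) {
    apply(inten[kept$protein == pr, , drop = FALSE], 2, median)
  }, numeric(length(ch))))
  rownames(out) <- keep_prot
  out
}

#' Kolmogorov-Smirnov comparison of a gene set on a ranked fold-change list
#'
#' Two-sample KS test between the log2 fold changes of the set members and
#' those of all other genes in the ranking.
#'
#' @param fc Named numeric vector of log2 fold changes (names = genes).
#' @param gene_set Character vector, a subset of `names(fc)`.
#' @return A tibble with `D`, `p`, `n_set`, `n_rest`.
#' @export
ranked_fc_ks <- function(fc, gene_set) {
  if (!length(gene_set)) abort("Empty gene set.")
  if (!all(gene_set %in% names(fc))) {
    abort("`gene_set` must be a subset of the ranking.")
  }
  in_set <- names(fc) %in% gene_set
  ks <- suppressWarnings(ks.test(fc[in_set], fc[!in_set]))
  tibble(D = unname(ks$statistic), p = ks$p.value,
         n_set = sum(in_set), n_rest = sum(!in_set))
}
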