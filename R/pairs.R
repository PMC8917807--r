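#' Canonicalize a paralog pair table
#'
#' Paralog pair lists exported from genome annotation resources usually
#' contain each pair twice, once in each orientation, with orientation-
#' specific reciprocal sequence identities. This function collapses the two
#' orientations into one canonical record per unordered pair so that every
#' downstream pairwise statistic sees each pair exactly once.
#'
#' The canonical orientation puts the lexicographically smaller gene
#' identifier in `gene_a`. When an input row arrives in the flipped
#' orientation its two identities are swapped accordingly, so `identity_ab`
#' is always "percent of `gene_a`'s sequence matching `gene_b`". The mean
#' reciprocal identity is recomputed as `(identity_ab + identity_ba) / 2`.
#'
#' @param pairs Data frame with columns `gene_a`, `gene_b`, `identity_ab`,
#'   `identity_ba`. Identities are percentages in \[0, 100\]. Extra columns
#'   are dropped.
#' @return A tibble with columns `gene_a`, `gene_b`, `identity_ab`,
#'   `identity_ba`, `mean_identity`, one row per unique unordered pair,
#'   sorted by (`gene_a`, `gene_b`).
#' @export
#' @examples
#' raw <- tibble::tibble(gene_a = c("A", "B"), gene_b = c("B", "A"),
#'                       identity_ab = c(80, 90), identity_ba = c(90, 80))
#' canonicalize_pairs(raw)
canonicalize_pairs <- function(pairs) {
  pairs <- as_tibble(pairs)
  needed <- c("gene_a", "gene_b", "identity_ab", "identity_ba")
  if (!all(needed %in% names(pairs))) {
    abort(paste0("`pairs` must have columns: ", paste(needed, collapse = ", ")))
  }
  if (any(pairs$gene_a == pairs$gene_b)) {
    abort("Self-pairs (gene_a == gene_b) are not valid paralog pairs.")
  }
  idents <- c(pairs$identity_ab, pairs$identity_ba)
  if (any(!is.na(idents) & (idents < 0 | idents > 100))) {
    abort("Sequence identities must lie in [0, 100].")
  }
  flipped <- pairs$gene_a > pairs$gene_b
  out <- tibble(
    gene_a = if_else(flipped, pairs$gene_b, pairs$gene_a),
    gene_b = if_else(flipped, pairs$gene_a, pairs$gene_b),
    identity_ab = if_else(flipped, pairs$identity_ba, pairs$identity_ab),
    identity_ba = if_else(flipped, pairs$identity_ab, pairs$identity_ba)
  )
  out <- out %>%
    distinct(.data$gene_a, .data$gene_b, .keep_all = TRUE) %>%
    mutate(mean_identity = (.data$identity_ab + .data$identity_ba) / 2) %>%
    arrange(.data$gene_a, .data$gene_b)
  out
}

#' Flag genes that have at least one paralog
#'
#' @param genes Character vector of gene identifiers.
#' @param pairs Canonical pair table (see [canonicalize_pairs()]); only
#'   `gene_a`/`gene_b` are used.
#' @return Named logical vector over `genes`: `TRUE` iff the gene occurs in
#'   at least one pair.
#' @export
flag_has_paralog <- function(genes, pairs) {
  in_pairs <- unique(c(pairs$gene_a, pairs$gene_b))
  setNames(genes %in% in_pairs, genes)
}

#' Read / write a paralog pair table
#'
#' TSV with columns `gene_a`, `gene_b`, `identity_ab`, `identity_ba`
#' (and optionally `mean_identity`). Reading canonicalizes the table.
#'
#' @param path File path.
#' @export
read_pair_table <- function(path) {
  canonicalize_pairs(readr::read_tsv(path, show_col_types = FALSE, na = "NA"))
}

#' @rdname read_pair_table
#' @param pairs Canonical pair tibble.
#' @export
write_pair_table <- function(pairs, path) {
  readr::write_tsv(pairs, path, na = "NA")
  invisible(pairs)
}
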