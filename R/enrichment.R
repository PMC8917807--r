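# Gene-set enrichment: Fisher overrepresentation, ranked KS enrichment,
# and the multiple-testing adjustments used across the package.

#' Fisher overrepresentation analysis over a gene-set collection
#'
#' One-sided (enrichment) Fisher exact test per term on the 2x2 table of
#' selected/background membership, i.e. the hypergeometric upper tail at
#' the observed overlap.
#'
#' @param selected Character vector of selected genes; must be a subset of
#'   `background`.
#' @param background Character vector, the gene universe.
#' @param sets Named list of gene sets (character vectors), or the output
#'   of [read_gmt()].
#' @param alternative `"greater"` (enrichment, default) or `"two.sided"`.
#' @param adjust Adjustment method passed to [adjust_pvalues()]
#'   (default `"hommel"`).
#' @return A tibble per term: `term`, `k` (selected in term), `n`
#'   (selected), `K` (background in term), `N` (background), `p`, `adj_p`.
#' @export
fisher_ora <- function(selected, background, sets,
                       alternative = c("greater", "two.sided"),
                       adjust = "hommel") {
  alternative <- match.arg(alternative)
  selected <- unique(selected)
  background <- unique(background)
  if (!all(selected %in% background)) {
    abort("`selected` must be a subset of `background`.")
  }
  genes_of <- function(s) if (is.list(s) && !is.null(s$genes)) s$genes else s
  n <- length(selected)
  N <- length(background)
  res <- purrr::imap(sets, function(s, term) {
    members <- intersect(genes_of(s), background)
    K <- length(members)
    k <- length(intersect(selected, members))
    p <- if (alternative == "greater") {
      stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    } else {
      fisher.test(matrix(c(k, n - k, K - k, N - K - n + k), 2))$p.value
    }
    tibble(term = term, k = k, n = n, K = K, N = N, p = p)
  })
  out <- bind_rows(res)
  out$adj_p <- adjust_pvalues(out$p, method = adjust)
  arrange(out, .data$adj_p, .data$p)
}

#' Ranked gene-set enrichment by two-sample Kolmogorov-Smirnov test
#'
#' For each term, compares the score distribution of in-set genes against
#' all other scored genes with a two-sample KS test (exact p-values for
#' small samples, asymptotic otherwise, per [stats::ks.test()]'s default).
#' Terms with fewer than 2 annotated genes in the ranking (or fewer than 2
#' outside) are skipped.
#'
#' @param scores Named numeric vector, gene -> ranking score.
#' @param sets Named list of gene sets or [read_gmt()] output.
#' @param adjust Adjustment method (default `"hommel"`).
#' @return A tibble: `term`, `n_set`, `n_rest`, `D`, `p`, `adj_p`, ranked
#'   by adjusted p.
#' @export
ks_gsea <- function(scores, sets, adjust = "hommel") {
  genes_of <- function(s) if (is.list(s) && !is.null(s$genes)) s$genes else s
  res <- purrr::imap(sets, function(s, term) {
    in_set <- names(scores) %in% genes_of(s)
    if (sum(in_set) < 2 || sum(!in_set) < 2) return(NULL)
    ks <- suppressWarnings(ks.test(scores[in_set], scores[!in_set]))
    tibble(term = term, n_set = sum(in_set), n_rest = sum(!in_set),
           D = unname(ks$statistic), p = ks$p.value)
  })
  out <- bind_rows(purrr::compact(res))
  if (!nrow(out)) return(out)
  out$adj_p <- adjust_pvalues(out$p, method = adjust)
  arrange(out, .data$adj_p, .data$p)
}

#' Multiple-testing adjustment
#'
#' Thin, validated wrapper over [stats::p.adjust()] exposing the two
#' corrections used in this package: Benjamini-Hochberg step-up (`"BH"`)
#' and Hommel's closed-testing procedure (`"hommel"`).
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @param method `"BH"` or `"hommel"` (case-insensitive).
#' @return Adjusted p-values, same length and order as `p`.
#' @export
adjust_pvalues <- function(p, method = c("BH", "hommel")) {
  method <- match.arg(tolower(method[1]), c("bh", "hommel"))
  if (any(!is.na(p) & (p < 0 | p > 1))) {
    abort("p-values must lie in [0, 1].")
  }
  p.adjust(p, method = if (method == "bh") "BH" else "hommel")
}
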