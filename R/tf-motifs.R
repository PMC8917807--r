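# Promoter motif scanning: JASPAR position frequency matrices, min-max
# scaled log-odds ("relative") scores, both-strand scanning with a hit
# threshold, and differential TF score profiles between paralog pair
# members.

#' Construct a motif model from a position frequency matrix
#'
#' Columns (positions) are converted to probabilities after adding a
#' pseudocount distributed according to the background composition, the
#' common convention for count-based JASPAR matrices.
#'
#' @param name TF name.
#' @param pfm Numeric matrix with rows `A`, `C`, `G`, `T` and one column
#'   per motif position; counts or probabilities.
#' @param background Background nucleotide probabilities, length 4
#'   (A, C, G, T); default uniform.
#' @param pseudocount Total pseudocount per position (default 0.8).
#' @return A `motif_model` list: `name`, `prob` (probability matrix),
#'   `background`, `width`.
#' @export
motif_model <- function(name, pfm, background = rep(0.25, 4),
                        pseudocount = 0.8) {
  if (nrow(pfm) != 4) abort("PFM must have 4 rows (A, C, G, T).")
  if (is.null(rownames(pfm))) rownames(pfm) <- c("A", "C", "G", "T")
  pfm <- pfm[c("A", "C", "G", "T"), , drop = FALSE]
  if (any(pfm < 0)) abort("PFM entries must be non-negative.")
  background <- background / sum(background)
  prob <- apply(pfm, 2, function(col) {
    (col + pseudocount * background) / (sum(col) + pseudocount)
  })
  rownames(prob) <- c("A", "C", "G", "T")
  structure(list(name = name, prob = prob, background = background,
                 width = ncol(prob)),
            class = "motif_model")
}

#' @export
print.motif_model <- function(x, ...) {
  cat("<motif_model> ", x$name, " (width ", x$width, ")\n", sep = "")
  invisible(x)
}

#' Consensus sequence of a motif
#'
#' @param motif A [motif_model()].
#' @return The string of most probable bases per position.
#' @export
motif_consensus <- function(motif) {
  paste(rownames(motif$prob)[apply(motif$prob, 2, which.max)],
        collapse = "")
}

#' Read JASPAR-format position frequency matrices
#'
#' Parses the JASPAR raw/pfm text format: a `>ID NAME` header followed by
#' four lines of counts, either bare numbers or the
#' `A [ 1 2 3 ]` bracketed style.
#'
#' @param path File path.
#' @inheritParams motif_model
#' @return A named list of [motif_model()] objects (named by TF name).
#' @export
read_jaspar <- function(path, background = rep(0.25, 4), pseudocount = 0.8) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  headers <- grep("^>", lines)
  if (!length(headers)) abort("No JASPAR records found.")
  out <- lapply(seq_along(headers), function(i) {
    start <- headers[i] + 1
    end <- if (i < length(headers)) headers[i + 1] - 1 else length(lines)
    body <- lines[start:end]
    if (length(body) != 4) abort("Each JASPAR record needs 4 matrix rows.")
    rows <- lapply(body, function(l) {
      l <- gsub("^[ACGTacgt]\\s*", "", trimws(l))
      l <- gsub("\\[|\\]", " ", l)
      as.numeric(strsplit(trimws(l), "\\s+")[[1]])
    })
    pfm <- do.call(rbind, rows)
    rownames(pfm) <- c("A", "C", "G", "T")
    hdr <- sub("^>\\s*", "", lines[headers[i]])
    parts <- strsplit(hdr, "\\s+")[[1]]
    name <- if (length(parts) > 1) parts[2] else parts[1]
    motif_model(name, pfm, background = background,
                pseudocount = pseudocount)
  })
  names(out) <- vapply(out, function(m) m$name, character(1))
  out
}

motif_logodds <- function(motif) {
  log2(motif$prob / motif$background)
}

#' Relative PWM score of a sequence window
#'
#' The log-odds score of the window under the motif versus the background,
#' min-max rescaled by the motif's minimum and maximum achievable scores so
#' the result lies in \[0, 1\]: 1 for the consensus, 0 for the
#' anti-consensus. Windows containing ambiguous bases return `NA` (skipped
#' by the scanner).
#'
#' @param motif A [motif_model()].
#' @param window Character string of exactly `motif$width` bases.
#' @return Relative score in \[0, 1\], or `NA` for ambiguous windows.
#' @export
pwm_relative_score <- function(motif, window) {
  bases <- strsplit(toupper(window), "")[[1]]
  if (length(bases) != motif$width) {
    abort("Window length must equal motif width.")
  }
  lo <- motif_logodds(motif)
  idx <- match(bases, rownames(lo))
  if (anyNA(idx)) return(NA_real_)
  score <- sum(lo[cbind(idx, seq_along(idx))])
  smin <- sum(apply(lo, 2, min))
  smax <- sum(apply(lo, 2, max))
  if (smax == smin) return(1)
  (score - smin) / (smax - smin)
}

revcomp <- function(seq) {
  chartr("ACGTacgt", "TGCAtgca",
         paste(rev(strsplit(seq, "")[[1]]), collapse = ""))
}

scan_scores <- function(motif, promoter) {
  bases <- strsplit(toupper(promoter), "")[[1]]
  w <- motif$width
  n <- length(bases) - w + 1
  if (n < 1) return(numeric(0))
  lo <- motif_logodds(motif)
  idx <- match(bases, rownames(lo))
  smin <- sum(apply(lo, 2, min))
  smax <- sum(apply(lo, 2, max))
  vapply(seq_len(n), function(i) {
    ii <- idx[i:(i + w - 1)]
    if (anyNA(ii)) return(NA_real_)
    s <- sum(lo[cbind(ii, seq_len(w))])
    if (smax == smin) 1 else (s - smin) / (smax - smin)
  }, numeric(1))
}

#' Scan a promoter for a motif
#'
#' Slides the motif over every position of the promoter and of its reverse
#' complement, takes the maximum relative score, and reports it only when
#' it reaches `threshold`; otherwise the promoter scores 0 for this TF
#' (absent motifs are zeros, not missing values). Windows with ambiguous
#' bases are skipped.
#'
#' @param motif A [motif_model()].
#' @param promoter Promoter sequence (string).
#' @param threshold Minimal relative score for a hit (default 0.8).
#' @param strands `"both"` (default) or `"forward"`.
#' @return Maximum relative score, or 0 when below threshold.
#' @export
scan_promoter <- function(motif, promoter, threshold = 0.8,
                          strands = c("both", "forward")) {
  strands <- match.arg(strands)
  if (nchar(promoter) < motif$width) {
    warn("Promoter shorter than motif; score 0.")
    return(0)
  }
  scores <- scan_scores(motif, promoter)
  if (strands == "both") {
    scores <- c(scores, scan_scores(motif, revcomp(promoter)))
  }
  scores <- scores[!is.na(scores)]
  if (!length(scores)) return(0)
  best <- max(scores)
  if (best >= threshold) best else 0
}

#' Gene-by-TF promoter score table
#'
#' Applies [scan_promoter()] to every promoter and motif.
#'
#' @param promoters Named character vector of promoter sequences
#'   (names = genes).
#' @param motifs List of [motif_model()] objects.
#' @param threshold Minimal relative score (default 0.8).
#' @return A tibble: `gene`, one column per TF, entries in
#'   `{0} U [threshold, 1]`.
#' @export
scan_promoters <- function(promoters, motifs, threshold = 0.8) {
  tf_names <- vapply(motifs, function(m) m$name, character(1))
  scores <- vapply(motifs, function(m) {
    vapply(promoters, function(p) scan_promoter(m, p, threshold),
           numeric(1))
  }, numeric(length(promoters)))
  if (length(promoters) == 1) scores <- matrix(scores, nrow = 1)
  colnames(scores) <- tf_names
  dplyr::bind_cols(tibble(gene = names(promoters)), as_tibble(scores))
}

#' Shared and exclusive TF repertoires of a paralog pair
#'
#' With presence defined as score > 0, the shared fraction is
#' `|A intersect B| / |A union B|`; the two exclusive fractions complete it
#' to 1.
#'
#' @param scores_a,scores_b Named numeric TF score vectors over the same
#'   TF universe.
#' @return A tibble: `shared`, `a_only`, `b_only` (all `NA` when both
#'   repertoires are empty).
#' @export
shared_tf_fraction <- function(scores_a, scores_b) {
  if (!identical(names(scores_a), names(scores_b))) {
    abort("Score vectors must share the same TF universe (same order).")
  }
  a <- scores_a > 0
  b <- scores_b > 0
  u <- sum(a | b)
  if (u == 0) return(tibble(shared = NA_real_, a_only = NA_real_,
                            b_only = NA_real_))
  tibble(shared = sum(a & b) / u, a_only = sum(a & !b) / u,
         b_only = sum(!a & b) / u)
}

#' Per-TF distribution of score differences across paralog pairs
#'
#' For every TF detected (score > 0 in at least one member) in at least
#' `min_pairs` pairs, the distribution of `score_first - score_second`
#' across pairs, summarised by its median and quartiles. Pair orientation
#' must be fixed upstream (e.g. the conserved-signature convention).
#'
#' @param score_table Output of [scan_promoters()].
#' @param pairs Tibble with `gene_a`, `gene_b` (oriented).
#' @param min_pairs Minimum pairs per TF (default 10).
#' @return A tibble: `tf`, `n_pairs`, `median_diff`, `q25`, `q75`, ordered
#'   by `abs(median_diff)` decreasing.
#' @export
tf_difference_distribution <- function(score_table, pairs, min_pairs = 10) {
  tfs <- setdiff(names(score_table), "gene")
  sa <- score_table[match(pairs$gene_a, score_table$gene), tfs]
  sb <- score_table[match(pairs$gene_b, score_table$gene), tfs]
  out <- purrr::map(tfs, function(tf) {
    a <- sa[[tf]]; b <- sb[[tf]]
    present <- !is.na(a) & !is.na(b) & (a > 0 | b > 0)
    if (sum(present) < min_pairs) return(NULL)
    d <- a[present] - b[present]
    tibble(tf = tf, n_pairs = sum(present), median_diff = median(d),
           q25 = unname(quantile(d, 0.25)), q75 = unname(quantile(d, 0.75)))
  })
  bind_rows(purrr::compact(out)) %>%
    arrange(dplyr::desc(abs(.data$median_diff)))
}
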