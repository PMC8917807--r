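# Small fixture builders shared across test files.

make_dataset <- function(values, conditions = NULL, replicates = NULL,
                         layer = "rna", scale = "log2") {
  if (is.null(conditions)) conditions <- colnames(values)
  if (is.null(replicates)) replicates <- rep("r1", ncol(values))
  meta <- tibble::tibble(sample = colnames(values), condition = conditions,
                         replicate = replicates, layer = layer)
  expression_dataset(values, meta, scale = scale)
}

# genes x samples matrix with named rows/cols from a list of row vectors
mat_from_rows <- function(rows, sample_prefix = "s") {
  m <- do.call(rbind, rows)
  rownames(m) <- names(rows)
  colnames(m) <- paste0(sample_prefix, seq_len(ncol(m)))
  m
}

# a small uniform-background random DNA string
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# 3-position toy motif with a sharp consensus ACG
toy_motif <- function(name = "TOY") {
  pfm <- matrix(c(8, 1, 1, 1,
                  1, 8, 1, 1,
                  1, 1, 8, 1), nrow = 4,
                dimnames = list(c("A", "C", "G", "T"), NULL))
  motif_model(name, pfm)
}
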