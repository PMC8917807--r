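# Readers and writers for the remaining tabular inputs: complex catalogs
# (long TSV or GMT), orthogroup maps, gene-set collections, promoter FASTA.

#' Read a protein complex catalog
#'
#' Accepts either a long TSV with columns `complex_id`, `member`, or a GMT
#' file (one complex per line: id, description, members). Members are
#' de-duplicated within a complex; a gene may belong to several complexes.
#'
#' @param path File path.
#' @param format `"tsv"` or `"gmt"`; guessed from the file extension by
#'   default.
#' @return A named list of character vectors (complex id -> member genes).
#' @export
read_complex_catalog <- function(path, format = c("auto", "tsv", "gmt")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gmt$", path, ignore.case = TRUE)) "gmt" else "tsv"
  }
  if (format == "gmt") {
    sets <- read_gmt(path)
    return(lapply(sets, function(s) s$genes))
  }
  tab <- readr::read_tsv(path, show_col_types = FALSE, na = "NA")
  if (!all(c("complex_id", "member") %in% names(tab))) {
    abort("Complex TSV must have columns `complex_id` and `member`.")
  }
  lapply(split(tab$member, tab$complex_id), unique)
}

#' @rdname read_complex_catalog
#' @param catalog Named list of member vectors.
#' @export
write_complex_catalog <- function(catalog, path) {
  tab <- tibble(
    complex_id = rep(names(catalog), lengths(catalog)),
    member = unlist(catalog, use.names = FALSE)
  )
  readr::write_tsv(tab, path, na = "NA")
  invisible(catalog)
}

#' Read a GMT gene-set file
#'
#' @param path File path. Each line: term id, description, then member genes,
#'   tab-separated.
#' @return Named list; each element a list with `name` (description) and
#'   `genes` (character vector).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) abort("Malformed GMT line (need id, name, genes).")
    list(name = parts[2], genes = unique(parts[-(1:2)]))
  })
  names(out) <- vapply(lines, function(l) {
    strsplit(l, "\t", fixed = TRUE)[[1]][1]
  }, character(1), USE.NAMES = FALSE)
  out
}

#' @rdname read_gmt
#' @param sets Named list as returned by [read_gmt()], or a named list of
#'   plain character vectors.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(seq_along(sets), function(i) {
    s <- sets[[i]]
    if (is.character(s)) s <- list(name = names(sets)[i], genes = s)
    paste(c(names(sets)[i], s$name, s$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(sets)
}

#' Read / write a gene-to-orthogroup map
#'
#' TSV with columns `gene`, `species`, `orthogroup`. A gene must map to at
#' most one orthogroup within a species.
#'
#' @param path File path.
#' @return A tibble with the three columns.
#' @export
read_orthogroup_map <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, na = "NA")
  if (!all(c("gene", "species", "orthogroup") %in% names(tab))) {
    abort("Orthogroup TSV must have columns `gene`, `species`, `orthogroup`.")
  }
  validate_orthogroup_map(tab)
}

validate_orthogroup_map <- function(map) {
  map <- as_tibble(map)
  dup <- map %>%
    distinct(.data$gene, .data$species, .data$orthogroup) %>%
    count(.data$gene, .data$species) %>%
    filter(.data$n > 1)
  if (nrow(dup)) {
    abort(paste0("Gene(s) mapping to multiple orthogroups in one species: ",
                 paste(head(dup$gene, 5), collapse = ", ")))
  }
  distinct(map, .data$gene, .data$species, .data$orthogroup)
}

#' @rdname read_orthogroup_map
#' @param map Orthogroup map tibble.
#' @export
write_orthogroup_map <- function(map, path) {
  readr::write_tsv(validate_orthogroup_map(map), path, na = "NA")
  invisible(map)
}

#' Read / write promoter sequences as FASTA
#'
#' Headers are gene identifiers. Sequences are returned as a named character
#' vector (uppercase DNA).
#'
#' @param path File path.
#' @export
read_promoters <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  setNames(toupper(as.character(seqs)), names(seqs))
}

#' @rdname read_promoters
#' @param promoters Named character vector of sequences.
#' @export
write_promoters <- function(promoters, path) {
  seqs <- Biostrings::DNAStringSet(promoters)
  Biostrings::writeXStringSet(seqs, path)
  invisible(promoters)
}
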