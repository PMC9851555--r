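#' Protein sequence tables
#'
#' A proteome is represented as a tibble with columns `id`, `species`,
#' `sequence` and optionally `source`. Most functions also accept a named
#' character vector of sequences, which is coerced with an empty species
#' label.
#'
#' @param x A tibble with `id` and `sequence` columns, or a named character
#'   vector of amino-acid sequences.
#' @param species Species label applied when `x` carries none.
#' @return A tibble with columns `id`, `species`, `sequence`.
#' @export
as_proteome <- function(x, species = NA_character_) {
  if (is.character(x)) {
    if (is.null(names(x)) || anyNA(names(x)) || any(names(x) == "")) {
      stop("a character proteome must be fully named", call. = FALSE)
    }
    x <- tibble(id = names(x), species = species, sequence = unname(x))
  }
  x <- as_tibble(x)
  stopifnot(all(c("id", "sequence") %in% names(x)))
  if (!"species" %in% names(x)) x$species <- species
  if (anyDuplicated(x$id)) {
    stop("duplicate protein ids: ",
         paste(unique(x$id[duplicated(x$id)]), collapse = ", "), call. = FALSE)
  }
  if (any(!nzchar(x$sequence))) stop("empty sequence in proteome", call. = FALSE)
  x[, c("id", "species", "sequence", intersect("source", names(x)))]
}

#' Read and write protein FASTA
#'
#' Thin wrappers around [Biostrings::readAAStringSet()] /
#' [Biostrings::writeXStringSet()] returning/consuming proteome tibbles.
#' Stop codons (`*`) at the end of translated sequences are dropped on read.
#'
#' @param path File path.
#' @param species Species label to attach to every record.
#' @return `read_proteome()` a proteome tibble; `write_proteome()` the path,
#'   invisibly.
#' @export
read_proteome <- function(path, species = NA_character_) {
  aas <- Biostrings::readAAStringSet(path)
  seqs <- toupper(as.character(aas))
  seqs <- sub("\\*$", "", seqs)
  ids <- sub("\\s.*$", "", names(aas))
  as_proteome(setNames(seqs, ids), species = species)
}

#' @rdname read_proteome
#' @param proteome A proteome tibble.
#' @export
write_proteome <- function(proteome, path) {
  proteome <- as_proteome(proteome)
  aas <- Biostrings::AAStringSet(setNames(proteome$sequence, proteome$id))
  Biostrings::writeXStringSet(aas, path)
  invisible(path)
}
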