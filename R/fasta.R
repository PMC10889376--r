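# FASTA input/output. Protein headers carry optional metadata fields:
#   >prot_001 species=sp03 tags=ribosomal|rRNA-binding
# The first whitespace-delimited token is the protein id; "species=" and
# "tags=" key-value fields are parsed from the remainder (tags are
# pipe-separated).

parse_fasta_header <- function(header) {
  parts <- strsplit(trimws(header), "\\s+")[[1]]
  id <- parts[1]
  species <- NA_character_
  tags <- character(0)
  for (p in parts[-1]) {
    if (startsWith(p, "species=")) species <- sub("^species=", "", p)
    if (startsWith(p, "tags=")) {
      tags <- strsplit(sub("^tags=", "", p), "|", fixed = TRUE)[[1]]
      tags <- tags[nzchar(tags)]
    }
  }
  list(id = id, species_id = species, function_tags = tags)
}

#' Read a protein FASTA file with species/tag metadata
#'
#' The header token before the first whitespace is the protein id; optional
#' `species=` and `tags=` key-value fields in the description are parsed
#' (tags pipe-separated).
#'
#' @param path Path to a FASTA file of amino-acid sequences.
#' @return Tibble with columns `id`, `species_id`, `function_tags`
#'   (list-column of character vectors) and `sequence`.
#' @export
read_protein_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  meta <- purrr::map(names(set), parse_fasta_header)
  tibble(
    id = purrr::map_chr(meta, "id"),
    species_id = purrr::map_chr(meta, "species_id"),
    function_tags = purrr::map(meta, "function_tags"),
    sequence = unname(as.character(set))
  )
}

#' Write a protein table to FASTA
#'
#' Inverse of [read_protein_fasta()]: writes `species=` and `tags=` fields
#' into the description line when present.
#'
#' @param proteins Tibble with `id`, `sequence` and optionally `species_id`
#'   and `function_tags` columns.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_protein_fasta <- function(proteins, path) {
  headers <- proteins$id
  if (!is.null(proteins$species_id)) {
    headers <- paste0(headers, " species=", proteins$species_id)
  }
  if (!is.null(proteins$function_tags)) {
    tagstr <- purrr::map_chr(proteins$function_tags, function(t) {
      if (length(t) == 0) "" else paste0(" tags=", paste(t, collapse = "|"))
    })
    headers <- paste0(headers, tagstr)
  }
  set <- Biostrings::AAStringSet(setNames(proteins$sequence, headers))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read an aligned FASTA file
#'
#' Reads a (possibly gapped) alignment, e.g. aligned 16S nucleotide
#' sequences, and checks all rows have equal length.
#'
#' @param path Path to an aligned FASTA file.
#' @return Named character vector of aligned sequences (names = id token
#'   before the first whitespace).
#' @export
read_aligned_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(set))
  names(seqs) <- purrr::map_chr(names(set), ~ strsplit(trimws(.x), "\\s+")[[1]][1])
  if (length(unique(nchar(seqs))) > 1) {
    stop_invalid("aligned FASTA rows must all have the same length")
  }
  seqs
}

#' Write aligned (or plain nucleotide) sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_aligned_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  invisible(path)
}
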