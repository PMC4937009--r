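#' Read protein sequences from a FASTA file
#'
#' Thin wrapper over [Biostrings::readAAStringSet()]: headers are
#' stripped of the leading `>` and truncated at the first whitespace,
#' sequences are uppercased, and file order is preserved. An empty file
#' yields an empty tibble with a warning.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` and `sequence`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("FASTA file not found: '", path, "'"))
  if (file.size(path) == 0) {
    warn(paste0("empty FASTA file: '", path, "'"))
    return(tibble(id = character(), sequence = character()))
  }
  set <- Biostrings::readAAStringSet(path)
  tibble(
    id = stringr::word(names(set), 1),
    sequence = unname(toupper(as.character(set)))
  )
}
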