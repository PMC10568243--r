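#' Load a genome FASTA
#'
#' Reads a (possibly gzip-compressed) multi-sequence FASTA. Sequence names
#' are taken from the headers up to the first whitespace.
#'
#' @param fasta_path Path to the FASTA file.
#' @return A `Biostrings::DNAStringSet`; per-sequence lengths via
#'   `Biostrings::width()`.
#' @export
load_genome <- function(fasta_path) {
  if (!file.exists(fasta_path)) stop(sprintf("genome FASTA not found: %s", fasta_path))
  gen <- Biostrings::readDNAStringSet(fasta_path)
  if (length(gen) == 0L) stop(sprintf("genome FASTA is empty: %s", fasta_path))
  names(gen) <- sub("\\s.*$", "", names(gen))
  if (anyDuplicated(names(gen))) {
    dup <- unique(names(gen)[duplicated(names(gen))])
    stop(sprintf("duplicate sequence name(s) in FASTA: %s", paste(dup, collapse = ", ")))
  }
  gen
}
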