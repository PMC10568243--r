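# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

DNA_BASES <- c("A", "C", "G", "T")

# IUPAC nucleotide codes expanded to the concrete bases they stand for.
# Ambiguous genome bases (N etc.) never appear on the right-hand side as
# matchable targets: only concrete A/C/G/T genome bases can satisfy a code.
IUPAC_MAP <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

is_iupac <- function(chars) all(chars %in% names(IUPAC_MAP))

chars_of <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

# Reverse complement of a plain character string (IUPAC-aware).
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

stop_crisprisk <- function(msg, class) {
  stop(structure(
    class = c(class, "crisprisk_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

# Normalize a genome to a named uppercase character vector of sequences.
as_genome_chars <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) {
    out <- toupper(as.character(genome))
  } else if (is.character(genome)) {
    out <- toupper(genome)
  } else {
    stop("genome must be a DNAStringSet or a named character vector")
  }
  if (is.null(names(out)) || anyNA(names(out)) || any(names(out) == "")) {
    stop("genome sequences must be named")
  }
  out
}

# 0-based half-open intervals -> GRanges (1-based closed internally to
# Bioconductor); strand deliberately dropped so all overlap tests are
# strand-blind.
ranges_to_granges <- function(chrom, start, end, seqlevels = NULL) {
  lv <- seqlevels %||% unique(chrom)
  GenomicRanges::GRanges(
    seqnames = factor(chrom, levels = lv),
    ranges = IRanges::IRanges(start = start + 1L, end = end)
  )
}

collapse_vals <- function(x, sep = ";") {
  if (length(x) == 0L) "" else paste(x, collapse = sep)
}
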