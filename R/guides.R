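#' Parse and validate a guide RNA
#'
#' Normalizes a raw protospacer sequence (whitespace-stripped, uppercased) and
#' attaches the PAM pattern that the nuclease requires next to it.
#'
#' @param raw Protospacer sequence, typically 20 nt, alphabet A/C/G/T.
#' @param pam_pattern IUPAC pattern for the protospacer-adjacent motif
#'   (default `"NGG"`, the SpCas9 PAM).
#' @param pam_side Which side of the protospacer carries the PAM:
#'   `"three_prime"` (SpCas9) or `"five_prime"` (e.g. Cas12a).
#' @param name Optional guide name used in outputs.
#' @return An object of class `guide_rna` with fields `protospacer`,
#'   `pam_pattern`, `pam_side`, `name`.
#' @examples
#' parse_guide("CACCCGATCCACTGGGGAGC")
#' @export
parse_guide <- function(raw, pam_pattern = "NGG", pam_side = c("three_prime", "five_prime"),
                        name = NULL) {
  pam_side <- match.arg(pam_side)
  seq <- toupper(gsub("\\s+", "", raw %||% ""))
  if (!nzchar(seq)) {
    stop_crisprisk("invalid guide: empty sequence", "invalid_guide")
  }
  sc <- chars_of(seq)
  if (!all(sc %in% DNA_BASES)) {
    bad <- unique(sc[!sc %in% DNA_BASES])
    stop_crisprisk(
      sprintf("invalid guide: non-ACGT character(s) %s in '%s'",
              paste(bad, collapse = ","), seq),
      "invalid_guide")
  }
  pam <- toupper(gsub("\\s+", "", pam_pattern))
  if (!nzchar(pam) || !is_iupac(chars_of(pam))) {
    stop_crisprisk(sprintf("invalid PAM pattern '%s'", pam_pattern), "invalid_guide")
  }
  structure(
    list(protospacer = seq, pam_pattern = pam, pam_side = pam_side,
         name = name %||% "guide"),
    class = "guide_rna")
}

#' @export
print.guide_rna <- function(x, ...) {
  side <- if (x$pam_side == "three_prime") {
    paste0(x$protospacer, "-", x$pam_pattern)
  } else {
    paste0(x$pam_pattern, "-", x$protospacer)
  }
  cat(sprintf("<guide_rna> %s  5'-%s-3'\n", x$name, side))
  invisible(x)
}

#' Read guide RNAs from a file
#'
#' Accepts either a plain text file with one protospacer per line or a
#' two-column tab-separated file (`name<TAB>sequence`). Blank lines and lines
#' starting with `#` are ignored.
#'
#' @param path Path to the guide file.
#' @inheritParams parse_guide
#' @return A list of `guide_rna` objects.
#' @export
read_guides <- function(path, pam_pattern = "NGG", pam_side = "three_prime") {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop_crisprisk("guide file contains no guides", "invalid_guide")
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) >= 2L) {
      out[[i]] <- parse_guide(fields[[2L]], pam_pattern, pam_side, name = fields[[1L]])
    } else {
      out[[i]] <- parse_guide(fields[[1L]], pam_pattern, pam_side,
                              name = sprintf("guide_%d", i))
    }
  }
  out
}

#' Search parameters for off-target discovery
#'
#' @param max_mismatches Maximum protospacer mismatches tolerated (PAM
#'   mismatches are never counted).
#' @param max_dna_bulges Maximum extra (unpaired) genome bases.
#' @param max_rna_bulges Maximum extra (unpaired) guide bases.
#' @param both_strands Search the reverse strand as well.
#' @return An object of class `search_params`.
#' @export
search_params <- function(max_mismatches = 4L, max_dna_bulges = 0L,
                          max_rna_bulges = 0L, both_strands = TRUE) {
  stopifnot(
    is.finite(max_mismatches), max_mismatches >= 0,
    is.finite(max_dna_bulges), max_dna_bulges >= 0,
    is.finite(max_rna_bulges), max_rna_bulges >= 0
  )
  structure(
    list(max_mismatches = as.integer(max_mismatches),
         max_dna_bulges = as.integer(max_dna_bulges),
         max_rna_bulges = as.integer(max_rna_bulges),
         both_strands = isTRUE(both_strands)),
    class = "search_params")
}
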