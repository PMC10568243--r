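# Interval annotation tracks (promoters, enhancers, regulator peaks,
# protein domains, miRNA genes, miRNA target sites) backed by BED files.

TRACK_KINDS <- c("promoter", "enhancer", "regulator_peak", "protein_domain",
                 "mirna_gene", "mirna_target")

new_track <- function(kind, records) {
  stopifnot(kind %in% TRACK_KINDS)
  structure(list(kind = kind, records = records), class = "annotation_track")
}

empty_track_records <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             name = character(), strand = character(),
             linked_gene_id = character(), stringsAsFactors = FALSE)
}

#' Load an annotation track from a BED file
#'
#' Accepts BED3 up to BED6 plus one optional extra column carrying the linked
#' gene identifier (e.g. the gene an enhancer regulates). With exactly four
#' columns the 4th doubles as both record name and linked gene; BED5/BED6
#' without a 7th column have no gene link.
#'
#' @param bed_path Path to the BED file.
#' @param kind Track kind, one of `promoter`, `enhancer`, `regulator_peak`,
#'   `protein_domain`, `mirna_gene`, `mirna_target`.
#' @return An `annotation_track` with a `records` data frame (`chrom`,
#'   `start`, `end`, `name`, `strand`, `linked_gene_id`).
#' @export
load_track <- function(bed_path, kind) {
  kind <- match.arg(kind, TRACK_KINDS)
  lines <- readLines(bed_path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!grepl("^(#|track|browser)", lines)]
  if (length(lines) == 0L) return(new_track(kind, empty_track_records()))
  rows <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L) {
      stop_crisprisk(sprintf("malformed BED record at line %d of %s: fewer than 3 columns",
                             i, bed_path), "malformed_record")
    }
    start <- suppressWarnings(as.integer(f[[2L]]))
    end <- suppressWarnings(as.integer(f[[3L]]))
    if (is.na(start) || is.na(end)) {
      stop_crisprisk(sprintf("malformed BED record at line %d of %s: non-integer coordinates",
                             i, bed_path), "malformed_record")
    }
    if (start < 0L || start >= end) {
      stop_crisprisk(sprintf("malformed BED record at line %d of %s: empty or inverted interval",
                             i, bed_path), "malformed_record")
    }
    name <- if (length(f) >= 4L && nzchar(f[[4L]])) f[[4L]] else sprintf("%s_%d", kind, i)
    strand <- if (length(f) >= 6L && f[[6L]] %in% c("+", "-")) f[[6L]] else "."
    linked <- if (length(f) >= 7L && nzchar(f[[7L]])) {
      f[[7L]]
    } else if (length(f) == 4L) {
      f[[4L]]
    } else NA_character_
    rows[[i]] <- data.frame(chrom = f[[1L]], start = start, end = end,
                            name = name, strand = strand,
                            linked_gene_id = linked, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  new_track(kind, out)
}

#' Write an annotation track back to BED
#'
#' Emits BED6 plus the linked-gene column when any record carries one, so a
#' write/reload round-trip reproduces the records exactly.
#'
#' @param track An `annotation_track`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_track <- function(track, path) {
  r <- track$records
  has_link <- any(!is.na(r$linked_gene_id))
  lines <- if (has_link) {
    sprintf("%s\t%d\t%d\t%s\t0\t%s\t%s", r$chrom, r$start, r$end, r$name,
            r$strand, ifelse(is.na(r$linked_gene_id), "", r$linked_gene_id))
  } else {
    sprintf("%s\t%d\t%d\t%s\t0\t%s", r$chrom, r$start, r$end, r$name, r$strand)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Derive promoter windows from transcription start sites
#'
#' For a plus-strand TSS at 0-based position `p` the promoter window is
#' `[p - upstream, p + downstream + 1)`, mirrored for the minus strand and
#' clipped at position 0 (and at the chromosome end when lengths are given).
#' The defaults follow the EPD convention of -499..+100 around the TSS.
#'
#' @param x A `gene_model_set` (TSS taken from each gene's strand-aware
#'   span start) or a data frame with columns `chrom`, `pos` (0-based TSS),
#'   `strand`, `gene_id`.
#' @param upstream,downstream Non-negative window extents in bp.
#' @param seqlengths Optional named vector of chromosome lengths for
#'   right-clipping.
#' @return An `annotation_track` of kind `promoter` with `linked_gene_id`
#'   set to the TSS's gene.
#' @export
derive_promoters <- function(x, upstream = 499L, downstream = 100L,
                             seqlengths = NULL) {
  stopifnot(upstream >= 0, downstream >= 0)
  tss <- if (inherits(x, "gene_model_set")) {
    g <- x$genes
    data.frame(chrom = g$chrom,
               pos = ifelse(g$strand == "-", g$end - 1L, g$start),
               strand = ifelse(g$strand == "-", "-", "+"),
               gene_id = g$gene_id, stringsAsFactors = FALSE)
  } else {
    stopifnot(all(c("chrom", "pos", "strand", "gene_id") %in% names(x)))
    x
  }
  plus <- tss$strand != "-"
  start <- ifelse(plus, tss$pos - upstream, tss$pos - downstream)
  end <- ifelse(plus, tss$pos + downstream + 1L, tss$pos + upstream + 1L)
  start <- pmax(start, 0L)
  if (!is.null(seqlengths)) {
    lim <- unname(seqlengths[tss$chrom])
    end <- ifelse(is.na(lim), end, pmin(end, lim))
  }
  keep <- start < end
  rec <- data.frame(chrom = tss$chrom[keep],
                    start = as.integer(start[keep]), end = as.integer(end[keep]),
                    name = paste0(tss$gene_id[keep], "_promoter"),
                    strand = tss$strand[keep],
                    linked_gene_id = tss$gene_id[keep], stringsAsFactors = FALSE)
  new_track("promoter", rec)
}

#' @export
print.annotation_track <- function(x, ...) {
  cat(sprintf("<annotation_track:%s> %d record(s)\n", x$kind, nrow(x$records)))
  invisible(x)
}
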