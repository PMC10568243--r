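# Gene model loading (GFF3/GTF) and derivation of per-gene segment
# intervals: exon union over transcripts, introns, CDS, 5'/3' UTRs.
# All internal coordinates are 0-based half-open.

SEGMENT_PRECEDENCE <- c("CDS", "5UTR", "3UTR", "exon", "intron")

#' Load gene models from GFF3 or GTF
#'
#' Parses `gene`, `transcript`/`mRNA`, `exon` and (optional) `CDS` features
#' and derives per-gene segment intervals: the exon union over all
#' transcripts defines the gene-level exonic space, introns are the gene
#' span minus that union, and exonic bases 5' of the leftmost CDS base
#' (strand-aware) are 5'UTR / 3' of the rightmost are 3'UTR. Genes without
#' CDS have no UTRs. 1-based closed file coordinates are converted to
#' 0-based half-open.
#'
#' @param path Path to a GFF3 (`.gff`/`.gff3`) or GTF (`.gtf`) file.
#' @param format Override format detection (`"gff3"` or `"gtf"`).
#' @return An object of class `gene_model_set` with data frames `genes`
#'   (`gene_id`, `gene_name`, `biotype`, `chrom`, `start`, `end`, `strand`),
#'   `segments` (`gene_id`, `chrom`, `segment`, `start`, `end`),
#'   `transcripts`, `exons` and `cds`.
#' @export
load_gene_models <- function(path, format = NULL) {
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
    format <- if (ext == "gtf") "gtf" else "gff3"
  }
  gr <- rtracklayer::import(path, format = format)
  type <- tolower(as.character(gr$type))
  mc <- S4Vectors::mcols(gr)
  get_col <- function(nm) if (nm %in% names(mc)) mc[[nm]] else NULL

  first_parent <- function(i) {
    p <- get_col("Parent")
    if (is.null(p)) return(NA_character_)
    pi <- p[[i]]
    if (length(pi) == 0L) NA_character_ else as.character(pi[[1L]])
  }
  strip_prefix <- function(x) sub("^(gene|transcript|mrna):", "", x, ignore.case = TRUE)

  ids <- get_col("ID")
  gene_id_col <- get_col("gene_id")
  tx_id_col <- get_col("transcript_id")
  biotype_col <- get_col("gene_biotype") %||% get_col("gene_type") %||% get_col("biotype")
  name_col <- get_col("gene_name") %||% get_col("Name")

  gi <- which(type == "gene")
  if (length(gi) == 0L) stop("no gene features found in ", path)
  gene_ids <- strip_prefix(
    if (!is.null(gene_id_col) && !all(is.na(gene_id_col[gi]))) as.character(gene_id_col[gi])
    else as.character(ids[gi]))
  genes <- data.frame(
    gene_id = gene_ids,
    gene_name = if (!is.null(name_col)) {
      nm <- as.character(name_col[gi]); ifelse(is.na(nm), gene_ids, nm)
    } else gene_ids,
    biotype = if (!is.null(biotype_col)) {
      bt <- as.character(biotype_col[gi]); ifelse(is.na(bt), "unknown", bt)
    } else "unknown",
    chrom = as.character(GenomicRanges::seqnames(gr))[gi],
    start = GenomicRanges::start(gr)[gi] - 1L,
    end = GenomicRanges::end(gr)[gi],
    strand = as.character(GenomicRanges::strand(gr))[gi],
    stringsAsFactors = FALSE)
  gene_key <- stats::setNames(genes$gene_id, strip_prefix(as.character(ids[gi])))

  ti <- which(type %in% c("transcript", "mrna"))
  tx_raw_ids <- strip_prefix(
    if (!is.null(tx_id_col) && length(ti) && !all(is.na(tx_id_col[ti]))) as.character(tx_id_col[ti])
    else as.character(ids[ti]))
  tx_gene <- character(length(ti))
  for (k in seq_along(ti)) {
    i <- ti[k]
    g <- if (!is.null(gene_id_col) && !is.na(gene_id_col[i])) {
      strip_prefix(as.character(gene_id_col[i]))
    } else strip_prefix(first_parent(i))
    if (is.na(g) || !nzchar(g)) {
      stop(sprintf("transcript '%s' lacks a gene parent", tx_raw_ids[k]))
    }
    if (g %in% names(gene_key)) g <- gene_key[[g]]
    if (!g %in% genes$gene_id) {
      stop(sprintf("transcript '%s' refers to unknown gene '%s'", tx_raw_ids[k], g))
    }
    tx_gene[k] <- g
  }
  transcripts <- data.frame(transcript_id = tx_raw_ids, gene_id = tx_gene,
                            stringsAsFactors = FALSE)

  collect_children <- function(what) {
    ci <- which(type == what)
    if (length(ci) == 0L) {
      return(data.frame(transcript_id = character(), chrom = character(),
                        start = integer(), end = integer(), stringsAsFactors = FALSE))
    }
    tx <- character(length(ci))
    for (k in seq_along(ci)) {
      i <- ci[k]
      t <- if (!is.null(tx_id_col) && !is.na(tx_id_col[i])) {
        strip_prefix(as.character(tx_id_col[i]))
      } else strip_prefix(first_parent(i))
      if (is.na(t) || !nzchar(t)) {
        stop(sprintf("%s feature at %s:%d lacks a transcript parent", what,
                     as.character(GenomicRanges::seqnames(gr))[i],
                     GenomicRanges::start(gr)[i]))
      }
      if (!t %in% transcripts$transcript_id) {
        stop(sprintf("%s feature refers to unknown transcript '%s'", what, t))
      }
      tx[k] <- t
    }
    data.frame(transcript_id = tx,
               chrom = as.character(GenomicRanges::seqnames(gr))[ci],
               start = GenomicRanges::start(gr)[ci] - 1L,
               end = GenomicRanges::end(gr)[ci],
               stringsAsFactors = FALSE)
  }
  exons <- collect_children("exon")
  cds <- collect_children("cds")

  out <- structure(
    list(genes = genes, transcripts = transcripts, exons = exons, cds = cds,
         segments = NULL),
    class = "gene_model_set")
  out$segments <- derive_segments(out)
  out
}

# Build the per-gene segment table from genes/transcripts/exons/cds.
derive_segments <- function(gms) {
  segs <- list()
  for (k in seq_len(nrow(gms$genes))) {
    g <- gms$genes[k, ]
    tx <- gms$transcripts$transcript_id[gms$transcripts$gene_id == g$gene_id]
    ex <- gms$exons[gms$exons$transcript_id %in% tx, , drop = FALSE]
    cd <- gms$cds[gms$cds$transcript_id %in% tx, , drop = FALSE]
    span <- IRanges::IRanges(g$start + 1L, g$end)
    add <- function(label, ir) {
      if (length(ir) == 0L) return()
      segs[[length(segs) + 1L]] <<- data.frame(
        gene_id = g$gene_id, chrom = g$chrom, segment = label,
        start = IRanges::start(ir) - 1L, end = IRanges::end(ir),
        stringsAsFactors = FALSE)
    }
    if (nrow(ex) == 0L) {
      add("exon", span)  # gene without annotated exons: whole span exonic
      next
    }
    exon_union <- IRanges::reduce(IRanges::IRanges(ex$start + 1L, ex$end))
    if (any(IRanges::start(exon_union) < g$start + 1L) ||
        any(IRanges::end(exon_union) > g$end)) {
      stop(sprintf("exons of gene '%s' extend beyond the gene span", g$gene_id))
    }
    introns <- IRanges::setdiff(span, exon_union)
    add("exon", exon_union)
    add("intron", introns)
    if (nrow(cd) > 0L) {
      cds_union <- IRanges::reduce(IRanges::IRanges(cd$start + 1L, cd$end))
      add("CDS", cds_union)
      utr <- IRanges::setdiff(exon_union, cds_union)
      if (length(utr) > 0L) {
        cds_min <- min(IRanges::start(cds_union))
        cds_max <- max(IRanges::end(cds_union))
        left <- IRanges::intersect(utr, IRanges::IRanges(g$start + 1L, cds_min - 1L))
        right <- IRanges::intersect(utr, IRanges::IRanges(cds_max + 1L, g$end))
        if (g$strand == "-") {
          add("3UTR", left); add("5UTR", right)
        } else {
          add("5UTR", left); add("3UTR", right)
        }
      }
    }
  }
  if (length(segs) == 0L) {
    return(data.frame(gene_id = character(), chrom = character(),
                      segment = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, segs)
  rownames(out) <- NULL
  out
}

#' @export
print.gene_model_set <- function(x, ...) {
  cat(sprintf("<gene_model_set> %d gene(s), %d transcript(s) on %d sequence(s)\n",
              nrow(x$genes), nrow(x$transcripts), length(unique(x$genes$chrom))))
  invisible(x)
}
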