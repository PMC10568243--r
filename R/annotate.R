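# Per-site aggregation of all overlap evidence and gene-function lookups
# into one structured annotation per off-target site.

#' Classify which gene segment a site disrupts
#'
#' When a site straddles segment boundaries the highest-precedence
#' overlapped segment wins: CDS > 5'UTR/3'UTR > exon > intron (5'UTR before
#' 3'UTR on the rare tie).
#'
#' @param site One site row (`chrom`, `start`, `end`).
#' @param gene_segments Segment rows of one gene (from a
#'   `gene_model_set$segments` table).
#' @return One of `"CDS"`, `"5UTR"`, `"3UTR"`, `"exon"`, `"intron"`.
#' @export
classify_segment <- function(site, gene_segments) {
  seg <- gene_segments[gene_segments$chrom == site$chrom &
                         gene_segments$start < site$end &
                         gene_segments$end > site$start, , drop = FALSE]
  if (nrow(seg) == 0L) {
    stop("site does not overlap the gene span; classify_segment contract violated")
  }
  for (label in SEGMENT_PRECEDENCE) {
    if (label %in% seg$segment) return(label)
  }
  stop("unreachable: unknown segment labels ", paste(unique(seg$segment), collapse = ","))
}

empty_hit_df <- function() {
  data.frame(name = character(), linked_gene_id = character(),
             stringsAsFactors = FALSE)
}

#' Annotate off-target sites against all loaded layers
#'
#' Intersects every site with gene spans (classifying the disrupted segment
#' per gene), with each annotation track, and attaches the functional record
#' of every gene referenced by a hit. Regulator peaks are additionally
#' flagged when the peak itself lies inside a promoter record.
#'
#' @param sites A site table.
#' @param gene_models A `gene_model_set`, or `NULL` to skip gene annotation.
#' @param tracks Named list of `annotation_track`s (names are ignored; kinds
#'   come from the tracks themselves). Multiple tracks of a kind are allowed.
#' @param function_index A `gene_function_index`, or `NULL` for all-empty
#'   functional records.
#' @param min_overlap Minimum overlap in bp for all intersections.
#' @return A list of `site_annotation` objects, one per site in input order.
#'   Each has the site row, `gene_hits` (`gene_id`, `gene_name`, `biotype`,
#'   `segment`), per-kind hit tables, `functional` (named list of
#'   [gene_function()] records) and `inside_coding_transcribed_region`.
#' @export
annotate_sites <- function(sites, gene_models = NULL, tracks = list(),
                           function_index = NULL, min_overlap = 1L) {
  n <- nrow(sites)
  anns <- vector("list", n)
  if (n == 0L) return(anns)
  fidx <- function_index %||% load_function_tables()

  gene_ov <- NULL
  if (!is.null(gene_models) && nrow(gene_models$genes) > 0L) {
    gene_ov <- intersect_intervals(sites, gene_models$genes, min_overlap)
  }
  track_list <- Filter(function(t) nrow(t$records) > 0L, unname(tracks))
  kinds <- vapply(track_list, function(t) t$kind, character(1))
  track_ov <- lapply(track_list, function(t) {
    intersect_intervals(sites, t$records, min_overlap)
  })
  promoter_records <- do.call(rbind, c(
    lapply(track_list[kinds == "promoter"], function(t) t$records),
    list(empty_track_records())))

  for (k in seq_len(n)) {
    site <- sites[k, , drop = FALSE]
    gene_hits <- data.frame(gene_id = character(), gene_name = character(),
                            biotype = character(), segment = character(),
                            stringsAsFactors = FALSE)
    if (!is.null(gene_ov)) {
      gi <- gene_ov$subject_idx[gene_ov$query_idx == k]
      if (length(gi) > 0L) {
        g <- gene_models$genes[gi, , drop = FALSE]
        seg <- vapply(g$gene_id, function(gid) {
          classify_segment(site,
                           gene_models$segments[gene_models$segments$gene_id == gid, ,
                                                drop = FALSE])
        }, character(1), USE.NAMES = FALSE)
        gene_hits <- data.frame(gene_id = g$gene_id, gene_name = g$gene_name,
                                biotype = g$biotype, segment = seg,
                                stringsAsFactors = FALSE)
      }
    }
    hit_lists <- stats::setNames(
      replicate(length(TRACK_KINDS), empty_hit_df(), simplify = FALSE),
      TRACK_KINDS)
    for (t in seq_along(track_list)) {
      ov <- track_ov[[t]]
      ri <- ov$subject_idx[ov$query_idx == k]
      if (length(ri) == 0L) next
      rec <- track_list[[t]]$records[ri, , drop = FALSE]
      hit <- data.frame(name = rec$name, linked_gene_id = rec$linked_gene_id,
                        stringsAsFactors = FALSE)
      if (kinds[t] == "regulator_peak") {
        hit$in_promoter <- vapply(ri, function(j) {
          r <- track_list[[t]]$records[j, ]
          nrow(intersect_intervals(r, promoter_records)) > 0L
        }, logical(1))
      }
      hit_lists[[kinds[t]]] <- rbind(hit_lists[[kinds[t]]], hit)
    }
    linked <- unlist(lapply(hit_lists[c("promoter", "enhancer")],
                            function(h) h$linked_gene_id), use.names = FALSE)
    fun_ids <- unique(c(gene_hits$gene_id, linked[!is.na(linked)]))
    functional <- stats::setNames(
      lapply(fun_ids, function(gid) gene_function(fidx, gid)),
      strip_gene_version(fun_ids))
    anns[[k]] <- structure(
      list(site = site,
           gene_hits = gene_hits,
           promoter_hits = hit_lists$promoter,
           enhancer_hits = hit_lists$enhancer,
           regulator_peak_hits = hit_lists$regulator_peak,
           domain_hits = hit_lists$protein_domain,
           mirna_gene_hits = hit_lists$mirna_gene,
           mirna_target_hits = hit_lists$mirna_target,
           functional = functional,
           inside_coding_transcribed_region =
             any(gene_hits$biotype == "protein_coding")),
      class = "site_annotation")
  }
  anns
}

#' Annotate a single site
#'
#' Convenience wrapper over [annotate_sites()].
#'
#' @inheritParams annotate_sites
#' @param site A one-row site table.
#' @return A `site_annotation`.
#' @export
annotate_site <- function(site, gene_models = NULL, tracks = list(),
                          function_index = NULL, min_overlap = 1L) {
  annotate_sites(site, gene_models, tracks, function_index, min_overlap)[[1L]]
}

# Functional record of a gene within an annotation (total lookup).
ann_fun <- function(ann, gene_id) {
  ann$functional[[strip_gene_version(gene_id)]] %||%
    list(gene_id = gene_id, phenotypes = character(0), is_cancer_gene = FALSE,
         tf_class = "none", rbp_functions = character(0),
         expression = stats::setNames(numeric(0), character(0)))
}

#' @export
print.site_annotation <- function(x, ...) {
  cat(sprintf("<site_annotation> %s:%d-%d(%s) genes:%d promoters:%d enhancers:%d\n",
              x$site$chrom, x$site$start, x$site$end, x$site$strand,
              nrow(x$gene_hits), nrow(x$promoter_hits), nrow(x$enhancer_hits)))
  invisible(x)
}
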