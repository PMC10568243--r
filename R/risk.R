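# Rule-based risk labelling of annotated off-target sites.
#
# Branch order: a site overlapping any gene is judged on its gene hits
# (coding branch for protein_coding genes, noncoding branch otherwise); only
# a site with no gene overlap at all can receive a regulatory label from
# promoter/enhancer hits; anything else is intergenic ("none"). Within the
# qualifying set the maximum-severity label wins. Gene-branch labels all
# outrank regulatory labels in the severity order so that removing an
# overlap can never raise a site's severity.

#' Risk label vocabulary, most severe first
#' @export
RISK_LABELS <- c("high-coding", "medium-coding", "medium-noncoding",
                 "low-coding", "low-noncoding", "medium-regulatory",
                 "low-regulatory", "none")

EXONIC_SEGMENTS <- c("CDS", "5UTR", "3UTR", "exon")

RISK_COLORS <- c(high = "red", medium = "orange", low = "yellow", none = "green")

label_tier <- function(label) {
  ifelse(label == "none", "none", sub("-.*$", "", label))
}

label_region <- function(label) {
  ifelse(label == "none", "intergenic", sub("^[a-z]+-", "", label))
}

risk_severity <- function(label) match(label, RISK_LABELS)

new_risk_label <- function(label, rationale) {
  structure(list(tier = label_tier(label), region = label_region(label),
                 label = label, rationale = rationale),
            class = "risk_label")
}

#' Assign a risk label to an annotated site
#'
#' Coding branch: an exonic hit (CDS/UTR/exon) in a protein-coding gene with
#' known phenotypes or a cancer role is `high-coding`; exonic without such
#' evidence `medium-coding`; intronic `low-coding`. Noncoding branch (gene
#' hits of any other biotype): exonic `medium-noncoding`, intronic
#' `low-noncoding`. A site with no gene overlap that hits a promoter or
#' enhancer is `medium-regulatory` when the linked gene has phenotypes or a
#' cancer role, else `low-regulatory`. A site with no overlap evidence at
#' all is `none` (intergenic). Across multiple qualifying genes/features the
#' maximum-severity outcome is kept. TF/RBP status and mismatch counts are
#' recorded as evidence but never change the tier.
#'
#' @param annotation A `site_annotation` from [annotate_sites()].
#' @return A `risk_label` with fields `tier`, `region`, `label` and
#'   `rationale` (the fired rule, e.g. `"coding.exonic.disease"`).
#' @export
assign_risk <- function(annotation) {
  stopifnot(inherits(annotation, "site_annotation"))
  cand <- character(0)
  why <- character(0)
  gh <- annotation$gene_hits
  if (nrow(gh) > 0L) {
    for (i in seq_len(nrow(gh))) {
      fun <- ann_fun(annotation, gh$gene_id[i])
      flagged <- length(fun$phenotypes) > 0L || isTRUE(fun$is_cancer_gene)
      exonic <- gh$segment[i] %in% EXONIC_SEGMENTS
      if (gh$biotype[i] == "protein_coding") {
        if (exonic && flagged) {
          cand <- c(cand, "high-coding"); why <- c(why, "coding.exonic.disease")
        } else if (exonic) {
          cand <- c(cand, "medium-coding"); why <- c(why, "coding.exonic")
        } else {
          cand <- c(cand, "low-coding"); why <- c(why, "coding.intronic")
        }
      } else {
        if (exonic) {
          cand <- c(cand, "medium-noncoding"); why <- c(why, "noncoding.exonic")
        } else {
          cand <- c(cand, "low-noncoding"); why <- c(why, "noncoding.intronic")
        }
      }
    }
  } else {
    reg <- rbind(annotation$promoter_hits[, c("name", "linked_gene_id")],
                 annotation$enhancer_hits[, c("name", "linked_gene_id")])
    if (nrow(reg) > 0L) {
      for (i in seq_len(nrow(reg))) {
        linked <- reg$linked_gene_id[i]
        flagged <- FALSE
        if (!is.na(linked)) {
          fun <- ann_fun(annotation, linked)
          flagged <- length(fun$phenotypes) > 0L || isTRUE(fun$is_cancer_gene)
        }
        if (flagged) {
          cand <- c(cand, "medium-regulatory"); why <- c(why, "regulatory.disease")
        } else {
          cand <- c(cand, "low-regulatory"); why <- c(why, "regulatory.plain")
        }
      }
    }
  }
  if (length(cand) == 0L) return(new_risk_label("none", "intergenic"))
  best <- which.min(risk_severity(cand))
  new_risk_label(cand[best], why[best])
}

#' Tally risk labels
#'
#' @param labels A list of `risk_label`s (or a character vector of labels).
#' @return A named integer vector over the full [RISK_LABELS] vocabulary
#'   (zero counts included), summing to the number of sites.
#' @export
risk_distribution <- function(labels) {
  lab <- if (is.character(labels)) labels else
    vapply(labels, function(l) l$label, character(1))
  bad <- setdiff(unique(lab), RISK_LABELS)
  if (length(bad) > 0L) stop("unknown risk label(s): ", paste(bad, collapse = ", "))
  tab <- table(factor(lab, levels = RISK_LABELS))
  stats::setNames(as.integer(tab), RISK_LABELS)
}

#' Color code for a risk label
#'
#' Tier-based map used in the summary table: high = red, medium = orange,
#' low = yellow, none = green.
#'
#' @param label Character label(s) from [RISK_LABELS].
#' @return Character color(s).
#' @export
risk_color <- function(label) {
  unname(RISK_COLORS[label_tier(label)])
}

#' @export
print.risk_label <- function(x, ...) {
  cat(sprintf("<risk_label> %s (%s)\n", x$label, x$rationale))
  invisible(x)
}
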