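# Reporting: the color-coded per-site summary table, per-database tables,
# chart data and file exports.

#' Build the per-site summary table
#'
#' One row per deduplicated site, color-coded solely by its risk label
#' (high = red, medium = orange, low = yellow, none = green). Gene hits are
#' collapsed as `gene_id|gene_name|biotype|segment` entries separated by
#' `;`; feature hits collapse their names. The cancer/TF/RBP flags report
#' whether any gene referenced by the site (hit directly or linked through a
#' promoter/enhancer) carries the attribute.
#'
#' @param annotations List of `site_annotation`s.
#' @param labels List of `risk_label`s, aligned with `annotations`.
#' @return A data frame with one row per site, in site order.
#' @export
build_summary <- function(annotations, labels) {
  if (length(annotations) != length(labels)) {
    stop("annotations and labels have different lengths")
  }
  rows <- lapply(seq_along(annotations), function(k) {
    a <- annotations[[k]]
    l <- labels[[k]]
    s <- a$site
    funs <- lapply(names(a$functional), function(g) a$functional[[g]])
    phen <- sort(unique(unlist(lapply(funs, `[[`, "phenotypes"))))
    data.frame(
      site = s$name %||% sprintf("site_%d", k),
      chrom = s$chrom, start = s$start, end = s$end, strand = s$strand,
      site_sequence = s$site_sequence, pam_sequence = s$pam_sequence,
      mismatches = s$mismatches, dna_bulges = s$dna_bulges,
      rna_bulges = s$rna_bulges,
      genes = collapse_vals(sprintf("%s|%s|%s|%s", a$gene_hits$gene_id,
                                    a$gene_hits$gene_name, a$gene_hits$biotype,
                                    a$gene_hits$segment)),
      promoters = collapse_vals(a$promoter_hits$name),
      enhancers = collapse_vals(a$enhancer_hits$name),
      regulator_peaks = collapse_vals(a$regulator_peak_hits$name),
      protein_domains = collapse_vals(a$domain_hits$name),
      mirna_genes = collapse_vals(a$mirna_gene_hits$name),
      mirna_targets = collapse_vals(a$mirna_target_hits$name),
      phenotypes = collapse_vals(phen),
      cancer_gene = any(vapply(funs, function(f) isTRUE(f$is_cancer_gene), logical(1))),
      tf_gene = any(vapply(funs, function(f) f$tf_class != "none", logical(1))),
      rbp_gene = any(vapply(funs, function(f) length(f$rbp_functions) > 0L, logical(1))),
      in_coding_region = a$inside_coding_transcribed_region,
      risk_label = l$label, risk_rationale = l$rationale,
      color = risk_color(l$label),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(NULL)))
  if (is.null(out)) {
    out <- utils::read.csv(text = paste(c(
      "site,chrom,start,end,strand,site_sequence,pam_sequence,mismatches",
      "dna_bulges,rna_bulges,genes,promoters,enhancers,regulator_peaks",
      "protein_domains,mirna_genes,mirna_targets,phenotypes,cancer_gene",
      "tf_gene,rbp_gene,in_coding_region,risk_label,risk_rationale,color"),
      collapse = ","), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

# Highest-precedence segment a gene is hit in across all sites.
best_segment <- function(segments) {
  SEGMENT_PRECEDENCE[min(match(segments, SEGMENT_PRECEDENCE))]
}

#' Build chart data
#'
#' Four datasets: per-chromosome site counts, the targeted gene-type
#' distribution (distinct genes per biotype and their highest-precedence
#' disrupted segment), the risk-label distribution, and the expression
#' matrix of targeted protein-coding genes across tissues.
#'
#' @inheritParams build_summary
#' @param function_index A `gene_function_index` supplying expression values
#'   (`NULL` for none).
#' @return A list with elements `locations`, `gene_types`, `risk` and
#'   `expression`.
#' @export
build_charts <- function(annotations, labels, function_index = NULL) {
  chroms <- vapply(annotations, function(a) a$site$chrom, character(1))
  locations <- if (length(chroms) > 0L) {
    tab <- table(chroms)
    data.frame(chrom = names(tab), sites = as.integer(tab),
               stringsAsFactors = FALSE)
  } else {
    data.frame(chrom = character(), sites = integer())
  }
  gh <- do.call(rbind, c(lapply(annotations, `[[`, "gene_hits"), list(NULL)))
  if (!is.null(gh) && nrow(gh) > 0L) {
    per_gene <- do.call(rbind, lapply(split(gh, gh$gene_id), function(d) {
      data.frame(gene_id = d$gene_id[1L], biotype = d$biotype[1L],
                 segment = best_segment(d$segment), stringsAsFactors = FALSE)
    }))
    tab <- stats::aggregate(gene_id ~ biotype + segment, data = per_gene,
                            FUN = length)
    names(tab)[names(tab) == "gene_id"] <- "genes"
    gene_types <- tab[order(tab$biotype, tab$segment), , drop = FALSE]
    coding_ids <- unique(per_gene$gene_id[per_gene$biotype == "protein_coding"])
  } else {
    gene_types <- data.frame(biotype = character(), segment = character(),
                             genes = integer())
    coding_ids <- character(0)
  }
  rownames(gene_types) <- NULL
  expr <- data.frame(gene_id = character(), stringsAsFactors = FALSE)
  if (!is.null(function_index) && length(coding_ids) > 0L &&
      length(function_index$tissues) > 0L) {
    recs <- lapply(sort(coding_ids), function(g) gene_function(function_index, g))
    keep <- vapply(recs, function(r) length(r$expression) > 0L, logical(1))
    recs <- recs[keep]
    if (length(recs) > 0L) {
      expr <- cbind(
        data.frame(gene_id = vapply(recs, `[[`, character(1), "gene_id"),
                   stringsAsFactors = FALSE),
        as.data.frame(do.call(rbind, lapply(recs, `[[`, "expression"))))
      rownames(expr) <- NULL
    }
  }
  list(locations = locations, gene_types = gene_types,
       risk = risk_distribution(labels), expression = expr)
}

#' Build the per-database result tables
#'
#' One table per annotation/function layer, mirroring the layered sources:
#' `gencode` (gene hits with segments), `mirgene`, `remap_epd` (promoter
#' hits and regulator peaks, peaks flagged when inside a promoter),
#' `enhancer`, `pfam`, `targetscan`, `omim` (phenotypes of referenced
#' genes), `tf`, `rbp`, `cosmic` (cancer genes referenced) and `expression`.
#'
#' @inheritParams build_charts
#' @return A named list of data frames.
#' @export
build_db_tables <- function(annotations, labels, function_index = NULL) {
  site_ids <- vapply(seq_along(annotations), function(k) {
    annotations[[k]]$site$name %||% sprintf("site_%d", k)
  }, character(1))
  bind_hits <- function(field, extra_cols = NULL) {
    rows <- lapply(seq_along(annotations), function(k) {
      h <- annotations[[k]][[field]]
      if (nrow(h) == 0L) return(NULL)
      cbind(data.frame(site = site_ids[k], stringsAsFactors = FALSE), h)
    })
    out <- do.call(rbind, c(rows, list(NULL)))
    if (is.null(out)) {
      cols <- c("site", "name", "linked_gene_id", extra_cols)
      out <- as.data.frame(stats::setNames(
        replicate(length(cols), character(0), simplify = FALSE), cols))
    }
    rownames(out) <- NULL
    out
  }
  gencode_rows <- lapply(seq_along(annotations), function(k) {
    gh <- annotations[[k]]$gene_hits
    if (nrow(gh) == 0L) return(NULL)
    cbind(data.frame(site = site_ids[k], stringsAsFactors = FALSE), gh)
  })
  gencode <- do.call(rbind, c(gencode_rows, list(NULL)))
  if (is.null(gencode)) {
    gencode <- data.frame(site = character(), gene_id = character(),
                          gene_name = character(), biotype = character(),
                          segment = character(), stringsAsFactors = FALSE)
  }
  rownames(gencode) <- NULL

  promoters <- bind_hits("promoter_hits")
  peaks <- bind_hits("regulator_peak_hits", "in_promoter")
  promoters$source <- rep("promoter", nrow(promoters))
  peaks$source <- rep("regulator_peak", nrow(peaks))
  if (!"in_promoter" %in% names(promoters)) {
    promoters$in_promoter <- rep(NA, nrow(promoters))
  }
  if (!"in_promoter" %in% names(peaks)) peaks$in_promoter <- rep(NA, nrow(peaks))
  common <- c("site", "source", "name", "linked_gene_id", "in_promoter")
  remap_epd <- rbind(promoters[, common, drop = FALSE], peaks[, common, drop = FALSE])
  rownames(remap_epd) <- NULL

  all_fun <- list()
  for (a in annotations) for (g in names(a$functional)) {
    all_fun[[g]] <- a$functional[[g]]
  }
  gids <- sort(names(all_fun))
  omim <- do.call(rbind, c(lapply(gids, function(g) {
    p <- all_fun[[g]]$phenotypes
    if (length(p) == 0L) return(NULL)
    data.frame(gene_id = g, phenotype = p, stringsAsFactors = FALSE)
  }), list(NULL))) %||% data.frame(gene_id = character(), phenotype = character())
  tf <- do.call(rbind, c(lapply(gids, function(g) {
    cl <- all_fun[[g]]$tf_class
    if (cl == "none") return(NULL)
    data.frame(gene_id = g, tf_class = cl, stringsAsFactors = FALSE)
  }), list(NULL))) %||% data.frame(gene_id = character(), tf_class = character())
  rbp <- do.call(rbind, c(lapply(gids, function(g) {
    f <- all_fun[[g]]$rbp_functions
    if (length(f) == 0L) return(NULL)
    data.frame(gene_id = g, rbp_function = f, stringsAsFactors = FALSE)
  }), list(NULL))) %||% data.frame(gene_id = character(), rbp_function = character())
  cosmic <- data.frame(
    gene_id = gids[vapply(gids, function(g) isTRUE(all_fun[[g]]$is_cancer_gene),
                          logical(1))],
    stringsAsFactors = FALSE)
  expression <- build_charts(annotations, labels, function_index)$expression
  rownames(omim) <- rownames(tf) <- rownames(rbp) <- NULL

  list(gencode = gencode,
       mirgene = bind_hits("mirna_gene_hits"),
       remap_epd = remap_epd,
       enhancer = bind_hits("enhancer_hits"),
       pfam = bind_hits("domain_hits"),
       targetscan = bind_hits("mirna_target_hits"),
       omim = omim, tf = tf, rbp = rbp, cosmic = cosmic,
       expression = expression)
}

charts_to_json_list <- function(charts) {
  list(locations = charts$locations, gene_types = charts$gene_types,
       risk = as.list(charts$risk), expression = charts$expression)
}

#' Export results to disk
#'
#' `csv` writes `summary.csv`, `charts.json`, `sites.bed` and one
#' `tables/<db>.tsv` per database table; `json` writes a single
#' `results.json` with keys `summary`, `charts` and `tables` (plus
#' `sites.bed`). Excel (`xlsx`) output is not supported and raises an error;
#' any other format name is rejected.
#'
#' @param summary Summary table from [build_summary()].
#' @param charts Chart bundle from [build_charts()].
#' @param tables Per-database tables from [build_db_tables()].
#' @param sites The site table (for `sites.bed`).
#' @param out_dir Output directory (created if needed).
#' @param formats Character subset of `c("csv", "json")`.
#' @return Invisibly, the vector of files written.
#' @export
export_results <- function(summary, charts, tables, sites, out_dir,
                           formats = "csv") {
  known <- c("csv", "json", "xlsx")
  bad <- setdiff(formats, known)
  if (length(bad) > 0L) stop("unknown export format(s): ", paste(bad, collapse = ", "))
  if ("xlsx" %in% formats) {
    stop("xlsx export is not supported; use 'csv' or 'json'")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  bed <- file.path(out_dir, "sites.bed")
  write_sites(sites, bed_path = bed)
  written <- c(written, bed)
  if ("csv" %in% formats) {
    f <- file.path(out_dir, "summary.csv")
    utils::write.csv(summary, f, row.names = FALSE)
    written <- c(written, f)
    f <- file.path(out_dir, "charts.json")
    jsonlite::write_json(charts_to_json_list(charts), f, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    written <- c(written, f)
    tdir <- file.path(out_dir, "tables")
    dir.create(tdir, showWarnings = FALSE)
    for (nm in names(tables)) {
      f <- file.path(tdir, paste0(nm, ".tsv"))
      utils::write.table(tables[[nm]], f, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      written <- c(written, f)
    }
  }
  if ("json" %in% formats) {
    f <- file.path(out_dir, "results.json")
    jsonlite::write_json(
      list(summary = summary, charts = charts_to_json_list(charts),
           tables = tables),
      f, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
    written <- c(written, f)
  }
  invisible(written)
}
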