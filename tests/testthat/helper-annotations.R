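# Construct site_annotation objects directly for risk-engine tests, without
# running the annotator: gene hits are (biotype, segment, phenotype?,
# cancer?) tuples, regulatory hits are linked-gene flag pairs.

mk_fun_rec <- function(gene_id, phenotype = FALSE, cancer = FALSE,
                       tf = "none", rbp = character(0)) {
  list(gene_id = gene_id,
       phenotypes = if (phenotype) paste0(gene_id, " syndrome") else character(0),
       is_cancer_gene = cancer, tf_class = tf, rbp_functions = rbp,
       expression = stats::setNames(numeric(0), character(0)))
}

empty_hits <- function() {
  data.frame(name = character(), linked_gene_id = character(),
             stringsAsFactors = FALSE)
}

# genes: list of list(biotype=, segment=, phenotype=, cancer=)
# promoters/enhancers: list of list(phenotype=, cancer=) for the linked gene
# (use linked = FALSE for a feature with no gene link)
mk_ann <- function(genes = list(), promoters = list(), enhancers = list(),
                   gene_prefix = "") {
  functional <- list()
  gene_hits <- data.frame(gene_id = character(), gene_name = character(),
                          biotype = character(), segment = character(),
                          stringsAsFactors = FALSE)
  for (i in seq_along(genes)) {
    g <- genes[[i]]
    gid <- sprintf("%sG%d", gene_prefix, i)
    gene_hits <- rbind(gene_hits, data.frame(
      gene_id = gid, gene_name = gid, biotype = g$biotype, segment = g$segment,
      stringsAsFactors = FALSE))
    functional[[gid]] <- mk_fun_rec(gid, isTRUE(g$phenotype), isTRUE(g$cancer))
  }
  mk_reg <- function(specs, prefix) {
    hits <- empty_hits()
    for (i in seq_along(specs)) {
      r <- specs[[i]]
      if (isFALSE(r$linked %||% TRUE)) {
        hits <- rbind(hits, data.frame(name = sprintf("%s%d", prefix, i),
                                       linked_gene_id = NA_character_,
                                       stringsAsFactors = FALSE))
        next
      }
      gid <- sprintf("%sG%d", toupper(prefix), i)
      hits <- rbind(hits, data.frame(name = sprintf("%s%d", prefix, i),
                                     linked_gene_id = gid,
                                     stringsAsFactors = FALSE))
      functional[[gid]] <<- mk_fun_rec(gid, isTRUE(r$phenotype), isTRUE(r$cancer))
    }
    hits
  }
  promoter_hits <- mk_reg(promoters, "prom")
  enhancer_hits <- mk_reg(enhancers, "enh")
  structure(
    list(site = data.frame(chrom = "chr1", start = 0L, end = 20L,
                           strand = "+", name = "s1",
                           site_sequence = NA_character_,
                           pam_sequence = NA_character_,
                           mismatches = NA_integer_, dna_bulges = 0L,
                           rna_bulges = 0L, alignment = NA_character_,
                           is_on_target = FALSE, stringsAsFactors = FALSE),
         gene_hits = gene_hits,
         promoter_hits = promoter_hits,
         enhancer_hits = enhancer_hits,
         regulator_peak_hits = empty_hits(),
         domain_hits = empty_hits(),
         mirna_gene_hits = empty_hits(),
         mirna_target_hits = empty_hits(),
         functional = functional,
         inside_coding_transcribed_region =
           any(gene_hits$biotype == "protein_coding")),
    class = "site_annotation")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

severity_rank <- function(label) match(label, crisprisk::RISK_LABELS)

# Exhaustive enumeration of annotation combinations used by the decision-
# table tests: gene hits over {biotype} x {segment} x {phenotype} x {cancer}
# plus promoter/enhancer hits over {absent, plain, flagged}.
enumerate_annotations <- function() {
  gene_opts <- list(NULL)
  for (biotype in c("protein_coding", "lncRNA", "TEC")) {
    for (segment in c("CDS", "5UTR", "3UTR", "exon", "intron")) {
      for (phenotype in c(FALSE, TRUE)) for (cancer in c(FALSE, TRUE)) {
        gene_opts[[length(gene_opts) + 1L]] <- list(
          biotype = biotype, segment = segment,
          phenotype = phenotype, cancer = cancer)
      }
    }
  }
  reg_opts <- list(NULL, list(phenotype = FALSE, cancer = FALSE),
                   list(phenotype = TRUE, cancer = FALSE),
                   list(phenotype = FALSE, cancer = TRUE))
  cases <- list()
  for (g in gene_opts) for (p in reg_opts) for (e in reg_opts) {
    cases[[length(cases) + 1L]] <- mk_ann(
      genes = if (is.null(g)) list() else list(g),
      promoters = if (is.null(p)) list() else list(p),
      enhancers = if (is.null(e)) list() else list(e))
  }
  cases
}

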