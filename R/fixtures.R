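# Synthetic test worlds: a random genome with planted on/off-target sites of
# chosen mismatch counts, gene models, regulatory tracks and function tables,
# plus a ground-truth manifest that fully determines the expected pipeline
# output. The background is screened with an independent brute-force scan so
# no unplanned site within the mismatch budget survives.

FIXTURE_CONTEXTS <- list(
  exon_disease    = list(label = "high-coding",      segment = "CDS",
                         biotype = "protein_coding", phenotype = TRUE,  cancer = FALSE),
  exon_cancer     = list(label = "high-coding",      segment = "CDS",
                         biotype = "protein_coding", phenotype = FALSE, cancer = TRUE),
  exon_plain      = list(label = "medium-coding",    segment = "CDS",
                         biotype = "protein_coding", phenotype = FALSE, cancer = FALSE),
  intron          = list(label = "low-coding",       segment = "intron",
                         biotype = "protein_coding", phenotype = FALSE, cancer = FALSE),
  noncoding_exon  = list(label = "medium-noncoding", segment = "exon",
                         biotype = "lncRNA",         phenotype = FALSE, cancer = FALSE),
  noncoding_intron = list(label = "low-noncoding",   segment = "intron",
                         biotype = "lncRNA",         phenotype = FALSE, cancer = FALSE),
  promoter_disease = list(label = "medium-regulatory", segment = NA_character_,
                         biotype = "protein_coding", phenotype = TRUE,  cancer = FALSE),
  promoter_plain  = list(label = "low-regulatory",   segment = NA_character_,
                         biotype = "protein_coding", phenotype = FALSE, cancer = FALSE),
  enhancer_cancer = list(label = "medium-regulatory", segment = NA_character_,
                         biotype = "protein_coding", phenotype = FALSE, cancer = TRUE),
  enhancer_plain  = list(label = "low-regulatory",   segment = NA_character_,
                         biotype = "protein_coding", phenotype = FALSE, cancer = FALSE),
  intergenic      = list(label = "none",             segment = NA_character_,
                         biotype = NA_character_,    phenotype = FALSE, cancer = FALSE)
)

#' Default fixture plan
#'
#' Ten planted sites with mismatch histogram `{0:1, 2:1, 3:3, 4:5}` spread
#' over every annotation context the risk schema distinguishes (disease and
#' cancer exons, plain exon, intron, noncoding exon/intron, disease
#' promoter, cancer and plain enhancers, intergenic), one of them on the
#' minus strand.
#'
#' @param guide Protospacer to plant sites for.
#' @param pam PAM pattern (planted PAMs instantiate its first expansion with
#'   `A` for `N`).
#' @param sites Data frame with columns `mismatches`, `context`, `strand`.
#' @param max_mismatches Screening budget: the background is guaranteed free
#'   of unplanned sites within this many mismatches.
#' @param slot_size Genome bp reserved per planted site (>= 1400).
#' @param tissues Tissue names for the expression table.
#' @return A `fixture_plan` list.
#' @export
fixture_plan <- function(guide = "CACCCGATCCACTGGGGAGC", pam = "NGG",
                         sites = data.frame(
                           mismatches = c(0L, 2L, 3L, 3L, 3L, 4L, 4L, 4L, 4L, 4L),
                           context = c("exon_disease", "exon_plain", "intron",
                                       "promoter_disease", "enhancer_plain",
                                       "exon_cancer", "noncoding_exon",
                                       "noncoding_intron", "enhancer_cancer",
                                       "intergenic"),
                           strand = c("+", "-", "+", "+", "+", "+", "+", "+", "+", "+"),
                           stringsAsFactors = FALSE),
                         max_mismatches = 4L, slot_size = 1500L,
                         tissues = c("blood", "brain", "liver")) {
  structure(list(guide = toupper(guide), pam = toupper(pam), sites = sites,
                 max_mismatches = as.integer(max_mismatches),
                 slot_size = as.integer(slot_size), tissues = tissues),
            class = "fixture_plan")
}

# Independent brute-force scan used only to screen fixture backgrounds:
# regex PAM matching plus per-window character comparison.
screen_scan <- function(seqs, guide, pam, max_mm) {
  L <- nchar(guide)
  P <- nchar(pam)
  gch <- chars_of(guide)
  pam_re <- paste0(vapply(chars_of(pam), function(cc) {
    paste0("[", paste(IUPAC_MAP[[cc]], collapse = ""), "]")
  }, character(1)), collapse = "")
  rows <- list()
  for (chrom in names(seqs)) {
    fwd <- seqs[[chrom]]
    n <- nchar(fwd)
    for (strand in c("+", "-")) {
      s <- if (strand == "+") fwd else revcomp(fwd)
      if (n < L + P) next
      starts <- seq_len(n - L - P + 1L)
      pams <- substring(s, starts + L, starts + L + P - 1L)
      cand <- starts[grepl(paste0("^", pam_re, "$"), pams)]
      for (p in cand) {
        w <- chars_of(substr(s, p, p + L - 1L))
        mm <- sum(w != gch)
        if (mm > max_mm) next
        if (strand == "+") {
          st <- p - 1L; en <- st + L
        } else {
          en <- n - (p - 1L); st <- en - L
        }
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = chrom, start = st, end = en, strand = strand,
          mismatches = mm, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, c(rows, list(NULL))) %||%
    data.frame(chrom = character(), start = integer(), end = integer(),
               strand = character(), mismatches = integer())
}

#' Generate a synthetic test world
#'
#' Writes a complete, internally consistent input set -- genome FASTA, gene
#' models (GFF3), promoter/enhancer/peak/domain/miRNA BED tracks, function
#' TSVs, a ready-to-run pipeline `config.yaml` -- plus a `manifest.json`
#' recording every planted site with its intended mismatch count and the
#' risk label the pipeline is expected to assign. The same seed always
#' produces byte-identical files.
#'
#' @param dir Output directory (created; must be empty or absent).
#' @param plan A [fixture_plan()].
#' @param seed Integer RNG seed.
#' @return Invisibly, a list with `dir`, `config` (path), `manifest` (parsed
#'   ground truth) and `files`.
#' @export
make_fixture <- function(dir, plan = fixture_plan(), seed = 42L) {
  stopifnot(inherits(plan, "fixture_plan"))
  bad <- setdiff(plan$sites$context, names(FIXTURE_CONTEXTS))
  if (length(bad) > 0L) stop("unknown fixture context(s): ", paste(bad, collapse = ", "))
  if (any(plan$sites$mismatches > plan$max_mismatches)) {
    stop("infeasible plan: planted mismatch count exceeds the screening budget")
  }
  L <- nchar(plan$guide)
  if (any(plan$sites$mismatches > L)) {
    stop("infeasible plan: more mismatches than guide positions")
  }
  if (plan$slot_size < 1400L) {
    stop("infeasible plan: slot_size below 1400 bp cannot hold a site and its annotations")
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)

  ns <- nrow(plan$sites)
  pam_concrete <- paste(vapply(chars_of(plan$pam), function(cc) {
    if (cc %in% DNA_BASES) cc else "A"
  }, character(1)), collapse = "")
  if (substr(plan$pam, 1L, 1L) == "N") {
    pam_concrete <- paste0("A", substr(pam_concrete, 2L, nchar(pam_concrete)))
  }
  P <- nchar(plan$pam)

  # one slot per site; first ~70% of sites on chr1, rest on chr2
  n1 <- max(1L, ceiling(ns * 0.7))
  chrom_of <- c(rep("chr1", n1), rep("chr2", ns - n1))
  slot_of <- c(seq_len(n1), seq_len(ns - n1))
  chrom_len <- c(chr1 = n1 * plan$slot_size + 200L,
                 chr2 = max(1L, ns - n1) * plan$slot_size + 200L)
  genome <- lapply(chrom_len, function(n) sample(DNA_BASES, n, replace = TRUE))

  plant <- function(chrom, pos0, chars) {
    genome[[chrom]][(pos0 + 1L):(pos0 + length(chars))] <<- chars
  }

  site_rows <- list(); gene_rows <- list(); tx_rows <- list()
  exon_rows <- list(); cds_rows <- list()
  promoter_rows <- list(); enhancer_rows <- list(); peak_rows <- list()
  domain_rows <- list(); mirna_target_rows <- list()
  phen_rows <- list(); cancer_rows <- list(); tf_rows <- list(); rbp_rows <- list()
  locked <- list(chr1 = integer(0), chr2 = integer(0))

  for (k in seq_len(ns)) {
    ctx_name <- plan$sites$context[k]
    ctx <- FIXTURE_CONTEXTS[[ctx_name]]
    mm <- plan$sites$mismatches[k]
    strand <- plan$sites$strand[k]
    chrom <- chrom_of[k]
    s <- (slot_of[k] - 1L) * plan$slot_size + 600L
    e <- s + L

    site_seq <- chars_of(plan$guide)
    if (mm > 0L) {
      pos <- sample.int(L, mm)
      for (p in pos) site_seq[p] <- sample(setdiff(DNA_BASES, site_seq[p]), 1L)
    }
    if (strand == "+") {
      plant(chrom, s, site_seq)
      plant(chrom, e, chars_of(pam_concrete))
      locked[[chrom]] <- c(locked[[chrom]], s:(e + P - 1L))
    } else {
      plant(chrom, s, chars_of(revcomp(paste(site_seq, collapse = ""))))
      plant(chrom, s - P, chars_of(revcomp(pam_concrete)))
      locked[[chrom]] <- c(locked[[chrom]], (s - P):(e - 1L))
    }

    gid <- sprintf("FXG%04d", k)
    gname <- sprintf("GENE%d", k)
    add_gene <- function(gstart, gend, exons, cds) {
      gene_rows[[length(gene_rows) + 1L]] <<- data.frame(
        gene_id = gid, gene_name = gname, biotype = ctx$biotype, chrom = chrom,
        start = gstart, end = gend, strand = "+", context = ctx_name,
        phenotype = ctx$phenotype, cancer = ctx$cancer, stringsAsFactors = FALSE)
      tid <- paste0(gid, ".t1")
      tx_rows[[length(tx_rows) + 1L]] <<- data.frame(
        transcript_id = tid, gene_id = gid, chrom = chrom,
        start = gstart, end = gend, stringsAsFactors = FALSE)
      for (ex in exons) {
        exon_rows[[length(exon_rows) + 1L]] <<- data.frame(
          transcript_id = tid, chrom = chrom, start = ex[1L], end = ex[2L],
          stringsAsFactors = FALSE)
      }
      for (cd in cds) {
        cds_rows[[length(cds_rows) + 1L]] <<- data.frame(
          transcript_id = tid, chrom = chrom, start = cd[1L], end = cd[2L],
          stringsAsFactors = FALSE)
      }
    }

    if (ctx_name %in% c("exon_disease", "exon_cancer", "exon_plain")) {
      add_gene(s - 150L, e + 150L, list(c(s - 150L, e + 150L)),
               list(c(s - 50L, e + 50L)))
    } else if (ctx_name == "intron") {
      add_gene(s - 250L, e + 250L,
               list(c(s - 250L, s - 100L), c(e + 100L, e + 250L)),
               list(c(s - 220L, s - 120L), c(e + 120L, e + 220L)))
    } else if (ctx_name == "noncoding_exon") {
      add_gene(s - 100L, e + 100L, list(c(s - 100L, e + 100L)), list())
    } else if (ctx_name == "noncoding_intron") {
      add_gene(s - 250L, e + 250L,
               list(c(s - 250L, s - 100L), c(e + 100L, e + 250L)), list())
    } else if (ctx_name %in% c("promoter_disease", "promoter_plain")) {
      add_gene(e + 200L, e + 700L, list(c(e + 200L, e + 700L)),
               list(c(e + 300L, e + 500L)))
      promoter_rows[[length(promoter_rows) + 1L]] <- data.frame(
        chrom = chrom, start = s - 60L, end = e + 60L,
        name = paste0(gid, "_prom"), strand = "+", linked_gene_id = gid,
        stringsAsFactors = FALSE)
    } else if (ctx_name %in% c("enhancer_cancer", "enhancer_plain")) {
      goff <- (slot_of[k] - 1L) * plan$slot_size
      add_gene(goff + 50L, goff + 350L, list(c(goff + 50L, goff + 350L)),
               list(c(goff + 120L, goff + 280L)))
      enhancer_rows[[length(enhancer_rows) + 1L]] <- data.frame(
        chrom = chrom, start = s - 60L, end = e + 60L,
        name = paste0(gid, "_enh"), strand = ".", linked_gene_id = gid,
        stringsAsFactors = FALSE)
    }

    has_gene <- !ctx_name %in% "intergenic"
    if (has_gene) {
      if (ctx$phenotype) {
        phen_rows[[length(phen_rows) + 1L]] <- data.frame(
          gene_id = gid, phenotype = paste0(gname, " deficiency syndrome"),
          stringsAsFactors = FALSE)
      }
      if (ctx$cancer) {
        cancer_rows[[length(cancer_rows) + 1L]] <- data.frame(
          gene_id = gid, stringsAsFactors = FALSE)
      }
    }
    if (ctx_name == "exon_plain") {
      tf_rows[[length(tf_rows) + 1L]] <- data.frame(
        gene_id = gid, tf_class = "TF", stringsAsFactors = FALSE)
    }
    if (ctx_name == "exon_disease") {
      rbp_rows[[length(rbp_rows) + 1L]] <- data.frame(
        gene_id = gid, rbp_function = "RNA stability and decay",
        stringsAsFactors = FALSE)
      domain_rows[[length(domain_rows) + 1L]] <- data.frame(
        chrom = chrom, start = s - 5L, end = e + 5L,
        name = paste0(gname, "_domain"), strand = ".", linked_gene_id = gid,
        stringsAsFactors = FALSE)
    }
    if (ctx_name == "promoter_disease") {
      peak_rows[[length(peak_rows) + 1L]] <- data.frame(
        chrom = chrom, start = s - 30L, end = e + 30L, name = "TF1_peak",
        strand = ".", linked_gene_id = NA_character_, stringsAsFactors = FALSE)
    }
    if (ctx_name == "noncoding_exon") {
      mirna_target_rows[[length(mirna_target_rows) + 1L]] <- data.frame(
        chrom = chrom, start = s - 10L, end = e + 10L, name = "miR-fx-1_site",
        strand = ".", linked_gene_id = NA_character_, stringsAsFactors = FALSE)
    }

    site_rows[[k]] <- data.frame(
      site_id = sprintf("planted_%d", k), chrom = chrom, start = s, end = e,
      strand = strand, mismatches = mm, context = ctx_name,
      site_sequence = paste(site_seq, collapse = ""),
      pam_sequence = pam_concrete,
      expected_label = ctx$label, expected_segment = ctx$segment,
      gene_id = if (has_gene) gid else NA_character_,
      stringsAsFactors = FALSE)
  }

  planted <- do.call(rbind, site_rows)

  # an miRNA gene nothing hits, to exercise the (empty) mirgene layer
  mirna_gene_rec <- data.frame(
    chrom = "chr1", start = chrom_len[["chr1"]] - 180L,
    end = chrom_len[["chr1"]] - 120L, name = "miR-fx-1", strand = "+",
    linked_gene_id = NA_character_, stringsAsFactors = FALSE)

  # screen the background: every brute-force hit must be a planted locus
  seqs_chr <- function() vapply(genome, function(g) paste(g, collapse = ""),
                                character(1))
  planted_key <- paste(planted$chrom, planted$start, planted$end, planted$strand)
  for (iter in seq_len(30L)) {
    hits <- screen_scan(seqs_chr(), plan$guide, plan$pam, plan$max_mismatches)
    key <- paste(hits$chrom, hits$start, hits$end, hits$strand)
    unplanned <- hits[!key %in% planted_key, , drop = FALSE]
    if (nrow(unplanned) == 0L) break
    if (iter == 30L) stop("infeasible plan: could not screen out unplanned sites")
    for (h in seq_len(nrow(unplanned))) {
      u <- unplanned[h, ]
      span0 <- if (u$strand == "+") u$start:(u$end + P - 1L) else (u$start - P):(u$end - 1L)
      span0 <- span0[span0 >= 0L & span0 < chrom_len[[u$chrom]]]
      free <- setdiff(span0, locked[[u$chrom]])
      if (length(free) == 0L) stop("infeasible plan: unplanned hit inside planted spans")
      p <- free[[sample.int(length(free), 1L)]]
      cur <- genome[[u$chrom]][p + 1L]
      genome[[u$chrom]][p + 1L] <- sample(setdiff(DNA_BASES, cur), 1L)
    }
  }
  # verify planted sites carry exactly the intended mismatch counts
  hits <- screen_scan(seqs_chr(), plan$guide, plan$pam, plan$max_mismatches)
  key <- paste(hits$chrom, hits$start, hits$end, hits$strand)
  for (k in seq_len(nrow(planted))) {
    i <- match(planted_key[k], key)
    if (is.na(i) || hits$mismatches[i] != planted$mismatches[k]) {
      stop("internal error: planted site not recovered by the screening scan")
    }
  }

  # ---- write files -------------------------------------------------------
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  wfile <- function(name) {
    paths[[name]] <<- file.path(dir, name)
    paths[[name]]
  }

  gen_set <- Biostrings::DNAStringSet(seqs_chr())
  names(gen_set) <- names(chrom_len)
  Biostrings::writeXStringSet(gen_set, wfile("genome.fa"), width = 70L)

  genes <- do.call(rbind, gene_rows)
  txs <- do.call(rbind, tx_rows)
  exs <- do.call(rbind, exon_rows)
  cds <- do.call(rbind, c(cds_rows, list(NULL)))
  gff <- c("##gff-version 3")
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    gff <- c(gff, sprintf(
      "%s\tfixture\tgene\t%d\t%d\t.\t%s\t.\tID=%s;gene_id=%s;gene_name=%s;gene_biotype=%s",
      g$chrom, g$start + 1L, g$end, g$strand, g$gene_id, g$gene_id,
      g$gene_name, g$biotype))
    tx <- txs[txs$gene_id == g$gene_id, ]
    for (j in seq_len(nrow(tx))) {
      t <- tx[j, ]
      gff <- c(gff, sprintf(
        "%s\tfixture\ttranscript\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
        t$chrom, t$start + 1L, t$end, g$strand, t$transcript_id, g$gene_id))
      ex <- exs[exs$transcript_id == t$transcript_id, ]
      for (x in seq_len(nrow(ex))) {
        gff <- c(gff, sprintf(
          "%s\tfixture\texon\t%d\t%d\t.\t%s\t.\tID=%s.e%d;Parent=%s",
          ex$chrom[x], ex$start[x] + 1L, ex$end[x], g$strand,
          t$transcript_id, x, t$transcript_id))
      }
      if (!is.null(cds)) {
        cd <- cds[cds$transcript_id == t$transcript_id, ]
        for (x in seq_len(nrow(cd))) {
          gff <- c(gff, sprintf(
            "%s\tfixture\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.c%d;Parent=%s",
            cd$chrom[x], cd$start[x] + 1L, cd$end[x], g$strand,
            t$transcript_id, x, t$transcript_id))
        }
      }
    }
  }
  writeLines(gff, wfile("genes.gff3"))

  write_bed <- function(rows, name) {
    rec <- do.call(rbind, c(rows, list(NULL))) %||% empty_track_records()
    write_track(new_track("enhancer", rec), wfile(name))  # kind irrelevant for writing
  }
  write_bed(promoter_rows, "promoters.bed")
  write_bed(enhancer_rows, "enhancers.bed")
  write_bed(peak_rows, "peaks.bed")
  write_bed(domain_rows, "domains.bed")
  write_bed(list(mirna_gene_rec), "mirna_genes.bed")
  write_bed(mirna_target_rows, "mirna_targets.bed")

  write_tsv <- function(rows, name, header_df) {
    df <- do.call(rbind, c(rows, list(NULL))) %||% header_df
    utils::write.table(df, wfile(name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  write_tsv(phen_rows, "phenotypes.tsv",
            data.frame(gene_id = character(), phenotype = character()))
  write_tsv(cancer_rows, "cancer.tsv", data.frame(gene_id = character()))
  write_tsv(tf_rows, "tf.tsv",
            data.frame(gene_id = character(), tf_class = character()))
  write_tsv(rbp_rows, "rbp.tsv",
            data.frame(gene_id = character(), rbp_function = character()))
  coding_ids <- genes$gene_id[genes$biotype == "protein_coding"]
  expr <- data.frame(gene_id = coding_ids, stringsAsFactors = FALSE)
  for (t in plan$tissues) {
    expr[[t]] <- round(stats::runif(length(coding_ids), 0, 150), 1)
  }
  utils::write.table(expr, wfile("expression.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)

  config <- c(
    "genome: genome.fa",
    paste0("guides: [", plan$guide, "]"),
    paste0("pam: ", plan$pam),
    "search:",
    paste0("  max_mismatches: ", plan$max_mismatches),
    "  max_dna_bulges: 0",
    "  max_rna_bulges: 0",
    "  both_strands: true",
    "databases:",
    "  gene_models: genes.gff3",
    "  promoters: promoters.bed",
    "  enhancers: enhancers.bed",
    "  regulator_peaks: peaks.bed",
    "  protein_domains: domains.bed",
    "  mirna_genes: mirna_genes.bed",
    "  mirna_targets: mirna_targets.bed",
    "  phenotypes: phenotypes.tsv",
    "  cancer: cancer.tsv",
    "  tf: tf.tsv",
    "  rbp: rbp.tsv",
    "  expression: expression.tsv",
    "out_dir: out",
    "formats: [csv, json]")
  writeLines(config, wfile("config.yaml"))

  expected_risk <- risk_distribution(planted$expected_label)
  loc_tab <- table(planted$chrom)
  manifest <- list(
    seed = seed, guide = plan$guide, pam = plan$pam,
    max_mismatches = plan$max_mismatches,
    genome = as.list(chrom_len),
    sites = planted,
    genes = genes,
    expected = list(
      n_sites = nrow(planted),
      mismatch_histogram = as.list(table(planted$mismatches)),
      risk_distribution = as.list(expected_risk),
      locations = as.list(loc_tab)))
  jsonlite::write_json(manifest, wfile("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")

  invisible(list(dir = dir, config = file.path(dir, "config.yaml"),
                 manifest = manifest, files = unlist(paths)))
}
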