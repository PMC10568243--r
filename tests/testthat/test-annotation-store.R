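write_fasta <- function(seqs, path) {
  con <- file(path, "w")
  for (nm in names(seqs)) {
    writeLines(c(paste0(">", nm), seqs[[nm]]), con)
  }
  close(con)
}

test_that("load_genome reads multi-FASTA, trims names, rejects duplicates", {
  f <- withr::local_tempfile(fileext = ".fa")
  write_fasta(c("chr1 assembly-1" = "ACGTACGT", chr2 = "TTTT"), f)
  g <- load_genome(f)
  expect_equal(names(g), c("chr1", "chr2"))
  expect_equal(unname(Biostrings::width(g)), c(8L, 4L))

  write_fasta(c(chr1 = "ACGT", chr1 = "TTTT"), f)
  expect_error(load_genome(f), "duplicate")

  writeLines(character(0), f)
  expect_error(load_genome(f))
})

test_that("gzip and plain FASTA load identically", {
  f <- withr::local_tempfile(fileext = ".fa")
  fz <- withr::local_tempfile(fileext = ".fa.gz")
  write_fasta(c(chr1 = "ACGTACGTAC", chr2 = "GGGCCC"), f)
  con <- gzfile(fz, "w")
  writeLines(readLines(f), con)
  close(con)
  expect_equal(as.character(load_genome(f)), as.character(load_genome(fz)))
})

gff3_lines <- function() c(
  "##gff-version 3",
  "chr1\ttest\tgene\t101\t400\t.\t+\t.\tID=G1;gene_name=GENE1;gene_biotype=protein_coding",
  "chr1\ttest\ttranscript\t101\t400\t.\t+\t.\tID=T1;Parent=G1",
  "chr1\ttest\texon\t101\t200\t.\t+\t.\tID=T1.e1;Parent=T1",
  "chr1\ttest\texon\t301\t400\t.\t+\t.\tID=T1.e2;Parent=T1",
  "chr1\ttest\tCDS\t151\t200\t.\t+\t0\tID=T1.c1;Parent=T1",
  "chr1\ttest\tCDS\t301\t350\t.\t+\t0\tID=T1.c2;Parent=T1")

test_that("gene models derive exon union, introns and UTRs", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(gff3_lines(), f)
  gm <- load_gene_models(f)
  expect_equal(gm$genes$gene_id, "G1")
  expect_equal(gm$genes$biotype, "protein_coding")
  seg <- gm$segments
  get <- function(what) seg[seg$segment == what, c("start", "end")]
  # one gene, one transcript, exons [100,200)+[300,400) -> intron [200,300)
  expect_equal(get("intron"), data.frame(start = 200L, end = 300L),
               ignore_attr = TRUE)
  expect_equal(get("exon"), data.frame(start = c(100L, 300L),
                                       end = c(200L, 400L)), ignore_attr = TRUE)
  expect_equal(get("CDS"), data.frame(start = c(150L, 300L),
                                      end = c(200L, 350L)), ignore_attr = TRUE)
  # exonic bases before the leftmost CDS base are 5'UTR (plus strand)
  expect_equal(get("5UTR"), data.frame(start = 100L, end = 150L),
               ignore_attr = TRUE)
  expect_equal(get("3UTR"), data.frame(start = 350L, end = 400L),
               ignore_attr = TRUE)
})

test_that("exon/intron partition matches a per-base occupancy oracle", {
  # two overlapping transcripts with staggered exons
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\ttest\tgene\t1\t1000\t.\t+\t.\tID=G1;gene_biotype=lncRNA",
    "chr1\ttest\ttranscript\t1\t1000\t.\t+\t.\tID=T1;Parent=G1",
    "chr1\ttest\texon\t1\t150\t.\t+\t.\tParent=T1",
    "chr1\ttest\texon\t400\t600\t.\t+\t.\tParent=T1",
    "chr1\ttest\ttranscript\t1\t1000\t.\t+\t.\tID=T2;Parent=G1",
    "chr1\ttest\texon\t100\t300\t.\t+\t.\tParent=T2",
    "chr1\ttest\texon\t550\t1000\t.\t+\t.\tParent=T2"), f)
  gm <- load_gene_models(f)
  seg <- gm$segments
  # per-base truth over the gene span (0-based)
  exonic <- rep(FALSE, 1000)
  for (iv in list(c(0, 150), c(399, 600), c(99, 300), c(549, 1000))) {
    exonic[(iv[1] + 1):iv[2]] <- TRUE
  }
  covered <- rep(NA_character_, 1000)
  for (i in seq_len(nrow(seg))) {
    if (!seg$segment[i] %in% c("exon", "intron")) next
    covered[(seg$start[i] + 1):seg$end[i]] <- seg$segment[i]
  }
  expect_false(anyNA(covered))  # exon u intron covers the span
  expect_equal(covered == "exon", exonic)  # and matches the per-base union
})

test_that("GTF and GFF3 encodings yield identical gene models", {
  f3 <- withr::local_tempfile(fileext = ".gff3")
  writeLines(gff3_lines(), f3)
  ft <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    paste0("chr1\ttest\tgene\t101\t400\t.\t+\t.\t",
           'gene_id "G1"; gene_name "GENE1"; gene_biotype "protein_coding";'),
    paste0("chr1\ttest\ttranscript\t101\t400\t.\t+\t.\t",
           'gene_id "G1"; transcript_id "T1";'),
    paste0("chr1\ttest\texon\t101\t200\t.\t+\t.\t",
           'gene_id "G1"; transcript_id "T1";'),
    paste0("chr1\ttest\texon\t301\t400\t.\t+\t.\t",
           'gene_id "G1"; transcript_id "T1";'),
    paste0("chr1\ttest\tCDS\t151\t200\t.\t+\t0\t",
           'gene_id "G1"; transcript_id "T1";'),
    paste0("chr1\ttest\tCDS\t301\t350\t.\t+\t0\t",
           'gene_id "G1"; transcript_id "T1";')), ft)
  a <- load_gene_models(f3)
  b <- load_gene_models(ft)
  expect_equal(a$genes, b$genes)
  expect_equal(a$segments, b$segments)
})

test_that("orphan features are rejected", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\ttest\tgene\t1\t100\t.\t+\t.\tID=G1",
               "chr1\ttest\ttranscript\t1\t100\t.\t+\t.\tID=T1;Parent=G9"), f)
  expect_error(load_gene_models(f), "unknown gene")
  writeLines(c("##gff-version 3",
               "chr1\ttest\tgene\t1\t100\t.\t+\t.\tID=G1",
               "chr1\ttest\ttranscript\t1\t100\t.\t+\t.\tID=T1;Parent=G1",
               "chr1\ttest\texon\t1\t100\t.\t+\t.\tID=E1"), f)
  expect_error(load_gene_models(f), "transcript")
})

test_that("promoter windows follow the TSS convention with clipping", {
  tss <- data.frame(chrom = "chr1", pos = c(1000L, 1000L, 10L),
                    strand = c("+", "-", "+"),
                    gene_id = c("G1", "G2", "G3"), stringsAsFactors = FALSE)
  pr <- derive_promoters(tss, upstream = 499L, downstream = 100L)
  r <- pr$records
  expect_equal(r$start, c(501L, 900L, 0L))
  expect_equal(r$end, c(1101L, 1500L, 111L))
  expect_equal(r$end[1] - r$start[1], 600L)
  expect_equal(r$linked_gene_id, c("G1", "G2", "G3"))

  # right-clipping against chromosome length
  pr2 <- derive_promoters(tss, 499L, 100L, seqlengths = c(chr1 = 1200L))
  expect_equal(pr2$records$end[2], 1200L)
})

test_that("tracks load from BED with optional gene links and round-trip", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200\tenh1\t0\t.\tG1",
               "chr1\t300\t400\tG2"), f)
  tr <- load_track(f, "enhancer")
  expect_equal(tr$records$linked_gene_id, c("G1", "G2"))

  writeLines("chr1\t100\t200", f)
  tr3 <- load_track(f, "regulator_peak")
  expect_true(is.na(tr3$records$linked_gene_id))

  writeLines("chr1\t100\t100\tzero", f)
  expect_error(load_track(f, "enhancer"), "line 1", class = "malformed_record")
  writeLines("chr1\tab\t200", f)
  expect_error(load_track(f, "enhancer"), "non-integer", class = "malformed_record")

  # write/reload round-trip preserves records exactly
  writeLines(c("chr1\t100\t200\tenh1\t0\t+\tG1", "chr2\t5\t50\tenh2\t0\t-\tG2"), f)
  tr <- load_track(f, "enhancer")
  f2 <- withr::local_tempfile(fileext = ".bed")
  write_track(tr, f2)
  expect_equal(load_track(f2, "enhancer")$records, tr$records)
})

test_that("function tables merge and lookups are total", {
  pf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tphenotype", "G1.5\tsyndrome A", "G1\tsyndrome A",
               "G1\tsyndrome B", "G2\tsyndrome C"), pf)
  cf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id", "G3"), cf)
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ttf_class", "G2\tco-TF"), tf)
  ef <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tliver\tbrain", "G1\t10.5\t0"), ef)
  idx <- load_function_tables(phenotypes = pf, cancer = cf, tf = tf,
                              expression = ef)
  g1 <- gene_function(idx, "G1.7")  # version suffix stripped
  expect_equal(g1$phenotypes, c("syndrome A", "syndrome B"))  # deduplicated union
  expect_false(g1$is_cancer_gene)
  expect_equal(g1$expression, c(liver = 10.5, brain = 0))
  g3 <- gene_function(idx, "G3")
  expect_true(g3$is_cancer_gene)
  expect_equal(g3$phenotypes, character(0))
  expect_equal(gene_function(idx, "G2")$tf_class, "co-TF")
  # unknown gene -> all-empty record, never an error
  unk <- gene_function(idx, "NOPE")
  expect_equal(unk$phenotypes, character(0))
  expect_false(unk$is_cancer_gene)
  expect_equal(unk$tf_class, "none")
  expect_length(unk$expression, 0L)

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tphenotype", "G1\tx"), bad)
  expect_error(load_function_tables(phenotypes = bad), "gene_id")
})
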