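# In-memory world shared by the annotator tests: one coding gene with
# CDS/UTR/intron structure, one lncRNA, an enhancer linked to a cancer gene.
make_world <- function() {
  gff <- withr::local_tempfile(fileext = ".gff3", .local_envir = parent.frame())
  writeLines(c(
    "##gff-version 3",
    "chr1\tt\tgene\t101\t700\t.\t+\t.\tID=G1;gene_name=ALPHA;gene_biotype=protein_coding",
    "chr1\tt\ttranscript\t101\t700\t.\t+\t.\tID=T1;Parent=G1",
    "chr1\tt\texon\t101\t300\t.\t+\t.\tParent=T1",
    "chr1\tt\texon\t501\t700\t.\t+\t.\tParent=T1",
    "chr1\tt\tCDS\t201\t300\t.\t+\t0\tParent=T1",
    "chr1\tt\tCDS\t501\t600\t.\t+\t0\tParent=T1",
    "chr1\tt\tgene\t2001\t2400\t.\t+\t.\tID=G2;gene_name=LINC1;gene_biotype=lncRNA",
    "chr1\tt\ttranscript\t2001\t2400\t.\t+\t.\tID=T2;Parent=G2",
    "chr1\tt\texon\t2001\t2400\t.\t+\t.\tParent=T2"), gff)
  gm <- load_gene_models(gff)

  enh <- withr::local_tempfile(fileext = ".bed", .local_envir = parent.frame())
  writeLines("chr1\t5000\t5200\tenh1\t0\t.\tG9", enh)
  pf <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(c("gene_id\tphenotype", "G1\talpha deficiency"), pf)
  cf <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(c("gene_id", "G9"), cf)
  list(gm = gm,
       tracks = list(enhancers = load_track(enh, "enhancer")),
       fidx = load_function_tables(phenotypes = pf, cancer = cf))
}

site_at <- function(start, end, chrom = "chr1") {
  data.frame(chrom = chrom, start = start, end = end, name = "s",
             strand = "+", site_sequence = "N", pam_sequence = "AGG",
             mismatches = 1L, dna_bulges = 0L, rna_bulges = 0L,
             alignment = "", is_on_target = FALSE, stringsAsFactors = FALSE)
}

test_that("segment classification follows the stated precedence", {
  w <- make_world()
  segs <- w$gm$segments[w$gm$segments$gene_id == "G1", ]
  # fully inside CDS
  expect_equal(classify_segment(site_at(210, 230), segs), "CDS")
  # inside 5'UTR only ([100,200) is exonic before the first CDS base)
  expect_equal(classify_segment(site_at(120, 140), segs), "5UTR")
  # inside 3'UTR ([600,700))
  expect_equal(classify_segment(site_at(620, 640), segs), "3UTR")
  # intron only ([300,500))
  expect_equal(classify_segment(site_at(350, 370), segs), "intron")
  # straddling exon/intron boundary -> exonic side wins (here via CDS)
  expect_equal(classify_segment(site_at(290, 310), segs), "CDS")
  # straddling 5'UTR/CDS -> CDS wins
  expect_equal(classify_segment(site_at(190, 210), segs), "CDS")
  # outside the gene span -> contract violation
  expect_error(classify_segment(site_at(5000, 5020), segs), "contract")
})

test_that("segment label equals the highest-precedence per-base class", {
  w <- make_world()
  segs <- w$gm$segments[w$gm$segments$gene_id == "G1", ]
  # per-base map over [100, 700)
  prec <- c(CDS = 1, `5UTR` = 2, `3UTR` = 3, exon = 4, intron = 5)
  base_class <- rep(NA_integer_, 700)
  for (lab in rev(names(prec))) {  # low precedence first, high overwrites
    rows <- segs[segs$segment == lab, ]
    for (i in seq_len(nrow(rows))) {
      base_class[(rows$start[i] + 1):rows$end[i]] <- prec[[lab]]
    }
  }
  set.seed(31)
  for (rep in 1:60) {
    st <- sample(100:680, 1)
    en <- st + sample(1:20, 1)
    got <- classify_segment(site_at(st, en), segs)
    expect_equal(prec[[got]], min(base_class[(st + 1):en]))
  }
})

test_that("annotate_sites composes hits, functional joins and flags", {
  w <- make_world()
  sites <- rbind(site_at(210, 230),   # CDS of disease gene G1
                 site_at(2100, 2120), # lncRNA exon
                 site_at(5050, 5070), # enhancer linked to cancer gene G9
                 site_at(9000, 9020)) # intergenic
  anns <- annotate_sites(sites, w$gm, w$tracks, w$fidx)
  expect_length(anns, 4L)

  a1 <- anns[[1]]
  expect_equal(a1$gene_hits$gene_id, "G1")
  expect_equal(a1$gene_hits$segment, "CDS")
  expect_true(a1$inside_coding_transcribed_region)
  expect_equal(a1$functional[["G1"]]$phenotypes, "alpha deficiency")

  a2 <- anns[[2]]
  expect_equal(a2$gene_hits$biotype, "lncRNA")
  expect_false(a2$inside_coding_transcribed_region)

  a3 <- anns[[3]]
  expect_equal(nrow(a3$gene_hits), 0L)
  expect_equal(a3$enhancer_hits$linked_gene_id, "G9")
  expect_true(a3$functional[["G9"]]$is_cancer_gene)

  a4 <- anns[[4]]
  expect_equal(nrow(a4$gene_hits), 0L)
  expect_equal(nrow(a4$enhancer_hits), 0L)
  expect_false(a4$inside_coding_transcribed_region)
  expect_length(a4$functional, 0L)
})

test_that("annotation is order-preserving, conserving and deterministic", {
  w <- make_world()
  set.seed(41)
  starts <- sample(0:8000, 25)
  sites <- do.call(rbind, lapply(starts, function(s) site_at(s, s + 20)))
  a <- annotate_sites(sites, w$gm, w$tracks, w$fidx)
  b <- annotate_sites(sites, w$gm, w$tracks, w$fidx)
  expect_length(a, nrow(sites))
  for (k in seq_along(a)) {
    expect_equal(a[[k]]$site$start, sites$start[k])
    expect_equal(a[[k]], b[[k]])
  }
})

test_that("regulator peaks are flagged when inside a promoter", {
  pk <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t140\tpeakA", "chr1\t900\t940\tpeakB"), pk)
  pr <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t50\t200\tprom1\t0\t+\tG1", pr)
  tracks <- list(peaks = load_track(pk, "regulator_peak"),
                 promoters = load_track(pr, "promoter"))
  anns <- annotate_sites(rbind(site_at(110, 130), site_at(910, 930)),
                         tracks = tracks)
  expect_true(anns[[1]]$regulator_peak_hits$in_promoter)
  expect_false(anns[[2]]$regulator_peak_hits$in_promoter)
})
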