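test_that("parse_guide normalizes and validates", {
  g <- parse_guide("CACCCGATCCACTGGGGAGC", "NGG")
  expect_s3_class(g, "guide_rna")
  expect_equal(nchar(g$protospacer), 20L)

  low <- parse_guide(strrep("acgt", 5))
  expect_equal(low$protospacer, strrep("ACGT", 5))

  expect_error(parse_guide("ACGUACGUACGU"), class = "invalid_guide")
  expect_error(parse_guide("   "), class = "invalid_guide")
  expect_error(parse_guide("ACGT", pam_pattern = "QGG"), class = "invalid_guide")
})

test_that("read_guides handles plain and two-column files", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# comment", "ACGTACGTACGTACGTACGT", "g2\tTTTTACGTACGTACGTACGT"), f)
  gs <- read_guides(f)
  expect_length(gs, 2L)
  expect_equal(gs[[2]]$name, "g2")
  expect_equal(gs[[2]]$protospacer, "TTTTACGTACGTACGTACGT")
})

test_that("perfect self-match and PAM gating behave as specified", {
  g <- parse_guide("CACCCGATCCACTGGGGAGC")
  genome <- c(chr1 = paste0("TTTT", g$protospacer, "AGG", "TTTTT"))
  s <- find_offtargets(genome, g, search_params(max_mismatches = 4))
  expect_equal(nrow(s), 1L)
  expect_equal(s$start, 4L)
  expect_equal(s$end, 24L)
  expect_equal(s$strand, "+")
  expect_equal(s$mismatches, 0L)
  expect_true(s$is_on_target)
  expect_equal(s$pam_sequence, "AGG")

  # no NGG anywhere near the protospacer on either strand -> PAM gate closes
  gate <- parse_guide("CACCCGATCCACTGGGGAGC", pam_pattern = "TTT")
  genome2 <- c(chr1 = paste0(g$protospacer, "AGG"))
  expect_equal(nrow(find_offtargets(genome2, gate, search_params(4))), 0L)
})

test_that("guide longer than every sequence yields an empty result", {
  g <- parse_guide(strrep("ACGT", 5))
  expect_equal(nrow(find_offtargets(c(chr1 = "ACGTACGT"), g, search_params(4))), 0L)
})

test_that("ambiguous genome bases never count as matches", {
  g <- parse_guide("ACGTACGTACGTACGTACGT")
  # N inside the protospacer is a mismatch
  genome <- c(chr1 = paste0("ACGTACGTACGTACGTACGN", "AGG"))
  s <- find_offtargets(genome, g, search_params(1, both_strands = FALSE))
  expect_equal(s$mismatches, 1L)
  # N inside the PAM blocks the site even though the pattern letter is N
  genome2 <- c(chr1 = paste0(g$protospacer, "NGG"))
  expect_equal(nrow(find_offtargets(genome2, g, search_params(4,
    both_strands = FALSE))), 0L)
})

test_that("search equals the brute-force oracle on random genomes with planted sites", {
  set.seed(101)
  g <- parse_guide(random_guide())
  gstr <- random_genome(5000)
  for (k in 0:3) {
    gstr[1] <- plant_site(gstr[[1]], mutate_seq(g$protospacer, k),
                          sample(4500, 1), sample(c("+", "-"), 1))
  }
  got <- find_offtargets(gstr, g, search_params(3))
  exp <- oracle_scan(gstr, g$protospacer, "NGG", 3)
  expect_setequal(site_key(got), site_key(exp))
})

test_that("reverse-complementing the genome mirrors every site", {
  set.seed(7)
  g <- parse_guide(random_guide())
  gstr <- random_genome(3000)
  gstr[1] <- plant_site(gstr[[1]], mutate_seq(g$protospacer, 2), 1500, "+")
  gstr[1] <- plant_site(gstr[[1]], mutate_seq(g$protospacer, 1), 2000, "-")
  n <- nchar(gstr[[1]])
  rc <- stats::setNames(oracle_revcomp(gstr[[1]]), "chr1")
  a <- find_offtargets(gstr, g, search_params(3))
  b <- find_offtargets(rc, g, search_params(3))
  mirrored <- data.frame(chrom = a$chrom, start = n - a$end, end = n - a$start,
                         strand = ifelse(a$strand == "+", "-", "+"),
                         mismatches = a$mismatches)
  expect_setequal(site_key(mirrored), site_key(b))
})

test_that("raising max_mismatches never removes a reported site", {
  set.seed(11)
  g <- parse_guide(random_guide())
  gstr <- random_genome(4000)
  for (k in c(0, 1, 2, 3, 4)) {
    gstr[1] <- plant_site(gstr[[1]], mutate_seq(g$protospacer, k),
                          300 + k * 700, "+")
  }
  prev <- character(0)
  for (mm in 0:4) {
    cur <- site_key(find_offtargets(gstr, g, search_params(mm)))
    expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("a verbatim protospacer+PAM occurrence is always reported with 0 mismatches", {
  set.seed(19)
  for (rep in 1:5) {
    g <- parse_guide(random_guide())
    gstr <- random_genome(2000)
    p <- sample(1500, 1)
    strand <- sample(c("+", "-"), 1)
    gstr[1] <- plant_site(gstr[[1]], g$protospacer, p, strand)
    s <- find_offtargets(gstr, g, search_params(0))
    expect_true(any(s$mismatches == 0L & s$strand == strand))
  }
})

test_that("dedupe_sites keeps the minimal alignment and sorts stably", {
  s <- rbind(
    data.frame(chrom = "chr2", start = 10L, end = 30L, name = "a", strand = "+",
               site_sequence = "x", pam_sequence = "AGG", mismatches = 4L,
               dna_bulges = 0L, rna_bulges = 0L, alignment = "",
               is_on_target = FALSE, stringsAsFactors = FALSE),
    data.frame(chrom = "chr2", start = 10L, end = 30L, name = "b", strand = "+",
               site_sequence = "y", pam_sequence = "AGG", mismatches = 2L,
               dna_bulges = 0L, rna_bulges = 0L, alignment = "",
               is_on_target = FALSE, stringsAsFactors = FALSE),
    data.frame(chrom = "chr1", start = 50L, end = 70L, name = "c", strand = "-",
               site_sequence = "z", pam_sequence = "AGG", mismatches = 3L,
               dna_bulges = 0L, rna_bulges = 0L, alignment = "",
               is_on_target = FALSE, stringsAsFactors = FALSE))
  d <- dedupe_sites(s)
  expect_equal(nrow(d), 2L)
  expect_equal(d$chrom, c("chr1", "chr2"))
  expect_equal(d$mismatches[d$chrom == "chr2"], 2L)

  # random records with planted duplicates match a set-based grouping oracle
  set.seed(23)
  n <- 50
  base <- data.frame(
    chrom = sample(c("chr1", "chr2"), n, TRUE),
    start = sample(10L, n, TRUE) * 10L, strand = sample(c("+", "-"), n, TRUE),
    mismatches = sample(0:4, n, TRUE), stringsAsFactors = FALSE)
  base$end <- base$start + 20L
  base$name <- sprintf("s%d", seq_len(n))
  base$site_sequence <- "x"; base$pam_sequence <- "AGG"
  base$dna_bulges <- 0L; base$rna_bulges <- 0L
  base$alignment <- ""; base$is_on_target <- FALSE
  d <- dedupe_sites(base)
  key <- paste(base$chrom, base$start, base$end, base$strand)
  oracle_mm <- tapply(base$mismatches, key, min)
  expect_equal(nrow(d), length(unique(key)))
  expect_equal(as.integer(oracle_mm[paste(d$chrom, d$start, d$end, d$strand)]),
               d$mismatches)
})

test_that("read_sites_bed parses BED6 and reports malformed lines", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t120\tsite1\t0\t+",
               "chr2\t5\t25\tsite2\t2\t-\t2",
               "chr1\t40\t60\tsite3\t.\t+"), f)
  s <- read_sites_bed(f)
  expect_equal(nrow(s), 3L)
  expect_equal(s$start, c(100L, 5L, 40L))
  expect_equal(s$mismatches, c(NA_integer_, 2L, NA_integer_))
  expect_equal(s$name, c("site1", "site2", "site3"))

  writeLines("chr1\t120\t100\tbad\t0\t+", f)
  expect_error(read_sites_bed(f), "line 1", class = "malformed_record")
  writeLines(c("chr1\t1\t30\tok\t0\t+", "chr1\tx\t30"), f)
  expect_error(read_sites_bed(f), "line 2", class = "malformed_record")
  writeLines("chr1\t100", f)
  expect_error(read_sites_bed(f), "fewer than 3", class = "malformed_record")

  writeLines("chr1\t100\t120", f)
  expect_warning(s <- read_sites_bed(f), "strand")
  expect_equal(s$strand, "+")
})

test_that("site tables round-trip through the extended TSV", {
  g <- parse_guide("CACCCGATCCACTGGGGAGC")
  genome <- c(chr1 = paste0("TT", g$protospacer, "AGGTTT"))
  s <- find_offtargets(genome, g, search_params(2))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_sites(s, tsv_path = tsv)
  expect_equal(read_sites_tsv(tsv), s)
})
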