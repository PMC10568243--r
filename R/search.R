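# Off-target site discovery: PAM-gated mismatch scan with optional
# bulge-tolerant gapped alignment. Coordinates are 0-based half-open and span
# the protospacer only; the PAM is stored separately.

empty_sites <- function() {
  data.frame(
    chrom = character(), start = integer(), end = integer(),
    name = character(), strand = character(),
    site_sequence = character(), pam_sequence = character(),
    mismatches = integer(), dna_bulges = integer(), rna_bulges = integer(),
    alignment = character(), is_on_target = logical(),
    stringsAsFactors = FALSE)
}

#' Find candidate off-target sites of a guide in a genome
#'
#' Scans every position of every sequence (both strands by default) for
#' protospacer-like matches adjacent to a PAM. Mismatches are counted over the
#' protospacer only; the PAM is matched by IUPAC expansion and never
#' contributes mismatches. Ambiguous genome bases (`N`) never count as
#' matches, neither in the protospacer nor in the PAM. When bulge budgets are
#' non-zero, PAM-anchored windows of every admissible length are aligned with
#' [align_gapped()].
#'
#' Minus-strand sites are reported in forward-genome coordinates;
#' `site_sequence` is the sequence as read 5'->3' on the targeted strand
#' (i.e. the reverse complement of the forward slice).
#'
#' @param genome A `DNAStringSet` (see [load_genome()]) or named character
#'   vector of chromosome sequences.
#' @param guide A [parse_guide()] object.
#' @param params A [search_params()] object.
#' @return A site table (one row per locus) with columns `chrom`, `start`,
#'   `end` (0-based half-open, protospacer span), `name`, `strand`,
#'   `site_sequence`, `pam_sequence`, `mismatches`, `dna_bulges`,
#'   `rna_bulges`, `alignment` (`=` match, `X` mismatch, `D` DNA bulge,
#'   `R` RNA bulge) and `is_on_target`, deduplicated by locus (keeping the
#'   fewest-bulge, then fewest-mismatch alignment) and sorted by
#'   (chrom, start).
#' @export
find_offtargets <- function(genome, guide, params = search_params()) {
  stopifnot(inherits(guide, "guide_rna"), inherits(params, "search_params"))
  seqs <- as_genome_chars(genome)
  if (length(seqs) == 0L) stop("genome is empty")
  rows <- list()
  strands <- if (params$both_strands) c("+", "-") else "+"
  for (chrom in names(seqs)) {
    fwd <- seqs[[chrom]]
    n <- nchar(fwd)
    for (strand in strands) {
      s <- if (strand == "+") fwd else revcomp(fwd)
      hits <- scan_strand(s, guide, params)
      if (is.null(hits) || nrow(hits) == 0L) next
      # hits$pos / hits$width are 1-based on the scanned strand
      if (strand == "+") {
        start0 <- hits$pos - 1L
        end0 <- start0 + hits$width
      } else {
        end0 <- n - (hits$pos - 1L)
        start0 <- end0 - hits$width
      }
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = chrom, start = start0, end = end0, name = NA_character_,
        strand = strand, site_sequence = hits$site_sequence,
        pam_sequence = hits$pam_sequence, mismatches = hits$mismatches,
        dna_bulges = hits$dna_bulges, rna_bulges = hits$rna_bulges,
        alignment = hits$alignment,
        is_on_target = hits$mismatches == 0L & hits$dna_bulges == 0L &
          hits$rna_bulges == 0L,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) return(empty_sites())
  sites <- do.call(rbind, rows)
  sites <- dedupe_sites(sites)
  sites$name <- sprintf("site_%d", seq_len(nrow(sites)))
  rownames(sites) <- NULL
  sites
}

# Scan one strand (sequence given 5'->3' as scanned). Returns 1-based
# positions of the protospacer span on the scanned strand.
scan_strand <- function(seq, guide, params) {
  if (params$max_dna_bulges == 0L && params$max_rna_bulges == 0L) {
    scan_mismatch_only(seq, guide, params$max_mismatches)
  } else {
    scan_bulged(seq, guide, params)
  }
}

scan_mismatch_only <- function(seq, guide, max_mm) {
  gi <- utf8ToInt(guide$protospacer)
  L <- length(gi)
  pam <- chars_of(guide$pam_pattern)
  P <- length(pam)
  si <- utf8ToInt(seq)
  n <- length(si)
  span <- L + P
  if (n < span) return(NULL)
  npos <- n - span + 1L
  off <- if (guide$pam_side == "three_prime") 0L else P   # protospacer offset in span
  poff <- if (guide$pam_side == "three_prime") L else 0L  # PAM offset in span
  mm <- integer(npos)
  for (i in seq_len(L)) {
    mm <- mm + (si[(off + i):(off + i + npos - 1L)] != gi[i])
  }
  ok <- rep(TRUE, npos)
  pam_allowed <- lapply(pam, function(cc) utf8ToInt(paste(IUPAC_MAP[[cc]], collapse = "")))
  for (j in seq_len(P)) {
    ok <- ok & (si[(poff + j):(poff + j + npos - 1L)] %in% pam_allowed[[j]])
  }
  keep <- which(ok & mm <= max_mm)
  if (length(keep) == 0L) return(NULL)
  proto_pos <- keep + off
  pam_pos <- keep + poff
  site_seq <- substring(seq, proto_pos, proto_pos + L - 1L)
  gch <- chars_of(guide$protospacer)
  aln <- vapply(site_seq, function(ss) {
    paste(ifelse(chars_of(ss) == gch, "=", "X"), collapse = "")
  }, character(1), USE.NAMES = FALSE)
  data.frame(
    pos = proto_pos, width = L, site_sequence = site_seq,
    pam_sequence = substring(seq, pam_pos, pam_pos + P - 1L),
    mismatches = mm[keep], dna_bulges = 0L, rna_bulges = 0L,
    alignment = aln, stringsAsFactors = FALSE)
}

# General search with bulges: anchor on PAM occurrences, then align every
# admissible window length next to the PAM.
scan_bulged <- function(seq, guide, params) {
  pam <- chars_of(guide$pam_pattern)
  P <- length(pam)
  si <- utf8ToInt(seq)
  n <- length(si)
  if (n < P) return(NULL)
  npam <- n - P + 1L
  ok <- rep(TRUE, npam)
  pam_allowed <- lapply(pam, function(cc) utf8ToInt(paste(IUPAC_MAP[[cc]], collapse = "")))
  for (j in seq_len(P)) {
    ok <- ok & (si[j:(j + npam - 1L)] %in% pam_allowed[[j]])
  }
  pam_starts <- which(ok)
  L <- nchar(guide$protospacer)
  widths <- max(1L, L - params$max_rna_bulges):(L + params$max_dna_bulges)
  out <- list()
  for (pp in pam_starts) {
    for (W in widths) {
      if (guide$pam_side == "three_prime") {
        wstart <- pp - W
        if (wstart < 1L) next
      } else {
        wstart <- pp + P
        if (wstart + W - 1L > n) next
      }
      window <- substr(seq, wstart, wstart + W - 1L)
      aln <- align_gapped(guide$protospacer, window,
                          params$max_mismatches,
                          params$max_dna_bulges, params$max_rna_bulges)
      if (is.null(aln)) next
      out[[length(out) + 1L]] <- data.frame(
        pos = wstart, width = W, site_sequence = window,
        pam_sequence = substr(seq, pp, pp + P - 1L),
        mismatches = aln$mismatches, dna_bulges = aln$dna_bulges,
        rna_bulges = aln$rna_bulges, alignment = aln$alignment,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) return(NULL)
  do.call(rbind, out)
}

#' Globally align a guide against a genomic window allowing bulges
#'
#' Exact dynamic program over (guide position, window position, DNA bulges
#' used, RNA bulges used) minimizing mismatches for each bulge combination,
#' then picking the minimum under the lexicographic cost (total bulges, then
#' mismatches). A DNA bulge is an extra genome base (gap in the guide); an
#' RNA bulge is an extra guide base (gap in the window). Ties between
#' equal-cost alignments are broken deterministically (matches/mismatches
#' placed before bulges at each column).
#'
#' @param guide_seq Guide protospacer (A/C/G/T).
#' @param window Genomic window sequence on the targeted strand.
#' @param max_mm,max_dna_bulge,max_rna_bulge Non-negative budgets.
#' @return `NULL` when no alignment fits all budgets, otherwise a list with
#'   `mismatches`, `dna_bulges`, `rna_bulges` and `alignment` (a column code
#'   string over `=`, `X`, `D`, `R`).
#' @export
align_gapped <- function(guide_seq, window, max_mm, max_dna_bulge, max_rna_bulge) {
  stopifnot(max_mm >= 0, max_dna_bulge >= 0, max_rna_bulge >= 0)
  g <- chars_of(toupper(guide_seq))
  w <- chars_of(toupper(window))
  G <- length(g); W <- length(w)
  # global alignment forces dna_bulges - rna_bulges == W - G
  diff <- W - G
  if (diff > max_dna_bulge || -diff > max_rna_bulge) return(NULL)
  INF <- .Machine$integer.max %/% 4L
  DB <- max_dna_bulge + 1L; RB <- max_rna_bulge + 1L
  M <- array(INF, dim = c(G + 1L, W + 1L, DB, RB))
  FROM <- array(0L, dim = c(G + 1L, W + 1L, DB, RB))  # 1 diag, 2 dna, 3 rna
  M[1L, 1L, 1L, 1L] <- 0L
  for (i in 0:G) for (j in 0:W) for (db in seq_len(DB)) for (rb in seq_len(RB)) {
    v <- M[i + 1L, j + 1L, db, rb]
    if (v >= INF) next
    if (i < G && j < W) {
      cost <- v + as.integer(g[i + 1L] != w[j + 1L] || !(w[j + 1L] %in% DNA_BASES))
      if (cost <= max_mm && cost < M[i + 2L, j + 2L, db, rb]) {
        M[i + 2L, j + 2L, db, rb] <- cost
        FROM[i + 2L, j + 2L, db, rb] <- 1L
      }
    }
    if (j < W && db < DB && v < M[i + 1L, j + 2L, db + 1L, rb]) {
      M[i + 1L, j + 2L, db + 1L, rb] <- v
      FROM[i + 1L, j + 2L, db + 1L, rb] <- 2L
    }
    if (i < G && rb < RB && v < M[i + 2L, j + 1L, db, rb + 1L]) {
      M[i + 2L, j + 1L, db, rb + 1L] <- v
      FROM[i + 2L, j + 1L, db, rb + 1L] <- 3L
    }
  }
  best <- NULL
  for (db in seq_len(DB)) for (rb in seq_len(RB)) {
    mm <- M[G + 1L, W + 1L, db, rb]
    if (mm >= INF || mm > max_mm) next
    cand <- c(bulges = (db - 1L) + (rb - 1L), mm = mm, db = db, rb = rb)
    if (is.null(best) || cand[["bulges"]] < best[["bulges"]] ||
        (cand[["bulges"]] == best[["bulges"]] && cand[["mm"]] < best[["mm"]])) {
      best <- cand
    }
  }
  if (is.null(best)) return(NULL)
  # traceback
  i <- G; j <- W; db <- best[["db"]]; rb <- best[["rb"]]
  cols <- character(0)
  while (i > 0L || j > 0L) {
    mv <- FROM[i + 1L, j + 1L, db, rb]
    if (mv == 1L) {
      cols <- c(if (g[i] == w[j]) "=" else "X", cols)
      i <- i - 1L; j <- j - 1L
    } else if (mv == 2L) {
      cols <- c("D", cols); j <- j - 1L; db <- db - 1L
    } else if (mv == 3L) {
      cols <- c("R", cols); i <- i - 1L; rb <- rb - 1L
    } else {
      stop("internal error: broken alignment traceback")
    }
  }
  list(mismatches = as.integer(best[["mm"]]),
       dna_bulges = as.integer(best[["db"]] - 1L),
       rna_bulges = as.integer(best[["rb"]] - 1L),
       alignment = paste(cols, collapse = ""))
}

#' Deduplicate a site table by genomic locus
#'
#' Sites sharing (chrom, start, end, strand) are collapsed to the record with
#' the fewest total bulges, then fewest mismatches (`NA` mismatch counts sort
#' last). The result is sorted by (chrom, start, end, strand).
#'
#' @param sites A site table as returned by [find_offtargets()] or
#'   [read_sites_bed()].
#' @return The deduplicated, sorted site table.
#' @export
dedupe_sites <- function(sites) {
  if (nrow(sites) == 0L) return(sites)
  bulges <- (sites$dna_bulges %||% 0L) + (sites$rna_bulges %||% 0L)
  bulges[is.na(bulges)] <- 0L
  mm <- sites$mismatches
  mm_rank <- ifelse(is.na(mm), Inf, mm)
  ord <- order(sites$chrom, sites$start, sites$end, sites$strand, bulges, mm_rank)
  sites <- sites[ord, , drop = FALSE]
  key <- paste(sites$chrom, sites$start, sites$end, sites$strand, sep = "\r")
  sites <- sites[!duplicated(key), , drop = FALSE]
  rownames(sites) <- NULL
  sites
}

#' Read off-target sites from a BED file
#'
#' Parses BED3-BED6 records as 0-based half-open intervals spanning the
#' protospacer. A missing strand column defaults to `+` (with a warning); an
#' optional 7th column supplies the mismatch count, otherwise mismatches are
#' recorded as unknown (`NA`).
#'
#' @param path Path to the BED file.
#' @return A site table (see [find_offtargets()]); sequence, PAM and
#'   alignment columns are `NA` until filled from a genome.
#' @export
read_sites_bed <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!grepl("^(#|track|browser)", lines)]
  if (length(lines) == 0L) return(empty_sites())
  rows <- vector("list", length(lines))
  warned_strand <- FALSE
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L) {
      stop_crisprisk(sprintf("malformed BED record at line %d: fewer than 3 columns", i),
                     "malformed_record")
    }
    start <- suppressWarnings(as.integer(f[[2L]]))
    end <- suppressWarnings(as.integer(f[[3L]]))
    if (is.na(start) || is.na(end)) {
      stop_crisprisk(sprintf("malformed BED record at line %d: non-integer coordinates", i),
                     "malformed_record")
    }
    if (start >= end) {
      stop_crisprisk(sprintf("malformed BED record at line %d: start >= end", i),
                     "malformed_record")
    }
    strand <- if (length(f) >= 6L && f[[6L]] %in% c("+", "-")) {
      f[[6L]]
    } else {
      if (!warned_strand) {
        warning(sprintf("BED line %d has no strand column; defaulting to '+'", i))
        warned_strand <- TRUE
      }
      "+"
    }
    mm <- if (length(f) >= 7L) suppressWarnings(as.integer(f[[7L]])) else NA_integer_
    rows[[i]] <- data.frame(
      chrom = f[[1L]], start = start, end = end,
      name = if (length(f) >= 4L && nzchar(f[[4L]])) f[[4L]] else sprintf("site_%d", i),
      strand = strand, site_sequence = NA_character_, pam_sequence = NA_character_,
      mismatches = mm, dna_bulges = 0L, rna_bulges = 0L,
      alignment = NA_character_,
      is_on_target = !is.na(mm) && mm == 0L,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read off-target sites from the extended TSV written by [write_sites()]
#'
#' The extended TSV preserves sequences, PAMs, mismatch/bulge counts and
#' alignment strings, so annotating a previously exported site list
#' reproduces a direct search-plus-annotate run exactly.
#'
#' @param path Path to the TSV.
#' @return A site table (see [find_offtargets()]).
#' @export
read_sites_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(
                            chrom = "character", name = "character",
                            strand = "character", site_sequence = "character",
                            pam_sequence = "character", alignment = "character"))
  need <- names(empty_sites())
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L) {
    stop_crisprisk(sprintf("site TSV is missing column(s): %s",
                           paste(missing, collapse = ", ")), "malformed_record")
  }
  df <- df[, need]
  df$start <- as.integer(df$start); df$end <- as.integer(df$end)
  df$mismatches <- as.integer(df$mismatches)
  df$dna_bulges <- as.integer(df$dna_bulges)
  df$rna_bulges <- as.integer(df$rna_bulges)
  df$is_on_target <- as.logical(df$is_on_target)
  df
}

#' Write a site table to BED and extended TSV
#'
#' @param sites A site table.
#' @param bed_path Output BED6 path (score column carries the mismatch
#'   count, `.` when unknown), or `NULL` to skip.
#' @param tsv_path Output extended TSV path (all site columns), or `NULL`.
#' @return Invisibly, the paths written.
#' @export
write_sites <- function(sites, bed_path = NULL, tsv_path = NULL) {
  if (!is.null(bed_path)) {
    score <- ifelse(is.na(sites$mismatches), ".", as.character(sites$mismatches))
    lines <- sprintf("%s\t%d\t%d\t%s\t%s\t%s", sites$chrom, sites$start,
                     sites$end, sites$name, score, sites$strand)
    writeLines(lines, bed_path)
  }
  if (!is.null(tsv_path)) {
    utils::write.table(sites, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
  }
  invisible(c(bed = bed_path, tsv = tsv_path))
}

# Fill site_sequence / pam_sequence / alignment for externally supplied sites
# from the genome (strand-aware). PAM length taken from `pam_length` on the
# 3' side when guide is unknown.
fill_site_sequences <- function(sites, genome, guide = NULL, pam_length = 3L) {
  seqs <- as_genome_chars(genome)
  if (nrow(sites) == 0L) return(sites)
  for (k in seq_len(nrow(sites))) {
    if (!is.na(sites$site_sequence[k])) next
    chrom <- sites$chrom[k]
    if (!chrom %in% names(seqs)) next
    s <- seqs[[chrom]]; n <- nchar(s)
    st <- sites$start[k]; en <- sites$end[k]
    if (st < 0L || en > n) next
    fwd <- substr(s, st + 1L, en)
    if (sites$strand[k] == "+") {
      sites$site_sequence[k] <- fwd
      pam_end <- min(n, en + pam_length)
      if (pam_end > en) sites$pam_sequence[k] <- substr(s, en + 1L, pam_end)
    } else {
      sites$site_sequence[k] <- revcomp(fwd)
      pam_st <- max(0L, st - pam_length)
      if (pam_st < st) sites$pam_sequence[k] <- revcomp(substr(s, pam_st + 1L, st))
    }
    if (!is.null(guide) &&
        nchar(sites$site_sequence[k]) == nchar(guide$protospacer)) {
      gch <- chars_of(guide$protospacer)
      sch <- chars_of(sites$site_sequence[k])
      sites$alignment[k] <- paste(ifelse(gch == sch, "=", "X"), collapse = "")
      if (is.na(sites$mismatches[k])) {
        sites$mismatches[k] <- sum(gch != sch)
        sites$is_on_target[k] <- sites$mismatches[k] == 0L
      }
    }
  }
  sites
}
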