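# Independent brute-force oracles the implementation is held against.
# These deliberately use a different computational route (regex PAM
# matching, per-window character comparison, recursive enumeration,
# all-pairs interval arithmetic) from the package internals.

ORACLE_IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

oracle_revcomp <- function(x) {
  paste(rev(chartr("ACGTN", "TGCAN", strsplit(x, "")[[1]])), collapse = "")
}

# Exhaustive per-position protospacer+PAM scan on both strands.
# Returns a data frame keyed like find_offtargets (0-based half-open,
# protospacer span only).
oracle_scan <- function(genome, guide_seq, pam = "NGG", max_mm = 3,
                        both_strands = TRUE) {
  L <- nchar(guide_seq)
  P <- nchar(pam)
  gch <- strsplit(guide_seq, "")[[1]]
  pam_re <- paste0("^", paste(vapply(strsplit(pam, "")[[1]], function(cc) {
    paste0("[", paste(ORACLE_IUPAC[[cc]], collapse = ""), "]")
  }, character(1)), collapse = ""), "$")
  rows <- list()
  for (chrom in names(genome)) {
    fwd <- genome[[chrom]]
    n <- nchar(fwd)
    if (n < L + P) next
    for (strand in if (both_strands) c("+", "-") else "+") {
      s <- if (strand == "+") fwd else oracle_revcomp(fwd)
      starts <- seq_len(n - L - P + 1L)
      pams <- substring(s, starts + L, starts + L + P - 1L)
      cand <- starts[grepl(pam_re, pams)]
      for (p in cand) {
        w <- strsplit(substr(s, p, p + L - 1L), "")[[1]]
        mm <- sum(w != gch)
        if (mm > max_mm) next
        if (strand == "+") {
          st <- p - 1L
        } else {
          st <- n - (p - 1L) - L
        }
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = chrom, start = st, end = st + L, strand = strand,
          mismatches = mm, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(chrom = character(), start = integer(), end = integer(),
                      strand = character(), mismatches = integer())
  }
  out[order(out$chrom, out$start, out$end, out$strand), , drop = FALSE]
}

site_key <- function(df) {
  paste(df$chrom, df$start, df$end, df$strand, df$mismatches, sep = ":")
}

# Exhaustive gapped-alignment enumeration: tries every interleaving of
# match/mismatch columns, guide gaps and window gaps within the budgets and
# returns the minimal (total bulges, mismatches) cost, or NULL.
oracle_align <- function(guide_seq, window, max_mm, max_db, max_rb) {
  g <- strsplit(toupper(guide_seq), "")[[1]]
  w <- strsplit(toupper(window), "")[[1]]
  best <- NULL
  rec <- function(i, j, mm, db, rb) {
    if (mm > max_mm || db > max_db || rb > max_rb) return()
    if (i > length(g) && j > length(w)) {
      cand <- c(bulges = db + rb, mm = mm)
      if (is.null(best) || cand[1] < best[1] ||
          (cand[1] == best[1] && cand[2] < best[2])) {
        best <<- cand
      }
      return()
    }
    if (i <= length(g) && j <= length(w)) {
      rec(i + 1, j + 1, mm + (g[i] != w[j] || !(w[j] %in% c("A", "C", "G", "T"))),
          db, rb)
    }
    if (j <= length(w)) rec(i, j + 1, mm, db + 1, rb)  # extra genome base
    if (i <= length(g)) rec(i + 1, j, mm, db, rb + 1)  # extra guide base
  }
  rec(1, 1, 0, 0, 0)
  best
}

# Naive all-pairs overlap oracle over 0-based half-open intervals.
oracle_intersect <- function(query, subject, min_overlap = 1L) {
  rows <- list()
  for (qi in seq_len(nrow(query))) for (si in seq_len(nrow(subject))) {
    if (query$chrom[qi] != subject$chrom[si]) next
    ov <- min(query$end[qi], subject$end[si]) -
      max(query$start[qi], subject$start[si])
    if (ov >= min_overlap) {
      rows[[length(rows) + 1L]] <- data.frame(
        query_idx = qi, subject_idx = si, overlap_bp = ov)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(query_idx = integer(), subject_idx = integer(),
                      overlap_bp = integer())
  }
  out[order(out$query_idx, out$subject_idx), , drop = FALSE]
}

# Vectorized variant for larger instances (outer product on one chromosome
# batch at a time).
oracle_intersect_fast <- function(query, subject, min_overlap = 1L) {
  rows <- list()
  for (ch in unique(query$chrom)) {
    qi <- which(query$chrom == ch)
    si <- which(subject$chrom == ch)
    if (length(qi) == 0L || length(si) == 0L) next
    ov <- pmin(outer(query$end[qi], subject$end[si], pmin) -
                 outer(query$start[qi], subject$start[si], pmax), Inf)
    hit <- which(ov >= min_overlap, arr.ind = TRUE)
    if (nrow(hit) == 0L) next
    rows[[length(rows) + 1L]] <- data.frame(
      query_idx = qi[hit[, 1]], subject_idx = si[hit[, 2]],
      overlap_bp = as.integer(ov[hit]))
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(query_idx = integer(), subject_idx = integer(),
                      overlap_bp = integer())
  }
  out <- out[order(out$query_idx, out$subject_idx), , drop = FALSE]
  rownames(out) <- NULL
  out
}

random_genome <- function(n, chrom = "chr1") {
  stats::setNames(paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                        collapse = ""), chrom)
}

random_guide <- function(L = 20) {
  paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
}

# Mutate k random positions of a protospacer.
mutate_seq <- function(seq, k) {
  ch <- strsplit(seq, "")[[1]]
  if (k > 0) {
    pos <- sample.int(length(ch), k)
    for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  }
  paste(ch, collapse = "")
}

# Plant a protospacer+AGG (forward or reverse) at 1-based position p of a
# genome string; returns the modified string.
plant_site <- function(genome_str, site_seq, p, strand = "+") {
  full <- if (strand == "+") paste0(site_seq, "AGG") else
    oracle_revcomp(paste0(site_seq, "AGG"))
  paste0(substr(genome_str, 1, p - 1), full,
         substr(genome_str, p + nchar(full), nchar(genome_str)))
}

random_intervals <- function(n, max_pos = 5000, max_len = 120,
                             chroms = c("chr1", "chr2")) {
  start <- sample.int(max_pos, n, replace = TRUE) - 1L
  len <- sample.int(max_len, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start, end = start + len,
             name = sprintf("iv%d", seq_len(n)), stringsAsFactors = FALSE)
}
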