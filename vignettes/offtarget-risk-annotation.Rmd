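---
title: "Off-target discovery and layered risk annotation with crisprisk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Off-target discovery and layered risk annotation with crisprisk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crisprisk)
```

## The problem

A CRISPR-Cas9 nuclease directed by a 20-nt guide RNA cleaves not only its
intended target but also genomic loci that resemble the protospacer and lie
next to a protospacer-adjacent motif (PAM, `NGG` for SpCas9). Whether an
off-target cut matters depends less on how *similar* the site is to the
guide than on *what it lands in*: an exon of a haploinsufficient disease
gene, the promoter of an oncogene, an intron, or bare intergenic sequence
are very different outcomes. `crisprisk` therefore couples a sequence-level
off-target search with layered genomic and functional annotation and
distills each site's evidence into a single rule-based risk label.

## Off-target search

`find_offtargets()` scans every position of every chromosome, on both
strands by default. A candidate must have a PAM-matching neighbour
(IUPAC-expanded) and at most `max_mismatches` mismatches over the
protospacer; PAM-proximal and PAM-distal mismatches are weighted equally
and **PAM bases never count toward the mismatch budget**, which matches the
convention of the established search tools in this space. Coordinates are
0-based half-open over the protospacer only, so site tables round-trip
through BED unchanged; minus-strand sites are reported in forward-genome
coordinates with `site_sequence` read 5'→3' on the targeted strand.

Two deliberate conservatisms:

* Ambiguous genome bases (`N`) never match anything — neither a protospacer
  position nor a PAM letter, even the pattern letter `N`. Assembly gaps
  therefore cannot produce spurious hits.
* Duplicate loci (the same `(chrom, start, end, strand)` reached through
  different alignments) keep the alignment with the fewest total bulges,
  then the fewest mismatches.

Bulge-tolerant search is off by default (`max_dna_bulges = 0`,
`max_rna_bulges = 0`), reflecting the common mismatch-only usage; when
enabled, every PAM occurrence anchors windows of all admissible lengths and
`align_gapped()` — an exact dynamic program over (guide position, window
position, DNA bulges used, RNA bulges used) — returns the minimal alignment
under the lexicographic cost (total bulges, then mismatches). Ties between
equal-cost alignments are broken deterministically, preferring
match/mismatch columns over bulges at each step. The test suite holds both
the genome scan and the gapped aligner to exhaustive brute-force oracles.

## Annotation layers

The annotator mirrors the layered-database design of off-target annotation
pipelines, but every layer is a declared file contract rather than a
download: gene models from GFF3/GTF, promoters / enhancers / regulator
peaks / protein domains / miRNA genes / miRNA target sites as BED3–6 (+ an
optional linked-gene column), and five gene-keyed TSV function tables
(phenotypes, cancer genes, TF class, RBP function, tissue expression). Any
subset may be supplied; omitted layers are skipped with a notice.

From the gene models we derive, per gene, the exon union across all
transcripts (a site is "exonic" if it touches any transcript's exon),
introns as the gene span minus that union, the CDS union, and UTRs as the
exonic bases strand-aware 5'/3' of the extreme CDS bases. When a site
straddles segment boundaries the highest-precedence overlapped segment wins:
`CDS > 5'UTR/3'UTR > exon > intron`.

Intersection uses BEDTools-`intersect` semantics — strand-blind, half-open,
at least `min_overlap` (default 1) shared bases — because Cas9 cleaves
double-stranded DNA, so feature disruption is strand-independent. Promoter
windows derived from a TSS default to −499..+100 (the EPD convention; the
named promoter databases supply windows of about this size) and are
configurable. Regulator peaks are reported independently of promoters and
additionally flagged when the peak lies inside a promoter record.
Chromosome names are taken verbatim from the inputs — a mismatch (e.g.
`chr1` vs `1`) triggers a warning listing the unshared names rather than a
silent empty annotation, which is the classic failure mode of mixed-source
annotation runs. Gene identifiers are joined after stripping a trailing
`.N` version suffix; no other identifier reconciliation is attempted.

## The risk schema

Each annotated site receives one label from

> high-coding > medium-coding > medium-noncoding > low-coding >
> low-noncoding > medium-regulatory > low-regulatory > none

by branch order:

1. **Coding** — the site overlaps a protein-coding gene. Exonic
   (CDS/UTR/exon) with disease evidence (any phenotype, or a cancer-gene
   flag, on that gene) → `high-coding`; exonic without → `medium-coding`;
   intronic → `low-coding`.
2. **Noncoding** — gene hits of any other biotype (lncRNA, pseudogene,
   TEC, miRNA...): exonic → `medium-noncoding`, intronic →
   `low-noncoding`.
3. **Regulatory** — only for sites with *no* gene overlap at all: a
   promoter or enhancer hit whose linked gene has disease evidence →
   `medium-regulatory`, otherwise `low-regulatory`.
4. `none` (intergenic) otherwise.

Across multiple qualifying genes or features the maximum-severity outcome
is kept. Design choices worth making explicit:

* The split of non-high coding sites into `medium-coding` (exonic) and
  `low-coding` (intronic) treats exon disruption as the more severe event;
  disease/cancer evidence is what elevates an exonic hit to `high-coding`.
* The noncoding labels and `none` complete the schema: a coding/noncoding/
  regulatory region classification needs a noncoding outcome, and
  intergenic sites need a value.
* In the severity order, every gene-branch label outranks every regulatory
  label. Because the branches are mutually exclusive, this ordering choice
  cannot change any assigned label; we fixed it this way so that severity
  is *monotone*: adding disease evidence to a hit gene can never lower a
  site's rank, and removing an overlap can never raise it. Ranking
  `medium-regulatory` above `low-coding` would break the second property
  (dropping a coding-gene overlap could then promote a site).
* TF/co-TF status, RBP function, protein domains, miRNA genes and miRNA
  target sites are reported as evidence but do not move the tier — no rule
  ties them to severity, and inventing one would be silent policy.
* Mismatch count does not affect risk: the 0-mismatch on-target inside a
  disease gene is `high-coding` like any other exonic disease hit.
* A site inside a coding gene's transcribed span (introns included) never
  receives a regulatory label.

The decision table is exercised exhaustively in the tests: every
combination of biotype × segment × phenotype × cancer × promoter ×
enhancer must produce exactly one in-vocabulary label, deterministically,
and satisfy the monotonicity and coding-precedence properties.

## Reporting

`build_summary()` emits one row per deduplicated site, color-coded purely
by tier (high → red, medium → orange, low → yellow, none → green).
`build_charts()` computes per-chromosome site counts, the targeted
gene-type distribution (distinct genes by biotype and highest-precedence
disrupted segment), the risk-label distribution, and the expression matrix
of targeted protein-coding genes. `build_db_tables()` reproduces the
layer-by-layer view (`gencode`, `mirgene`, `remap_epd`, `enhancer`,
`pfam`, `targetscan`, `omim`, `tf`, `rbp`, `cosmic`, `expression`).
Exports are CSV (one file per table, plus `charts.json` and `sites.bed`)
and a single JSON document; both round-trip losslessly. Excel output is
not offered; requesting `xlsx` raises a clear error rather than silently
writing something else.

The `annotate` entry point accepts either plain BED6(+mismatch column) or
the extended TSV written by `search`. Only the TSV carries sequences,
bulge counts and alignment strings, so the `run ≡ search | annotate`
identity is exact for the TSV route; BED-borne sites have their sequences
re-filled from the genome and unknown fields left `NA`.

## The synthetic world generator

`make_fixture()` builds the test bed everything above is verified on. Its
default plan plants ten sites of one guide — mismatch histogram
`{0:1, 2:1, 3:3, 4:5}`, one site on the minus strand — across two
chromosomes (~12 kb and ~5 kb), one 1.5-kb slot per site, each slot
carrying the annotation context its site is meant to exercise: disease
exon (the on-target), cancer exon, plain exon, intron, lncRNA exon and
intron, disease promoter, cancer and plain enhancers, and bare intergenic
background. Every risk label is therefore represented at least once. A
protein domain, a regulator peak, a miRNA target site and an unhit miRNA
gene decorate the world so the evidence-only layers are populated.

Planted protospacers get their mismatches at uniformly random positions
(never in the PAM, which is planted as a concrete `NGG` instance). The
random background is then *screened*: an independent brute-force scan
(regex PAM matching + per-window comparison, a different route from the
search engine) repeatedly locates any unplanned hit within the mismatch
budget and mutates one of its free bases until only the planted sites
remain, and verifies each planted locus carries exactly its intended
mismatch count. The manifest — planted loci, sequences, contexts,
expected segments and labels, expected distributions — fully determines
the correct pipeline output, which is what the end-to-end tests and the
acceptance script compare against.

What the fixtures deliberately do **not** emulate: real human genome
composition (repeats, GC structure, assembly gaps), realistic database
scale or identifier churn, overlapping gene models at real density, or
guides with genome-wide hit counts in the hundreds. Passing tests
demonstrate correctness of the search, annotation and labelling logic
under the declared file contracts — not performance or robustness against
the pathologies of full-scale public annotation sources.

## Numerical and scale choices

* Oracle-equivalence tests run 100 random genomes of 0.5–4 kb with
  budgets up to 3 mismatches, the interval oracle runs 1000×1000 random
  intervals over three seeds, and the gapped-alignment oracle enumerates
  guide/window pairs up to 10 nt with bulge budgets ≤ 1 — sizes at which
  the brute-force references are themselves fast and trustworthy.
* All randomized tests fix their seeds; the fixture generator restores the
  caller's RNG state and is byte-reproducible per seed.
* Degenerate inputs have defined behaviour: empty site lists annotate to
  empty (but well-formed) reports; guides longer than every chromosome
  return an empty site table; unknown genes look up as all-empty records.

## Limitations

* No cleavage-efficiency or likelihood scoring (CFD/MIT-style); the label
  is purely location-based, by design.
* Regulatory annotation requires the element's gene link; an enhancer with
  no linked gene can only ever be `low-regulatory`.
* Nearest-gene assignment for intergenic sites is out of scope — only
  direct overlaps annotate.
* Genome-scale search performance parity with dedicated scanners is a
  non-goal; the engine is exact and test-scale.
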