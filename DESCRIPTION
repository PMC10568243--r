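Package: crisprisk
Title: CRISPR Off-Target Discovery and Layered Risk Annotation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Finds candidate CRISPR-Cas9 off-target sites in a genome by
    PAM-aware mismatch and bulge search (or ingests a user-supplied site
    list), intersects the sites with layered genomic annotation (gene models
    with derived exon/intron/CDS/UTR segments, promoters, enhancers,
    transcriptional-regulator peaks, protein domains, miRNA genes and miRNA
    target sites), joins gene-level functional evidence (genetic phenotypes,
    cancer involvement, transcription-factor class, RNA-binding-protein
    function, tissue expression), assigns each site a rule-based risk label,
    and emits color-coded summary tables, chart data and exports. A synthetic
    fixture generator plants ground-truth sites and annotations for
    self-contained end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    optparse,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
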