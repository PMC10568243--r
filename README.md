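# crisprisk

CRISPR-Cas9 genome editing is only as safe as its off-target profile.
Given a guide RNA, `crisprisk` finds every genomic locus that resembles
the 20-nt protospacer next to a PAM (`NGG` by default) within configurable
mismatch and bulge budgets, annotates each candidate site against layered
genomic and functional resources — gene models with derived
exon/intron/CDS/UTR segments, promoters, enhancers, transcriptional-
regulator peaks, protein domains, miRNA genes and target sites, plus
gene-level phenotype, cancer, transcription-factor, RNA-binding-protein
and tissue-expression tables — and assigns each site a rule-based **risk
label**. It is aimed at researchers designing or reviewing guides who
need to know not just *where* a nuclease might cut, but *what that cut
would disrupt*.

## The risk schema

Every site gets one label, by branch order and maximum severity:

| branch | condition | label |
|---|---|---|
| coding | exonic (CDS/UTR/exon) in a protein-coding gene with a known phenotype or cancer role | `high-coding` |
| coding | exonic, no such evidence | `medium-coding` |
| coding | intronic | `low-coding` |
| noncoding | exonic in a non-protein-coding gene | `medium-noncoding` |
| noncoding | intronic | `low-noncoding` |
| regulatory | no gene overlap; promoter/enhancer of a phenotype/cancer gene | `medium-regulatory` |
| regulatory | no gene overlap; promoter/enhancer, unflagged gene | `low-regulatory` |
| — | no overlap evidence at all | `none` (intergenic) |

Mismatch counts never alter the label; the PAM never counts toward the
mismatch budget; overlap testing is strand-blind with BEDTools-`intersect`
(0-based half-open) semantics. The rationale for every rule, the segment-
precedence convention (`CDS > UTR > exon > intron`) and the severity order
are laid out in `vignettes/offtarget-risk-annotation.Rmd`.

## Worked example

The package ships a synthetic-world generator that plants ground-truth
sites and annotations, so the whole pipeline can be exercised without any
external downloads:

```r
library(crisprisk)

fx  <- make_fixture("fx", seed = 42)          # genome + annotations + manifest
res <- run_pipeline(fx$config, quiet = TRUE)  # search -> annotate -> label -> export

res$sites[1:3, c("chrom","start","end","strand","mismatches","site_sequence")]
#>   chrom start  end strand mismatches        site_sequence
#> 1  chr1   600  620      +          0 CACCCGATCCACTGGGGAGC
#> 2  chr1  2100 2120      -          2 CACCCGATCCTATGGGGAGC
#> 3  chr1  3600 3620      +          3 CACCCGGACGACTGGGGAGC

res$charts$risk
#>       high-coding     medium-coding  medium-noncoding        low-coding
#>                 2                 1                 1                 1
#>     low-noncoding medium-regulatory    low-regulatory              none
#>                 1                 2                 1                 1

res$summary[c(1, 4, 10), c("site","chrom","start","genes","risk_label","color")]
#>       site chrom start                            genes        risk_label  color
#> 1   site_1  chr1   600 FXG0001|GENE1|protein_coding|CDS       high-coding    red
#> 4   site_4  chr1  5100                                  medium-regulatory orange
#> 10 site_10  chr2  3600                                               none  green
```

Site 1 is the planted on-target: 0 mismatches, inside the CDS of a
protein-coding gene with a known phenotype, hence `high-coding` (red).
Site 4 overlaps no gene but sits in the promoter of a disease-linked gene
(`medium-regulatory`); site 10 is intergenic background (`none`). The run
writes `summary.csv`, `charts.json`, `results.json`, per-database tables
under `tables/` and `sites.bed` to the configured output directory.

The same stages are available from the shell via the installed
`exec/crisprisk` script:

```sh
crisprisk fixture --out fx --seed 42
crisprisk run --config fx/config.yaml --out results_dir
crisprisk search --guide CACCCGATCCACTGGGGAGC --genome fx/genome.fa --out hits
crisprisk annotate --sites hits/sites.tsv --config fx/config.yaml --out results2
```

`run` is exactly `search` piped into `annotate` (byte-identical outputs
when the extended site TSV is used).

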