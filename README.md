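# ecosplice

Comparative alternative-splicing (AS) analysis between two ecotypes sharing
a genome — the motivating case being human head and body lice, con-specific
morphs with distinct niches whose transcript pools may differ even where
their genomes do not. Given spliced transcript alignments for each ecotype,
a gene annotation, and short-read splice junctions, `ecosplice`:

1. builds per-gene **exon–intron templates** from the transcript alignments
   and detects and classifies AS events against them — exon skipping (ES),
   intron retention (IR), alternative 5′-donor (5S), alternative
   3′-acceptor (3S), and double-alternative (3S5S) sites, strand-aware;
2. **confirms** events by exact coordinate match of a junction end to an
   event boundary, and partitions confirmed events (and their genes) into
   shared and ecotype-specific sets;
3. computes a **coverage-corrected AS index** per gene — the mean number of
   distinct events over 100 subsamples of 10 transcripts, with the template
   rebuilt inside each subsample — and genome-wide AS prevalence;
4. tests **enrichment** of event types and gene functions among
   ecotype-specific events by randomization: 10,000 equal-sized draws from
   the pool, an empirical Z with two-sided p (exact hypergeometric moments
   reported as cross-check), Bonferroni over the 10 (type × ecotype) tests,
   Benjamini–Hochberg across GO categories with small terms (<100
   background genes) grouped, and a pooled two-proportion Z
   `z = (p1 - p2) / sqrt(p(1-p)(1/n1 + 1/n2))` for between-ecotype
   comparison of type shares;
5. ships a **synthetic-data generator** with an exact ground-truth manifest
   for end-to-end validation of all of the above.

All coordinates are handled internally as 0-based half-open; GFF3's 1-based
convention is converted at the I/O boundary. The methods vignette
(`vignettes/ecosplice-methods.Rmd`) documents the classification rules, the
template design, the index, the tests, and the generator in detail.

## Worked example

The numbered scripts under `analysis/` run the whole workflow on a
simulated 400-gene, two-ecotype dataset (written under `results/`):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_detect.R
Rscript analysis/03_confirm_partition.R
Rscript analysis/04_index.R        # ~8 min: 2 x 400 genes x 100 subsamples
Rscript analysis/05_enrichment.R
```

Stage 3 prints, for the default seed:

```
Confirmed 157 of 205 distinct events (76.59%)
Partition of confirmed events:
  shared: 94  head-specific: 24  body-specific: 39
Genes with ecotype-specific events: head 23 / body 39 / both 2 / union 60
Recovery vs manifest: precision 1 ; per-type recall: ... all 1
```

i.e. every planted event is detected, correctly typed, and confirmed
exactly when a matching junction was emitted, and the shared/specific
partition equals the generator's ground truth. Stage 4 reports the
coverage-corrected prevalence (`head: prevalence 28.2%`,
`body: prevalence 31.8%` — the generator plants events in 35% of genes,
some visible in only one ecotype), and stage 5 recovers the planted
functional biases among genes with body-specific events
(`body GO categories at BH p < 0.05: GO:B1 (enriched)`;
`reproductive p_adj=0.011`) while the unbiased immune lists and the head
gene set stay quiet. The ecotype-specific event sets of this small example
(24 and 39 events) are deliberately under-powered for type enrichment; the
acceptance suite runs that test at its proper scale (~200 specific events
per ecotype) and recovers the planted ES-enrichment/IR-depletion exactly.

Programmatic use mirrors the scripts:

```r
library(ecosplice)
catalog <- read_gene_annotation("genes.gff3")
alns <- c(read_spliced_alignments("head.bed", "head"),
          read_spliced_alignments("body.bed", "body"))
asg <- assign_transcripts(alns, catalog)
raw <- do.call(rbind, lapply(names(asg$assigned), function(g)
  detect_gene_events(g, asg$assigned[[g]])))
events <- confirm_events(deduplicate_events(raw), read_junctions("junctions.tsv"))
part <- partition_specificity(confirmed_only(events))
```

`run_pipeline(config)` orchestrates all stages from a single YAML/JSON/list
config and writes the result tables plus a run-summary JSON.

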