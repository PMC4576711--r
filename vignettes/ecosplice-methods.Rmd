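---
title: "Methods: comparative alternative-splicing analysis between ecotypes"
author: "ecosplice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative alternative-splicing analysis between ecotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Two con-specific ecotypes — the motivating case is the human head louse and
body louse, morphs of *Pediculus humanus* that occupy different niches on the
same host — can share an essentially identical genome yet differ in their
transcript pools. Alternative splicing (AS) is one mechanism by which such
differences can arise without genomic change. `ecosplice` implements a
coordinate-based comparative AS analysis for exactly this design: one pooled
transcript sample per ecotype aligned to a common genome, a set of short-read
splice junctions for independent confirmation, and the question of which AS
events are shared and which are specific to one ecotype, whether the specific
events are biased in type, and whether the genes they affect are biased in
function.

The pipeline is purely coordinate-based: it consumes spliced transcript
alignments (BED12), a gene annotation (GFF3), and junction coordinates (TSV);
no sequence is read. All internal coordinates are 0-based half-open, and the
1-based conventions of GFF3 are converted only at the I/O boundary, so that
boundary-exact comparisons (the heart of both event classification and
junction confirmation) are free of off-by-one ambiguity.

## Gene templates

Transcripts are assigned to a gene when their genomic span overlaps exactly
one annotated gene on the same strand; intergenic transcripts and transcripts
overlapping two genes carry no interpretable signal and are discarded with
counted reasons (`no_gene`, `ambiguous`). The annotation contributes only the
gene extents and strands. The splicing structure itself is learned from the
data: each gene's *template* is the union of all of its transcripts' exon
blocks, merged where overlapping or bookended, with the complementary gaps as
template introns. Template exons and introns therefore alternate and tile the
template span — an invariant the test suite asserts on randomized inputs.

The template additionally records the set of *distinct observed introns*
across the contributing transcripts. This is deliberate and load-bearing: a
transcript that retains an intron contributes a block that covers it, so the
retained intron is absorbed into the merged exon union and is invisible in
the gap structure. Keeping the observed introns alongside the union makes
retention detectable and — importantly — attributes it to the transcripts
that retain the intron, which is what per-ecotype support counting needs. A
template whose exon union and gap structure were the only record would make
intron retention undetectable for any gene in which the retaining transcript
itself helped build the template.

## Event classification

For a transcript compared against its gene's template, five event types are
recognised. Donor and acceptor are strand-aware: the donor is the intron
boundary abutting the transcript-5' exon (the left boundary on `+`, the
right on `-`).

* **ES** (exon skipping): a transcript intron fully contains one or more
  template exons. One event is emitted per skipped exon, with the skipped
  exon as the event interval, so that an intron skipping two exons yields two
  events. This granularity makes the event identity tuple
  `(gene, type, start, end)` well defined and deduplication unambiguous.
* **IR** (intron retention): a transcript block fully contains a template
  intron or an observed intron, extending at least one base into the exon on
  each side. The margin requirement guards against terminal-exon truncation
  artifacts mimicking retention. The event interval is the retained intron.
* **5S** (alternative 5'-donor): a transcript intron shares its
  acceptor-side boundary with a template intron but not its donor-side
  boundary; interval = the intron.
* **3S** (alternative 3'-acceptor): donor side shared, acceptor side not.
* **3S5S**: the intron overlaps a template intron, shares neither boundary,
  and contains no complete template exon.

Three suppression rules complete the decision tree. An intron exactly
matching a template gap intron is concordant and emits nothing. An intron
lying strictly within a merged template exon emits nothing: it is the
splicing counterpart of a retention event that is already detected on, and
attributed to, the retaining transcripts. A block lying inside a template
exon emits nothing. When an intron both skips an exon and has one shifted
boundary, the ES event(s) are emitted and, by default
(`emit_side_with_es = TRUE`), the boundary-shift event as well; this
preserves the per-boundary exhaustiveness of the rules and can be switched
off.

Classification is validated against an independent brute-force oracle that
enumerates every (intron, template-feature) and (block, candidate-intron)
pair with plain loops and applies the definitions literally; an exhaustive
sweep over all two-to-four-exon templates on a coarse coordinate grid, with
all skip/shift/retention edits of their boundaries on both strands (several
thousand instances), must agree case-for-case. Two symmetries are asserted
as properties: reading the same geometry on the opposite strand swaps 5S and
3S and fixes the other types, while mirroring the locus *and* flipping
strand preserves transcript-relative geometry and therefore every type.

Raw events are deduplicated on the identity tuple with per-ecotype transcript
support summed; a duplicate transcript adds support but never a new distinct
event.

## Junction confirmation and specificity

An event is *confirmed* when some short-read junction end (donor or acceptor
position, same chromosome) equals the event's start or end exactly.
Confirmation is coordinate-only — junction strand is ignored, and junctions
with unknown strand are fully usable. Matching is monotone in the junction
set: adding junctions can only confirm more events, and confirmation under a
union of junction sets equals the union of the confirmations. Unconfirmed
events are retained in the outputs with `confirmed = FALSE` but excluded
from partitioning and all downstream enrichment.

Specificity is presence/absence: a confirmed event is *shared* when it has
transcript support in both ecotypes and *specific* when supported in exactly
one. With one pooled sample per ecotype there is no replication to support a
quantitative differential-splicing test, and none is attempted. The
partition counts obey inclusion–exclusion identities
(`shared = observed_A + observed_B - total`, etc.) which are asserted, not
assumed, on every run. A gene enters an ecotype's specific set when at least
one of its events is specific to that ecotype; the gene union identity
`|union| = |A| + |B| - |both|` is likewise asserted.

## The coverage-corrected AS index

Deeper transcript coverage mechanically reveals more AS events, so raw
per-gene event counts are not comparable across genes or datasets. The
corrected index removes this bias by subsampling: for each gene with at
least `k` transcripts (default `k = 10`), draw `n_samples = 100` subsamples
of `k` transcripts without replacement, rebuild the template *from the
sampled transcripts only*, detect and deduplicate events within the sample,
and report the mean distinct-event count. Genes below `k` transcripts are
ineligible and reported as missing, never as zero. Genome-wide *prevalence*
is the fraction of eligible genes with a positive index — a threshold-free
reading of "gene is alternatively spliced".

Two design points were genuinely open and are resolved as follows.
Subsampling is per gene rather than global: only per-gene sampling yields a
per-gene index whose mean is comparable across datasets of different
coverage. The template is rebuilt inside every subsample rather than reused
from the full data: a full-data template would leak coverage information
into the subsample and defeat the correction. Three properties pin the
behaviour: an isoform-homogeneous gene has index exactly 0; a 12-transcript
gene with 6 exon-including and 6 exon-skipping isoforms has index exactly 1
at `k = 10` (every one of the C(12,10) = 66 subsamples contains both
isoforms — verified by enumeration); and duplicating every transcript
m-fold moves the index by less than the Monte-Carlo standard error at 100
subsamples.

## Randomization enrichment

Whether ecotype-specific events are biased toward an event type, or the
genes they affect toward a functional category, is tested by randomization:
draw 10,000 samples of the test-set size from the reference pool without
replacement, count feature-positive items in each, and compare the observed
count with the empirical null by a Z statistic with a two-sided normal p.
Because the draws are without replacement the exact null is hypergeometric;
the closed-form mean, standard deviation, and exact p are reported alongside
the empirical ones as a cross-check, and a property test requires the
empirical moments to converge to the exact ones within three Monte-Carlo
standard errors. Direction (enriched/depleted) is reported separately from
the two-sided p. When the null is degenerate (`sd = 0`) the empirical tail
proportion is reported with a warning instead of a Z.

Event-type tests run per ecotype and type (5 types x 2 ecotypes) against the
pool of all confirmed events, with Bonferroni correction over the family of
10 — the family is all tests corrected together, passed explicitly so that
subsetting cannot silently change it. The strength of the ES/IR bias is
compared between ecotypes with a pooled-variance two-proportion Z test.
Functional tests take the background to be all alternatively spliced genes
(so that expression/detectability bias cancels), pool GO terms annotating
fewer than `min_term = 100` background genes into one composite category
before testing, and apply Benjamini–Hochberg across categories. Curated
gene lists are tested individually without grouping. A calibration property
holds the machinery to account: under a uniform null the Z-based test
rejects at nominal rate (measured within three binomial standard errors of
5% over 1,000 replicate tests); the discrete empirical-tail p is
conservative by construction and is reported, not used, for calibration.

## The synthetic-data generator

`simulate_dataset()` produces a complete, seed-reproducible dataset — gene
catalog, two ecotype transcript pools, junctions, GO map, curated lists —
with a ground-truth manifest. Transcripts are exon-subset/boundary-edit
derivatives of each gene's full isoform, so every planted event corresponds
to an exact geometric edit matching one of the five definitions and truth
labels are exact rather than probabilistic. Planted events occupy disjoint
intron slots within a gene, so edits compose without interference;
each event is carried by some but never all of an ecotype's transcripts, so
the template always retains the constitutive form.

Defaults encode the study conditions the analysis assumes: ~30% of genes
alternatively spliced (the prevalence scale observed across arthropods);
event categories at 57% shared / 17% A-specific / 26% B-specific, the
proportions of the confirmed-event partition in the louse study; junction
confirmation probability 0.7649, the observed confirmation rate; and type
mixtures that plant exon-skipping enrichment and intron-retention depletion
in both ecotypes' specific events, stronger in the B ecotype (ES 30→50→60%
and IR 40→20→10% across shared/A/B), with the three splice-site-shift types
held at equal proportions across categories. The last point matters for
interpretation: because enrichment is measured against the pool that
includes the specific sets themselves, planting a bias in one category
mechanically shifts the pool and makes the *other* category's unchanged
mixture register as the opposite deviation; holding 5S/3S/3S5S constant
keeps them null by construction. A 3-fold GO-term bias and a 2-fold
curated-list bias among genes with B-specific events emulate the functional
enrichment signal.

Junctions are emitted only at planted-event boundaries (each with the
configured confirmation probability — for ES events the flanking
constitutive intron, whose acceptor coincides with the skipped exon's start;
for all other types the event's own intron) plus uniform noise junctions
kept at least 2 bp from every true event boundary so they can never
accidentally confirm an event. The manifest's expected partition counts are
computed two independent ways (per-event categories vs. per-ecotype exhibit
flags) and must agree exactly.

What the generator does *not* emulate bounds what passing tests show about
real data: there are no alignment errors, no partially covered transcripts
(every simulated read spans its full gene), no spurious splicing noise, no
junctions at constitutive introns away from events, and no expression-level
variation. Recovery of recall/precision 1.0 on noise-free instances
validates the geometry and bookkeeping of the pipeline, not its robustness
to alignment artifacts — which the minimum-intron threshold only partially
addresses.

## Numerical and threshold choices

* `min_intron = 40` bp: alignment gaps shorter than this are treated as
  indels and merged at read time, below the shortest credible arthropod
  intron; configurable.
* Boundary matching everywhere is exact (integer equality), which is why a
  single internal coordinate convention is enforced at the I/O boundary.
* Event tables are sorted by `(chrom, start, end, event_type)`; ties cannot
  arise because identity tuples are unique after deduplication.
* Degenerate inputs have defined behaviour: `k < 2` is an error (no
  disagreement is possible), an empty junction set confirms nothing, a
  zero-variance null falls back to the empirical tail with a warning, a
  pooled proportion of 0 or 1 yields `z = 0, p = 1` with a warning, and an
  empty gene-list file is an error (misconfiguration, not an empty set).
* Seeds: every stochastic entry point takes an explicit seed and restores
  the caller's RNG state; identical inputs and seeds give bit-identical
  results, including byte-identical simulator output files.

## Problem sizes

The test and acceptance suites run the pipeline at desk scale, chosen so the
statistical checks meet their own premises: the classifier sweep covers all
two-to-four-exon template shapes with 50/100 bp segments and every
enumerated edit on both strands; calibration uses 1,000 replicate tests at
1,000 draws each; planted-bias recovery uses 700 genes with 2–3 events per
event gene so that each ecotype-specific set holds ~200 events (the scale at
which a 2-fold mixture shift is decisive under Bonferroni); and the
end-to-end worked example uses 400 genes at 10–16 transcripts per gene per
ecotype with the index at its defaults (100 subsamples of 10). At these
sizes the ecotype-specific sets of the worked example (~25–40 events) are
deliberately *under*-powered for type enrichment — the example shows honest
non-flags there while the functional biases, which act on better-powered
gene sets, are recovered.

## Known limitations

* Detection granularity (one ES per skipped exon; side events emitted with
  ES) follows this package's definitions; other tools draw event boundaries
  differently, so absolute event counts are not comparable across tools.
* Retention detection requires the intron to be observed spliced in at least
  one transcript of the same gene; retention of an intron that no sampled
  transcript ever splices is indistinguishable from a long exon.
* Specificity is presence/absence under one pooled sample per ecotype; it
  conflates biological specificity with sampling depth, which is precisely
  why the confirmed-event partition and the coverage-corrected index are
  reported together.
* Mutually exclusive exons and alternative first/last exons are outside the
  five-type taxonomy and are not detected.
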