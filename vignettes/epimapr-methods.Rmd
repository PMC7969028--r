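---
title: "Models and design choices in epimapr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in epimapr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The analysis problem

Oocytes build their epigenome through an interplay of promoter-associated
H3K4me3, the Polycomb repressive marks H3K27me3 (PRC2) and H2AK119ub1
(PRC1), transcription-coupled H3K36me3, and de-novo DNA methylation.
Knocking out a chromatin regulator perturbs this network: marks
redistribute, hypermethylated domains fail to form, and transcription
shifts. epimapr implements the downstream analysis layer for such a
two-genotype (WT vs KO) comparison, starting from aligned-read surrogates,
peak calls, bisulfite cytosine counts and FPKM tables, and ending in
promoter chromatin states, a directional bin-change taxonomy, methylome
summaries and differential expression — with a synthetic generator that
plants all of these so the pipeline can be validated end to end.

All coordinates are 0-based half-open (BED convention); lengths are always
`end - start`. Chromosome names are opaque strings. The methylation
coverage dialect is declared 0-based here; tables in the 1-based dialect
are converted on load with `one_based = TRUE`.

## Signal quantification

Reads are length-normalized as reads per kilobase of feature per million
mapped reads. A read is assigned to a feature when its **midpoint** falls
inside it. The paper trail behind this choice: midpoint assignment makes
counts additive over any non-overlapping tiling (the sum of bin counts
equals the number of reads in the tiled span), which gives every
quantification an exact counting oracle; overlap-based assignment would
double-count reads spanning bin borders.

* Promoters are ±2 kb around the annotated, strand-aware TSS (4-kb
  windows); unstranded genes are rejected because a TSS is undefined
  without orientation.
* Peaks with RPKM < 2 are excluded; a peak at exactly 2 is retained (the
  exclusion is strict).
* Z-scores use the population SD (divisor *n*); zero-spread rows map to
  all zeros so constant features do not poison heat maps. Heat-map row
  order is deterministic (sorted), not shuffled, for reproducibility.
* Peak genomic distribution assigns each peak by midpoint with precedence
  TSS > TES > gene body > intergenic, so the reported fractions always sum
  to one.
* TSS metaprofiles bin read midpoints by signed offset; minus-strand
  anchors are flipped so positive offsets are always downstream.

## Promoter chromatin states and expression

A mark is "present" at a promoter when its RPKM is **strictly** greater
than 1 (a promoter at exactly 1 has no marks). The state is the subset of
{K4, K27, ub} present — eight states — and the four-group label collapses
ub: A = K4 without K27, B = bivalent, C = K27-only, D = neither.
Expression is summarised per state with medians, quartiles and 1.5 × IQR
whiskers clamped to observed values.

Differential expression uses the printed fold rule made numerically safe:
`(FPKM_WT + 0.1) / (FPKM_KO + 0.1) > 1.5` calls a gene down, symmetric for
up, with an FPKM ≥ 0.5 floor on the elevated genotype. The pseudocount and
floor exist because a bare ratio rule explodes as FPKM → 0; both are
configuration parameters.

## The six-class bin taxonomy

Each 10-kb bin gets a per-mark directional call between genotypes:

> up ⇔ (KO + 0.5)/(WT + 0.5) ≥ 2 and KO ≥ 2 RPKM; down symmetric.

"Significant change" is deliberately operationalized as a deterministic
fold rule with a pseudocount and an RPKM floor (the floor echoes the
peak-quality bar) rather than a statistical test: it is oracle-checkable,
reproducible, and honest about the fact that the exact genome-wide rule
used in practice varies. The (K27, ub) call pair maps to:

| K27  | ub   | class |
|------|------|-------|
| up   | none | I     |
| up   | up   | II    |
| none | up   | III   |
| down | none | IV    |
| down | down | V     |
| none | down | VI    |

Opposite-direction pairs get an explicit `mixed` class rather than silent
exclusion, and everything else is `unchanged`, so the classes partition
the bins. The IV–VI assignment mirrors I–III (K27-only / both / ub-only
losses); this mirror correspondence is an interpretation, flagged here, as
the loss classes are not individually spelled out in the source material
the taxonomy emulates. Relabeling the genotypes swaps I↔IV, II↔V, III↔VI
and up↔down exactly — a property the test suite asserts.

Per-class covariates are resolved to bins (methylation: mean CpG level of
sites in the bin; expression: genes whose body midpoint falls in the bin)
and tested with two-tailed Student's *t*: unpaired for region-level
covariates, paired when the same genes are compared across genotypes. The
*t* machinery delegates to `stats::t.test(var.equal = TRUE)`; degenerate
inputs are handled explicitly (zero variance with equal means: t = 0,
p = 1; with unequal means: infinite statistic and the smallest
representable p).

## Methylome summaries

Per-site levels are `methylated / (methylated + unmethylated)` for sites
at or above the coverage floor (default 1, suited to desk-scale simulated
data; real WGBS practice typically uses 3–5). All aggregations are
**unweighted site means** — each covered site counts once — matching the
"average of levels" convention; coverage-weighted pooling would answer a
different question (fraction of methylated reads). Element aggregation
lets a site contribute to every class it overlaps (a gene-body CGI site
counts in both), while `intergenic` is defined negatively (neither gene
body nor promoter). Absent element classes (e.g. no exon/intron
subdivision in a toy annotation) are reported as missing, never as zero —
the same rule as uncovered ICRs and absent contexts.

Conversion efficiency pools all cytosine calls on the spike chromosome:
`1 − methylated/total`. Sample clustering uses 1 − Pearson correlation
over the CpG sites covered in every sample with average linkage — the
field's default when the choice is not otherwise pinned down; both metric
and linkage are the obvious alternatives to swap, and the implementation
fails loudly (rather than returning NaN) when a sample has constant
levels or too few shared sites. 5mC and 5hmC are not distinguished, which
mirrors what bisulfite data can support.

## The synthetic generator

The generator emulates the statistical structure of a two-genotype
multi-omic oocyte study: two 5-Mb chromosomes tiled with 500
non-overlapping, strand-alternating genes; alternating 100-kb hyper-
(mean CpG level 0.8) and hypomethylated (0.1) domains; CpG islands at half
the promoters; eight imprinting control regions centred in hyper domains
(maternal ICRs at 0.85 in WT falling to 0.55 in KO, paternal at 0.05); a
48.5-kb spike chromosome whose cytosines methylate at
1 − conversion efficiency (0.995); 200k fixed-length 150-bp reads per ChIP
sample; WGBS sites every 100 bp (80% CpG, 10% CHG, 10% CHH) at Poisson
30× coverage; and log-normal FPKM around state-determined means.

Reads are drawn from a mixture of a uniform genomic background and the
regions where the planted truth puts the mark, weighted by
`enrichment_fold`. The default is very high (1e5) for a geometric reason
worth spelling out: at desk scale a single read in a 4-kb promoter is
already 1.25 RPKM, so the fixed RPKM > 1 presence threshold only behaves
as it does on a full-size genome if the background contributes well under
one expected read per promoter. The default therefore emulates the
*RPKM contrast* of a clean low-input ChIP against a 2.5-Gb genome, not its
literal fold enrichment; it is a configuration parameter like every other
effect size here, chosen once for comfortable statistical separation.

Every coupling between data layers is an explicit switch, so tests can
verify the pipeline does not manufacture correlations:

* `couple_methylation` — Polycomb-gain classes (I–III) are placed only in
  WT-hypermethylated domains and lose methylation in KO (planted level
  0.8 → 0.2 in those bins); loss classes (IV–VI) only in hypomethylated
  domains. Off: classes are placed without regard to domains and KO
  methylation is untouched by class.
* `couple_expression` — genes in Polycomb-gain bins are down in KO
  (×0.4), genes in K27-loss bins up (×2); K27-containing promoter states
  have low planted FPKM (K27 dominant-repressive), K4-only the highest.
* `couple_k36` — H3K36me3 covers the gene bodies of expressed genes per
  genotype, so genes that lose expression in KO also lose gene-body
  H3K36me3.

A planted fraction (30%) of K4-only genes is down-regulated in KO by a
4-fold effect, comfortably beyond the 1.5-fold DE threshold at the default
dispersion (log-SD 0.3). Change-class bins avoid promoter-overlapping bins
so promoter and bin signals do not confound each other.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: read-level noise structure (mappability, GC,
duplicates), fragment-size variation, peak-shape realism, biological
replicate variance in ChIP, allele-specific signal, partially methylated
domains, and sequence context (cytosine contexts are labels; context
classification from sequence is exercised separately on explicit
trinucleotides). Recovery rates on synthetic data are upper bounds.

Determinism: the whole dataset is a pure function of the configuration
(which includes the seed); the genome layout and cytosine/context layout
are derived from the seed independently of genotype, so all samples of one
simulated study share one genome. Re-running a fixture bundle reproduces
identical checksums, and the analysis stage is seed-free, so two runs over
the same inputs are byte-identical.

## Problem sizes and runtime envelope

The default study scale — 10 Mb of genome, 500 genes, 1,000 bins, 8 ChIP
samples × 200k reads, 4 methylomes × ~102k sites — was chosen so the full
simulate-and-analyse cycle completes in well under a minute and the whole
validation suite (including 100 clustering replicates and 50
coupling-ablation runs) in a few minutes on one CPU, while keeping every
per-feature expectation (≈800 reads per planted promoter, ≈50 CpGs per
bin) large enough for the thresholds to sit in flat parts of their
operating curves.

## Known limitations

* The fold-rule change caller has no error model; bins near the RPKM floor
  flip calls with single reads at very low depth (visible in the tiny
  unit-test fixtures, not at the default scale).
* `aggregate_by_element` reports unweighted site means only (a
  read-weighted variant is a natural extension).
* The pipeline links expression to bins by gene-body midpoint; genes
  spanning several bins contribute to one.
* Peak calling itself, input/IgG correction, spike-in normalization and
  browser-track rendering are out of scope; peaks enter as BED intervals.
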