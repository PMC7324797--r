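---
title: "Methods: downstream WGBS analysis in sparsely methylated genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: downstream WGBS analysis in sparsely methylated genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bsmethyl)
library(dplyr)
```

# Scope and model

`bsmethyl` implements the downstream, post-alignment stages of a
whole-genome bisulfite sequencing (WGBS) analysis for genomes where
methylation is sparse and concentrated in the CpG context, as in insects:
roughly 1% of cytosine calls methylated overall, CpG levels an order of
magnitude above CHG/CHH, gene bodies more methylated than intergenic
space, and exons more methylated than introns. The input unit is the
Bismark cytosine report (CX): one row per strand-specific cytosine with
methylated and unmethylated call counts, context and trinucleotide.

Four analysis layers sit on top of that input:

1. **Context classification.** Reading 5'→3' on the cytosine's own strand,
   the next base decides CpG; otherwise the base after next decides CHG
   (G) versus CHH (A/C/T). A minus-strand cytosine sits at a plus-strand
   G and is classified on the reverse complement. An N among the deciding
   bases, or a contig edge, yields UNDEFINED — except that C followed
   directly by G is CpG regardless of the second base, which is the
   standard CpG-first precedence.

2. **Observed/expected context ratios.** For a region set, overlapping
   mono-, di- and trinucleotide windows are counted per contiguous region
   (no window spans a region boundary; windows containing N are excluded
   from numerator and denominator alike) and pooled before normalising:

   $$CpG_{O/E} = \frac{F_{CG}}{F_C\,F_G},\qquad
     CHG_{O/E} = \frac{F_{CAG}+F_{CTG}+F_{CCG}}{3\,F_C\,\bar F_H\,F_G},\qquad
     CHH_{O/E} = \frac{\sum_{H_1,H_2} F_{CH_1H_2}}{9\,F_C\,\bar F_H^2},$$

   with $\bar F_H = (1-F_G)/3$ the average frequency of a single non-G
   base. Writing the H-slot expectation this way makes the three ratios
   dimensionally parallel: each compares an observed context frequency to
   its expectation under base independence, so each converges to 1 on
   i.i.d. sequences of any fixed composition, and values below 1 read as
   depletion. (An alternative reading that treats the whole non-G mass
   $1-F_G$ as a single-slot frequency while keeping the combinatorial 3
   and 9 gives limits of 1/3 and 1/9, which would make the CHG and CHH
   ratios incomparable with the CpG ratio and with the neutral line of 1;
   we use the 1-normalised form.) The CHH numerator sums the nine
   canonical C-H-H trinucleotides with H ∈ {A,C,T}. Frequencies are
   computed on the plus strand only — the dinucleotide CG and the pooled
   context sums are strand-symmetric, and the choice is stated here so it
   can be revisited if a strand-asymmetric genome ever warrants it.

3. **Stratified methylation levels.** The default level estimator is
   call-weighted: $100\cdot\sum m_i / \sum (m_i+u_i)$ over the sites of a
   stratum, which matches the "methylated calls over total calls" framing
   of genome-wide totals and makes strata exactly additive (the genic and
   intergenic calls sum to the global calls). Zero-coverage sites are kept
   in files (the CX convention lists every cytosine) but never enter a
   denominator. Strand balance is reported under both definitions found
   in the field — difference in per-strand levels, and difference in each
   strand's share of methylated calls — because the two are routinely
   conflated and are not numerically equivalent. Replicate summaries are
   the unweighted mean and the sample (n−1) SD of the per-replicate
   statistic.

4. **Differential methylation.** Loci are filtered to the configured
   context (CpG by default), to genic positions when requested, and to a
   minimum coverage (default 10×) in *every* replicate of *both* groups.
   Per group, methylation at a locus is pooled across replicates,
   $\hat p_g = \sum_r m_r / \sum_r n_r$, with beta-binomial variance
   $$\widehat{\mathrm{Var}}(\hat p_g) = \hat p_g(1-\hat p_g)\,
     \frac{\sum_r n_r\,(1 + (n_r-1)\varphi_g)}{(\sum_r n_r)^2},$$
   where $\varphi_g$ is the group's dispersion. The Wald statistic is
   $(\hat p_1-\hat p_2)/\sqrt{\widehat{\mathrm{Var}}_1+\widehat{\mathrm{Var}}_2}$
   with a two-sided normal p-value; a locus jointly fixed at 0 or 1 in
   both groups is defined to have statistic 0. No smoothing across loci is
   performed: in sparse, AT-rich methylomes neighbouring CpGs are too far
   apart for local pseudo-replicates to be trustworthy, so each locus
   stands on its own replicates.

# Dispersion estimation

$\varphi$ is estimated per group by a pooled method of moments. Under the
beta-binomial model the expected between-replicate variance of the
proportion at a locus with coverages $n_r$ is
$p(1-p)\,\overline{(1+(n_r-1)\varphi)/n_r}$; summing the gap between the
observed per-locus sample variances and this expectation over all loci
gives a monotone function of $\varphi$ whose root is the estimate
(`uniroot` on [0, 0.999], truncated at 0 when the data are
under-dispersed). The $p(1-p)$ term uses the pooled $\hat p$ with a
$\varphi$-dependent bias correction, since
$E[\hat p(1-\hat p)] = p(1-p)(1 - \mathrm{Var}(\hat p)/(p(1-p)))$.
This single pooled $\varphi$ deliberately trades the per-locus shrinkage
of empirical-Bayes approaches for a fully explicit estimator; simulation
tests recover planted $\varphi \in \{0, 0.05\}$ within Monte-Carlo error.

# Region calling

Significant loci (raw $p < \alpha$, default 0.05) seed regions.
Consecutive significant loci whose methylation differences share a sign
are merged while the gap between them is at most 100 bp; a candidate
region spans its first to last significant locus. The region is kept when
it contains at least 3 tested loci, spans at least 50 bp, and at least
50% of the tested loci inside the span are significant. Its **area
statistic** is the sum of the Wald statistics of *all* tested loci in the
span (not only the significant ones), so a region diluted by
non-significant loci is penalised; output is ordered by decreasing
|area statistic| with coordinate order breaking ties. The same-sign rule
applies to the seeding loci: requiring every locus in the span to share a
sign would reject true regions on the sign noise of their null
neighbours, while letting opposite-signed *significant* loci join would
merge a hyper- and a hypomethylated event into one incoherent "region".
A gene is called differentially methylated (a DME) when at least one
region overlaps its span by one base or more.

Benjamini–Hochberg adjusted p-values are computed and reported next to
the raw ones, but region seeding follows the raw $p < 0.05$ rule to stay
comparable with analyses that report DML counts at a raw threshold; users
wanting FDR-controlled seeding can filter `tidy(fit)` on `padj` and call
`call_dmr()` on the result.

# Coordinate conventions

Everything in memory is 1-based inclusive, the convention of GFF3, CX
reports and the GenomicRanges stack this package is built on; the single
exception is BED export, where starts are shifted to 0-based half-open at
the writer. Keeping the internal convention identical to the dominant
input formats and to IRanges means the only coordinate shift in the code
base is one subtraction in `write_dmr_bed()`.

For overlapping genes, position classes follow the precedence
exon > intron > intergenic: a position exonic in any gene is exonic, and
any non-exonic position under any gene span is intronic. The annotation
model is deliberately minimal — `gene` and `exon` features with
ID/Parent links; UTRs and CDS phases are out of scope.

# The simulator: what it emulates, and what it does not

`sim_config()` describes a synthetic WGBS experiment: an i.i.d. genome at
a configurable GC fraction (default 0.4, AT-rich as in aphids); genes of
deterministic exon/intron geometry placed at regular intervals; a
methylation model of per-stratum success probabilities keyed by context,
feature class and strand; replicate-level beta-binomial dispersion
$\varphi$ (a Beta-distributed per-site, per-replicate rate with mean
equal to the planted probability); negative-binomial coverage; bisulfite
non-conversion (unmethylated cytosines read as methylated) and
inappropriate conversion (the reverse); and planted DMRs that override
the CpG probability for one group inside given coordinates. Every output
is deterministic given the seed.

The named presets plant the summary levels this package is designed to
recover, at genome sizes chosen so the Monte-Carlo standard error of the
pooled estimate is well below the last reported digit:

| preset | genome | planted values |
|---|---|---|
| `context` | 2 Mb, ≥100k CpG sites | CpG 5.19%, CHG 0.27%, CHH 0.34% |
| `feature` | 2.5 Mb, 15% genic | genic 1.58%, intergenic 0.808% |
| `global` | 1.25 Mb, ≥500k cytosines | 1.126% everywhere |
| `dmr-null` | 1 Mb, 40% genic | two identical groups, genic CpG 0.30, φ = 0.02 |
| `dmr-alt` | as dmr-null | + twenty 2 kb genic DMRs at +0.30 (0.30 → 0.60) |

All presets use 3 replicates per group, mean coverage 30 with
negative-binomial overdispersion 0.1, $\varphi = 0.02$ and zero
conversion error (non-conversion is configurable but defaults to 0, as no
conversion-efficiency control is modelled).

Two preset choices deserve justification. First, the calibration presets
plant a genic CpG level of 0.30 rather than the ~5% of the emulated
organism: the Wald statistic relies on a normal approximation whose
accuracy needs adequate methylated counts per locus, and at 5%
methylation with 30× coverage the expected methylated count per group
(~4.5) makes the test visibly *conservative* (empirical type-I error
below nominal). A calibration benchmark should measure the test where its
assumptions hold; the conservatism at low levels is a genuine limitation
of unsmoothed Wald testing in sparse methylomes and is stated here rather
than hidden in the benchmark design. Second, replicate-level dispersion
$\varphi = 0.02$ is kept in the recovery presets too — it inflates the
estimator's Monte-Carlo error slightly but leaves it unbiased, and
dropping it would make the recovery experiments easier than the data they
emulate.

What the simulator does **not** emulate: read-level errors and M-bias,
sequence-dependent coverage (coverage is independent of the local
sequence), repeat structure, correlated methylation along the genome
(sites are independent given their stratum), and replicate-level *global*
shifts (the between-replicate SD of the global level in real data
reflects batch effects the site-level beta model does not produce).
Passing recovery tests therefore demonstrates estimator correctness under
the stated sampling model, not robustness to every artefact of real
libraries.

# Numerical and degenerate-input choices

* Percent summaries with an empty denominator are `NA` ("undefined
  flagged"), never 0.
* O/E ratios with a zero denominator are `NA`; an all-N region yields
  `NaN` frequencies and is flagged the same way.
* The dispersion root-search is bounded at 0.999 and returns 0 when the
  moment gap is already non-positive at $\varphi = 0$.
* Ties in region ordering are broken by contig and start coordinate, so
  identical inputs give byte-identical outputs.
* Negative assay percentages (sample OD below the negative control) are
  reported as-is with a `below_negative_control` flag — clamping to zero
  would hide a QC problem.
* The plate-assay grouping `[(sample−neg)/S] / [(pos−neg)·k/P] · 100`
  (k = 2 for the 5mC kit's 50%-methylated control, k = 5 for the 5hmC
  kit) is the only reading under which the result is a percentage of the
  input DNA; the two assays are identical up to the kit factor, which the
  tests exploit as an invariant.

# Problem sizes used in validation

The validation suite runs entirely on simulated data at the preset scales
above (the largest single experiment is the 2.5 Mb feature preset, three
replicates, ~3 M site draws), plus a 1 Mb i.i.d. genome for the O/E limit
law and 100 random kilobase sequences for classifier/oracle agreement.
These sizes put the Monte-Carlo error of every recovered quantity below
the printed precision of the value it is compared against while keeping
a full run of tests and recovery experiments in the minutes range on one
CPU.

# Known limitations

* The Wald test is conservative at very low methylation levels and low
  coverage (see above); no exact or likelihood-ratio alternative is
  provided.
* One pooled dispersion per group: loci with atypical biological
  variability are not shrunk individually.
* `genic` classification ignores strand and nesting: any position under
  any gene span is genic, which slightly overcounts genic cytosines in
  genomes with genes nested inside other genes' introns.
* The O/E profile is pooled per region class; no sliding-window O/E along
  chromosomes and no CpG-island calling.
* qPCR efficiencies are taken as given (from the user's dilution series);
  no standard-curve fitting or Cq calling from fluorescence data.
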