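---
title: "Methods: quantifying cytosine base editor off-target mutagenesis from WGS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying cytosine base editor off-target mutagenesis from WGS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cbescan)
```

## The problem

Cytosine base editors (CBEs) couple a catalytically impaired Cas9 to an
APOBEC-family cytidine deaminase and convert C:G pairs to T:A without
double-strand breaks. The deaminase moiety, however, can act on
single-stranded DNA genome-wide, independent of guide RNA binding. Whole
genome sequencing of single-cell-derived edited clones against their parental
line is the unbiased way to measure this: each clone's somatic variant
catalog is the editor's genome-wide footprint. `cbescan` implements the
analysis chain for such experiments — paired somatic filtering, mutation
spectrum accounting, APOBEC sequence-signature statistics, PAM proximity and
CRISPR off-target checks, and inter-clone comparisons — together with a
seeded simulator that generates inputs with known truth so every stage can be
validated quantitatively.

## Somatic filtering

A candidate site carries ref/alt read counts in the clone ("tumor") and the
parental line ("normal"). `fisherSomaticP()` computes the one-sided Fisher
exact p-value on the 2x2 table `[[tAlt, tRef], [nAlt, nRef]]` against the
alternative that the clone's alt fraction exceeds the parental one; this is
the hypergeometric upper tail with margins fixed, evaluated with
`stats::phyper` so that thousands of sites vectorise cheaply. The direction
of interest is gain of the alt allele in the clone, which is why the default
is one-sided; a two-sided option exists for sensitivity analysis.

`filterSomatic()` then applies four strict cut-offs, all exclusive
inequalities as is conventional for this caller family:

| parameter          | default | meaning                                   |
|--------------------|---------|-------------------------------------------|
| `maxP`             | 0.001   | Fisher p must be `< maxP`                 |
| `maxNormalVaf`     | 0.05    | parental VAF must be `< maxNormalVaf`     |
| `minTumorVaf`      | 1/3     | clone VAF must be `> minTumorVaf`         |
| `minTumorAltReads` | 6       | clone alt reads must be `> 6` (i.e. >= 7) |

The clone VAF threshold is usually quoted as "33.33%". We take the exact
fraction 1/3 as the default and expose the printed constant 0.3333 as an
alternative; the two differ only for sites whose VAF lies in
(0.3333, 1/3], and the boundary behaviour is tested explicitly. Sites with
no alt evidence in the clone evaluate to p = 1 and are rejected rather than
skipped, keeping the filter total over its input. Every rejection records
the complete set of failed criteria (`p`, `normal_vaf`, `tumor_vaf`,
`alt_reads`) so that filter audits are reproducible line by line.

```{r}
site <- data.frame(chrom = "chr1", pos = 99L, ref = "C", alt = "T",
                   tRef = 18L, tAlt = 12L, nRef = 49L, nAlt = 1L)
filterSomatic(site, cloneId = "demo")$calls[, c("pValue", "tumorVaf",
                                                "normalVaf", "verdict")]
```

## Mutation spectrum

Substitutions are reported pyrimidine-normalised: each SNV is assigned to one
of six classes (C:G>T:A, C:G>G:C, C:G>A:T, A:T>C:G, A:T>G:C, A:T>T:A) by the
pyrimidine-strand representation, so a class is invariant under strand
complementation. Indels form a seventh class. `summarizeCatalog()` counts
every variant exactly once; equal-length multi-base substitutions are
decomposed into their differing positions and counted as independent SNVs,
which matches per-base spectrum accounting. `typeFraction()` reports
percentages; printed reports round half-up to one decimal while machine
output keeps full precision (base R's round-half-to-even would print 86.75
as 86.7 where conventional reporting prints 86.8 — we keep the conventional
rule and retain the unrounded value).

Fold changes divide a clone's per-class count by the arithmetic mean of the
control clones' counts for that class. The control set is an explicit
argument (in the pipeline, a config key): typically the procedure-control
clones transfected with a GFP-only plasmid. A zero control mean yields a
flagged `NA` rather than an infinity.

## Sequence-context signature (TCW)

For each mutated C:G site the flanking window is read on the strand where
the mutated base is a cytosine: `ref == "C"` reads the plus strand,
`ref == "G"` the reverse complement, so "downstream" is always 3' of the
deaminated base. This orientation is what makes deamination footprints
visible; averaging over both strands would wash them out. The default window
is -5..+25 (`contextWindow(5, 25)`), the range over which CBE footprints are
customarily displayed; narrower windows are a display choice, not an
analysis one. Windows that leave the chromosome or overlap an N are excluded
and counted — never padded, because padding biases column frequencies.

`buildContextMatrix()` computes column-wise base frequencies and the
information content 2 - H bits per position (H the Shannon entropy,
0·log 0 = 0) — the sequence-logo statistics. The small-sample correction
e(n) = 3/(2 n ln 2) is available but off by default: context sets here are
in the hundreds to thousands, where the correction is below 0.005 bits and
the published logos derive from comparable n.

The APOBEC signature motif is TCW (T at -1, mutated C at 0, A or T at +1).
`tcwFraction()` measures the motif fraction among oriented contexts, and
`tcwEnrichment()` compares it against the fraction of *all* genomic
cytosines (both strands) whose trinucleotide context is TCW, computed by
trinucleotide counting on the analysed genome itself — not a canned
human-genome constant, so synthetic genomes are self-consistent. The test is
a one-sided exact binomial test of the observed TCW count against that
background. Cytosines without a complete N-free trinucleotide context are
excluded from the background denominator, mirroring the exclusion rule for
observed contexts.

The C:G>G:C context matrix is only produced for clones with more than 40
such transversions (config key `cg_logo_min`): below that, a logo is mostly
sampling noise.

## PAM proximity and off-target intersection

If off-target editing required Cas9 binding, mutated cytosines should be
enriched for an NGG PAM at the characteristic distance. For every mutated
cytosine, `pamProximityFraction()` tests the 6 bases at distances 15..20
downstream — on the mutated-C strand, the same orientation rule as context
extraction — for a fully contained NGG (`containsNgg()`, 4 possible start
offsets; the reverse-strand CCN is deliberately not counted since the motif
of interest is NGG on the oriented strand). The original analyses do not
state the strand convention; a `orientation = "reference"` flag provides the
plus-strand reading for sensitivity analysis. The genomic null is
`backgroundPamFrequency()`: windows drawn uniformly over all in-bounds,
N-free start positions genome-wide (chromosomes weighted by valid starts)
with a seeded generator, reported with a binomial standard error. On a
synthetic uniform-composition genome both statistics converge to the
exhaustive 4096-hexamer enumeration value, which is how they are validated.

`intersectOffTargets()` counts catalog variants whose position falls inside
predicted CRISPR off-target intervals (`[start - flank, end + flank)`,
0-based half-open), returning per-site counts ordered by descending CFD
score. The expected result for genuine APOBEC (Cas9-independent) off-target
activity is zero hits.

## Inter-clone comparisons

`overlapMatrix()` counts shared mutations for every clone pair. The default
is allele-aware matching on (chrom, pos, ref, alt); because recurrence is
sometimes assessed by position alone, `position_only` mode is provided and
is provably at least as permissive — both are reported rather than silently
choosing one. `chromosomeDistribution()` gives each eligible clone's
per-chromosome fraction of C:G>T:A and C:G>G:C mutations, restricted to
clones with more than 500 total mutations (below that the per-chromosome
fractions are dominated by noise), with group mean and sample SD (n - 1)
across user-configured clone groups; singleton groups are flagged rather
than given an SD of 0.

## The simulator

`simulateStudy()` generates the full input set from one seeded config:

* **Genome** — i.i.d. bases at a configurable GC content (default 0.41,
  human-like), split over equal chromosomes. Defaults to 1 Mb: large enough
  that TCW-site sampling and PAM backgrounds are well-behaved, small enough
  that the whole suite runs in seconds.
* **Catalogs** — 900 APOBEC SNVs planted at TCW cytosines on either strand
  (C->T with probability 0.85, else C->G), 100 uniform background SNVs
  (alt base uniform among the three non-reference bases), 40 short anchored
  indels; positions drawn without replacement; a complete truth table
  records origin and planting context. The 900/100 split gives a clone
  whose C:G>T:A share (~85-90%) matches the high-load edited clones, while
  the `control-like` regime (nApobec = 0) reproduces the flat spectrum of
  uninduced clones.
* **Counts** — clone depth Poisson(40), alt reads binomial at
  VAF 0.5 adjusted by the error rate (0.001); parental alt reads binomial
  at the bare error rate; 200 non-mutant decoy sites with error-only alt
  reads in both samples. Depth 40 sits in the 30-60x range typical of
  clone-resequencing designs; at that depth the binomial tail of the VAF
  > 1/3 criterion is the binding constraint and the filter recovers ~97% of
  planted heterozygous variants while rejecting every decoy.

What the simulator does *not* emulate: alignment artifacts, strand bias,
mapping-quality structure, copy-number variation, clonal subpopulations, or
human trinucleotide composition (the background substitution classes are
uniform by design, so any spectrum deviation is attributable to the planted
signal). Passing tests therefore validate the statistical machinery and its
conventions, not robustness to real sequencing artifacts.

All randomness derives from the single config seed through fixed per-stage
offsets, so every output is byte-identical under a fixed seed — a property
the suite asserts on whole written bundles.

## Numerical and edge-case conventions

* Internal coordinates are 0-based half-open; VCF stays 1-based and BED-like
  tables 0-based on disk. Round-trips are asserted field-by-field.
* Chromosome names match exactly; there is no "chr" aliasing — a mismatch is
  a hard error, because silent aliasing hides data bugs.
* Indels are VCF-anchored (shared first base). A `plusminus` reader flag
  accepts the `+SEQ`/`-SEQ` dialect used by some callers, converting on
  read, since published variant lists are not explicit about their dialect.
* Frequencies in a `ContextMatrix` must sum to 1 within 1e-9 per position;
  information content is clamped to [0, 2] by validity checks.
* Fisher p-values are exact (no continuity or mid-p adjustments); the test
  suite checks equality with full hypergeometric enumeration over all 2x2
  tables with total <= 60 at 1e-12.

## Problem sizes used by the test suite

The packaged checks run on synthetic genomes of 1 kb to 1 Mb, catalogs of
10 to 3000 variants, count tables of ~1200 sites, 1e5 to 1e6 sampled PAM
windows, and three simulator seeds for the parameter-recovery checks; these
sizes keep the whole suite in the low minutes while leaving every binomial
comparison well inside its 99% interval.

## Known limitations

* The somatic filter implements the four published criteria only; it does
  not reproduce a specific caller's pileup parsing, strand-bias or
  homopolymer heuristics.
* Functional annotation (exonic/non-synonymous classes) is out of scope —
  it requires a gene-model database.
* Off-target site *prediction* is consumed, never performed; CFD scores are
  taken as given.
* Sex chromosomes are not modelled separately: calls on haploid chromosomes
  of a male line simply pass the VAF filter more easily, which matters for
  interpretation but not for the mechanics implemented here.
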