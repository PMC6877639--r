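# cbescan

Genome-wide off-target mutation analysis for cytosine base-edited clones.

Cytosine base editors (CBEs) fuse a catalytically impaired Cas9 to an
APOBEC-family cytidine deaminase and convert C:G to T:A without double-strand
breaks. Because the deaminase can also act genome-wide on single-stranded
DNA, whole-genome sequencing (WGS) of single-cell-derived edited clones
against their parental line is the unbiased way to measure a CBE's
off-target footprint. `cbescan` is for researchers doing exactly that: it
takes per-clone variant calls (VCF) or paired clone/parental allele-count
tables plus a reference FASTA, and quantifies whether the clone's mutation
load carries the hallmarks of APOBEC activity rather than Cas9-guided
cutting.

## What it computes

* **Somatic filtering** — one-sided Fisher exact test on the paired 2×2
  count table [[t_alt, t_ref], [n_alt, n_ref]] per site, retaining calls
  with p < 0.001, normal VAF < 5%, tumor VAF > 1/3 and tumor alt reads > 6
  (all strict; every rejection lists its failed criteria).
* **Mutation spectrum** — pyrimidine-normalised six-class substitution
  counts plus indels (e.g. G→A is recorded as C:G>T:A), per-class
  percentages, and per-class fold changes against a control-clone mean.
* **APOBEC signature** — strand-oriented context extraction around mutated
  cytosines (the window is read on the strand where the base is C),
  position frequency matrices with information content 2 − H bits
  (sequence-logo math), and TCW-motif (T-C-W, W ∈ {A,T}) enrichment over
  the genome's own trinucleotide background with an exact binomial test.
* **PAM proximity** — fraction of mutated cytosines with an NGG PAM fully
  inside the 6-base window 15–20 bases downstream, versus a seeded sample
  of windows drawn genome-wide (the Cas9-independence null).
* **Off-target intersection** — variant hits inside predicted CRISPR
  off-target intervals, per site, ordered by CFD score.
* **Inter-clone comparisons** — shared-mutation overlap matrices
  (allele-aware and position-only) and per-chromosome mutation
  distributions with group mean ± SD.
* **Simulator** — seeded synthetic genomes, catalogs with a planted APOBEC
  component at TCW sites, and paired read counts with truth records, so the
  entire pipeline is testable against known parameters.

## Worked example

Simulate a high-load edited clone (900 APOBEC events at TCW cytosines, 85%
C→T; 100 background SNVs; 40 indels; 40× coverage), run the somatic filter,
and measure the signature:

```r
library(cbescan)

cfg <- simulationConfig(seed = 42)
sim <- simulateStudy(cfg)

fs <- filterSomatic(sim$counts[[1]], cloneId = "clone1", genome = sim$genome)
fs$catalog
#> VariantCatalog 'clone1': 1023 variant(s) (984 SNV, 16 insertion, 23 deletion, 0 MNV)
#>   provenance: somatic filter on paired counts

summarizeCatalog(fs$catalog)
#> SpectrumSummary 'clone1': total 1023
#> C:G>T:A C:G>G:C C:G>A:T A:T>C:G A:T>G:C A:T>T:A   indel
#>     770     143       9      23      15      24      39

enr <- tcwEnrichment(fs$catalog, sim$genome)
enr$observedFraction; enr$backgroundFraction; enr$pValue
#> [1] 0.9791
#> [1] 0.1748
#> [1] 0
```

The filter recovered 1023 of the 1040 planted variants and no decoy sites.
The spectrum is dominated by C:G>T:A (75%) with a C:G>G:C minority — the CBE
fingerprint — and 97.9% of the mutated cytosines sit in a TCW context
against a genomic background of 17.5%, a ~5.6-fold enrichment. The
PAM-proximity fraction of the same catalog (0.144) is statistically
indistinguishable from the sampled genomic background (0.137 ± 0.001·3),
i.e. the planted mutations are PAM-independent, as expected for
deaminase-driven rather than Cas9-guided events.

The same stages run from a YAML config over real inputs:

```r
runPipeline("analysis.yaml")          # see ?readAnalysisConfig for keys
```

or from the shell via the thin front end:

```sh
Rscript inst/scripts/cbescan run --config analysis.yaml --out results/
```

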