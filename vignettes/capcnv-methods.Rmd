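---
title: "Coverage-based CNV and consequence analysis for capture data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coverage-based CNV and consequence analysis for capture data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The analysis problem

Targeted sequence capture enriches a chosen set of genes — here, the
flowering-time regulatory network of an allotetraploid *Brassica*-type crop
and its two diploid progenitor species — before short-read sequencing.
Because capture depth is roughly proportional to the underlying copy
number, read depth carries the copy-number signal, while the reads
themselves carry SNPs and short InDels. `capcnv` implements the full
decision chain from per-base depth tracks and variant calls to biological
conclusions: which gene copies are deleted or duplicated between two
genotypes, which tetraploid copies are missing, retained or exchanged
between subgenomes relative to the progenitors, where large deletions
hide below the InDel-calling size limit, and how severe the coding
consequences of the retained variants are.

# Normalized coverage

All copy-number reasoning is done on normalized coverage

$$\mathrm{nc} = \frac{\text{read count}}{\text{region length}} \times
  \frac{\text{genome size}}{\text{total mapped reads}}$$

(`normalize_coverage()`). The factors are chosen so that nc is
dimensionless, invariant under joint rescaling of read count and library
size, and comparable across references of different sizes. A useful
consequence: with equal library sizes, a diploid progenitor's reads
mapped onto the tetraploid reference concentrate on half the target
space, so a retained copy shows roughly **200%** of the tetraploid
control's nc — the baseline expectation behind the cross-species status
calls. Read counts over a region are obtained as depth mass divided by
read length, so a read contributes to a region in proportion to its
overlap; at capture depths the difference from whole-read counting is
negligible, and it keeps region counting a pure function of the depth
track.

Analyzable regions are maximal runs of depth at least 2 (two overlapping
reads) whose nc reaches 10; regions are then tied to annotated genes (or
to externally supplied capture-target hits) and gene spans replace raw
regions wherever an annotation exists. When a region overlaps several
annotations, the gene with the largest overlap wins, ties broken by
lexicographic gene identifier — the underlying protocol leaves this case
open, and a deterministic tie-break keeps reruns byte-identical.

# CNV classification between two genotypes

`classify_cnv_pair()` applies a three-step rule to a region's nc in two
genotypes of the same species:

1. **Unbalance test.** A CNV requires the higher coverage to be at least
   `unbalance_factor` = 1.5 times the lower. The protocol states this
   test in two non-equivalent ways ("less than 50% coverage" vs "at
   least 50% higher"); only the 1.5-fold reading is consistent with the
   published worked example called at a low/high ratio of 0.57, so 1.5
   is the default and the factor is configurable.
2. **Clear deletion.** If the lower coverage is below 30% of the higher,
   the low genotype carries a deletion.
3. **Population tiebreak.** Otherwise the low genotype's nc is compared
   with the mean nc of the orthologous region in a tetraploid reference
   population: below 30% of it the call remains a deletion in the low
   genotype; otherwise the high genotype is called duplicated. The low
   genotype's *own-reference* nc is compared directly to the tetraploid
   population mean without ploidy correction — the two scales agree
   because half the reads on half the genome cancel in the nc formula,
   and this is the only reading consistent with the published deletion
   example whose low/high ratio (0.56) passes step 2. With no population
   value available the call is reported `unresolved` rather than forced.

# Cross-species copy status and reconciliation

For each tetraploid gene copy, the diploid genotypes' nc on the
tetraploid reference is expressed as a percentage of the population mean.
The copy's own subgenome decides which progenitor is "matching". All
matching percentages below 30% mean `absent`; all at or above 60% mean
`present`; anything else is `reduced_ambiguous`. If the matching
progenitor is absent or reduced while every genotype of the *other*
progenitor reaches 120%, the copy is labelled a homoeologous
`exchanged` copy with the direction of the donor subgenome. The
30/60/120 bands interpolate the percentages the original study printed
for its absent (2–13%), present (≥87%) and exchange-supporting (≥136%)
cases; all three are configurable in `threshold_config()`.
`reconcile_copy_sets()` then folds these calls together with an ortholog
map into per-copy fates (retained, lost, gained, exchanged, covered but
unannotated).

# Large deletions as zero-coverage windows

Gapped short-read mapping of 100 bp reads resolves InDels only up to
18 bp, so larger deletions are invisible to the InDel caller. They are
recovered by scanning for maximal windows of **at least 19 bp with
exactly zero strict-mapping depth** in the carrier that are strongly
covered in the other genotype while the carrier's own gapped mapping
stays low (ruling out pure reference-mapping dropouts). "Strongly" and
"low" are not quantified in the protocol; the defaults are a mean depth
of at least 10 in the other genotype and at most 2 in the carrier's
gapped track, both configurable. The candidate interval is the zero run
itself, so breakpoints are resolved to single-base precision up to the
stochastic loss of flanking reads.

# Variant filtering and consequence annotation

SNPs are retained at mapping quality ≥ 50 and depth ≥ 10, InDels at
MQ ≥ 30 and DP ≥ 10. Heterozygosity is reported per variant type, and
only homozygous variants are treated as true variants downstream — in
inbred diploid material residual heterozygous calls mostly flag
paralog collapse rather than real alleles.

The annotator classifies each record against every gene copy it
overlaps, independently: CDS substitutions are translated strand-aware
into synonymous, nonsynonymous, stop-gain or stop-loss; CDS InDels into
in-frame or frameshift by length modulo 3; substitutions in the first or
last two intron bases into splice donor/acceptor (the canonical GT/AG
positions; the protocol does not state a width); anything else inside
the gene span is *silent*, deliberately distinct from *synonymous*.
Nonsynonymous changes carry the Grantham (1974) distance, binned by the
classical convention (≤50 conservative, 51–100 moderately conservative,
101–150 moderately radical, >150 radical). This reproduces 27 of the 29
radicality labels the original study printed; the two exceptions (H81Y
at distance 83, T176N at 65) fall in the moderately-conservative bin
under any standard binning and are treated as upstream inconsistencies.
Genes whose CDS length is not divisible by three are flagged as
pseudogene candidates and excluded from translation-dependent calls.
For reporting, categories are ordered hierarchically (frameshift >
stop gain/loss > splice > nonsynonymous by radicality > in-frame InDel >
synonymous > silent) and only a copy's most severe category is shown in
the pathway report.

# Neighbor-joining trees

Gene-copy trees use the Saitou–Nei agglomeration on p-distances
(mismatch fraction over sites ungapped in both sequences). The original
analysis ran inside a GUI tool whose distance model is unstated, so the
simplest model was chosen and the testable contract is topology-level.
Ties in the Q-criterion are broken by the lowest pair index for
determinism; negative branch lengths are clamped to zero with a flag.
Bootstrap support resamples alignment columns with replacement
(100 replicates by default) and scores each internal bipartition of the
full-data tree by the fraction of replicates containing it.

# The synthetic data generator

The generator builds the study conditions the pipeline is validated
under, not a general genome simulator:

* **References.** One A-like chromosome of evenly spaced two-exon genes
  (ATG…stop CDS, GT/AG introns) and a C-like homoeologous chromosome
  derived from it by 5% random substitution (terminal codons and splice
  motifs spared, so every copy stays structurally intact). The
  tetraploid is the union of both chromosomes; each diploid progenitor
  is byte-identical to one subgenome. The defaults — 20 genes of 2 kb
  per subgenome on 200 kb chromosomes, 100 bp single-end reads, 100:1
  on-target enrichment — describe the smallest geometry on which all
  depth-based inferences are stable.
* **Variants.** Injected events (SNPs, short InDels, large deletions,
  whole-gene losses, tandem duplications, homoeologous exchanges) are
  recorded in a truth ledger with realized coordinates; heterozygous
  events touch only one of two haplotypes, halving their depth effect
  and yielding 0/1 genotypes in the emitted VCF.
* **Reads.** Reads are placed intervals, not sequences: capture
  enrichment weights start positions, each read homes to its true origin
  on the mapping reference, and a placement is kept only if its mismatch
  count there (computed from the actual sequences) stays within a
  per-mode budget (2 strict, 5 gapped). A read crossing a deletion
  breakpoint is lost under strict mapping and is split around the gap
  under gapped mapping if the InDel is at most 18 bp; duplication and
  exchange junctions are unmappable in both modes. Near-identical
  reference locus pairs (an exchanged copy and its donor) can be
  registered so reads landing in one are assigned to either with equal
  probability — the random best-hit behavior of strict aligners.
  There is no base-error, quality or GC model: the pipeline consumes
  depth and already-called variants, so sequencing-error realism would
  add nothing the tests could detect. MQ and DP in the synthetic VCFs
  are constants plus Gaussian/Poisson noise, so the filter stage has
  true records to reject.
* **Default study.** `simulate_dataset()` widens gene spacing to 48 kb
  and raises enrichment to 2000:1 so that target fraction, on-target
  read fraction (~98%) and nc magnitudes resemble a real capture
  experiment at about 48x on-target depth, with 20 k reads per genotype
  and a 12-genotype population baseline — sizes chosen so the full
  study builds in seconds while every rate estimate stays far from its
  decision threshold. The engineered homoeologous exchange is fixed in
  the tetraploid *reference* but carried by only a sixth of the
  baseline population: a fully fixed exchange depresses nothing, and
  the donor-locus read splitting alone caps the other progenitor's
  signal at 100% of the population mean, below the 120% exchange band.
  A partially penetrant exchange lowers the population mean at the
  locus and is what makes the published-style >120% signature
  reproducible; it also matches the observation that homoeologous
  exchanges segregate in resynthesized material.

What passing tests on this generator do **not** show: robustness to
GC-dependent capture bias, mappability artifacts, base-calling error,
multi-mapping across tandem paralog arrays, or annotation errors in real
references — all of which the original protocol handles upstream of the
interfaces this package consumes.

# Numerical and interface conventions

Coordinates are 0-based half-open internally; VCF and GFF3 use their
native 1-based dialects at file boundaries only. All randomness flows
through explicit integer seeds and the generator restores the caller's
RNG state, so every simulation, dataset and report bundle is
byte-reproducible. Thresholds live in a single validated
`threshold_config()` object that every stage logs into the bundle
manifest.

# Known limitations

* CNV calls are per-region ratio tests; no segmentation or HMM smoothing
  across adjacent regions is attempted, matching the protocol's scope.
* Breakpoints of large deletions are window bounds, not base-pair
  refined junctions.
* Multi-allelic VCF records are reduced to their first alternate allele.
* The cross-species caller assumes the population baseline and the
  diploid libraries were mapped to the same tetraploid reference.
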