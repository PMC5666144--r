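---
title: "Methods: backcross introgression mapping and strain comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: backcross introgression mapping and strain comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Industrial *Trichoderma reesei* strains descend from the female-sterile
isolate QM6a. Crossing QM6a-background strains with a fertile wild isolate
restores female fertility, but every cross also drags wild-isolate genome
into the laboratory background. The classical remedy is recurrent
backcrossing: cross the fertile hybrid back to QM6a every generation while
selecting progeny that remain female fertile (and carry the required mating
type). After $n$ crosses, genome unlinked to the selected loci reverts to
the recurrent parent at an expected donor fraction of $0.5^n$, while a
*linkage-drag* block of donor genome survives around each selected locus
because recombination rarely separates tightly linked sites.

`introgmap` models this experiment end to end for haploid fungi: it
simulates the breeding scheme with known ground truth, annotates the SNP
catalog that distinguishes the parents, detects retained donor blocks and
clustered high-nonsynonymous regions, tests marker–trait association in a
fertile/sterile progeny panel, and provides the profiling layer (ANOVA,
fold-change filters, hierarchical clustering, relative growth, category
enrichment) used to compare strain backgrounds.

# Models and procedures

## Meiosis: the Haldane crossover process

Per linkage group, `meiosis_gamete()` draws a Poisson number of crossovers
with mean equal to the group's genetic length (Morgans), places breakpoints
uniformly on the genetic map, and alternates parental origin across them,
starting from either parent with probability 1/2. There is no crossover
interference, so the recombination fraction between loci $d$ Morgans apart
is Haldane's map function

$$r(d) = \tfrac12\left(1 - e^{-2d}\right),$$

which doubles as a closed-form oracle: the test suite recovers $r$ from the
engine at $d \in \{0.05, 0.1, 0.5\}$ within Monte-Carlo error. We chose the
Haldane model because no genetic map is available for the emulated cross
and it is the minimal standard model with exact expectations; interference
models would add parameters nothing in the data could constrain.

Genetic marker positions are linear interpolations of the group's genetic
length along its physical length — a uniform recombination landscape.
Real fungal chromosomes have centromeric suppression and hot spots;
nothing downstream depends on this simplification, but block lengths in
base pairs inherit it.

## The breeding scheme

`run_backcross_line()` starts from the all-donor × all-recurrent cross and
then crosses the selected progeny to the recurrent parent each round.
Selection is rejection sampling of gametes (capped, default 10,000/round)
until the gamete carries the donor allele at `FS` (the fertility locus —
only the donor allele restores female fertility) and satisfies the
mating-type rule at `MAT`. The default selects `MAT1-1` every round, since
the female-fertile crossing partner must be compatible with the `MAT1-2`
recurrent parent; a final-round switch to `MAT1-2` reproduces the
construction of fertile lines of the opposite mating type. "$n$
backcrosses" counts *total* crosses, so the unselected retention after the
default $n = 10$ is $0.5^{10} \approx 9.77\times10^{-4}$ — the convention
that makes a 9,127-gene genome yield an expectation of 9 unselected donor
genes. Intermediate generations are selected on phenotype only (fertility
and mating type), not genotyped, matching how such breeding lines are
actually constructed.

`simulate_association_panel()` performs the final mapping round: gametes
from (line × recurrent parent) are binned by fertility until 20 fertile
and 20 sterile individuals are collected, and genotyped at 17 markers —
markers inside the line's true donor intervals (the FS marker always
included) plus matched controls on groups without retained donor genome —
emulating a small SNP-marker panel spanning the candidate regions.

## Default study conditions and scale

The generator's defaults are fixed once and describe the emulated design:
7 linkage groups (the *T. reesei* karyotype) of 1 Morgan and 1.2 Mb each,
1200 markers per group (0.083 cM spacing), 150 gene models per group, FS
mid-group 2 and MAT mid-group 6, 10 backcrosses, three independent lines,
a 20 + 20 panel, 17 association markers. Physical size and gene count are
scaled down ~5-fold from a real 34 Mb / 9,127-gene genome so every
analysis, including 200-panel replication studies, runs in seconds; the
genetic scale (Morgans) — which controls segregation, drag and association
— is *not* scaled. Marker density was chosen so that a 25-marker scan
window spans ~2 cM, well below the 10–20 cM linkage-drag blocks expected
around a locus selected through 10 meioses (each flank of the block is the
minimum of 10 exponential crossover distances, i.e. Exp(10), mean 0.1 M).

## SNP coding effects

`classify_snps()` assigns each biallelic SNP its gene context by span
overlap and classifies it against the reference codon: positions outside
every CDS segment (introns, UTRs, intergenic) are `noncoding`; otherwise
the codon containing the position is rebuilt from the concatenated CDS
(reverse-complemented on the minus strand), the alternate allele is
substituted, and both codons are translated with the standard genetic code
(translation table 1, appropriate for fungal nuclear genes). Stop gain and
loss are folded into `nonsynonymous`, matching the binary
synonymous/nonsynonymous convention of comparative genome reports.
Multiple SNPs in one codon are classified independently against the
reference codon, as per-site annotators do; haplotype-aware codon
reconstruction is out of scope. A SNP in two overlapping genes is counted
in both, with the tally reported. Reference-allele mismatches against the
genome are hard errors — they almost always indicate a coordinate bug, and
silently mis-phased codons are the worst failure mode of this kind of
annotation.

The synthetic SNP catalog determines its truth labels through a different
route — mutate the whole CDS, translate the whole protein, compare — so
generator and classifier can disagree in principle; the test suite also
checks the classifier against a third, Biostrings-translated whole-protein
oracle on 1,000 random SNPs over random gene structures on both strands.

## Region detection

Two interval callers share the `RegionCall`-style output (group, span,
members, statistic):

* `scan_nonsyn_regions()` finds runs of at least 5 positionally
  consecutive genes each carrying at least 10 nonsynonymous SNPs. The
  criterion "5 or more genes in close vicinity containing 10 nonsynonymous
  SNPs" is read as *each gene* ≥ 10, consistent with the per-gene
  "more than 10" analysis that precedes it in such studies; "close
  vicinity" is operationalized as positional adjacency with a configurable
  gap allowance (default 0 interposed below-threshold genes). Both
  thresholds are parameters, and a cumulative mode (windows of `min_genes`
  genes by summed counts) supports sensitivity analysis.
* `detect_donor_blocks()` slides a fixed window (default 25 markers) and
  flags windows whose donor-call fraction among non-missing calls reaches
  0.9, merging overlapping/adjacent flagged windows into maximal blocks.
  The window/fraction design matches the density logic of "regions of
  increased SNP abundance" and tolerates genotyping error and missing
  calls (excluded from denominators; windows under 50% coverage are
  skipped); an HMM would be an unsupported embellishment at this data
  scale. The caller has an explicit **resolution floor**: a donor run
  shorter than `ceiling(0.9 × window)` markers can never be flagged.
  Because selected-locus block lengths are approximately Gamma(2, n)
  Morgans after n backcrosses, arbitrarily short FS blocks occur with
  small but nonzero probability, so properties of the form "the FS region
  is always recovered" hold only above the floor; the tests condition on
  it and verify that the condition itself is met in the vast majority of
  simulated lines at default density. The end-to-end demo scans with a
  13-marker window (~1.1 cM) — appropriate for error-free simulated calls
  on a dense grid — halving the floor.

`consensus_regions()` intersects each line's merged blocks across all
lines per group; member genes are genes overlapping the intersection. It
is associative and order-independent, so "regions present in all lines"
is well defined regardless of how lines are combined.

## Inheritance statistics

* `expected_retention(n, G)`: fraction $0.5^n$, genes
  $\mathrm{round}(0.5^n G)$ (nearest integer, ties up — 8.913 rounds to
  9), plus the unrounded expectation.
* `segregation_test()`: exact binomial test of the fertile:sterile split
  against 1:1, two-sided by the minimum-likelihood convention (outcomes
  with probability ≤ the observed outcome's are summed). The doubling
  convention would differ in asymmetric cases, so the choice is documented
  and matches `binom.test`.
* `associate_markers()`: per marker, Fisher's exact test (two-sided) on
  the 2×2 origin × phenotype table, complete cases with reduced margins
  reported, Bonferroni correction across the tested markers by default.
  An exact test is the right tool at n = 40; chi-squared is available for
  comparison. Note that the two-sided exact p for a perfect 20/20 split is
  $2/\binom{40}{20} \approx 1.45\times10^{-11}$ — both extreme tables have
  equal probability and are summed.
* `rank_candidate_locus()`: the maximal run of adjacent corrected-significant
  markers containing the smallest p-value, reported as the candidate
  interval, with FS containment flagged when truth is available.

## Profiling layer

`one_way_anova()` is computed from the sums-of-squares definitions (the
two-group case is checked to equal the squared pooled-variance t test, and
the general case to match `anova(lm(...))`). `de_filter()` takes fold
change as the ratio of linear-scale group means — reported fold values in
microarray-era comparisons are linear ratios — with the p-threshold
applied on top (defaults mirror the 2-fold and 5-fold, p < 0.01 designs);
rows with a zero denominator mean are excluded and tallied.
`hierarchical_cluster()` defaults to 1 − Pearson distance with average
linkage, the characteristic pattern-clustering configuration of
HCE-style tools; the distance is configurable, and the archetype-recovery
tests use Euclidean geometry because a "flat" archetype is a *level*, not
a pattern — noisy flat rows are mutually uncorrelated, so no
correlation-based method can group them, which is a real limitation of
pattern clustering worth knowing about. Zero-variance rows are assigned
by a nearest-centroid post-pass instead of crashing the correlation
distance. `relative_growth()` pairs replicate i with replicate i when
counts match (SD of the paired ratios); with unequal counts it reports
the ratio of means with a bootstrap SD, since no single pairing is
defensible there. `enrich_categories()` is the one-sided hypergeometric
upper tail with raw p-values by default, as classical functional-category
reports publish them; a correction flag exists for modern use.

# Numerical and degenerate-input choices

* Coordinates are 1-based closed everywhere (GFF3/VCF convention); BED
  export is the single 0-based half-open surface and round-trips
  losslessly.
* Haploid calls only; diploid GT fields in VCF input are rejected, since
  the progeny are haploid ascospore derivatives. Missing calls stay
  missing — no imputation anywhere; each consumer defines its handling.
* Multiallelic and indel VCF records are skipped and counted, not errors.
* Genes whose CDS length is not divisible by 3 are flagged
  non-annotatable, excluded from coding-effect calls, retained elsewhere.
* ANOVA with zero within-group variance and unequal means reports p = 0
  with a degeneracy flag; fully constant data report F = 0, p = 1.
* All stochastic stages consume the session RNG; `sim_config(seed = )`,
  `emit_dataset()` and `run_demo()` seed it explicitly, and identical
  configurations produce byte-identical output files.

# What the synthetic data does and does not show

The generator reproduces the *structure* of the emulated study — haploid
biallelic segregation, selection-driven linkage drag, planted
high-nonsynonymous gene runs, planted expression archetypes with planted
fold differences — under known truth, which is exactly what is needed to
verify the analysis machinery. It does not emulate genotyping error,
segmental aneuploidy or ascospore inviability (both reported in the real
cross), recombination-landscape heterogeneity, microarray normalization
artifacts, or correlated expression noise. Passing tests therefore
demonstrate correctness of the algorithms and calibration of the tests at
the stated conditions, not robustness to those real-data pathologies; the
window-based block caller and the complete-case association handling are
the two places where such robustness was explicitly designed in.

# Problem sizes used by the test suite

Simulation-heavy checks run at deliberately chosen sizes: 40,000 gametes
per distance for the Haldane recovery, 10,000 gametes for the segregation
fraction, 200 independent 20 + 20 panels for locus-recovery coverage, 20
full 10-backcross lines for the linkage-drag inequality, 200 replicate
lines for the $0.5^n$ retention checks at $n \in \{1, 3\}$, 6,000 null
rows for the 1% type-I calibration, and exhaustive enumeration of all 2×2
tables with margins ≤ 12 for the Fisher oracle. These sizes put
Monte-Carlo standard errors well inside the asserted tolerances while
keeping the whole suite in the minutes range on one core.

# Known limitations

* No crossover interference; block-length distributions are exponential
  where real ones are not.
* The per-gene region criterion and the block window/fraction thresholds
  are declared operationalizations of prose criteria; both are parameters.
* No moderated-variance (empirical-Bayes) testing: the profiling layer
  reproduces a plain-ANOVA design, by construction.
* One-way ANOVA only — no batch covariates.
* Sister strains from independent breeding lines are treated as plain
  replicates in profiling contrasts, as the emulated design did.
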