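---
title: "Methods: defined-community multi-omics with syncomics"
author: "syncomics authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: defined-community multi-omics with syncomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(syncomics)
```

## Scope and rationale

`syncomics` implements the computational backbone of defined ("gnotobiotic")
gut-community experiments: a known set of sequenced bacterial species
colonises germ-free animals, diets are switched in phases, and the community
is read out by shotgun sequencing of feces (species proportions), microbial
RNA-Seq and expression arrays (transcription), shotgun proteomics
(spectral counts), transposon-insertion sequencing (genetic fitness), and
in-vitro growth phenotyping.  Because every genome in the community is
known, reads, peptides and insertions can be attributed to species exactly —
and the package's analyses are built around that attribution.

All analyses are exercisable on data from the in-package simulator, which
generates genomes, reads, count tables, insertion libraries and growth
curves with the statistical structure the analyses assume.  The simulator is
first-class, tested code: its parameters define the study conditions under
which the package's claims are verified.

## Community profiling (COPRO-Seq)

Species proportions are estimated from fixed-length shotgun reads in three
steps:

1. **Informative genome size.** For k equal to the (trimmed) read length
   (default 25 bp), each genome's informative size is the number of
   positions whose canonical k-mer (the lexicographic minimum of the k-mer
   and its reverse complement) occurs exactly once in the union of all
   community genomes.  Genomes sharing sequence with other members have
   proportionally fewer informative positions.
2. **Unique read assignment.** A read counts for a species iff it matches
   exactly (either strand) in exactly one species; reads matching several
   species are tallied as ambiguous, reads matching none as unassigned.
   Unique + ambiguous + unassigned always equals the input read count.
3. **Quantification.** Normalized abundance is unique reads divided by
   informative size; the per-sample proportion is the normalized abundance
   as a percentage of the sample total.  This normalization makes the
   estimator unbiased even when a block of sequence is fully shared between
   two species, because the lost (ambiguous) reads are exactly compensated
   by the smaller denominator — a property the test suite checks by
   simulation.

Matching is exact (no mismatches), which is appropriate for the error-free
synthetic reads the package generates and keeps the operation
oracle-checkable against a brute-force substring scan; an aligner-backed
assigner could be substituted behind the same contract for real data.
Reads are trimmed to the first k bases before matching, mirroring the
trim-to-25-bp convention of short-read community profiling.

A species is called **present** at a proportion of at least 0.003%
(inclusive; the comparison's strictness is a package decision, as the
convention only states the cutoff).  Sub-threshold rows are flagged rather
than zeroed so downstream consumers can choose.  **PoMA** (percentage of
maximum achieved) rescales each species' trajectory within each animal to
its maximum proportion across that animal's time-points, putting species
whose absolute abundances differ by orders of magnitude on a common
response scale.  Ordination uses the Hellinger distance on per-sample
proportion vectors with classical metric scaling (PCoA); Hellinger
distances are Euclidean-embeddable, so eigenvalues are nonnegative up to
rounding, and negative eigenvalues (if any) are reported but excluded from
percent-variance denominators.

## Metatranscriptomics

**Normalization.** Size factors are median-of-ratios: for each sample, the
median (taken on the log scale) of the ratios of counts to per-feature
geometric means, computed over features observed in every sample.
*Community-level* normalization computes one size-factor set from all genes
and preserves each species' share of the metatranscriptome;
*species-level* normalization computes factors within each species' genes
independently and removes shifts in the species' total output, exposing
regulation within the species.  Samples with no always-observed feature
fall back to library-size ratios with a warning; normalizing an
already-normalized matrix is an error.

**Functional binning.** Raw counts are collapsed by EC number before
testing; genes without an EC contribute to no bin and multi-EC genes
contribute their full count to each of their ECs (no fractional
splitting — the collapse is by annotation, not by read apportionment).

**Differential tests.** Two are provided. The exact Mann–Whitney U test
enumerates all group labelings (up to combined n of 12 without ties;
midranks plus enumeration otherwise, with a tie-corrected normal
approximation beyond an enumeration cap).  The negative-binomial exact
test conditions on each feature's total count: group sums are NB with a
per-feature method-of-moments dispersion, pooled within groups and floored
at 1e-8; at dispersion zero it reduces exactly to the conditional binomial
test.  Because a moment estimate from a handful of samples is noisy enough
to make the conditional test anti-conservative, each feature's dispersion
is additionally floored at the median dispersion across features — a
deliberately conservative moderation under which the test holds its
nominal size on null simulations (checked at 1000 features, 4 + 4
samples).  Which dispersion variant the classical NB count tests used is
not fixed by convention; this one is chosen for being simple, honest about
its direction of error, and testable.

**Masking.** A community-level trend can contradict the trend within the
dominant contributing species when that species' share of the whole
metatranscriptome shifts between conditions.  `ec_mwu_test()` evaluates
each EC at both normalization levels (the species level evaluates the EC
within its dominant contributor) and `detect_masking()` flags features
significant at both levels with opposite directions.  The canonical
synthetic scenario (`simulate_masking_scenario()`) uses a 12-species
community in which one species' output drops to 1/16 on the second diet
while one of its genes is up-regulated 4-fold within the species: the
community view shows a 4-fold *decrease*, the species view a 4-fold
*increase*.  The load shift is deliberately larger than the within-species
effect — masking only exists when the share shift dominates — and the
magnitudes are chosen so that, under the generator's dispersion of 0.05,
four-versus-four complete separation (exact p = 2/70) is attained at both
levels in essentially every seed.  The shifted species carries one
additional null EC: any exchangeable null EC has an irreducible 2/70
chance per seed of spurious complete separation at the species level, so a
scenario with many null ECs on the shifted species would produce
occasional extra flags not through any defect of the detector but through
the granularity of the exact test.

**Response kinetics.** Over a diet phase, the net change is the phase-end
minus switch-day value.  Changes below a response floor (default a quarter
of the trajectory's dynamic range) are `none`; otherwise `rapid` means at
least 2/3 of the net change within two days of the switch, `delayed` means
at most 1/3 early and at least 2/3 accruing in the final inter-sample
interval, `gradual` anything between.  The 1/3 and 2/3 thresholds are
package choices made for symmetry; the qualitative classes they formalise
(immediate, steady, end-of-phase) are the standard reading.

**Array-style calls.** A gene is present when detected in at least 5 of 7
animals on at least one diet (`ceiling(5/7 * n)` for other group sizes).
Differential expression requires p < 0.01 and a symmetric fold change of
at least 2.  The p-value comes from a regularized t-statistic whose
per-gene variance is shrunk toward the mean variance of a window of genes
with similar mean expression (window 101 genes, prior df 10) — the same
idea as the Bayesian-regularized t tools used with small-n array data.  A
posterior probability of differential expression is accepted as an
optional input (threshold 0.99) but not computed; when absent the rule
uses p and fold change only.

**Clustering.** Average-linkage hierarchical clustering on correlation
distance with ordinary bootstrap support: the fraction of
feature-resampled trees containing each original cluster's exact leaf set.
Supports above 0.95 are conventionally "strongly supported".  This is the
plain bootstrap proportion, not the multiscale-bootstrap AU value;
ordinary proportions are known to be conservative for large clusters.

## Theoretical peptidome

Proteins are digested in silico with the classical trypsin rule (cleave
C-terminal to K/R, suppressed before P), keeping fragments with up to a
maximum number of missed cleavages.  Peptide masses are monoisotopic
residue sums plus one water (18.01056 Da), unmodified; the default index
window is 600–4890 Da with at most 1 missed cleavage.  These index
defaults are deliberately distinct from typical database-search settings
(which may allow up to 4 missed cleavages); both are parameters.  A
peptide is **unique** when its sequence occurs exactly once in the whole
composite database (community proteomes + host + distractor species +
contaminants); a peptide occurring at two loci of one protein is nonunique
under this default occurrence definition, with the per-protein collapsed
reading available behind a flag.  Per-species summaries report each
species' unique fraction and its contribution to the pool of unique
peptides (contributions sum to 100%).  Initial methionines are not
removed and no semi-tryptic fragments are generated.

## Spectral-count proteomics

Raw spectral counts arrive per protein, sample and technical run (two runs
per sample in the emulated design).  **NBC** divides by the run's total
community spectra, **NBS** by the run total of the protein's species
(missing, not zero, when the species is absent from a run).  A protein is
**present** in a sample at ≥ 4 raw spectra summed over the sample's runs;
it is **eligible** for testing with ≥ 3 valid runs, a valid run having
strictly more than 5 spectra.  Eligible proteins are tested between diets
with the exact Mann–Whitney test on normalized per-sample values (runs are
averaged within samples: runs are the unit of eligibility, samples the
statistical unit).  q-values follow Storey's procedure: pi0 estimated on a
lambda grid (0.05–0.95) with a cubic-smoother extrapolation, falling back
to pi0 = 1 (Benjamini–Hochberg) below 20 p-values where the smoother is
unstable.  Under NBC, q-values are computed over all proteins; under NBS,
within each species' set.  A call is **UP** when p < 0.05, q < 0.05 and
the group-median raw-count difference exceeds 5 (strictly); DOWN
symmetric; otherwise NULL.  Both raw and normalized median differences are
reported because the count-difference rule is stated on counts while the
test runs on normalized values.  Note the granularity interaction: with
four samples per group the exact test's smallest p is 2/70, so q < 0.05
requires a reasonably large set of concordant discoveries; with two
samples per group (as in minimal designs) the test cannot reach
significance at all — a power limitation of the design, not of the
implementation.

RNA–protein agreement is summarised as the Pearson correlation of paired
log fold-changes, overall and within functional categories of at least
three genes, computed only over genes detected in both assays on both
diets.

## PUL activation

Adjacent susC-followed-by-susD gene pairs within a PUL (allowing up to one
intervening gene by default) mark polysaccharide utilization loci.
Expression on each substrate is compared to the minimal-medium-glucose
reference as (value + 1) / (mean reference + 1) per replicate.  A pair is
**reported** when either gene exceeds 100-fold in at least one replicate;
it is **activated** when *both* genes exceed 100-fold in at least two
replicates *and* both genes' mean fold-change across all replicates
exceeds 100.  All comparisons are strict: exactly 100-fold never counts.
The mean is arithmetic by default with a geometric option, since the
convention does not say which; with two replicates the two-replicate
clause means both must pass.  In-vivo cross-referencing labels a pair
expressed at the RNA level when both genes are detected in ≥ 5 of 7
animals and at the protein level when detected in all (2 of 2) animals,
upgrading to "expressed_significant" when the pair is differentially
expressed.

## INSeq fitness

Input and output libraries are normalized to within-population proportions;
a mutant's fitness is its output proportion over its input proportion.
Mutants absent from the output — and any computed ratio below 0.01 — are
reported at the 0.01 floor with a flag, matching the convention of plotting
undetectable mutants as "<0.01"; the raw ratio is retained.  Mutants absent
from the input cannot be normalized and are excluded.  Gene-level fitness
is the arithmetic mean over insertions within the first 80% of the gene
(3'-proximal insertions may not disrupt function); genes with no
qualifying insertion are absent from the output.  Library statistics
(percent ORFs covered, mean insertions per covered ORF) use the same
first-80% rule.  Because fitness is *relative* representation, simulations
in which the selected gene is a large fraction of the library inflate all
other ratios; recovery fixtures therefore use 40 ORFs so the selected gene
is a realistic, small share.

## Growth phenotyping

Curve summaries are deliberately raw: A_max and A_min are the extreme
OD600 readings (each at the earliest time attaining it — the tie rule when
extrema repeat), total growth A_tot = A_max − A_min, and rate =
A_tot / (t_max − t_min), zero (flagged) when the extrema coincide in time.
No blank subtraction, log-phase fitting or parametric growth model is
applied, because the summarised statistics are defined on raw extrema; an
optional centred moving average is available but off by default, and its
use is recorded by the caller.  A culture **grew** when A_tot reaches a
threshold (default 0.1 OD, configurable; the growth/no-growth criterion is
a package decision).  Replicates aggregate as mean ± sample SD, and
per-substrate winners are the species with the highest mean rate among
growers, ties reported jointly.

## The simulator

`synthetic_design()` fixes the study conditions; all randomness flows from
its single seed, and identical designs reproduce every output
byte-identically.  Defaults: 12 species, two diet groups with 4 animals
each (the size of the emulated RNA-Seq arm; array-style rules scale their
5-of-7 threshold to the group size), negative-binomial dispersion 0.05 —
a typical biological-replicate dispersion for moderately expressed genes —
and an expected sequencing depth of 2e5 counts per sample, which keeps
desk-scale runs fast while leaving counting noise negligible relative to
the dispersion.  Genomes are uniform random DNA with evenly spaced gene
models; homology between species is modelled as copied blocks with point
substitutions at (100 − identity)% of positions — far simpler than an
evolutionary model, but it produces the two consequences the analyses care
about: ambiguous reads and shared peptides.  Proteins are random
amino-acid strings per gene, copied (with the same substitution rate)
for genes inside homology blocks.  Reads sample species proportionally to
abundance × genome length (shotgun reads sample DNA mass), uniform
positions, both strands, optional per-base substitution error, no quality
model.  Spectral tables split sample counts into two technical runs by
binomial thinning (p = 0.5).  Insertion libraries place mutants uniformly
over the concatenated genome and draw output counts multinomially with
weights input × fitness.  Growth curves are lagged logistics rescaled to
attain the initial OD at t = 0 and the carrying capacity at the end of the
run exactly — so noise-free total growth equals capacity − initial to
machine precision — with additive Gaussian noise clamped at 0 OD.

What the generator does **not** emulate: realistic error and quality
profiles, GC and fragment-length bias, phylogenetically structured genome
evolution, peptide detectability and run-to-run retention variation,
insertion-site preference.  Tests passing on these synthetics demonstrate
the correctness of the implemented rules and estimators under the stated
models, not robustness to every artefact of real instruments.

## Problem sizes and determinism

The test and acceptance workloads use desk-scale sizes chosen so the whole
suite runs in well under a minute per module: toy genomes of 0.4–3 kb for
oracle comparisons, 1e5 reads for proportion recovery, 1000 random
proteins (≤ 200 aa) for digestion/uniqueness oracles, 1000 features for
test-size checks, 100 seeds for the masking end-to-end rate, 3000-mutant
insertion libraries, and 72 h growth curves at 0.5 h resolution.  Every
stochastic check runs under a fixed or caller-supplied seed.
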