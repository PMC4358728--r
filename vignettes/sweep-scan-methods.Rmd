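---
title: "Methods: diversity statistics, sweep scans and nucleotide fixation in divsweep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diversity statistics, sweep scans and nucleotide fixation in divsweep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(divsweep)
```

# Scope and model

`divsweep` analyses a multi-population panel of biallelic SNVs — the setting
of crop domestication genomics, where a wild progenitor, traditional
landraces and modern elite cultivars are resequenced together. The package
asks three questions of such a panel:

1. How much nucleotide diversity was lost across the two breeding
   transitions (wild → landrace "domestication", landrace → elite
   "improvement")?
2. Where in the genome did artificial selection act (selective sweeps)?
3. Which individual variants became *fixed* in one population while still
   polymorphic in another, and what do they do to coding sequence?

All statistics operate on a `genotype_matrix`: diploid genotype codes
(0 hom-ref / 1 het / 2 hom-alt / −1 missing) at coordinate-sorted biallelic
sites. Each diploid sample contributes two alleles; per-site allele counts
use only non-missing calls.

# Windowed diversity statistics

Windows default to 20 kb sliding in 2 kb steps. Terminal partial windows
are dropped so every retained window has identical span and the genome-wide
Z standardization below compares like with like; a chromosome shorter than
one window collapses to a single logged whole-chromosome window.

Per window we report:

* **θπ** — the sum over sites of the unbiased per-site heterozygosity
  `2 c (n − c) / (n (n − 1))` (c alternate alleles of n at the site),
  divided by the window span. Each site uses its *own* n, so missing data
  shrink a site's weight rather than biasing it.
* **θw** — `S / (a1 · span)` with `a1 = Σ 1/i` up to n − 1, evaluated at
  the window's *median* haploid sample size (per-site n varies under
  missingness; the median is robust and exact when data are complete).
* **Tajima's D** — `(Θπ − S/a1) / sqrt(e1 S + e2 S (S−1))` on window
  totals, constants from the classical 1989 formulation at the median n.
  Undefined when S = 0; undefined windows are excluded from scans and can
  never be selected.

Per-site denominators use the full window span by default, matching a
per-nucleotide framing; a `denominator = "callable"` flag divides by the
number of genotyped variant sites instead (per-variant-site diversity),
since which convention an upstream pipeline used is often unknowable.

The diversity-reduction summary expresses everything relative to the wild
baseline: retention `100·θπ_cult/θπ_wild`, domestication reduction
`100·(θπ_wild − θπ_landrace)/θπ_wild`, improvement reduction
`100·(θπ_landrace − θπ_elite)/θπ_wild`. The two reductions telescope to
the total wild-to-elite loss, which is why the improvement term is scaled
by wild (not landrace) diversity.

```{r}
diversity_reduction_summary(3.84e-3, 2.40e-3, 2.08e-3, 2.25e-3)
```

# Sweep scans

**Domestication (bottleneck-model scan).** Per window, the log ratio
`ln((θπ_cult + δ)/(θπ_wild + δ))` and cultivated Tajima's D. The raw ratio
is heavily right-skewed; the log restores approximate normality, and the
pseudocount δ = 1e-5 (per site, ~3 orders below typical diversity) keeps
zero-diversity windows finite without masking them. Both statistics are
standardized genome-wide and converted to lower-tail normal P values; a
window is selected when **both** fall below α = 0.05.

**Improvement (population-branch scan).** Per window, Hudson Fst for the
three population pairs, the branch transform `T = −ln(1 − Fst)` (Fst
clamped to [0, 1 − 1e-6]), and the elite branch length
`PBS = (T_el + T_ew − T_lw)/2`. PBS is standardized genome-wide; the
upper-tail P is Bonferroni-corrected by the number of defined windows and
compared to 0.001. Because windows overlap 10-fold at the default
geometry, this correction is conservative; corrected-P < 0.001 and
raw-P < 0.001/N coincide under this implementation, so the two readings of
"P < 0.001 after Bonferroni" are equivalent here.

**Z calibration by sigma clipping.** The mean and standard deviation
behind each Z score are estimated with iterative 3σ clipping: windows
beyond three estimated SDs are removed and the moments re-estimated until
stable, then every window is scored against the final estimates. On a real
genome sweeps occupy a fraction of a percent and clipping changes nothing
measurable. On compact validation genomes (2 Mb with ten injected sweeps,
~10 % of windows sweep-elevated) the plain moments are contaminated by the
very signal being hunted: the inflated SD caps attainable Z below the
Bonferroni threshold and the scan loses all power regardless of effect
size. Clipping removes that self-masking while leaving sweep-free null
genomes essentially untouched (it discards ~0.1–1 % of windows there).

**Fst estimator.** Hudson's ratio-of-sums is the default: per usable site
(≥ 2 alleles in both groups) numerator
`(p1−p2)² − p1(1−p1)/(n1−1) − p2(1−p2)/(n2−1)` and denominator
`p1(1−p2) + p2(1−p1)`, summed across the window before dividing. It is
robust to the unequal sample sizes typical of these panels (31/15/24
accessions). A Weir–Cockerham 1984 variant sits behind
`estimator = "wc"` since the generic "Fst" of an upstream description
cannot be pinned to one estimator.

Selected windows merge into regions by interval union (overlapping or
book-ended windows join); region min-P is the best member window.

A configurable exclusion list removes named accessions before grouping,
because published panels sometimes drop individual samples from scans
without stating reasons; exclusion is configuration, not inference.

# Nucleotide fixation

A fixation locus is a site where every sample of the focal group carries
the *same* genotype code while the comparison group shows at least two
codes. Identity of code — not homozygosity — is the criterion; a uniformly
heterozygous focal group technically qualifies but is biologically
implausible (it would require a balanced duplication or universal
heterozygosity) and is therefore flagged rather than dropped. Detection
requires a consensus matrix without missing calls; `assign_ml_genotypes()`
produces one by taking, per sample and site, the genotype with maximal
likelihood (ties → lowest code, counted; all-zero triples → missing,
counted).

Fixation loci are annotated with sweep-region membership, the wild
alternate-allele frequency (the standing frequency of the fixed allele
before selection), and a coding effect. Effects are classified by locating
the site in the spliced, phase-adjusted CDS of the overlapping gene model
(longest-CDS transcript per gene by default), assembling the codon —
reverse-complementing on minus-strand genes and joining codons across
splice junctions — and translating reference versus alternate with the
standard nuclear code. Genes whose CDS length is not a multiple of three
are skipped with a warning and the effect left `unclassified`.

# Population structure

PCA uses the standard genotype normalization: center by twice the allele
frequency, scale by `sqrt(p(1−p))`, mean-impute missing calls, drop
monomorphic sites, and decompose by SVD. The neighbor-joining tree is
built on allele-sharing distances (mean of `|code_i − code_j|/2` over
co-genotyped sites; a raw mismatch option exists) — the distance choice is
this package's, as tree-building conventions differ between tools.
Negative NJ branch lengths are retained and flagged rather than clamped so
that additive matrices invert exactly (a property the tests rely on).
Bootstrap support resamples sites with replacement (default 1000
replicates; validation suites use ~25–100 since support of deep splits
saturates far earlier) and reports the fraction of replicates containing
each internal bipartition of the full-data tree.

# QTL narrowing and enrichment

QTL intervals are intersected with sweep regions that contain at least one
fixation locus ("qualifying" regions; a flag relaxes this to all regions).
Summaries are computed on interval unions so overlapping QTLs are not
double-counted, hence retained ≤ input Mb always. Genes map to regions by
any-overlap of the gene span. Category enrichment uses the one-sided
hypergeometric (Fisher) test plus a permutation test drawing random gene
sets of the observed size — empirical P `(1 + #{k* ≥ k})/(reps + 1)`, so it
is never zero — with Benjamini–Hochberg q-values across categories.
Permutation resamples genes uniformly and ignores gene length; with
length-biased selection signals this understates P, a documented
limitation. The enrichment background is always an explicit argument:
results are only interpretable relative to a stated gene universe.

# The synthetic-data generator

The generator emulates the statistical structure the analysis assumes,
not a full coalescent:

* **Standing variation.** Segregating-site count
  `S ~ Poisson(θ · a1 · L)`; wild derived counts from the neutral spectrum
  `P(i) ∝ 1/i`; this yields wild per-site θπ converging to the configured
  θ (default 3.84e-3, a realistic wild-soybean value).
* **Nested bottlenecks.** Landrace frequencies are binomial resamples of
  wild frequencies through a founder pool whose size is mixed between k
  and k+1 per site so that expected heterozygosity retention equals the
  configured fraction exactly (a single integer pool only reaches
  1 − 1/k). Defaults 0.625 (landrace/wild) and 0.867 (elite/landrace)
  reproduce the observed group-diversity ratios. The generator exposes
  retention fractions rather than effective population sizes — a
  deliberate modelling stand-in, since realistic Ne values for these
  populations are not established.
* **Sweeps.** Inside each sweep interval, a site hitchhikes to fixation
  for the allele on the beneficial haplotype with probability
  `1 − sqrt(f)` (f = relative distance from the focal site) and otherwise
  escapes with a `sqrt(f)`-ramped frequency, so expected heterozygosity
  follows a linear ramp to zero at the focal site. This yields all three
  sweep signatures at once: diversity loss, truly fixed linked sites
  (elevated fixation density), and high-frequency escapees (negative
  Tajima's D). Domestication sweeps transform landrace and elite with a
  *shared* haplotype outcome; improvement sweeps transform elite only.
  The focal beneficial allele is the alternate and is forced to frequency
  1 in the selected populations, with the comparison population kept
  polymorphic.
* **Genotypes and reads.** Hardy–Weinberg sampling within population;
  likelihoods from a Poisson(10) depth and 1 % per-read error binomial
  model, matching low-coverage resequencing.
* **Determinism.** All randomness flows from the config seed; identical
  configs give bit-identical outputs.

What the generator does *not* emulate: linkage disequilibrium between
sites (windows are exchangeable given frequencies — acceptable because
every statistic here is single-site within windows), recombination-graph
genealogies, gene conversion, realistic chromosome counts/sizes, and
population admixture. Passing recovery tests on this generator therefore
demonstrates the statistical machinery, not robustness to LD-driven
false-positive structure in real data.

# Validation problem sizes

The shipped suites run the scans on 2 Mb single-chromosome genomes with
five 40 kb sweeps per transition across 20 seeds, null calibrations on
sweep-free genomes of the same size (domestication: fully panmictic;
improvement: landrace and elite drawn from one bottlenecked population),
oracle checks on ≤ 30-sample fixtures, and a full pipeline run on a
smaller genome. These sizes were chosen so the statistical claims (≥ 90 %
sweep recovery, null false-selection bounds, oracle agreement) are tested
at meaningful replication while the suite stays interactive.

# Known limitations

* Z-test calibration assumes approximate normality of the window
  statistics; the PBS null is mildly right-skewed, so the Bonferroni
  guarantee is approximate (observed: at most one seed in twenty shows a
  false selection on null genomes).
* The derived allele is equated with the alternate allele for spectra —
  an approximation whenever the reference itself carries derived states.
* Rarefaction defines "detected" as ≥ 1 sampled accession carrying ≥ 1
  alternate allele, i.e. discovery against the reference.
* Coding-effect classification evaluates one substitution at a time;
  compound codon changes from multiple nearby fixations are not combined.
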