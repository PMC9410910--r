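---
title: "Methods: simulating and measuring germline mtDNA mutagenesis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and measuring germline mtDNA mutagenesis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mitoduplex)
```

# What this package models

Mutation-accumulation (MA) experiments in *C. elegans* propagate each
lineage through a single randomly chosen L4 individual every generation.
Because the effective population size is one, selection is nearly
powerless and new mutations accumulate at close to the mutation rate,
while heteroplasmy (the fraction of mtDNA copies carrying an allele)
drifts through the germline bottleneck of roughly 60 transmitted copies.
Duplex Sequencing of these lines detects single-nucleotide mutations at
frequencies of 10⁻⁷–10⁻⁸ per base pair by requiring that a mutation be
observed independently on both strands of one original DNA molecule.

`mitoduplex` implements that whole measurement chain as testable code:
lineage simulation with ground truth, UMI-tagged read-family simulation
with realistic error strata, duplex consensus calling with the standard
filters, and the downstream statistics (frequency, spectrum, strand bias,
trinucleotide signatures, dN/dS, cross-group tests).

# The bottleneck simulator

Each generation has two phases:

1. **Mutation.** The pool of `copy_number` genome copies acquires
   `Poisson(copy_number × Λ)` new mutations, where `Λ` is the summed
   per-site per-generation rate over targeted positions. A site's rate is
   its strand-resolved class rate (12 classes, e.g. `C>A` vs `G>T`
   separately) times an optional multiplier on its 96-channel
   (class × trinucleotide context).
2. **Drift.** The next generation's pool is one multinomial resample of
   `copy_number` copies — the single-individual bottleneck collapsed into
   one Wright–Fisher step. Intra-generational copy-number dynamics are
   deliberately not modeled: they are unidentifiable from an MA design
   that transmits through one individual per generation.

Neutrality makes heteroplasmy a martingale, which the test suite verifies
by Monte-Carlo (10,000 replicate lineages started at h = 0.5 stay at mean
0.5 within 3 standard errors, while individual lineages fix or lose the
allele).

Numerical choices worth knowing:

* Rates are keyed to the **reference** base even after a site mutates; a
  second hit replaces the stored allele, and an event's alternate base is
  drawn from the three non-reference bases. At the per-site rates used
  anywhere in this package (≤ 1e-4/generation) double hits are vanishingly
  rare, so this bookkeeping choice has no measurable effect; it is stated
  here because it means literal back-mutation to the reference never
  occurs.
* `expected_mutation_count()` returns `Λ × generations`: the expected
  number of events along one **line of descent** (per transmitted copy),
  not the `copy_number`-fold larger count injected into the whole pool.
  The Monte-Carlo check divides the pool event count by `copy_number`,
  which has the same expectation because every copy accumulates events at
  the same rate.
* Selection is deliberately absent: dN/dS ≈ 1 is the package's null, so
  the simulator must not encode fitness effects.

# The read simulator

A molecule is a fragment with uniform start over positions whose whole
fragment lies in the capture target (circular wrap allowed when the
target permits). Fragment lengths default to Normal(300, 30) floored at
25 bp; strand-family sizes default to a zero-truncated negative binomial
with mean 6 — a documented free choice, since real family-size
distributions depend on library tuning that is not part of this model.

Error strata, in the order they enter:

| stratum | default | scope |
|---|---|---|
| true variant | Bernoulli(h) | per molecule, both strands |
| PCR error | 1e-5 /base | per strand family, all of its reads |
| sequencing error | 1e-3 /base | per read |
| end artifact | 1e-4 /base | per read, within 12 bp of fragment ends |

This layering is what gives the consensus caller something real to
suppress: sequencing errors are strand- and read-confined; PCR errors are
strand-confined but family-wide (they survive SSCS and must be killed by
duplex disagreement); end artifacts motivate the 12-bp clip.

What the generator does **not** emulate: UMI sequencing errors and family
collisions (rate parameter exists, defaults to 0), chimeras, mapping
ambiguity, and nuclear insertions of mtDNA (NUMTs). A green test
therefore establishes correctness of the consensus arithmetic and the
statistical machinery, not robustness to alignment artifacts of real
capture data.

# Consensus calling

Families are keyed by (canonical UMI pair, fragment start, fragment
length); including coordinates in the key prevents UMI collisions across
loci. Per strand family, an SSCS needs at least `min_reads = 3` reads,
and each position needs a within-family majority of at least
`consensus_frac = 0.70` (inclusive — a 7/10 column is called); otherwise
the position is masked `N`. The DCS keeps a base only where both SSCS
agree and neither is masked, and always masks the first and last
`clip = 12` bp of the fragment.

Two readings of the published filter wording are possible: the minimum
read count could apply per strand family or per molecule, and the 70%
cutoff at SSCS or DCS level. This package follows the Duplex-Seq
convention — both at SSCS level — and exposes both as parameters
(`min_reads`, `consensus_frac`), so the other reading is one argument
away.

Variant calls deduplicate to unique (position, alternate) pairs per
sample; distinct alternates at one position are distinct variants by
default (`strict_per_position = TRUE` gives the stricter
once-per-position reading). Denominators — error-corrected nucleotides,
per-reference-base and per-context sequenced counts — accumulate over
unmasked positions of on-target DCS only, because the frequency formulas
divide by what was actually interrogated, not by genome composition.
Fixed polymorphisms (allele fraction ≥ 0.99 in **all** samples) are
removed as strain background rather than de novo mutations.

# Statistics

* **Overall frequency** = unique variants / error-corrected nucleotides.
* **Class frequencies** pool each substitution class with its complement
  and divide by the matching sequenced-base total (C and G for C-classes,
  T and A for T-classes).
* **Strand asymmetry** compares each class against its complement with an
  exact two-sided binomial test at p = 1/2, Bonferroni-adjusted over the
  pairs tested.
* **Trinucleotide signatures** are 96-vectors (6 pyrimidine-centered
  classes × 16 flank combinations). Three normalization modes carry an
  explicit tag, because "relative contribution" is ambiguous in the
  field's usage: `raw` counts; `occurrence` (counts divided by the
  targeted genome's context occurrences — a rate per available site); and
  `relative` (elementwise ratio to a baseline, e.g. the mean raw vector
  of a control group, with division-by-zero entries reported as missing
  rather than imputed). Cosine similarity excludes undefined entries
  pairwise and reports the effective dimension used.
* **dN/dS** is a transparent counting estimator:
  `(dn_obs/dn_exp)/(ds_obs/ds_exp)`, with expected counts from exhaustive
  enumeration of all coding substitutions under translation table 5
  (TGA = Trp, AGA/AGG = Ser, ATA = Met), optionally weighted per 96-channel
  by the sample's mutation rates so a biased spectrum is not mistaken for
  selection. Nonsense changes count as nonsynonymous (stop-loss too). The
  CI is a seeded percentile bootstrap over variants; the expected-site
  weights are held fixed across resamples. This estimator intentionally
  does **not** reproduce covariate-regression dN/dS software numerically;
  only the neutrality diagnostic (≈ 1, CI covering 1) is the target, and
  a 200-replicate calibration test holds its 95% CI coverage at ≥ 90%.
  Variant sets may be pooled across lines or computed per line — both are
  just different `variants` inputs to `dnds()`.
* **Group comparisons**: Welch t, ANOVA + Tukey HSD, Fisher's exact with
  Bonferroni. Two-way ANOVA uses Type II sums of squares (configurable to
  Type I) because MA-line extinctions make designs unbalanced and the
  published analyses do not state an SS type; without within-cell
  replication the saturated model has no residual degrees of freedom, so
  the table falls back to the additive model. Fisher tests larger than
  2×2 use exact enumeration up to table total 200 and a seeded
  Monte-Carlo p above it, with the method stated in the output.

# Synthetic genome

`generate_synthetic_genome()` emulates an animal mtDNA: compact, AT-rich
(default GC 0.24), circular, ≥ 80% tiled by protein-coding genes under the
invertebrate mitochondrial code, plus one non-coding AT-rich interval
(default 500 bp) that the capture target excludes — the analogue of the
repetitive region that hybridization panels skip. Genes are coordinate
annotations over random sequence; internal stop codons are not purged,
which is harmless because observed and expected dN/dS counts use the same
classification of the same sequence. Coordinates are 0-based half-open
internally everywhere; TSV/VCF exporters emit 1-based positions, BED
stays 0-based per its standard.

# Tolerances and degenerate inputs

* The 70% consensus threshold is applied as `count ≥ ⌈frac·n − 1e-9⌉`,
  making the boundary inclusive and immune to floating-point noise.
* Ties in a consensus column cannot pass any threshold > 0.5; at
  thresholds ≤ 0.5 the lexicographically first base wins,
  deterministically.
* Zero-generation or zero-rate simulations return empty truth tables;
  empty truth is a valid reference-only library; zero molecules is an
  error.
* `dnds()` with zero observed synonymous variants returns an explicitly
  undefined ratio with its counts, rather than infinity.
* A cosine similarity against a zero vector is an error, not 0.

# Known limitations

* Consensus ignores base qualities (the simulator emits constant Q30).
* No indel calling anywhere; insertions and deletions are out of scope.
* The naive 31-mer seed-and-extend mapper is a convenience for external
  FASTQ, not a competitive aligner.
* The worked-example verifier checks in-print arithmetic of the
  motivating study; one printed figure (the per-line average, 70) is the
  authors' own rounding of 760/11 = 69.1 and carries an explicit
  tolerance of 1 in the verifier. No other empirical claim is made that
  the tests or the acceptance script do not themselves compute.
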