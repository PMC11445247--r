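---
title: "Ploidy inference from allele balance: model, parameters, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ploidy inference from allele balance: model, parameters, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radploidy)
```

## The model

At a heterozygous biallelic site in an individual carrying *m* segregating
allele copies, an unbiased sequencer samples reads from the two alleles in
proportion to their dosage: a site where *d* of the *m* copies carry the
alternative allele yields alternative-read counts distributed as
Binomial(*D*, *p*) at depth *D*, with

$$p = \frac{d}{m}(1 - e) + \left(1 - \frac{d}{m}\right)e,$$

where *e* is the per-read miscall probability pulling both homozygote
classes towards the interior. Pooling many such sites, the density of
alternative-allele fractions concentrates around the error-adjusted dosage
fractions *k/m*, *k* = 1..*m* − 1 — one mode at 0.5 for *m* = 2, two modes
near 1/3 and 2/3 for *m* = 3, three near 1/4, 1/2, 3/4 for *m* = 4. The
caller inverts this: it estimates the density, finds its modes, and asks
which *m* explains them.

Two assumptions matter:

* **Subgenome specificity (diploidization).** In a diploidized
  allopolyploid, most reduced-representation loci map to exactly one
  subgenome, so the copy number visible in allele balance is
  ploidy / 2. `cytotype_factor` (default 2) converts the effective copy
  number to the reported cytotype: *m* = 2 → "4x", *m* = 3 → "6x",
  *m* = 4 → "8x". For an autopolyploid whose loci segregate across all
  homologues, set `cytotype_factor = 1`.
* **Unbiased sampling at usable depth.** Mapping bias, paralog collapse and
  extreme depth distort allele balance; the filters below exist to keep
  such sites out rather than to model them.

## Site filters

`filter_config()` defaults:

| parameter | default | why |
|---|---|---|
| `min_total`, `max_total` | 20, 200 | below ~20 reads the binomial spread blurs adjacent dosage modes; far above the typical coverage, sites are enriched for collapsed repeats |
| `min_alt` | 7 (strictly more, i.e. ≥ 8 reads) | an allele seen 8+ times at depth ≥ 20 is very unlikely to be a sequencing artefact |
| `min_ref` | 7, disable with `NA` | symmetric requirement restricting the histogram to confidently heterozygous sites; the ploidy signal lives in the interior modes, not in the 0/1 boundary mass |
| `min_mapq` | 20 | operationalises "uniquely mapped reads" on the alignment path |
| `min_baseq` | 13 | standard pileup base-quality floor |
| `fraction_window` | [0.05, 0.95] | trims residual homozygote and error mass |

Whether the "more than 7 reads" support rule should bind the alternative
allele only, or each allele, is genuinely open; both are exposed and the
symmetric version is the default (`min_ref = NA` disables it). Fractions
are computed per SNP, not pooled per locus. On the alignment path, sites
where a third base exceeds 10% of the column depth are discarded outright
(paralog-collapse paranoia), and organellar contigs can be excluded by
name, since organellar stoichiometry has nothing to do with nuclear ploidy.

## Density, modes, and scoring

* **KDE**: Gaussian kernel, bandwidth 0.02 on the fraction axis, 512-point
  uniform grid on [0, 1], renormalised to integrate to 1 (trapezoid,
  tolerance 1e-6). The bandwidth must resolve the tightest pair of
  competing expectations — 1/3 vs 1/4, a gap of 0.083 — at realistic
  depths; 0.02 does so while still smoothing binomial noise at depth 20–60.
* **Mode detection**: local maxima filtered by topographic prominence
  (≥ 10% of the global maximum) with a minimum separation of 0.08;
  when two qualifying peaks are closer than that, the more prominent one
  wins. A near-flat density yields at most its global maximum.
* **Peak-match score**: detected modes are greedily matched to the
  error-adjusted dosage fractions within a tolerance of 0.06 (just under
  the 1/3 − 1/4 gap); the score is
  `n_matched − n_unmatched_expected − n_unmatched_observed`.
* **Octoploid plateau**: empirically, octoploid-class samples often show a
  broad interior mass between roughly 0.35 and 0.65 instead of three
  resolved peaks — adjacent dosage modes 0.25 apart merge at modest depth.
  The *m* = 4 candidate therefore also matches a plateau: at least 70% of
  the density mass inside [0.3, 0.7] with no dominant single mode (a lone
  0.5 peak at least twice the shoulder density is a tetraploid signature,
  not a plateau). How such a plateau should be discriminated from the
  hexaploid bimodal pattern is not prescribed anywhere; this rule is this
  package's design choice, and deliberately produces a *tie* on the peak
  score that the mixture criterion then breaks.
* **Mixture criterion**: a beta mixture with component means fixed at the
  error-adjusted dosage fractions, free weights, and one shared
  concentration parameter κ. At fixed κ the weights are fitted by EM from
  a deterministic uniform initialisation (tolerance 1e-6, cap 500
  iterations); κ is profiled out by golden-section search over
  [2, 10⁴] on the log scale. Candidates are compared by BIC with K free
  parameters per K-component candidate (K − 1 weights + κ), penalising
  larger copy numbers. Fixing the means keeps the fit identifiable and the
  comparison honest: each candidate may only explain the data where its
  dosage model says the data should be.
* **Call selection**: highest peak score wins; ties go to the lower BIC,
  then to the smaller *m*. A call is flagged `ambiguous` when the top two
  candidates tie on peaks and sit within 10 BIC units, and `low_sites`
  (with a warning, but still emitted) below 200 retained sites. Everything
  is deterministic: the same profile and configuration serialize to the
  same call, bit for bit.

Mirror symmetry is built in: the expected dosage fractions are symmetric
about 0.5 and the error adjustment preserves that symmetry, so relabelling
alleles (f → 1 − f) cannot change the reported ploidy. Odd effective copy
numbers report odd × factor cytotypes (m = 3 → "6x"); aneuploidy and
mixoploidy are out of scope and surface as `ambiguous` at best.

## The simulator: what it emulates, what it does not

`simulate_sample()` draws, per site, a dosage from `dosage_weights`
(default uniform over 1..m − 1), a depth from `depth_law` (uniform 25–60
by default — bracketing a typical RAD-seq mean coverage near 30 — or
negative binomial), and an alternative-read count from the binomial model
above (`error_rate` 0.005 by default, a typical post-filter Illumina
miscall rate). An optional `hom_fraction` adds homozygous-alternative
contaminant sites, which the standard filters should strip. A single seed
governs everything, with per-site substreams derived from the site index,
so enlarging `n_sites` extends a dataset without reshuffling existing
sites, and exports are byte-identical across runs.
`simulate_admixed_sample()` draws each site from one of several parent
laws with given mixing proportions — a crude contact-zone individual.

The generator emulates exactly the signal the caller reads: binomial
allele sampling at subgenome-specific heterozygous sites. It does **not**
emulate mapping bias, reference bias, linked loci, RAD locus dropout,
paralog collapse, GC-dependent coverage, or base-quality structure. A
passing recovery suite therefore demonstrates that the caller inverts its
own generative model reliably at realistic depth and site counts — not
that every real library will be as clean; the coverage filters are the
guard against precisely the artefacts the generator omits.

## The admixture and flow-cytometry calculus

* **Expected ploidy** of an admixed individual is the plain weighted sum
  Σ wᵢ pᵢ of lineage ploidies, rounded half-away-from-zero to one decimal
  (0.77·8 + 0.23·4 = 7.08 → 7.1). Proportions are used as given, not
  renormalised: published admixture proportions are rounded and may sum to
  0.99, and the published expectations are the plain weighted sums (a
  departure beyond ±0.05 from 1 warns). Base R's `round()` would round
  half to even and is deliberately not used.
* **Expected F1 ploidy** of two parental lineages is (p₁ + p₂)/2; for
  records with more than two source lineages the F1 column uses the two
  largest-proportion lineages, which reproduces every printed cell in the
  packaged panel.
* **Neoploidy** is a strict comparison up to ε = 0.05, not a ±0.5 band:
  an individual predicted 8x against an expectation of 7.5 counts as
  increased. On the packaged 16-individual panel this yields 14 increased
  and 2 decreased.
* **Flow classification** is nearest-class on the 2C value with class
  means 4x 1.99 pg, 6x 3.09 pg, 8x 3.99 pg (the medians of the packaged
  panel's predicted-ploidy groups); ties break to the lower ploidy, and the
  rule is monotone in genome size. The class set is configurable. On the
  packaged panel of 56 measured individuals the read-based predictions and
  the flow classes agree for 55 (98.2%); the one discrepancy (I12,
  predicted 4x, measured 3.92 pg) is surfaced in the concordance report
  rather than resolved.
* **Inbreeding coefficient**: F = 1 − H·p/(p − 1) for heterozygosity H at
  ploidy p; F ≤ 1 always, can be negative under excess heterozygosity, and
  is strictly decreasing in H.

## Problem sizes and test design

The recovery suite simulates 50 replicates per *m* ∈ {2, 3, 4} at 3000
sites each (depth uniform 25–60, error 0.005) and requires ≥ 95% correct
calls per class; 3000 retained sites is a conservative per-sample yield
for a reduced-representation library and keeps the whole suite in the
one-minute range. The alignment-vs-variant equivalence property runs on a
5 kb synthetic contig with 1 bp reads, where an exact pileup oracle is a
straight tabulation. Monotonicity of recovery in the site count is checked
on the grid {300, 1000, 3000} with common random seeds.

## Known limitations

* Copy numbers above 4 (cytotypes above 8x with the default factor) are
  not in the default candidate set; the dosage modes involved differ by
  less than typical binomial spread at RAD-seq depths.
* The caller assigns one genome-wide copy number; chromosome-level
  aneuploidy, mixoploidy and contaminated libraries violate that premise
  and at best surface as `ambiguous`.
* Admixture proportions and heterozygosities are consumed as inputs, not
  estimated.
* The plateau rule is a heuristic for merged octoploid modes; a sample
  whose true density is broad for other reasons (e.g. heavy mapping bias)
  can match it, which is why the mixture criterion always has the final
  word in ties.
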