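---
title: "Coverage bias and sequencing-error profiling: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coverage bias and sequencing-error profiling: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitocovbias)
```

## The problem

Ultra-deep resequencing of a small, haploid, circular genome — vertebrate
mtDNA recovered as a by-product of whole-genome sequencing — puts tens of
thousands of reads on every position. At that depth the Poisson component
of coverage variation is negligible (CV ≈ `1/sqrt(depth)` ≈ 1% at
10,000X), so observed site-to-site variation in coverage is essentially
all systematic, and per-site minor-allele frequencies of order 0.1% are
measured with useful precision. This package asks, of such data:

1. How does coverage depend on local GC content, base identity and gene
   context?
2. Where do sequencing errors concentrate, and how do error-prone
   sequence motifs relate to local coverage?
3. Which sites show a second allele at intermediate frequency in exactly
   one individual — the signature of heteroplasmy rather than error?
4. What per-base error rate does the k-mer spectrum of the raw reads
   imply, independently of any alignment?
5. How repeatable is the coverage profile across individuals, and across
   distantly related species over homologous regions?

## Coverage geometry

Mapping a circular molecule against a linearised reference starves the two
ends of coverage, so the reference is extended by an `o`-bp copy of its
start before mapping; `fold_circular_overlap()` adds the extension's
counts back onto the first `o` positions (`out[i] = ext[i] + ext[L+i]`),
conserving total read mass. Repeat-rich control-region ends that cannot be
aligned reliably are then removed with `trim_retained_region()`; both
bounds are explicit arguments — the package hard-codes no genome-specific
positions. For the canonical 16,537-bp case, retaining positions
29–15,816 removes 749 bp.

All internal coordinates are 0-based half-open, with 1-based conversion
only at the pileup/BED boundaries, so there is a single conversion point
per format.

Windowing (`window_profile()`) anchors at the first retained site, uses
non-overlapping windows when `step = width`, and discards a trailing
partial window; 15,788 retained sites yield 315 fifty-bp windows, hence
the linear regression's 313 residual degrees of freedom. GC fractions
exclude `N` from numerator and denominator.

## GC dependence

`fit_gc_regression()` is ordinary least squares of window mean coverage on
GC (degree 1) or GC and GC² (degree 2). Models are compared with the
Gaussian profile AIC, `n log(RSS/n) + 2 (degree + 2)`, counting the
residual variance as a parameter; the difference `AIC(quad) − AIC(lin)` is
negative when curvature is supported, and exactly +2 on noiseless linear
data because the RSS is floored at `machine_eps · n · var(y)` to keep
degenerate fixtures finite. For the quadratic, the stationary point
`vertex_gc = −b1/(2 b2)` estimates the GC content of maximal coverage.

The per-base contrast (`at_gc_coverage_ttest()`) uses Welch's
unequal-variance *t*, which matches the fractional degrees of freedom such
analyses report; a pooled test would give integer `n − 2`. The site-level
ANCOVA (`site_ancova()`) fits
`coverage ~ base + gene_type + gc50` with treatment coding and reports
Type II sums of squares — each term adjusted for the others — because the
design is unbalanced and no interaction is modelled; the reference levels
are stated in the output, since factor coding conventions differ between
tools.

## Error structure

The per-site error rate is substitution-only:
`e = (depth − n_consensus)/depth`, with deletion placeholders excluded
from numerator and depth — the definition is phrased in terms of aberrant
nucleotides, and indel calls in pileup data have distinct error modes.
Consensus is the pooled-count majority, ties broken toward the provided
reference, then alphabetically; zero-depth sites are `N` and carry no
rate.

`scan_iupac_motifs()` reports every overlapping occurrence of a pattern
and of its reverse complement (as strand −), optionally wrapping the
origin of a circular sequence; the rotation-invariance of the circular hit
count is property-tested. The error-prone flank of a `+`-strand `CCNGCC`
hit is placed **upstream** (`[start − flank, start)`): the motif lies
directly downstream of the high-error base, so the coverage footprint is
on that side. Sites in overlapping flanks are counted once, at their
minimum distance to a motif edge. The proximity statistic is the Spearman
correlation between coverage and that distance; positive values mean
coverage rises away from the motif. One special case: if every flank site
has identical coverage, the rank correlation is undefined and the
proximity analysis reports `r = 0` (no ordering information), whereas the
general correlation functions report `NA` for constant input.

Heteroplasmy calling screens every non-consensus base at every site:
a call requires exactly one individual at frequency ≥ `high_freq` (default
1%, with depth ≥ 100) while **all** others sit at ≤ `low_freq` (default
0.1%); sites where two or more individuals exceed the high threshold are
reported separately as shared variants. The defaults mirror the observed
separation between carrier frequencies (1.3–67.9%) and the background
error (~0.1%).

## k-mer spectrum

`count_kmers()` is an exact, in-memory counter (canonical by default:
each k-mer identified with the lexicographic minimum of itself and its
reverse complement, since read strand is arbitrary; a flag restores
stranded counting). It is intended for desk-scale synthetic read sets
(≤ ~10⁷ k-mer instances), not production genome data.

The spectrum of deep data is bimodal: error k-mers pile up at low
multiplicity, genuine k-mers peak at the mean k-mer coverage *M*.
`find_error_threshold()` expands the histogram to a dense grid,
`log1p`-transforms, smooths with a 3-bin moving median, and takes the
first local minimum that has a later rise; a strictly decreasing spectrum
is an error prompting a manual cutoff (which, when supplied, is returned
verbatim). *M* is estimated as the instance-weighted mean multiplicity
above the cutoff rather than the histogram argmax: on finite data the
argmax jitters by several bins around the mode, while the weighted mean is
unbiased for a unimodal mode and coincides with the "peak" in the sense of
mean k-mer coverage.

A single-base miscall corrupts up to `k` overlapping k-mers, so the
per-base error rate is the error-instance fraction divided by `k`. Because
a read of length `L` contains `L − k + 1` k-mers, base-level depth is
recovered from the peak as `N = M·L/(L − k + 1)`; this is the inverse of
the k-mer-coverage correction and reproduces reported value pairs such as
`M = 52,000 → N = 68,000` at `k = 25, L = 102`.

## The synthetic cohort

`simulate_site_profiles()` draws, for site *i* and individual *j*,

```
mu_ij = mean_depth_j · q(gc50_i) · s_i · dip_i · eta_ij ,   depth_ij ~ Poisson(mu_ij)
```

* `q(g) = exp(curvature · (g − vertex_gc)^2)`, normalised to mean 1 —
  the GC-dependence of log-mean coverage, defaults `vertex_gc = 0.27`,
  `curvature = −8`;
* `s_i ~ lognormal(0, 0.20)` — a site effect shared by all individuals
  (the reproducible, sequence-intrinsic component);
* `dip_i` — a linear decay from `1 − motif_dip_depth` (default 0.6) at
  the high-error edge of an active motif to 1 at `motif_dip_range`
  (100 bp): the localized coverage drop at SSE motifs, with the true
  functional form unknown;
* `eta_ij ~ lognormal(0, 0.12)` — individual noise.

Base counts are multinomial around the reference base with error rate
`e0 = 0.0011` (0.11%, the HiSeq-scale post-filter rate), raised to
`e_motif = 0.02` at the focal site of an active motif; errors spread
uniformly over the three alternatives, so the expected ti/tv of pure error
is 0.5. Six heteroplasmic (site, individual) pairs receive an alternative
base at a frequency drawn from U(0.013, 0.679). Defaults were fixed once,
from the observed ranges these mechanisms must reproduce: ≈4–8-fold
per-site coverage variation, cross-individual rank correlations around
0.7–0.9, and a mean error rate of 0.11%. With 11 individuals at
`mean_depth = 4000` the default cohort matches the scale of a
deeply-sequenced cohort's *additional* individuals; simulating the
>100,000X focal individual is unnecessary for any of the statistics and
would only inflate run time.

What the generator does **not** emulate: mapping ambiguity and repeat
misalignment (the reason real control regions must be trimmed), read-level
error correlation along fragments, strand asymmetry of SSE errors, indels,
and base-quality structure. Passing tests therefore demonstrate that the
statistics recover what their models assume, not that those models exhaust
real data.

## Design notes on the recovery experiments

* **Vertex recovery.** The quadratic's stationary point is only
  statistically identifiable when the covariate spans both sides of it. At
  a realistic genome GC of ~0.385 the vertex (0.27) sits at the lower
  extreme of the window-GC range — as it does in real data — and the
  linear-scale quadratic fit of an exponential-in-GC mean is then biased
  low by model mismatch. The recovery experiment therefore centres window
  GC on the vertex (`gc_target = 0.27`), where the fit recovers the vertex
  to well within ±0.03 at ~300 windows.
* **Heteroplasmy recovery depth.** At 4,000X the expected count of a
  specific background alternative is `depth · e0/3 ≈ 1.5`, and the 0.1%
  screening threshold is 4 reads — close enough that a non-carrier
  individual occasionally fluctuates above it and costs a call. Perfect
  precision *and* recall are therefore evaluated at 25,000X (well inside
  the ultra-deep regime), where the exceedance probability is ~10⁻⁶; a
  fixed-seed check at 4,000X is kept as a unit test.
* **Active motif count.** The number of active motifs is deterministic
  (`round(p_motif_active · n_motifs)`, default 3 of 22) rather than
  Bernoulli, so that small replicate simulations cannot draw zero active
  motifs and void the proximity analysis.
* **Window-count bookkeeping.** `floor((L − w)/s) + 1` windows for step
  `s`; e.g. 15,788 sites give 315 windows at `w = s = 50` and 420 at
  `w = 250, s = 37`.

## Numerical choices and degenerate inputs

Decoded pileup depth overrides the depth column (mismatches are logged);
`.`/`,` at an `N` reference base are dropped with a message. The Welch
statistic floors a zero pooled variance at machine-epsilon scale so a
planted mean difference on constant groups yields a large finite *t*
rather than 0/0. Spearman correlations use midranks and the *t*
approximation for p-values; constant vectors yield `NA` (except the
proximity special case above). Zero-coverage profiles cannot be scaled and
raise errors; zero-depth sites yield `N` consensus and undefined error
rates rather than zeros.

## Problem sizes

The test suite and the acceptance script run the recovery experiments at
15,050 sites (≈300 windows), 100 seeded replicates for the sign and
proximity properties, an 11 × 6,000-site cohort at 25,000X for
heteroplasmy, and ~10⁴ simulated reads (~7.5 × 10⁵ k-mer instances) for
the spectrum; these sizes give stable statistics for every property while
keeping a full run in the tens of seconds.

## Limitations

Analyses consume pileups as given — no base-quality filtering, BAQ, or
strand-aware calling (strand evidence is the natural next discriminator
for SSE-driven false SNPs, but requires per-strand counts this pipeline
deliberately collapses). Fragment-level coverage, read trimming/mapping
themselves, and homology search are out of scope; alignment blocks for the
cross-species comparison are consumed precomputed, using only columns
ungapped in both species.
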