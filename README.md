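# mitocovbias

Coverage-bias and sequencing-error profiling for ultra-deep mitochondrial
resequencing data.

When a whole-genome sequencing run covers the mitochondrial genome at tens
of thousands of reads per site, stochastic sampling noise becomes
negligible and what remains of the site-to-site variation in coverage is
systematic: driven by local GC content, by gene context, and by
sequence-specific error (SSE) motifs such as `GGC`/`GGCNG` contexts, whose
`CCNGCC` reverse-complement extension sits directly downstream of
high-error bases. The same ultra-deep data resolves per-site error rates of
order 0.1% precisely enough to separate sequencing error from genuine
low-frequency variation, and so to flag candidate heteroplasmic sites —
positions where a single individual carries a second mtDNA haplotype at
intermediate frequency.

`mitocovbias` implements this analysis as a tested R package:

* **I/O** — `samtools mpileup` text decoded into per-site base counts
  (`parse_pileup()`), FASTA and BED annotation with intergenic gap-filling,
  and a TSV site-table format with exact round-trips.
* **Coverage geometry** — folding of the circular-mapping overlap
  (`fold_circular_overlap()`: position *i* of the extension is added back
  onto reference position *i*), end trimming to a retained region, scaling
  of cohort profiles to a common mean, and windowed GC/coverage tables.
* **GC dependence** — OLS of window mean coverage on GC (degree 1 and 2)
  with Gaussian AIC `n log(RSS/n) + 2(degree + 2)` and the stationary point
  `-b1/(2 b2)` of the quadratic; Welch *t*-test of per-site coverage for
  A/T versus G/C bases; site-level ANCOVA (Type II) with base identity,
  gene type and surrounding 50-bp GC.
* **Error structure** — per-site error rate `e = (depth − n_consensus)/depth`,
  the 4×4 substitution spectrum with transition/transversion ratio, IUPAC
  motif scanning on both strands (circular-aware), coverage versus distance
  to the nearest motif edge within a 100-bp flank (Spearman), and
  single-carrier heteroplasmy calls (carrier frequency ≥ 1%, every other
  individual ≤ 0.1%).
* **k-mer spectrum** — exact canonical k-mer counting, valley detection
  between the error mode and the main peak, per-base error
  `= error-instance fraction / k`, and depth from the peak via
  `N = M·L/(L − k + 1)`.
* **Concordance** — pairwise Spearman matrices across individuals,
  per-window cross-individual CVs, and cross-species coverage correlation
  over aligned homologous blocks.
* **Synthetic data** — `sim_config()` / `generate_reference()` /
  `simulate_site_profiles()` / `simulate_reads()` generate cohorts with
  known ground truth (GC-dependent log-mean coverage, shared site effects,
  planted motifs with coverage dips, planted heteroplasmy), so every stage
  is testable without the original reads.

## Worked example

The `analysis/` directory holds the numbered workflow. Stage 2, on the
default synthetic cohort (seed 101):

```
$ Rscript analysis/01_simulate.R
cohort: 11 individuals x 16500 sites
mean depth (ind1): 4103X; per-site range 674-10332X
planted: 22 motifs (3 active), 6 heteroplasmic sites

$ Rscript analysis/02_coverage_gc.R
330 windows of 50 bp
linear:    F = 932.45, R2 = 0.740, df = 328, slope = -6209
quadratic: F = 541.67, R2 = 0.768, df = 327, vertex at GC = 0.177
delta AIC (quad - lin) = -36.1 -> quadratic preferred
A/T mean 4166X vs G/C mean 4005X: Welch t = 8.89, df = 13794
```

The negative slope says coverage falls with window GC; the negative ΔAIC
says the quadratic adds real curvature, with its peak near the lower edge
of the observed GC range, so the relationship is essentially negative over
the data. Stage 3 reports a mean site error of 0.110% with ti/tv 0.499
(the uniform-error expectation is 0.5, far from biological variation) and
recovers all six planted heteroplasmic sites; stage 4 recovers the planted
read error rate from the k-mer spectrum (0.109% versus 0.110% planted);
stage 5 gives cross-individual rank correlations of 0.79–0.80 and a
cross-cohort correlation of 0.24 over 2,594 homologous sites.

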