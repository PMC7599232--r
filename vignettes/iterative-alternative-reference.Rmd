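---
title: "Iterative alternative-reference construction: model, defaults and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Iterative alternative-reference construction: model, defaults and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iterref)
```

## The problem and the procedure

A linear reference genome represents one haplotype of one individual.
Reads from a diverged breed fail to map exactly where divergence is
densest: once a region carries more mismatches than a mapper tolerates
within one read, it produces no alignments at all. Because variant calling
sees only mapped reads, such *highly variable regions* (HVRs; runs of three
or more consecutive mismatching positions) are invisible — not called, not
flagged, apparently conserved.

`iterref` implements the iterative fix as a pipeline of small, separately
testable stages. One *round* is:

1. **map** all reads to the current reference (k-mer seed, ungapped
   Hamming extension, unique-best placement);
2. **call** SNPs from the pileup with hard depth and allele-fraction
   cutoffs;
3. **substitute** the homozygous-alternate alleles into the reference,
   yielding the next reference.

Substituting the flanking alleles of a variable region lets reads that
reach slightly deeper map in the next round, so the recovered territory
grows inward from both edges until the region is fully resolved. The loop
stops early when a round substitutes nothing (rounds are deterministic
functions of the reference and the fixed read set, so nothing can change
afterwards).

Two decisions are made from logistic saturation curves fitted to
log2-transformed variant counts:

* **optimal coverage** — counts against coverage follow the rising form
  `y = a / (1 + b e^(-cx))`; the recommended coverage is the ceiling of
  the `x` where the analytic tangent slope `a b c e^(-cx) / (1 + b e^(-cx))^2`
  falls to `1e-4`, maximized over breeds (the slowest-saturating breed
  decides);
* **optimal iteration count** — counts against round follow the falling
  form `y = a / (1 - b e^(-cx))`; the optimum is the smallest round
  `n >= 2` with `|slope| <= 1e-4`.

The reported alternative reference is the one after the optimal round, not
after the last round run.

## Assumptions

* **SNP-only divergence and substitution.** Unlike consensus tools that
  also apply indels, `apply_substitutions()` is substitution-only. This
  keeps every round coordinate-identical to the original reference, so HVR
  detection and genome similarity are positional comparisons rather than
  whole-genome alignments, and no liftover is ever needed. Indel-bearing
  data must be handled upstream.
* **Homozygous-only substitution by default.** A heterozygous site has
  both alleles in the reads at roughly equal fractions; substituting one
  of them just makes the other allele the "variant" of the next round, and
  the reference flip-flops. `hom_only = FALSE` is retained deliberately —
  it reproduces that oscillation, which is visible as variant counts that
  move up and down between consecutive rounds instead of decreasing.
* **Ungapped mapping.** Extension is Hamming distance over the full read.
  Gapped alignment would add nothing to substitution-only references.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `k` (seed length) | 17 | bases | random 17-mer hits are ~`G/4^17` per read at desk-scale `G`; a best hit with `m` mismatches is guaranteed found when `floor(L/k) > m` (pigeonhole), so 100 bp reads are fully covered at `m = 3` |
| `max_mismatches` | 3 | count | tolerates simulated divergence while preserving the "unmappable variable region" effect the method exists to fix |
| `require_unique_best` | TRUE | – | ambiguous placements are dropped rather than guessed; ties otherwise resolve to the lowest `(chrom, pos, strand)` |
| `min_depth` | 3 | reads | below three observations a genotype call is guesswork even without errors |
| `hom_threshold` / `het_band` | 0.8 / (0.2, 0.8) | alt fraction | standard hard cutoffs; adequate for error-free or low-error synthetic reads (the genotyper is deliberately simple, not a haplotype-assembly caller) |
| `tau` | 1e-4 | log2 counts per unit x | the tangent-slope threshold used for both decisions |
| `max_rounds` | 30 (12 in the demo) | rounds | the loop almost always early-stops first |
| `log_base` | 2 | – | the published asymptotes match the terminal variant counts only in base 2 (e.g. `a = 21.34 ≈ log2(2.64e6)`); configurable |

## What the synthetic-data generator emulates

`simulate_breed()` plants three kinds of variation into a reference:
background SNPs (rate `snp_rate = 0.005`/bp), a heterozygous fraction among
them (`het_fraction = 0.2`), and `n_hvr = 30` clustered variable regions of
9–36 bp. The truth "breed genome" is the alternate-carrying haplotype
(every planted variant applied); the reference-carrying haplotype is
derived by reverting het sites, and `simulate_reads()` draws one haplotype
per read with probability 1/2, uniform start positions, a random strand and
independent per-base errors. Defaults: 50 bp reads, 30x, error-free.
Quality strings are constant because no stage uses base qualities.

Two generator choices deserve explanation because they are what make the
end-to-end properties *structural* rather than lucky:

* **Cluster anatomy.** Each planted cluster carries one defining run of
  exactly three consecutive substitutions plus extra substitutions at rate
  `hvr_divergence = 0.1`/bp, thinned to a minimum separation of 8 bp.
  Unthinned Bernoulli placement occasionally produces runs of four or more
  tightly packed substitutions — and a run of four is *unmappable in
  principle* at `max_mismatches = 3`: a read covering its first three
  bases must end in the 1 bp gap before the fourth, so the expected number
  of usable reads is `coverage/read_length` per boundary position (~0.6 at
  the defaults), below any sensible `min_depth`. A run of three, by
  contrast, is always recoverable once isolated, because three mismatches
  fit the budget of any read spanning it.
* **Frontier depth arithmetic.** Recovery proceeds from a cluster's edges
  inward. The mapped depth available at a recovery frontier is roughly
  `coverage × (max_mismatches / divergence) / read_length` — the reads
  that cover the next substitution but stop before the one past the
  budget. At the defaults this is `30 × (3/0.1) / 50 = 18`, comfortably
  above `min_depth = 3`; at a within-cluster divergence of 0.4 with 100 bp
  reads it would be ~2, and recovery would stall. The defaults were set by
  this arithmetic, and the 50 bp read length doubles the read-boundary
  density (1.2 starts+ends/bp at 30×) that frontier steps depend on.

**What the generator does not emulate:** indels and structural variants,
GC or positional coverage bias, quality decay, chimeric fragments, and
clusters denser than the mismatch budget (see above — real genomes have
them, and on real data they remain unrecoverable by this method; LASTZ-class
whole-genome alignment is the appropriate tool there). Passing tests
therefore demonstrate the mechanism and the statistics, not performance on
real sequencing artifacts.

## Numerical choices

* **Fitting.** `fit_logistic()` uses Levenberg–Marquardt
  (`minpack.lm::nlsLM`) on the log2 counts with analytic-free
  initialization: asymptote from the data's extreme value (offset 0.1% to
  keep the transformed residual positive), rate from a log-linear
  regression of `±(a0/y − 1)`, shape solved from the intercept; up to 20
  random restarts (log-normal perturbations, sd 0.5) on non-convergence;
  parameters bounded positive. Denominators near the falling form's pole
  are floored at `1e-9` so the optimizer is steered away instead of
  crashing. Noiseless curves are recovered to `1e-6` relative.
* **Two fit-quality figures.** `r_squared = 1 − SSres/SStot`, and
  `r = sqrt(max(r_squared, 0))` — the *correlation coefficient* that
  CurveExpert-style fitting programs print as their goodness of fit.
  Published "R²" columns for these fits follow the `r` convention (the
  values only reconcile as `r`: a coverage-series refit gives
  `r_squared = 0.9907`, whose square root `0.9954` matches print), so the
  fit object carries both and the tests compare like with like.
* **Threshold crossing.** `threshold_coverage()` brackets from the slope
  maximum `x = ln(b)/c` and expands right geometrically, then bisects
  (`uniroot`, tolerance `1e-6`, tighter than the `1e-4` the decision
  needs). The recommendation is the ceiling — coverage is bought in whole
  units. If the slope never exceeds `tau`, the lower domain bound is
  returned with a `boundary` flag and a warning rather than an error.
* **Degenerate inputs.** Fits require four points; rounds with zero
  variant counts are excluded from the saturation series (log of zero);
  if fewer than four usable rounds remain — common when the loop
  early-stops on clean synthetic data — the trace is still returned and
  the optimal round count is `NA` with a warning, and the final genome is
  the last one produced.
* **Parameter-recovery testing.** The recovery test uses curves
  (rising `a=20, b=1, c=0.35`; falling `a=21, b=0.7, c=0.8`) chosen so the
  5% recovery bound has statistical power at noise sd 0.05 over
  `x = 1..30`: worst-case errors are 2.4%/3.2% over 100 seeds. A falling
  curve as steep as the published iteration fit (`c ≈ 1.9`) leaves only
  two or three informative points and cannot meet 5% at this noise — a
  property of the information in the data, not of the fitter.
* **Coordinates.** Per-site records are 1-based (VCF convention);
  intervals are 0-based half-open (BED convention); conversion happens
  only at format boundaries (VCF and GTF read/write). N bases are legal in
  genomes but are never substituted into, never match, never mismatch, and
  break HVR runs.
* **Determinism.** The mapper, caller and substituter are fully
  deterministic; randomness exists only in the simulator and downsampler,
  each seeded per call (`with_seed` restores the caller's RNG state), with
  child seeds derived arithmetically and kept below 2^31.

## Test problem sizes

The suite exercises the full loop at sizes chosen to keep the default test
run fast while leaving the properties meaningful: oracle-equivalence
checks on 1–2 kb genomes with exhaustive scans, module tests on 3–30 kb,
and the end-to-end property runs on a 100 kb genome at 30× (the spec-level
conditions for recovery and monotonicity). The demo runs the same 100 kb
configuration in a few seconds.

## Known limitations

* Substitution clusters denser than the mismatch budget are unrecoverable
  (by any parameterization of this method — see the frontier arithmetic
  above); the generator plants recoverable clusters and the limitation is
  documented instead of simulated.
* Reads shorter than `(max_mismatches + 1) × k` lose the pigeonhole seed
  guarantee: a read with that many mismatches can lack any clean k-mer and
  go unmapped even though its Hamming distance is within budget. At the
  default `k = 17` the guarantee needs 68 bp reads; the 50 bp simulated
  reads map via their clean flanks in practice, but oracle-equivalence
  tests use 100 bp reads where the guarantee is exact.
* Paired-end reads are simulated on request but mapped independently; no
  pairing constraint or insert-size model is used anywhere.
* The genotyper has no error model beyond depth and allele-fraction
  cutoffs; at realistic error rates a GATK-class caller is assumed
  upstream (callsets can be supplied as VCF).
* `compare_callsets()` is genotype-aware by default (a matching locus with
  the wrong genotype is both a false positive and a false negative); the
  positional-only mode exists for sensitivity analyses.
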