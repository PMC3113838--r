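---
title: "Methods: identifying and characterizing mitochondrially enriched miRNAs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: identifying and characterizing mitochondrially enriched miRNAs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitomir)
```

## Overview

`mitomir` implements the computational chain used to ask whether specific
nuclear-encoded microRNAs accumulate in mitochondria: dual-channel microarray
profiling of the mitochondrial (Hy5-labeled) versus cytosolic (Hy3-labeled)
RNA fraction of the same cells, classification of each probe as
mitochondria-enriched, cytosol-enriched or unchanged, and downstream
characterization of the mitochondria-enriched set ("mitomiRs"): seed target
sites on the circular mitochondrial genome with a Poisson random-match
significance, exact mature-sequence mapping to mtDNA, secondary-structure
thermodynamics (MFE, AMFE, MFEI), cross-species conservation scores, and
pixel-wise co-localization statistics for dual-channel microscopy.

Every stage can be driven end to end from synthetic inputs with known ground
truth (`simulate_inputs()`, `run_pipeline()`), so the whole chain is testable
offline.

## Enrichment model

One hybridization yields a spot table: per spot, foreground and background
intensity in each channel (arbitrary fluorescence units) plus a calibrator
flag. The chain per array is:

1. **Net intensity** — foreground minus local background, per channel.
   Negative nets are possible and always fail the filter.
2. **Background filter** — a spot is kept only if its net intensity reaches
   the 50th percentile of the channel's background intensities in *both*
   channels. The percentile uses the mean-of-middle-two convention for even
   counts. An optional calibrator adjustment scales each channel's threshold
   by the ratio of that channel's median calibrator net to the geometric
   mean of the two channels' median calibrator nets; the unadjusted
   threshold is the default because no unique adjustment formula is
   standard.
3. **Spot ratio** — Hy5 net over Hy3 net on kept spots.
4. **Calibrator normalization** — every ratio is divided by the median spot
   ratio of the spike-in calibrators (18 oligonucleotides added equally to
   both samples), which absorbs dye bias, labeling-efficiency and scanner
   gain differences exactly. This median is computed on the log scale
   (geometric mean of the middle two for even counts) so that swapping the
   channels maps the normalizer to its exact reciprocal.
5. **Probe ratio** — the mean of the kept replicate-spot ratios
   (quadruplicate spots by design). The arithmetic mean is the conventional
   default; a geometric option exists because only the geometric mean makes
   the whole chain exactly antisymmetric under a channel swap (the
   arithmetic mean of reciprocals is not the reciprocal of the mean). The
   package's antisymmetry property test runs in the geometric mode.

Across replicate arrays, a probe is called **mito** when its normalized
ratio is at or above the fold cutoff (default 1.5, must be > 1) in *every*
array in which it passes the filters, and it passes in at least
`min_arrays` arrays (default: all provided arrays — the reproducibility
rule). **cyto** is the mirror call on reciprocal ratios; everything else is
**unchanged**, or **filtered** when the probe passes in too few arrays.
Whether the cutoff should apply per array or to the cross-array mean is
genuinely open; per-array with reproducibility is the default and a
mean-based mode (`mode = "mean"`) is provided. The reported fold is
`max(m, 1/m)` of the cross-array mean ratio `m`.

## Synthetic arrays

`planted_truth()` and `gen_array_scans()` emulate the layout of the array
used in this design space: 1460 miRNA probes plus 97 controls spotted in
quadruplicate (6228 spots), 18 spike-in calibrators. Spot foregrounds are
log-normal around (abundance x planted fold x dye bias) with an additive
per-spot Gaussian background; the reported background column equals the
added background, so with zero noise the calibrator-normalized probe ratio
recovers the planted fold to machine precision. Defaults: 13 planted
mitochondria-enriched probes with folds drawn log-uniformly on [1.5, 56]
(the observed range of mitochondrial enrichment folds), 44 cytosol-enriched
probes with reciprocal folds, dye bias 1.3 on the Hy5 channel, background
50 ± 10, per-probe abundance log-normal (median 500, sdlog 0.5), and spot
noise with a coefficient of variation of 0.1. No noise model for this
platform is published; these are explicit stand-ins, all exposed as
parameters. Under those defaults, three arrays and 100 simulations, the
classifier recovers the planted mito set with mean sensitivity ≈ 0.98 and
mean false-discovery rate 0; the residual misses are planted folds so close
to the 1.5 cutoff that one of three noisy arrays falls below it, which is
the intended behavior of the reproducibility rule rather than an error.

What the generator does *not* emulate: spatial artifacts (dust, smears,
print-tip effects), intensity-dependent dye bias (no loess-style curvature),
saturation, or cross-hybridization. Passing tests therefore demonstrate the
correctness of the normalization/classification algebra and its statistical
behavior under the stated noise model, not robustness to every failure mode
of real scans.

## Seed-site scanning and the Poisson statistic

The scanner takes the 5'-proximal heptamer of a mature miRNA by default
(`k = 7`, `seed_start = 1`; `seed_start = 2` gives the canonical 2–8 seed)
and reports every genome position whose strand sequence equals the reverse
complement of the seed — i.e. perfect seed target sites. Both strands are
scanned by default because both mitochondrial strands are transcribed.
Circular genomes are scanned across the origin with a (k−1)-nt wrap window;
coordinates are 1-based inclusive on the forward strand, and an
origin-spanning hit keeps `end = start + k − 1 > L` (interpret modulo the
genome length).

Significance: under the null, the number of random matches is modeled as
Poisson with mean

λ = n_positions × p_match,

where `n_positions` is L per scanned strand (circular) or L − k + 1
(linear), and `p_match` is the product of background base frequencies over
the required site bases. The default composition is the genome's
mononucleotide frequencies (mtDNA is strongly AT/CG-skewed); a uniform
4^−k mode is provided for cross-checks. The p-value is the upper tail
P(X ≥ n_obs), with p = 1 at zero observed hits. Self-overlap (clumping)
corrections are *not* applied — the statistic is the simple Poisson — and
this is a documented limitation: for self-overlapping seeds the null
variance exceeds λ and p-values are slightly anticonservative. Because the
exact null convention (strand count, composition, linear versus circular
position count) admits several defensible choices, the package exposes all
of them as parameters rather than promising agreement with any one
published p-value; its guarantees are the closed form of the tail and
strict monotonicity in the observed count.

Exact mature mapping (`exact_mature_match()`) is the complementary
operation: full-length, zero-mismatch occurrences of the miRNA itself
(U→T) on either strand, the operation by which miRNA-like small RNAs can
be traced to mitochondrial tRNA/rRNA loci.

## Folding model

MFE is computed by dynamic programming over all nested secondary
structures: Watson–Crick plus G·U pairs, hairpin loops of at least 3
unpaired bases, no pseudoknots. The energy of a structure is the sum of
nearest-neighbor stacking energies of adjacent pairs, from an embedded
6 × 6 table (kcal/mol, all entries negative) that is symmetric under
reading the duplex backwards; unstacked (isolated) pairs contribute
nothing, and the open chain scores 0, so MFE ≤ 0 always. Loop-size
penalties beyond the minimum-hairpin constraint are deliberately omitted:
they would require interior-loop enumeration without changing any property
the package relies on. This is a *reduced* model — the full Turner
parameterization lives in dedicated folding software, and externally
computed energies can be ingested via `feature_table(mfe_file = ...)` for
exact parity with published MFE tables; the provenance of each energy is
flagged in the output.

Numerical choices: co-optimal structures are resolved by a deterministic
traceback (pair the leftmost base, smallest partner index first, continued
stack before a branch; zero-energy pairs left unpaired), so equal inputs
give identical dot-brackets. The DP is validated against exhaustive
enumeration of all nested structures for sampled sequences of length
5–12 nt, and the returned structure must reproduce the returned energy
exactly.

Derived features follow their defining identities exactly:
AMFE = (−MFE / length) × 100 (per-100-nt normalization, positive for
stable folds) and MFEI = AMFE / (G+C)% (undefined at 0% GC, reported as an
error).

## Conservation scoring

The score summarizes cross-species presence lists: 0 when the species list
contains only human (human-specific), 2 when the sequence is conserved in
more than two taxonomic orders, 1 otherwise. The published rule does not
say what an exactly-two-orders case scores; the package scores it 1 (the
conservative reading, since "more than 2 orders" is the stated condition
for 2). The rule presumes a human miRNA, so a species list without human
is an error. The bundled panel
(`inst/extdata/mitomir_conservation.tsv`) carries the printed
species/order lists of the 13 mitochondria-enriched miRNAs and is what
`scripts/acceptance.R` rescores.

## Co-localization statistics

`pearson_coloc()` is the Pearson coefficient over paired pixel
intensities of the two channels (green = AGO2 staining, red =
mitochondria, by the field's convention); it is invariant under positive
affine intensity transforms and undefined for zero-variance channels. The
cross-correlation function translates one image horizontally by dx ∈
[−max_dx, +max_dx] pixels and records the coefficient over the valid
overlap only — no wrap and no zero padding, because padding biases the
coefficient toward 0. The shift axis is horizontal only, matching the
single-dx convention of the original cross-correlation protocol; no
intensity thresholding or background subtraction is applied before
correlating. A curve is classified **bell** when its maximum lies within a
tolerance window of dx = 0 (default: 10% of max_dx, at least 1 px) and
exceeds the mean over the outermost 10% of shifts by a margin of 0.1
correlation units; **hollow** is the mirror condition on the minimum;
otherwise **flat**. The published classification is visual, so this
quantification is the package's own and every constant is a parameter.
The image generator places Gaussian blobs (σ = 2 px by default) on a dark
background with a controllable co-localized fraction, optional mutual
exclusion, translation (wrap-around) and additive noise; per-cell ROI
segmentation is out of scope — statistics are per provided image.

## Two-group comparisons and enrichment

Feature distributions between the mitomiR and control groups are compared
with a two-tailed Welch t test (unequal variances, Welch–Satterthwaite
degrees of freedom, computed in closed form and cross-checked against the
reference implementation in tests) and a two-sided Fisher–Snedecor F test
for variances (larger variance in the numerator, doubled tail capped at 1,
hence symmetric in its arguments). Both are always reported because the
published analysis does not say which test carried each significance call.
Gene-set overlap is reported as 100·|target ∩ reference|/|target|, and
category enrichment as the upper-tail hypergeometric probability, with an
optional Benjamini–Hochberg adjustment at 5% FDR for multi-category scans.

## Problem sizes and determinism

All randomness flows through explicit `seed` arguments implemented with
isolated RNG streams, so generators never perturb the caller's RNG state
and equal seeds give byte-identical outputs (including written files).
The test suite exercises: 100 full-size (1557-probe, 3-array) simulations
for the sensitivity/FDR property; brute-force oracle comparisons on 2-kb
genomes, 50-probe scans, and 5–12-nt folds; 200 random genomes for the
λ-calibration of the Poisson null; and 1000 generated hairpins
(stems 3–10 bp, loops 3–8 nt) for the AMFE/MFEI identities. These sizes
were chosen so the full suite completes in about a minute on one CPU while
keeping every statistical tolerance at 3–4 standard errors.

## Known limitations

- The folding energies are a reduced stacking model: rankings and
  qualitative behavior match thermodynamic folders, absolute values do not;
  use the external-energy path when parity matters.
- The Poisson seed statistic ignores clump corrections and dinucleotide
  composition.
- No image QC, segmentation, or Manders/Costes coefficients.
- No between-array normalization beyond the spike-in calibrators, and no
  dye-swap designs.
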