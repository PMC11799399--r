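---
title: "Multiplexed MALDI TIMS MS/MS imaging: methods and design"
author: "iprmtools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiplexed MALDI TIMS MS/MS imaging: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iprmtools)
```

## The problem

MALDI imaging measures, at every pixel of a tissue section, a mass
spectrum of the tryptic peptides released in situ. On its own it yields
MS1 masses only, so peptide identity must be inferred indirectly. Adding
trapped ion mobility separation (TIMS) gives every ion a second
coordinate, the inverse reduced mobility 1/K0 (V·s/cm²), and makes a
multiplexed targeted MS/MS mode possible: a precursor list of (m/z, 1/K0
window) pairs is submitted, ions are trapped and released by mobility,
and every laser position yields fragment (MS2) spectra for all listed
precursors at once — iprm-PASEF. This package implements the complete
data-analysis chain around that acquisition mode:

1. **MS1 survey analysis** — normalization, feature finding in
   (m/z, 1/K0), segmentation, co-localization statistics;
2. **precursor scheduling** — turning ranked candidates into a valid
   precursor list with disjoint mobility windows;
3. **MS2 identification** — mobilogram-filtered extraction, averaging,
   decoy-controlled peptide-spectrum matching;
4. **corroboration** — fragment–parent co-localization and cross-platform
   (LC-ESI) mass/mobility comparison;
5. **a phantom simulator** that generates both MS1 and MS2 imaging data
   with complete ground truth, so that every stage is testable without
   instrument data.

## Chemical core

All arithmetic is monoisotopic. Residue masses are tabulated to five
decimals, with water 18.010565 Da and proton 1.007276 Da; a peptide's
singly protonated mass is the residue sum plus water plus one proton.
MALDI produces almost exclusively singly charged tryptic peptide ions,
so all m/z values are treated as 1+ and fragment ions are computed as
singly protonated b/y series only (no a/c/x/z ions, no neutral losses,
no isotope envelopes). Tryptic digestion cleaves C-terminal to K/R
except before proline; up to two missed cleavages are kept by default,
matching common search-engine settings for FFPE material.

Hydroxyproline — ubiquitous in collagen peptides, which dominate the
extracellular signal of FFPE tissue — is registered with the nominal
+15.999 Da delta used in the bracket notation `GVVGLP[16]GQR`, so that
printed reference masses reproduce exactly. The general oxidation entry
(H/W/P/M) uses the exact monoisotopic +15.994915 Da. The registry
accepts arbitrary user deltas. Variable-modification expansion defaults
to at most two simultaneous modifications per peptide: one is too
restrictive for the doubly hydroxylated collagen peptides that do occur
(e.g. `GAAGPP[16]GATGFP[16]GAAGR`), while unlimited placement inflates
the search space combinatorially on proline-rich sequences.

## MS1 feature finding

Proprietary feature finders for mobility-resolved imaging data are not
reproducible outside their vendor software. The replacement here is
deliberately the simplest auditable definition: pool all centroided
peaks of the RMS-normalized dataset and form the connected components of
the graph that links two peaks when they lie within 10 ppm in m/z *and*
0.01 V·s/cm² in mobility (single linkage). Components become features
with intensity-weighted centroids, and are filtered at 50% tissue
coverage and 1% relative intensity (relative to the dataset-wide maximum
normalized peak intensity, since the vendor's reference is unpublished).
The implementation uses union-find over tolerance-sized cells and is
exactly equivalent to the brute-force all-pairs oracle, which the test
suite verifies directly. This is a reproducibility-motivated
replacement, not a claim of equivalence to any vendor algorithm, and
vendor feature counts are consequently not comparison targets.

RMS normalization divides each pixel spectrum by the root mean square of
its intensities, computed per spectrum over the acquired m/z range
(whether the vendor normalizes before or after window restriction is
unpublished; per-spectrum-global is assumed). It is idempotent and scale
invariant, both asserted as properties.

## Segmentation and co-localization

Segmentation uses bisecting k-means under correlation distance
d(u, v) = 1 − r(u, v): starting from one cluster, the cluster with the
largest inertia is split by 2-means until k clusters exist. The inner
2-means runs on row-standardised vectors via the identity
1 − r = ‖z_u − z_v‖²/(2(p−1)), which makes every bisection an ordinary
Euclidean k-means and keeps the procedure deterministic for a fixed
seed. Constant pixels (undefined correlation) are placed at the origin
of z-space and a degenerate split is reported with a warning.

Co-localization of an ion image with a tissue region is the Pearson
correlation against the binary region indicator (the vendor's exact
operand is unpublished; the indicator was chosen because its exact
r = ±1 limits are testable), with a two-sided t-test p-value and a
p < 0.05 significance gate. Candidate selection keeps significant
features with |r| ≥ 0.7; the threshold is applied inclusively because
published selections report r = 0.71 as passing at two-decimal
rounding. p-values are not multiplicity-corrected by default (a
Benjamini–Hochberg option exists) — the selection step is exploratory,
not inferential. Literature-guided manual picks can be forced into the
candidate list via `manual_ids`.

## Precursor scheduling

Multiplexed trapping requires pairwise disjoint 1/K0 windows (touching
endpoints are treated as overlap, since no minimum inter-window gap is
documented, zero gap is assumed) and a practical limit of 25 entries.
Published workflows schedule by hand; the exact optimizer here is this
package's own contribution and is validated against a brute-force
subset-enumeration oracle rather than against any published list.
Windows default to ±0.025 V·s/cm² around the feature centroid — wide
enough for efficient isolation, yet allowing ~18 disjoint windows across
the 0.9 V·s/cm² acquisition range; it is configurable. The optimizer is
exact weighted-interval scheduling: sort windows by upper edge, then
dynamic programming over (entry, cardinality) maximizes total priority
(|r| by default) under the plex limit, with deterministic tie-breaking
towards higher individual priority and then lower m/z. Collision energy
is annotated by linear interpolation from 45 eV at m/z 100 to 140 eV at
m/z 2000 and is not used in any simulation — fragment intensities do not
model energy dependence.

## MS2 extraction, averaging and identification

Per precursor, MS2 frames are filtered over the mobilogram (fragment
mobility inside the precursor window) and averaged across all
contributing pixels: peaks are pooled, merged by 1-D single linkage at
0.05 Da, and reported with the intensity-weighted mean m/z and the
zero-filled mean intensity (sum divided by the number of contributing
pixels). Averaging operates on raw intensities, because per-pixel
normalization constants differ and would distort fragment ratios. No
quality filtering precedes averaging.

Scoring replaces the proprietary search engine with a defined
probability model: with N theoretical b/y ions, m of them matched at
0.3 Da, and a per-ion chance-hit probability
q = min(1, 2·tol·n_peaks/span), the score is −10·log10 P(X ≥ m) for
X ~ Binomial(N, q). The score is zero at m = 0, monotone in m, and its
null calibration is checked by Monte Carlo on random spectra.
Proprietary scores from the original software are therefore *not*
comparable numbers; only identities, ppm errors and ion-count
denominators are. Candidates are all target and reversed-decoy peptide
isoforms within 100 ppm of the precursor mass; q-values follow the
standard target-decoy estimate FDR(t) = #decoys ≥ t / #targets ≥ t,
monotonized, with acceptance at q ≤ 0.01.

## Cross-platform corroboration

If the same modified sequence is identified by LC-ESI-TIMS-MS/MS, its
precursor m/z and 1/K0 can be compared with the MALDI values. The
comparison joins on the bracket-notation sequence, computes the signed
ppm difference and the mobility difference in the MALDI − LC
orientation, and suppresses the mobility comparison when the LC charge
state is not 1+ (1/K0 is charge-dependent). Reference tables bundled
with the package carry the published measured values for five iRT
calibration peptides and nine FFPE-tissue peptides; their printed
derived columns reproduce from the raw m/z pairs to ±0.01 ppm. One
orientation subtlety is handled explicitly: the iRT table's 1/K0
difference column is an unsigned magnitude (one row is negative under
either consistent sign convention), so magnitude comparison is used for
that table, while the tissue table is signed MALDI − LC throughout.

## The phantom simulator

The simulator emulates the statistical structure the pipeline assumes,
not instrument physics. A 64×48-pixel tissue (50 µm pixels) contains an
elliptical "cellular" core (~26% of the tissue) and an "extracellular"
remainder. Twelve peptides per region are drawn by in-silico digestion
of three bundled synthetic protein sequences — a proline/glycine-rich
collagen-like sequence for the extracellular panel and histone-like and
actin-like sequences for the cellular panel — mirroring the biology of
FFPE peptide imaging without external downloads. Panel masses span
roughly 850–1950 Da with ≥60 ppm pairwise separation.

Per pixel, each panel peptide contributes a peak at its [M+H]+ with
multiplicative Gaussian m/z jitter (σ = 3 ppm, inside the 10 ppm
linking tolerance), its mobility with additive jitter (σ = 0.003
V·s/cm², inside the 0.01 tolerance), and intensity = mean abundance ×
LogNormal(0, σ = 0.3) — multiplicative noise being the natural model for
ion counts spanning decades; no detector saturation is modelled.
Peptides appear at 5% of their mean abundance outside their home region
("bleed"), so coverage-based filters see realistic near-full coverage
while region contrast stays strong. Matrix background is Poisson(5)
peaks per pixel, uniform over the acquisition ranges, log-normal in
intensity.

Mobility itself is a transparent affine stand-in, not a CCS predictor:
[M+H]+ is mapped from [800, 2000] Da onto [1.3, 1.9] V·s/cm² plus a
fixed per-peptide Gaussian jitter (σ = 0.02), clipped to [1.2, 2.1].
This reproduces the qualitative mass–mobility trend of singly charged
tryptic peptides, which is all the pipeline logic requires
(window-separable, consistent values). Consequences: simulated
mobilities carry no structural information (isomers are
indistinguishable), and passing tests say nothing about real CCS
behaviour.

The MS2 simulator fragments every panel peptide whose mobility falls in
a scheduled window: each theoretical b/y ion receives a fixed
Uniform(0.2, 1) fragmentation factor (a seeded property of the
(peptide, ion) pair), scaled by the pixel's parent abundance and
log-normal noise, with peaks below 0.5% of the pixel maximum dropped.
A window covering two panel peptides therefore yields genuinely
chimeric spectra — and a matched fragment can then belong to the
co-isolated contaminant, which shows up as an anti-correlated
fragment–parent image, exactly the failure mode the co-localization
corroboration is designed to expose.

What the phantom does **not** emulate: isotope envelopes, ionization
suppression, mass-dependent detector response, spatial intensity
gradients within a region, CCS structure, or chimeric contamination
from non-panel (background) ions. Parameter-recovery results on the
phantom therefore demonstrate internal consistency of the pipeline, not
performance on real tissue.

## Numerical choices and problem sizes

* Ties in fragment matching resolve to the nearest peak by m/z; each
  theoretical ion matches at most one peak.
* The scheduler's DP compares priority sums exactly and breaks ties
  lexicographically, so results are order-independent.
* Degenerate inputs are first-class: all-zero spectra are flagged and
  left unchanged, zero-variance images return an undefined correlation
  marked not-significant, empty candidate sets and empty precursor
  lists return empty results with reasons.
* The test and acceptance workloads use the default 64×48 phantom, a
  decoyed database of the three panel proteins plus 1000 random
  150-residue background proteins (≈2 million indexed isoforms), 50
  seeded identification runs, 500 random scheduling instances against
  the exhaustive oracle, and 200 random peptides against the fragment
  oracle — sizes chosen to exercise every code path at desk scale.

## A worked example

```{r example, eval = FALSE}
spec <- phantom_spec(seed = 1)
sim <- simulate_ms1(spec)
ds <- rms_normalize(sim$dataset)
features <- find_features(ds)

M <- feature_matrix(ds, features)
seg <- bisecting_kmeans(M, k = 2, seed = 1)

region <- segmentation_map(seg, ds$width, ds$height) == 0
res <- do.call(rbind, lapply(seq_len(nrow(features)), function(j)
  coloc_to_region(feature_image(ds, features[j, ]), region,
                  feature_id = features$id[j])))
cand <- select_candidates(res, threshold = 0.7)

entries <- do.call(rbind, lapply(seq_len(nrow(cand)), function(i)
  assign_window(features[features$id == cand$feature_id[i], ],
                priority = abs(cand$r[i]))))
sched <- schedule(entries, max_n = 25)

ms2 <- simulate_iprm(spec, sched)
avg <- average_spectra(extract_ms2(ms2$dataset, sched[1, ]),
                       precursor = sched[1, ])
```

The same chain is available through `run_pipeline()` with a YAML
configuration (see `default_config()`), each stage writing TSV/imzML/MGF
outputs plus a JSON manifest with the config hash and seed.

## Known limitations

* imzML support covers processed-mode files with 64-bit float external
  arrays (the dialect the package writes, also readable by common
  Python imzML tooling); continuous-mode and compressed files are
  rejected explicitly.
* The binomial PSM score ignores intensity information and fragment-ion
  series structure; it is calibrated for ranking and FDR control, not
  for cross-study score comparison.
* Single-linkage feature finding can chain distinct species connected
  by a dense bridge of intermediate peaks; the phantom's ≥60 ppm panel
  separation avoids this by construction, real data may not.
* Scheduling optimizes a single acquisition; multi-pass scheduling
  across several runs is out of scope.
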