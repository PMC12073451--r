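---
title: "Methods: a CE-ESI-MS untargeted metabolomics pipeline"
author: "cemetab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a CE-ESI-MS untargeted metabolomics pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cemetab)
```

# Scope and study design

`cemetab` re-implements, as reusable and tested code, the data-processing
chain of an untargeted capillary electrophoresis electrospray ionization
mass spectrometry (CE-ESI-MS) infection study: *Drosophila melanogaster*
larvae either uninfected (Ctrl, n = 4), infected with symbiotic
*Steinernema carpocapsae* nematodes carrying *Xenorhabdus nematophila*
bacteria (Sym, n = 4), or infected with axenic nematodes lacking the
bacteria (Axe, n = 3). Each larval extract yields one CE-ESI-MS run: cations
between m/z 50 and 500 recorded over a ~50 min separation. The processed
data comprise 122 molecular features (unique m/z x migration-time signals),
50 of which match an in-house-style reference database of small polar
metabolites.

No instrument raw data are distributed with the package. Instead a
first-class synthetic-data module generates scan-level traces with known
ground truth, so every downstream stage is verified against planted
quantities rather than against itself.

# Mass arithmetic

Theoretical m/z values are computed from elemental formulas with IUPAC
monoisotopic atomic masses (C exactly 12, H 1.0078250, N 1.4003074e1, O
15.9949146, S 31.9720707, Na 22.9897693). Two adduct types occur in
positive-mode small-molecule CE-ESI-MS here:

* protonated molecules \[M+H\]^+^: m/z = M + m~p~ with the **proton** mass
  m~p~ = 1.0072765 Da. Adding a hydrogen *atom* instead would be wrong by
  the electron mass (0.5 mDa, i.e. 3-5 ppm in this window) — the packaged
  reference values reproduce only with proton addition;
* intrinsic cations \[M\]^+^ (quaternary ammonium species): m/z = M -
  m~e~ with the electron mass m~e~ = 0.00054858 Da, M being the cation
  formula mass. Three database entries are stored this way: choline,
  acetylcholine, and N^6^,N^6^,N^6^-trimethyllysine (the printed reference
  value of the last reproduces only as an intrinsic cation, not as a
  protonated neutral).

Reported m/z values are rounded half-even to 4 decimals, deviations to 1
decimal. Two deviation metrics are exposed: the signed relative error in
ppm, (measured - theoretical)/theoretical x 10^6^, which drives
identification, and the absolute (theoretical - measured) x 1000 in mDa.
Reference tables of this kind sometimes label the absolute column as ppm;
for most database rows the printed deviation equals the mDa value, while
one row (pyridoxine) matches neither metric, so the package computes both
and leaves the interpretation to the analyst. A related transcription note:
the database's "Pyridoxine" entry carries the composition C~8~H~9~NO~3~
(theoretical 168.0655), which is the pyridoxal formula; pyridoxine proper
(C~8~H~11~NO~3~) would give 170.0812. The packaged entry preserves the
reference value as printed.

# The synthetic-data generator

The generator's defaults *are* the study conditions; they are fixed and are
not tuning knobs.

* **Panel.** 122 features per experiment: the 50 database metabolites at
  their theoretical m/z and reference migration times (MT), plus 72
  unknowns drawn uniformly in m/z over \[50, 500\] and MT over \[11, 48\]
  min. Unknowns keep a 0.01-Da exclusion zone around every reference m/z
  (and 0.025 Da around calibrant clusters) so that identification tests
  cannot collide by construction. Two early-migrating polyamines
  (spermidine 8.5 min, putrescine 9.1 min) precede the ~11 min onset of
  the remaining signals; the generator plants the reference times as
  given.
* **Peaks.** Each feature is a Gaussian electrophoretic peak, sigma
  uniform on 0.05-0.15 min, sampled on a 0.02-min centroided scan grid
  (profile-mode synthesis is out of scope). Peak amplitude follows from
  the planted area: area = amplitude x sigma x sqrt(2 pi).
* **Abundances.** Baseline log10 areas uniform on 4.7-5.7; per-sample
  multiplicative log-normal noise with unit mean and CV 20%. Group
  effects: +0.5 log10 units in Sym for the nine Sym-enriched metabolites
  (pyridoxine, histidine, carnitine, GABA, sarcosine, trolamine, lysine,
  choline, methylhistidine) and +0.5 in Axe for the three Axe-enriched
  ones (acetylhomoserine, homolysine, methylaspartate). No numeric effect
  sizes are printed for the original study; 0.5 log10 at CV 20% is chosen
  once as a realistically strong differential signal at n = 11 and kept.
* **Per-run distortions.** A monotone cubic polynomial maps true MT to
  observed MT (intercept U\[-0.5, 0.5\] min, slope U\[0.95, 1.05\], small
  quadratic/cubic terms redrawn until monotone); a global m/z bias uniform
  on +/-10 ppm; per-centroid m/z jitter 0.5 ppm. These are what the
  calibration stage must undo, per run.
* **Calibrants and noise.** Sodium-formate clusters (m/z = m(Na^+^) + n x
  m(NaHCO~2~), n = 1..7) appear in every scan and carry the run's ppm
  bias; random baseline centroids (Poisson 8 per scan, exponential
  intensity, mean 30 counts) provide chemical noise.

The generator does **not** emulate: ionization suppression between
co-migrating species, isotope envelopes, MS/MS spectra (MS/MS support is a
boolean provenance flag only), detector saturation, or electroosmotic-flow
physics. Passing tests therefore demonstrate correctness of the processing
chain under idealized peak shapes and independent noise — not performance
on real instrument data.

# Feature extraction

Extracted ion electropherograms (EICs) are built at +/-5 mDa. In automatic
mode, candidate m/z centers come from single-linkage clustering of all
centroids (split at gaps > 5 mDa; clusters under 5 centroids discarded;
species closer than 5 mDa merge — below the resolution of the rule).
Numerical choices in peak detection:

* noise = 1.4826 x MAD of the lowest-50% intensity points of the EIC,
  floored at 1 count (detector quantization); the lowest-50% rule is robust
  to peaks anywhere in the run, unlike a fixed pre-peak window;
* apexes must exceed S/N 15 (study gate) **and** be supported by >= 3
  consecutive scans at half height, which deterministically rejects
  single-scan spikes in sparse EICs;
* integration boundaries walk outward to the nearest valley or to 1% of
  apex, whichever comes first; the under-the-curve area is the trapezoidal
  integral (within 1% of the analytic value for an isolated Gaussian, the
  1%-of-apex truncation itself costing 0.24%);
* no smoothing is applied by default (centroided synthetic data are
  clean), keeping the analytic-area check unbiased;
* duplicates (same m/z within 5 mDa, apexes within one full width at half
  maximum) keep the higher-S/N record. The full-pipeline reference point
  of 122 features per run is met whenever the drawn peak widths resolve
  all planted pairs; the isobaric leucine/isoleucine pair (identical m/z,
  0.3 min apart) genuinely merges when both drawn sigmas are wide, in
  which case one feature of the pair is lost — the tests account for this
  with a ground-truth merge oracle. Calibrant m/z windows are excluded
  from feature discovery, as their continuous traces are not
  electrophoretic peaks.

The original study used a semi-automatic extraction script with manual
curation; this module is fully automatic.

# Calibration and alignment

m/z recalibration is a per-run **linear** map (gain, offset) fitted by
ordinary least squares of theoretical on observed sodium-formate cluster
positions (>= 3 required; TOF mass error is near-linear over one decade of
m/z). Migration-time alignment to the reference database uses a
third-order polynomial, fitted in two passes: pass 1 matches features to
references by m/z alone (3 ppm) within a wide +/-20%-of-run MT window,
keeping only unique matches and dropping m/z-ambiguous references (another
reference within 3 ppm — e.g. leucine/isoleucine, valine/glycine betaine,
sarcosine/alanine, creatine/guanidinopropanoate, glutamate/methylaspartate
— because isobars poison the fit); pass 2 removes anchors with residuals
above 3 x RMS and refits. A cubic requires >= 8 anchors (else linear), and
a fitted polynomial that is not monotone over the observed range has its
order reduced 3 -> 2 -> 1 until monotone: a non-monotone time axis is
physically inadmissible even though the nominal order is 3. Runs with
fewer than 3 calibrants or 4 anchors are flagged and fall back to identity
maps rather than aborting the experiment. Anchor selection and outlier
handling are this package's own scheme; the upstream description fixes
only the polynomial order.

# Identification

A feature is identified when a reference lies within 3 ppm in m/z **and**
3% in migration time (relative to the reference time — the convention
adopted here). Among references passing both gates, the assignment
minimizes the tolerance-normalized distance d = sqrt((dppm/3)^2 +
(dMT%/3)^2), with ties broken lexicographically by name, so matching is
deterministic under any input order. One-to-one matching is deliberately
not enforced: a reference claimed by two features (e.g. after peak
splitting) is flagged ambiguous rather than silently dropped. Confidence
flags are copied from the database (m/z + MT match; MS/MS-supported); no
spectral scoring is performed.

# Quantification, QC, preprocessing

Per-run matched features are assembled into a features x samples matrix:
identified features keyed by name (areas of split peaks summed), unknowns
clustered across runs by consensus m/z (3 ppm single linkage) and aligned
MT (3%). Missing cells receive half the feature's minimum observed area, a
standard below-detection convention; imputation counts are reported and
observed cells never change. Replicate QC computes per-group relative
standard deviations of corrected MT and area against the study gates (< 5%
and < 25%); with n = 3-4 replicates these estimates are noisy, so failing
features are *flagged* by default and dropped only on request. Groups with
fewer than two observations are recorded as not evaluable.

Preprocessing follows the median-normalize / log10 / scale convention:
each sample is multiplied by (reference median / sample median), the
reference being the median of sample medians — making the normalization
exactly invariant to per-sample multiplicative scaling (when the rescaled
sample is not itself the reference-defining one, a boundary case the tests
pin down); then log10; then per-feature autoscaling to mean 0 / sd 1.
"Data scaling" is not further specified upstream; autoscaling is the
common default and Pareto scaling is available as an option without any
fidelity claim. Zero-variance features map to all-zero rows.

# Sparse PLS-DA

The discriminant analysis is written from scratch. Classes are one-hot
encoded; X and Y are column-centred. Each component runs the NIPALS loop
with an X-weight sparsity step — w <- soft-threshold(X'u) keeping the
keepX largest absolute entries (threshold at the (keepX+1)-th largest
magnitude), renormalized; t <- Xw; a <- Y't normalized; u <- Ya — to
convergence (tolerance 1e-9 on the weight update, comfortably below the
1e-6 score agreement verified against an independently coded SVD-based
dense PLS oracle), followed by deflation of X and Y on t. Initialization
is deterministic (largest-variance Y column), so fits are reproducible
without seed bookkeeping. With keepX equal to the feature count the model
is exactly dense PLS-DA. keepX defaults to 30 per component, mirroring the
size of the reported influence ranking; no keepX is stated upstream.

Component selection uses stratified cross-validation with the fold count
capped at the sample size — "10-fold" at n = 11 degenerates toward
leave-one-out, with fold class proportions as even as integers allow.
Held-out samples are classified by nearest class centroid in score space;
predictions are pooled over folds into a balanced error rate (BER), and
the smallest component count attaining the minimum BER is chosen.
Influence ranking uses the absolute component-1 weight (ties by name),
the simplest defensible reading of "most influential features"; VIP
scores are available as an alternative ranking.

Two small-sample behaviors deserve explicit documentation:

* **Scaling leakage.** Autoscaling the full matrix before cross-validation
  couples each held-out sample to its training split (centred rows make it
  the negative sum of the others), which distorts error estimates at
  n = 11. The default CV mirrors the upstream global-scaling workflow;
  `rescale = TRUE` re-estimates scaling within each training fold, and the
  permutation-null check uses that mode at a fixed single component, where
  the null mean sits at the theoretical 2/3 chance level. At two or more
  components the permuted-label CV error rises *above* chance — a real
  property of overfit cross-validation under label permutation, not a
  defect.
* **Residual error on separable data.** Even with planted effects strong
  enough to separate the groups perfectly in the informative subspace, the
  Axe-vs-Ctrl contrast rests on only three planted features while keepX =
  30 admits ~27 noise features per component; held-out error therefore
  bottoms out near 0.17 rather than 0 at n = 11 (the same level an
  independent sPLS-DA implementation reaches on identical data). This is
  reported as a documented limitation of the sample size, not asserted
  away.

# Pathway overrepresentation

For a query of identified metabolites mapped onto a library universe
(unmapped names reported and excluded from the query size n), each pathway
of size K in a universe of N receives the exact hypergeometric upper-tail
p-value P(X >= k) for k observed hits, and a topology impact: betweenness
centrality (shortest-path, unit weights, endpoint-exclusive, undirected —
the conventional symmetrized treatment of compound graphs) normalized to
relative centralities summing to 1 (1/|V| each when all are zero), summed
over hit nodes, so impact lies in \[0, 1\] and reaches 1 when every member
is hit. Pathways are reported sorted by p, flagged significant at p < 0.05
with impact > 0.

The packaged pathway library is a **synthetic demo**: names and sizes are
shaped like the fruit-fly amino-acid pathways such analyses return (e.g. a
29-member arginine-and-proline pathway), with members mixing real
metabolite names and filler compound ids and edges forming plausible
reaction chains. Reproducing published p-values for real data would
require the exact KEGG-derived library and background universe size, which
are not distributed with such studies; exact-value reproduction is
therefore out of scope, while the algorithmic machinery is fully verified
against enumeration oracles. A random-library generator supports
planted-enrichment simulations.

# Problem sizes used by the test suite

The suite verifies alignment/identification recovery on 20 independently
seeded full runs, sPLS-DA ranking on 20 seeded abundance matrices, the
permutation null on 50 label shuffles, planted pathway enrichment on 100
random libraries, and exhaustive hypergeometric enumeration up to N = 12.
These sizes give stable pass/fail behavior for the stochastic properties
while keeping the default test run lightweight.

# Known limitations

* Peak shapes are ideal Gaussians; co-migrating isobars closer than one
  peak width merge (leucine/isoleucine being the canonical casualty).
* The QC gates at n = 3-4 replicates have low power; they flag rather
  than filter by default.
* The pathway stage operates on a demo library; conclusions about real
  pathway biology require supplying a real library in the documented JSON
  format.
* MS/MS evidence is modelled as a boolean flag; no spectral matching is
  performed.
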