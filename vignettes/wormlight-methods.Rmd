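---
title: "Methods: from transcript counts and luminescence traces to undulation statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from transcript counts and luminescence traces to undulation statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wormlight)
```

wormlight is a toolkit for characterizing rhabdomeric-opsin-expressing
sensory cell types in marine annelids — cephalic eye photoreceptors
(EP cells) and the segmentally repeated trunk r-opsin1-expressing
(TRE) cells — from four kinds of evidence: cluster-level transcript
quantification, enrichment-signature set logic, cross-species gene-set
overlap statistics, opsin spectral sensitivity from heterologous
dose–response assays, and periodogram-based scoring of undulation
behavior. This vignette describes each model, its assumptions, the
tunable parameters, and the design decisions taken where the
procedure was genuinely open. Every stage can be exercised on
synthetic data with known ground truth; the last section explains
what those tests do and do not establish about real data.

## Cluster-level quantification

De novo assemblies fragment genes into redundant, partially
overlapping transcripts. The quantification unit here is therefore a
*cluster*: `cluster_transcripts()` links two transcripts whenever they
share an exact substring of at least `min_overlap` bp (default 50 bp,
the read length the assembly was built from, so that a read maps
unambiguously to one cluster) and takes the transitive closure.
A shared substring of length ≥ *k* exists iff a shared *k*-mer exists,
so indexing canonical 50-mers makes the rule exact rather than
heuristic; matching is strand-agnostic by default
(`both_strands = FALSE` disables reverse-complement matches), and
windows containing `N` never match. Transcripts shorter than 250 bp
are discarded first (`filter_transcripts()`).

Each cluster gets a *nominal length*: the longest member plus, for
every other member in decreasing length order (ties broken by id),
the portions not covered by an exact ≥ 50 bp overlap with the growing
concatenate — equivalently, the length of the union of the members'
unique sequence. Expression is then

$$E_{gs} = \frac{C_{gs}}{L_g / 1000 \cdot N_s / 10^6},$$

counts per kilobase of nominal length per million counted reads,
where $N_s$ is the column sum of the count table — the only total a
count table can supply, so "reads in the sample" is interpreted as
mapped reads. A gene counts as *expressed* at ≥ 12 expression units in
at least one biological replicate (`is_expressed()`), roughly the
level below which enrichment cannot be called significantly.

## Enrichment signatures

`filter_low_counts()` applies the usual pre-filter before differential
testing: counts-per-million strictly greater than 1 in at least three
samples. The differential-expression engine itself (edgeR-style
negative-binomial testing) is deliberately an *input*, not a
component: `call_enriched()` consumes a table with group means and an
FDR column and calls a gene enriched iff FDR ≤ 0.05 (inclusive) *and*
its mean in the sorted population exceeds both unsorted backgrounds
(head and trunk). Means are taken on normalized expression values.
`partition_signatures()` splits two enriched sets into
population-specific and common signatures; the partition identities
(|specific| + |common| = |enriched|) are enforced by construction.

## Cross-species overlap statistics

Homology is assigned by best hit: for each query-species gene, the
target gene with the lowest e-value at or below `1e-20`
(`best_hit_map()`); ties break by higher bit-score, then lexicographic
target id. The stringent threshold can be relaxed (to, say, `1e-8`)
for short or fast-evolving proteins that have no hit at `1e-20`.

`permutation_overlap_test()` asks whether the homologs of a gene set
overlap a target signature more than chance: the observed statistic is
the number of *distinct* target genes (several queries may share one
homolog) hit by the set and present in the signature; the null draws
10⁴ same-sized sets uniformly without replacement from the
query-species universe and recomputes the statistic. The p-value is
the plain exceedance frequency; when no null set reaches the observed
overlap it is reported as the resolution bound p < 1/n_perm rather
than zero, with `p_is_bound = TRUE`.

Two numerical points deserve note. First, on an injective, fully
mapped universe the null is exactly hypergeometric, which the test
suite uses as a closed-form oracle; with many-to-one maps the null
departs from it, which is the reason the permutation construction
exists at all. Second, the overlap count is integer-valued, so the
plain p-value is discrete and sub-uniform under the null; calibration
diagnostics must use the randomized p-value
(`randomized_p()`, exactly Uniform(0,1) under exchangeability) or they
will flag a perfectly calibrated test as non-uniform.

## Spectral sensitivity and λ_max

Each luminescence trace reduces to a response amplitude: maximum
post-stimulus value minus the mean of the pre-stimulus baseline
window, unclamped (`peak_response()`). Per wavelength, responses
against log₁₀ irradiance are fitted with a variable-slope logistic

$$R(x) = B + \frac{T - B}{1 + 10^{\,h\,(\log EC_{50} - x)}}$$

with the bottom asymptote $B$ hard-fixed to the measured baseline
(`fit_dose_response()`, Levenberg–Marquardt with deterministic starts:
$T$ = max response, $h$ = 1, $\log EC_{50}$ = median dose). Fits that
do not converge or return a non-activating shape ($h \le 0$,
$T \le B$) are flagged, excluded from the spectrum with a warning, and
never silently used.

Relative sensitivity is reciprocal EC₅₀ normalized to the most
sensitive wavelength, $s(\lambda) = EC_{50}^{\min} / EC_{50}(\lambda)$,
so the spectrum's maximum is exactly 1. `fit_lambda_max()` scans
candidate peak wavelengths (default 400–550 nm at 1 nm) and minimizes
the sum of squared differences to the A1 retinaldehyde pigment
template (`govardovskii_template()`): an α-band
$1/(e^{A(a-x)} + e^{B(b-x)} + e^{C(c-x)} + D)$ with
$x = \lambda_{\max}/\lambda$, A = 69.7, B = 28, C = −14.9, D = 0.674,
b = 0.922, c = 1.104,
$a = 0.8795 + 0.0459\,e^{-(\lambda_{\max}-300)^2/11940}$, plus a β-band
Gaussian (amplitude 0.26, centre $189 + 0.315\lambda_{\max}$, width
$-40.5 + 0.195\lambda_{\max}$; disable with `beta_band = FALSE`). The
summed bands are renormalized to their own peak so values stay in
(0, 1]. An A2 (3,4-didehydroretinal) template is out of scope — a
marine invertebrate A1 pigment is assumed.

On precision: with the default assay design (nine bandpass
wavelengths, 8 doses spanning 3.5 decades — a 0–3.5 neutral-density
wheel in 0.5 steps — and three replicate responses per dose),
the statistical information available per curve bounds the standard
error of $\log EC_{50}$ at about 0.06 decades when response noise is
5% of the top asymptote; that corresponds to roughly ±4–5 nm spread in
the recovered λ_max. Recovery to within ±3 nm in ≳95% of runs holds at
the action-spectrum level (sensitivity errors around 0.05), and
exactly (to the grid) in the noise-free case; end-to-end noisy
recovery rates are computed, not assumed, by the acceptance script.

## Undulation behavior

Keypoint tracks carry seven named points (jaws, body1–body5, tail)
per frame. Quality control excludes any animal with a point annotated
in less than 90% of frames (`qc_tracks()`); interior gaps are filled
by linear interpolation and edge gaps by nearest-value extension,
where interpolation is undefined (`interpolate_missing()`).

`classify_window()` scores non-overlapping 10-s windows: for each of
the five trunk points a mean-removed, untapered periodogram is
computed per coordinate axis; the dominant frequency is the peak bin
(DC excluded) of the axis with the larger peak power, and movement is
the larger of the two axes' peak-to-peak ranges. A window is
*undulation* iff ANY trunk point moves 0.5–10 px (inclusive) with a
dominant frequency of 0.5–1.5 Hz (inclusive). "Total movement" is not
otherwise defined for keypoints, so the peak-to-peak range per axis
was chosen; the frame rate must satisfy the Nyquist bound
fps ≥ 2 × 1.5 Hz. Windows are aligned to the recording start.

`undulation_ratio()` bins window labels into 3-min bins;
`interval_auc()` integrates the ratio (trapezoid, bin midpoints, in
hours) over an analysis interval such as zeitgeber/circadian time
6–14 h; `compare_groups()` runs Shapiro–Wilk per group, a paired
Wilcoxon signed-rank test for light-vs-dark within genotype, and an
unpaired rank-sum test between genotypes, flagging significance at
α = 0.05. The large-sample Wilcoxon statistic is used without
continuity correction — AUC ties are common, so exact nulls are
unavailable anyway — and all-zero paired differences are reported as
a degenerate p = 1 rather than an error.

## Synthetic data: what it emulates, and what it does not

Each generator is seed-deterministic and returns its ground truth:

- `gen_transcript_clusters()` plants chains of transcripts with exact
  suffix–prefix overlaps and rejection-checks that different clusters
  share no 50-mer. It emulates assembly redundancy, not sequencing
  error: real overlaps can carry mismatches, which the exact-match
  rule (like the one used on real assemblies) would split.
- `gen_count_experiment()` draws negative-binomial counts
  (dispersion 0.1, a typical bulk biological CV²) for three groups ×
  three replicates, plants enriched genes at a chosen fold change in
  the sorted group, and emits an FDR column consistent with the truth.
  It does *not* re-implement a DE test — synthetic FDRs keep the set
  logic testable while leaving the DE engine an input.
- `gen_homology_universe()` builds injective or many-to-one best-hit
  maps with e-values below 1e-20 plus above-threshold decoy hits, and
  a query set hitting the signature at a planted multiple of the
  background rate.
- `gen_action_spectrum_data()` derives per-wavelength EC₅₀s from the
  pigment template at a known λ_max and samples 4PL responses on a
  per-wavelength dose grid centred on the true logEC₅₀ (a fixed
  absolute grid would leave off-peak wavelengths without upper
  asymptote coverage and the fit unidentifiable).
- `gen_tracks()` schedules sinusoidal bouts (per-point phase offsets,
  optional drift and missingness) on otherwise quiescent animals.
  Real worm kinematics — variable amplitude, aperiodic pauses,
  tube-building — are not modeled; window labels at bout boundaries
  are marked ambiguous and excluded from accuracy scoring.

Problem sizes in the test suite are desk-scale by design: ≤ 50
transcripts for clustering oracles, 10³-gene universes with 10⁴
permutations (2 × 10³ in the 200-run calibration study), 100 seeded
spectral recoveries, and 16 animals per group × 10 min of 5 fps video
for the behavioral comparison. Passing them shows the machinery is
correct under its stated model; it does not certify performance on
inputs violating those assumptions (mismatched overlaps, non-NB
counts, non-sinusoidal movement).

## Known limitations

- Clustering requires exact substring overlaps; highly polymorphic or
  error-rich assemblies may under-cluster.
- The 4PL fit assumes a saturating activating response; wavelengths
  that never approach saturation yield flagged fits and drop out of
  the spectrum.
- The permutation test conditions on the homology map; uncertainty in
  the map itself is not propagated.
- AUC comparisons assume a shared analysis interval across animals;
  recordings must cover it.
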