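# wormlight

Marine annelids such as *Platynereis dumerilii* carry rhabdomeric-opsin
photoreceptors in two very different places: the cephalic eyes (EP
cells) and a segmentally repeated population of trunk
*r-opsin1*-expressing (TRE) cells. Asking what these cell types share —
molecularly, spectrally, and behaviorally — requires a chain of small,
unglamorous computations that are easy to get subtly wrong: clustering
redundant assembly transcripts into genes, length-normalized expression,
enrichment set logic, cross-species overlap statistics on best-BLAST-hit
homology maps, EC50-based action spectra fitted with a visual-pigment
template, and periodogram-based scoring of undulation behavior from
keypoint tracks. wormlight implements that chain as a tested R package,
with seed-deterministic synthetic-data generators so every stage can be
validated against known ground truth.

## What it computes

- **Cluster quantification** — transcripts sharing an exact ≥ 50 bp
  substring (strand-agnostic) are grouped by transitive closure; each
  cluster gets a nominal length (longest member + non-overlapping
  remainder of the rest) and expression
  `E = C / (L/1000) / (N/1e6)` — counts per kilobase per million
  mapped reads. Expression call: ≥ 12 units in ≥ 1 replicate.
- **Enrichment signatures** — genes with FDR ≤ 0.05 whose sorted-cell
  mean exceeds both unsorted backgrounds; two enriched sets partition
  into specific and common signatures.
- **Cross-species overlap** — best tblastn-style hit at E ≤ 1e-20 maps
  each query gene to one target gene; the observed count of distinct
  signature targets is compared against 10⁴ random same-size query
  sets. Zero exceedances are reported as `p < 1/n_perm`.
- **Spectral sensitivity** — per-wavelength 4PL dose–response fits with
  the bottom fixed at baseline give EC50s; relative sensitivity
  `EC50_min / EC50(λ)` is scanned against Govardovskii A1 pigment
  templates to find the least-squares λ_max.
- **Undulation behavior** — 10-s windows of 7-point keypoint tracks are
  undulatory when any trunk point moves 0.5–10 px with a dominant
  periodogram frequency of 0.5–1.5 Hz; ratios per 3-min bin, AUC over
  ZT/CT intervals, Shapiro–Wilk and Wilcoxon group comparisons.

## Worked example

```r
library(wormlight)

# spectral sensitivity: noisy dose-response data simulated from a
# 471 nm pigment, fitted back through peaks -> EC50s -> template scan
d   <- gen_action_spectrum_data(lambda_max = 471, noise_sd = 10, seed = 42)
res <- action_spectrum_pipeline(d$doses, baseline = 100)
res$template_fit
#> Template fit: lambda_max = 473 nm (ss = 0.01467, grid 1 nm)
head(res$spectrum, 3)
#>   wavelength         ec50 sensitivity
#> 1        420 6.177443e+13   0.4897482
#> 2        442 4.459893e+13   0.6783552
#> 3        458 3.216557e+13   0.9405685

# cross-species overlap of a planted-enrichment query set
g   <- gen_homology_universe(n_query = 1000, n_target = 800,
                             mapped_frac = 0.6, signature_size = 80,
                             planted_enrichment = 4,
                             query_set_size = 60, seed = 42)
map <- best_hit_map(g$hits)
permutation_overlap_test(g$universe, g$query_set, map, g$signature,
                         n_perm = 10000, seed = 1)
#> Cross-species overlap permutation test
#>   observed overlap: 13 distinct target genes
#>   null (10000 sets): mean 3.34, sd 1.7
#>   p < 1e-04

# signature set arithmetic
partition_signatures(paste0("g", 1:278), paste0("g", c(1:133, 400:627)))
#> Signature sets:
#>   EP-enriched:  278
#>   TRE-enriched: 361
#>   common:       133
#>   EP-specific:  145
#>   TRE-specific: 228
```

The recovered λ_max of 473 nm sits 2 nm from the planted 471 nm truth
under 2% response noise; the overlap of 13 distinct targets against a
null of mean 3.3 is beyond the 10⁴-permutation resolution, hence the
bound `p < 1e-04`; and 278/361 enriched genes with 133 shared leave 145
and 228 population-specific genes.

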