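---
title: "Methods and modelling choices in floralshift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and modelling choices in floralshift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(floralshift)
```

`floralshift` implements the quantitative core of a multilevel study design
for intraspecific floral colour transitions: scent chemistry, bee-perceived
colour, antennal physiology, behavioural preference, phenotype derivations,
trait integration and genome-wide variation. This vignette documents the
models, the parameters that matter, the numerical conventions, and what the
synthetic-data generators do and do not emulate.

## Floral volatiles

### The filter cascade

GC-MS peak exports from a sensitive default integrator contain many
artefactual rows. Four predicates are applied in sequence
(`filter_peaks()`), each depending only on the individual peak and the
fixed blank table, so the retained set equals the joint conjunction
regardless of order (a tested invariant):

1. **Area** (`min_area`, default 1e5 counts): peaks *under* the threshold
   are integrator noise. The stated thresholds are worded as "under" and
   "after", so equality is retained throughout — boundaries are strict.
2. **Retention** (`max_retention`, default 30 min): later-eluting compounds
   are too heavy to be plausible airborne attractants.
3. **Blank subtraction**: a sample peak is background if some blank peak
   shares its *top-ranked* library identification, elutes within
   `blank_rt_window` (0.1 min), and the sample area is less than
   `blank_fold` (5) times the blank area. Matching on the top-ranked hit is
   the default because ranked triples make "the same tentative
   identification" ambiguous; `blank_match = "any"` relaxes this to any
   shared hit. Any qualifying blank peak excludes the sample peak; the
   nearest-in-time trigger is recorded in the exclusion log.
4. **Contaminants**: a peak is removed only when *all three* library hits
   contain a contaminant substring (`silox`, `silic`, `phthal`,
   case-insensitive) — one clean hit keeps the peak.

The manual "visual comparison of spectra" step that bench chemists apply to
uncertain peaks has no computational counterpart and is deliberately not
emulated; the cascade is the reproducible subset of the workflow.

### Kovats retention index

Oven programs here are temperature-ramped, so `kovats_index()` uses the
linear (van den Dool–Kratz) convention,
$RI = 100n + 100\,(t - t_n)/(t_{n+1} - t_n)$, not the isothermal
logarithmic form. The index is exactly $100n$ at every alkane rung,
piecewise-linear and strictly increasing inside the ladder span, and an
error outside it (no extrapolation: an index outside the calibrated range
is not interpretable).

### Quantification

`quantify_emissions()` inverts each compound's standard curve,
$\mathrm{mass}_{ng} = \max(0, (\mathrm{area} - b)/m)$, and divides by a
per-sample scaling factor. The default scaling $2 \times 24 = 48$ encodes
two flowers per headspace sample collected over 24 h; elution volume,
aliquot concentration and injection volume are absorbed into a single
configurable calibration factor (default 1) because these cancel only under
a protocol-specific bookkeeping that the package cannot know. Compounds
without their own standard are routed to a named structurally similar
surrogate curve via the `surrogates` map. Negative back-calculated masses
(area below the curve intercept) clip to zero with a warning rather than
propagating as negative emissions.

Group contrasts use `fold_change()` (ratio of group means) and `welch_t()`
(unequal-variance t test, Welch–Satterthwaite df).

## Bee colour vision

Reflectance spectra are averaged hierarchically
(technical replicates → flower → plant → line) so each biological unit
contributes equally regardless of replicate counts. All spectra entering a
model must share one grid; `interpolate_spectrum()` harmonizes measured
spectra onto 1-nm steps over 300–700 nm, the range relevant to insect
vision.

Receptor sensitivities come from the Govardovskii-family A1 visual-pigment
nomogram (`receptor_template()`). The default uses the alpha band only, so
the curve peaks exactly at $\lambda_{max}$; the optional beta band
(`beta = TRUE`) adds the short-wavelength shoulder, at the cost of shifting
the combined UV-receptor peak a few nm below its nominal $\lambda_{max}$
where the two bands overlap. Default peak wavelengths are the standard
honeybee triple (344, 436, 544 nm), configurable for other trichromats.

Quantum catches are Riemann sums $Q = \sum R(\lambda) S(\lambda)
I(\lambda)\,\Delta\lambda$; the illuminant defaults to flat (equal-energy)
because the downstream quantities are ratios in which a smooth daylight
spectrum changes little, and no standard choice is canonical for glasshouse
conditions. von Kries adaptation divides by the catch of the adapting
background; the bundled `green_leaf_background()` is a *synthetic* smooth
green-foliage curve (documented as such) — supply a measured leaf spectrum
for real analyses. The hexagon transduction $E = q/(q+1)$ and coordinates
$x = \tfrac{\sqrt3}{2}(E_g - E_{uv})$, $y = E_b - (E_{uv}+E_g)/2$ place the
background at the origin; distance from the origin is the chromatic
contrast statistic. A tested invariant: any stimulus proportional to the
background maps exactly to the origin (uniform intensity scaling is
invisible under von Kries adaptation), and this holds *only* for uniform
proportionality across receptors.

No receptor-noise (RNL) discriminability, tetrachromatic models or
ordination of reflectance are included.

## EAG normalization

Antennae fatigue over a session, roughly multiplicatively. The positive
control is presented in blocks (first, middle, final); `control_baseline()`
summarizes each maximal run of consecutive control presentations by its
mean index and mean amplitude, interpolates linearly between blocks and
extends constantly beyond them. Linear interpolation is the minimal drift
model given three anchors; it cancels any drift that is linear between
anchors exactly (a tested property) and approximates exponential fatigue
well at realistic decay rates. `drop_first_responses()` removes the first
presentation of each test stimulus (solvent blow-off) before
normalization. Corrected amplitude is raw/baseline; the scaled amplitude
re-references to the initial control, and because "the initial response"
could mean the very first presentation or the first block's mean, the
package defaults to the block mean (robust to single-presentation noise)
with `scale_ref = "first_presentation"` as the alternative; under the
default the two outputs coincide.

Mixed-model inference on the normalized responses is out of scope; the
module outputs tidy normalized responses, and `welch_t()` serves for simple
group contrasts.

## Choice statistics

`chisq_gof()` is the uncorrected two-cell goodness-of-fit statistic against
a 50:50 null — no Yates correction, which is what reproduces published
worked examples of this design exactly (e.g. 59 vs 30 visits gives
$\chi^2_1 = 9.45$). Pooling across trials (`pool_counts()`) supports
visits, probes, summed handling seconds (rounded to whole seconds when
treated as counts) and per-bee first choices. Handling-time GLMMs with
per-bee random effects are out of scope; `per_bee_summary()` provides the
per-bee layer such models would consume, and its margins reproduce the
pooled counts exactly (tested). Trials in which a bee never foraged are
simply absent from the event log: only successful trials carry events.

## Trait integration

`pcc_census()` computes all $k(k-1)/2$ pairwise Pearson correlations on
pairwise-complete observations, with p-values from
$t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ df (identical to `cor.test()`, which
the tests use as an independent cross-check). Significance is counted at
unadjusted $\alpha = 0.05$ — the census is a descriptive integration
summary, not a family of confirmatory tests, and published pair-census
arithmetic of this kind is unadjusted. Constant columns are dropped with a
warning; pairs with fewer than three complete observations are excluded
from the census. One published census of this kind prints 34 traits with
544 pairwise comparisons — internally inconsistent (34 traits give 561
pairs) — so pair counts should always be recomputed from the trait count,
which is what `n_pairs()` is for. Reflectance principal components enter as
precomputed trait columns; the PCA itself is routine and out of scope.

`category_f_test()` is the classical one-way ANOVA F on |PCC| values
grouped by line, and `terpenoid_carotenoid_correlation()` tests the
biosynthetic-precursor tradeoff between total terpenoid emission and total
carotenoids within colour groups.

## Variant-density tracks

`window_counts()` tiles each chromosome with fixed-width windows stored
0-based half-open; VCF positions are 1-based, so position $p$ falls in the
window containing $p-1$. The conversion lives in one place and is tested at
the boundaries. Total counts are conserved per chromosome (tested
invariant). Sites, not alleles, are counted: a multi-allelic record is one
variant. `window_size` is deliberately a required argument: both 50 kb and
30 kb have been used for this analysis in the motivating literature, and a
silent default would bake in one of them.

`smooth_track()` implements Savitzky–Golay smoothing: a centred local
least-squares quadratic over $2 \cdot \mathrm{neighbors} + 1$ windows
("50 neighbors" means 50 per side, a 101-point window — the convention of
the plotting software family the phrase comes from). At the edges the
window shrinks symmetrically, which keeps polynomial signals of degree
$\le 2$ exactly reproduced everywhere, not just in the interior (tested).
`overlay_summary()` compares two species' tracks on a shared grid via
per-window differences and per-chromosome Spearman rank correlations;
statistical testing of such divergence is intentionally not provided, as
the comparison is descriptive.

## Synthetic data: what it does and does not show

The `synth_*` generators fix the study conditions once:

- `synth_gcms()`: 15 samples per colour group, true emission fold 2.3,
  log-normal area noise (CV 0.25), plus injected integrator noise
  (sub-threshold areas), late eluters, all-contaminant hit triplets and
  blank-shared background peaks placed within 0.1 min of their blank
  counterparts — so every filter stage is exercised and the true fold is
  recoverable end-to-end.
- `synth_spectra()`: a yellow-like line (high plateau above ~520 nm with a
  small UV bump, a subtle bullseye) and a red-like line (dark below 600 nm
  with a sharp long-wavelength shoulder), Gaussian noise, and the synthetic
  green-leaf background.
- `synth_eag()`: nine antennae, control blocks of four at first/middle/
  final positions, amplitudes $A e^{-ki} \rho_s (1+\varepsilon)$ with
  $k = 0.04$, multiplicative noise (SD 0.05), and inflated first
  presentations for the outlier rule to remove.
- `synth_choice()`: ten successful trials, visits per bee zero-truncated
  Poisson(9), $P(\mathrm{yellow}) = 2/3$ — the two-to-one preference
  regime.
- `synth_variants()`: inhomogeneous Poisson positions with
  piecewise-constant intensities over mock chromosomes (2 Mb and 1.5 Mb by
  default), written as plain-text VCF.

These magnitudes (fold ≈ 2.3, preference ≈ 2:1) are the observed scale of
real red/yellow morph contrasts, so recovery tests run in a realistic
regime. Determinism is by integer seed through R's RNG: identical seeds
give identical outputs (tested).

What passing these tests shows: the pipeline's algebra, conventions and
statistical calibration are correct, and known effects of realistic size
survive the full processing chain. What it does not show: performance on
real chromatograms (co-elution, baseline drift, library mis-hits),
measured reflectance (specular artefacts, instrument noise structure),
real antennal preparations, or real genomes — raw instrument data live
outside the package and are not emulated at signal level.

## Validation problem sizes

The suite validates the filter cascade against a brute-force four-predicate
oracle on 1 000 random peak tables; χ² calibration uses 10 000 simulated
pooled experiments (type-I error within ±0.01 of 0.05; power ≥ 0.85 at
$P(\mathrm{yellow}) = 2/3$ with ~90 pooled visits); fold-change recovery
uses 25 full pipeline replicates at 15 samples/group (recovered mean within
3 Monte-Carlo SE of 2.3); the hexagon yellow-versus-red contrast ordering
is checked over 100 generator seeds (≥ 95% must order correctly); EAG ratio
recovery uses 9 antennae with 3-SE bounds. These sizes were chosen to make
Monte-Carlo error comfortably smaller than the effects being verified while
keeping the suite fast on a laptop.

## Known limitations

- The cascade reproduces the *rule-based* part of peak curation only; no
  spectral deconvolution or library searching.
- The hexagon model gives relative contrast geometry; absolute
  discriminability would need a receptor-noise model.
- EAG baseline anchoring assumes fatigue is multiplicative and smooth
  between control blocks; step changes (e.g. preparation drift) violate it.
- The integration census treats p < 0.05 descriptively; no multiplicity
  control is applied or implied.
- Nectar volume uses the printed capillary constant 103.87 µL (full
  length), which agrees with $\pi r^2 h$ at $r = 0.575$ mm to the rounding
  of that constant.
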