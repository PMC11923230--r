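# floralshift

Analysis toolkit for studying **intraspecific red-to-yellow floral colour
transitions** and the incipient pollinator shifts they may represent (e.g.
hummingbird-pollinated monkeyflowers evolving toward bumblebee attraction).
Such studies span many biological levels at once — floral scent chemistry,
colour as bees see it, antennal physiology, behavioural choice, phenotype
integration and genome-wide variation — and `floralshift` packages the
recurring computational steps of that workflow for R users:

- **Floral volatiles (GC-MS)** — a four-stage peak-filter cascade
  (minimum area 1×10⁵ counts; retention ≤ 30 min; blank subtraction: a peak
  is background if a blank peak with the same top library hit elutes within
  0.1 min and the sample area is < 5× the blank area; contaminant removal
  when *all three* library hits contain siloxane/silica/phthalate terms),
  Kovats retention indices by the van den Dool–Kratz formula
  `RI = 100n + 100(t − tₙ)/(tₙ₊₁ − tₙ)`, standard-curve quantification to
  ng/flower/hour, total emissions, group fold-changes, Welch t tests.
- **Bee colour vision** — hierarchical replicate averaging of reflectance
  spectra (300–700 nm), Govardovskii-family receptor templates, quantum
  catches `Q = Σ R(λ)S(λ)I(λ)Δλ` with von Kries adaptation to a green
  background (`q = Q/Q_bg`), hexagon transduction `E = q/(q+1)` and the
  colour-hexagon coordinates
  `x = (√3/2)(E_g − E_uv)`, `y = E_b − (E_uv + E_g)/2`; distance from the
  origin approximates chromatic contrast against green foliage.
- **Electroantennography (EAG)** — removal of inflated first responses,
  piecewise-linear drift baselines through interleaved positive-control
  (PAA) anchor blocks, and normalization of responses as fractions of the
  local control.
- **Pollinator choice** — pooled and first-choice χ² goodness-of-fit tests
  against a 50:50 null (no continuity correction), per-bee summaries.
- **Phenotypes** — mass-standardized pigment absorbance (AU/g), capillary
  nectar volume (`h/100 × 103.87` µL for a 1.15 mm × 100 mm capillary),
  signed herkogamy.
- **Trait integration** — all-pairs Pearson correlation censuses with pair
  counts `k(k−1)/2`, percent-significant summaries, one-way F comparisons
  of |PCC| distributions, terpenoid–carotenoid tradeoff correlations.
- **Genome-wide variants** — per-window variant-site counts from VCF
  (1-based positions, 0-based half-open windows) and Savitzky–Golay
  (2nd-order, 50-neighbour) smoothing for cross-species overlays.
- **Synthetic data** — seeded generators (`synth_*`) that emulate every
  input shape above with known ground truth, used throughout the test suite
  for parameter recovery.

## Worked example

Process a synthetic GC-MS experiment with a known 2.3-fold emission
difference between yellow and red morphs, and test a pooled bee-choice
result:

```r
library(floralshift)

syn <- synth_gcms(seed = 42)                 # 15 samples/group, fold = 2.3
res <- filter_peaks(syn$peaks, syn$blanks)   # four-stage cascade
table(res$log$rule)
#>   blank_match   contaminant max_retention      min_area
#>            54            64            21            77

em  <- quantify_emissions(res$peaks, syn$curves, scaling = 48,
                          ladder = syn$ladder)
head(em, 3)
#>   sample_id     compound emission kovats_ri
#> 1       s01 alpha-pinene 388.4858  850.7658
#> 2       s01 beta-myrcene 165.0481 1108.3919
#> 3       s01     sabinene 184.6066 1364.5110

tot <- merge(sample_totals(em), syn$samples)
fold_change(tot$total[tot$group == "yellow"],
            tot$total[tot$group == "red"])
#> [1] 2.460864

chisq_gof(59, 30)
#> Choice preference: yellow 59 vs red 30 (66.3% yellow)
#>   chi-square(1) = 9.449, p = 0.002112
```

The exclusion log shows each filter doing its job (77 sub-threshold peaks,
21 late eluters, 54 blank-matched background peaks, 64 contaminants); the
estimated fold-change 2.46 sits within sampling error of the generator's
true 2.3 at n = 15 samples/group; and 59 visits to yellow versus 30 to red
rejects the no-preference null (χ²₁ = 9.45, p ≈ 0.002) — a two-to-one
preference for the yellow morph.

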