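---
title: "Quantifying radiation-induced plasmid DNA damage with radbreaks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying radiation-induced plasmid DNA damage with radbreaks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radbreaks)
```

## The assay and the model

A supercoiled (SC) circular plasmid relaxes to an open circle (C) at its
first single-strand break (SSB), linearizes (L) at a double-strand break
(DSB), and fragments (F) when cut twice or more. Agarose gel
electrophoresis separates these forms into bands, so a band-intensity
profile per irradiated sample encodes the molecule's break load. With
breaks accumulating independently (Poisson statistics), a population with
mean `x` SSBs and `y` DSBs per molecule partitions as

$$f_{SC} = e^{-x-y},\qquad f_C = (1-e^{-x})\,e^{-y},\qquad
  f_L = y\,e^{-y},\qquad f_F = 1-(1+y)\,e^{-y},$$

which `cowan_fractions()` evaluates and `cowan_invert()` inverts in closed
form. The SSB load always comes from the SC:(SC+C) ratio,
$x=\ln((f_{SC}+f_C)/f_{SC})$, which no lane normalization can disturb. For
the DSB load the normalization matters: gels cannot integrate the fragment
smear, so practical lanes are renormalized over the three full-length
bands. Under that convention $-\ln(f_{SC}+f_C)$ is biased by
$\ln(1-f_F)$ — about $-4\%$ at the top of the usable dose range — and the
package instead uses the exact, normalization-invariant form
$y = f_L/(f_{SC}+f_C)$. The textbook logarithmic form remains available via
`normalization = "all"` for fractions of the entire population, and a lane
with no detectable SC band is reported as saturated rather than forced
through the logarithm.

An optional first-order term converts coincident opposite-strand SSBs
within a gap of `h` bp (default 10) into DSBs, moving
$x^2(2h+1)/4L$ between the channels. It is off by default: it is a
sub-percent correction to the SSB channel on a 4361-bp plasmid, and
keeping it off leaves the closed-form inversion exactly consistent with
the forward model. The matching conversion rule in the simulator's
topology classifier is likewise off by default and configurable.

## From fractions to yields

G-values (events Mbp$^{-1}$ Gy$^{-1}$) are slopes of events-per-Mbp
against dose with a free intercept (`fit_g_value()`). Two numerical
choices matter in practice:

* **Dose window.** Above the dose where the supercoiled fraction falls
  under about 1%, the SSB inversion saturates. `g_values()` therefore
  restricts each fit to doses whose mean SC fraction is at least `min_fsc`
  (default 0.01), found adaptively per series: enzyme-treated series carry
  roughly triple the break rate and saturate near 4 Gy where the untreated
  series is usable to 10 Gy, so a fixed window would be wrong exactly
  where the enzyme differences are formed.
* **Uncertainty.** Inverted break numbers are strongly heteroscedastic:
  counting noise grows as the SC band empties, and multiplicative
  densitometry noise saturates with dose. Lane variances are propagated by
  the delta method (`cowan_invert_var()`), evaluated at dose-level mean
  fractions so that weight fluctuations do not correlate with lane errors
  (per-lane empirical weights drag a weighted slope downward), and the
  reported sem is the larger of the known-variance WLS error and the
  residual-based error with a Student-t small-sample correction. The
  convention is deliberately conservative: downstream recovery checks read
  ±2 sem as a ~95% interval.

Base lesions and non-DSB clustered lesions come from enzyme differences
(`enzyme_differences()`): Fpg converts oxidized purines and Nth oxidized
pyrimidines into extra breaks, so excess SSBs measure base lesions and
excess DSBs measure opposed-lesion clusters. The two enzyme classes are
disjoint, hence the default summation (configurable to the mean). The
untreated slope enters the sum twice, so its variance contributes
four-fold to the quadrature. Negative point estimates are flagged, never
clipped, to keep simulation nulls honest.

One correction is applied before differencing (`coincidence_correct()`):
enzymatic cleavage multiplies the SSB load, and some new breaks land
opposite unrelated existing breaks by chance, registering as spurious
clustered DSBs. For independently placed breaks the expected excess is
$(x_{enz}^2 - x_0^2)(2h+1)/4L$ — an accidental-coincidence background in
the counting-experiment sense — which is subtracted from the enzyme-lane
DSB load (and restored to its SSB load, which the fused molecules left).
Genuinely clustered lesions are spatially correlated and survive the
correction.

Summary statistics are plain arithmetic on the yields: damage-based RBE is
the DSB induction ratio against the X-ray reference (`rbe()`), and
`damage_ratio()` forms the clusters/DSB, base-lesions/SSB and SSB/DSB
summaries. Scavenging capacity is the product $k \times S$
(`scavenging_capacity()`), with Tris at $1.5\times10^9$ and C3CA at
$6.8\times10^9\ \mathrm{M^{-1}s^{-1}}$; the no-added-scavenger condition
is represented as residual buffer at $10^5\ \mathrm{s^{-1}}$, not zero, so
log-capacity plots and `protection_table()` reductions stay defined.

## The synthetic experiment

`sim_config()` + `simulate_population()` generate the populations a
beamline irradiation would have produced. Defaults are the proton
beam-entrance condition: 101.101 SSB, 1.914 DSB, 275.852 base lesions and
10.908 non-DSB clusters Mbp$^{-1}$Gy$^{-1}$, a 0/1/2/4/8/10/15/20/30/50 Gy
dose panel, 10-bp cluster window, 5% band-intensity coefficient of
variation and a unit supercoiled dye factor.

The generator is parameterized at the *assay level*: the configured SSB
yield is what a noiseless gel would report (including the break member of
each planted cluster), the base-lesion yields are the net enzyme-revealed
excesses, and the cluster yield is the rate of strand-break-plus-opposed-
base-lesion pairs that convert to DSBs under cleavage. Internally the
isolated-lesion rates are adjusted (isolated base rate = configured base
rate + cluster rate per class) so that every configured number equals the
low-dose expectation of its estimator. That makes parameter recovery
well-defined without bookkeeping gymnastics in the analysis code.

Scavenging scales every channel by
$(1-\varphi) + \varphi\,c_0/(c_0+\mathrm{capacity})$ with
$\varphi = 0.9$ (the dominant, scavengeable indirect pathway) and
$c_0 = 10^5\ \mathrm{s^{-1}}$. The study this package models reports only
empirical protection points; this saturating competition law is a
documented modeling choice for test generation — monotone and bounded,
which is all the downstream analysis assumes — not an inference from data.

What the simulator deliberately does not emulate: LET-dependent spatial
correlation of breaks along particle tracks, dose-rate effects, enzyme
titration artifacts, gel migration physics and band-shape effects. Passing
recovery tests therefore demonstrate that the estimator stack is unbiased
and calibrated *under the stated noise model*, not that real gels are free
of systematic error.

A validation loop, `recovery_study()`, simulates complete experiments
(four measurement replicates — duplicate gels with duplicate image
analyses — untreated doses 0–10 Gy, enzyme-treated 0–4 Gy, 5000 molecules
per lane) and checks each planted yield against its ±2 sem interval. At
these problem sizes a 500-run study completes in minutes and covers at
roughly the nominal 95%.

## AFM contour lengths

`render_afm()` draws fragments as discrete worm-like chains (5-nm steps,
50-nm persistence length — the canonical dsDNA value) or as gently
wobbling rings, places them without overlap, stamps them at 0.5 nm height,
applies a Gaussian tip point-spread (10 nm) and adds background noise on
the standard 512 × 512 px, 5 × 5 µm geometry (9.766 nm/px).

`afm_measure()` runs the measurement chain: threshold segmentation into
8-connected components, Zhang–Suen thinning reduced to a minimal
8-connected curve (staircase corners collapse to diagonal steps), spur
pruning (short endpoint-to-junction branches are removed; a junction with
a single long continuation keeps its longest short branch, which is the
genuine curve end), endpoint-to-endpoint or around-the-loop tracing, and
chain-code length. Skeletons that retain junctions are excluded as
branched/overlapping molecules rather than cut apart — a deterministic
stand-in for the manual curation a semi-automatic tool would allow.

Two estimator choices matter:

* `chain_code_length()` is the plain Freeman estimator (orthogonal steps
  1, diagonal steps $\sqrt2$). On straight digital segments it
  overestimates by up to 8% depending on orientation, so molecule
  measurement defaults to the corner-corrected digital length
  (Vossepoel–Smeulders coefficients 0.980/1.406/−0.091), accurate to ~1–2%
  on smooth curves at any orientation. The plain estimator remains
  available (`estimator = "freeman"`).
* Open-curve ends erode during thinning. Each end is extended sub-pixel
  along its tangent through the bilinearly interpolated height field up to
  the threshold contour, and a constant overshoot (0.6 px per end,
  calibrated once against rendered ground truth for the default imaging
  model) is subtracted.

With these defaults, rendered straight 500-nm fragments are each
recovered within 5%, and full-length rings calibrate the pixel scale
within 2% (`afm_calibrate()` uses the median ruler length, robust to a
partially compacted ruler). The per-molecule resolution floor is set by
pixel quantization: the skeleton length of a single molecule scatters by
roughly ±1 px (≈10 nm), so individual fragments below roughly 250 nm carry
more than 5% scatter even though the *distribution* of measured lengths
remains unbiased down to well under 100 nm. Apparent lengths are reported
as-is — supercoiled molecules adsorb compactly and read short, and no
unfolding correction is attempted.

`length_distribution()` bins lengths into half-open 50-nm bins over
0–1550 nm (31 bins), with relative frequencies over in-range molecules and
a separate overflow tally.

## Worked example

```{r example, eval = FALSE}
scn <- read_scenario(system.file("extdata", "example_scenario.yaml",
                                 package = "radbreaks"))
lanes <- simulate_scenario(scn, seed = 1)
report <- run_report(lanes, reference_condition = "xray", seed = 1)
report
write_report(report, "yields.csv")
```

Every number the report prints is recomputed from the lane intensities at
run time; two runs on the same inputs are byte-identical.

## Degenerate inputs and edge rules

* Lanes with zero total full-length intensity (pure fragment smears) are
  flagged degenerate and rejected with row numbers.
* Observed fractions are clipped to $[10^{-9}, 1-10^{-9}]$ before
  logarithms; an SC fraction below $10^{-6}$ marks the lane saturated and
  its SSB estimate is withheld instead of clipped into pseudo-data.
* `f_sc + f_c \ge 1` alongside a positive linear band is rejected as
  inconsistent.
* Fragment arcs are cut at DSB coordinates on a 0-based circular bp map;
  per-molecule fragment lengths sum to the full contour exactly, and `m`
  cuts yield `m` fragments.
* Opposed-pair fusion is greedy, shortest circular distance first with
  position tie-break, making enzyme action deterministic given the lesion
  map.

## Known limitations

The competition law and the lesion spatial model are generative choices,
not fitted laws; real scavenging curves need not follow them. The gel
noise model is multiplicative and band-independent, whereas real
densitometry errors correlate across bands in a lane. The AFM pipeline
measures apparent lengths only — it does not classify SC/C/L conformations
and excludes crossed molecules, which truncates the long tail of crowded
fields at high surface density.
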