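---
title: "Simulating biofluid 1H NMR spectra with mixnmr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating biofluid 1H NMR spectra with mixnmr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mixnmr)
```

## The mixture model

A processed 1D 1H NMR spectrum of a metabolite mixture is, to an
excellent approximation, a linear combination of the spectra of its
pure components. mixnmr simulates a mixture spectrum as

$$ y(\delta) = \sum_{k=1}^{K} c_k \, p_k \, \gamma_k(\delta) $$

where $\gamma_k$ is metabolite $k$'s pure spectrum on a shared
chemical-shift grid, $c_k$ its concentration and $p_k$ its observable
proton count. The package normalizes each library spectrum so that its
trapezoidal integral equals $p_k$ (one area unit per proton at unit
concentration). With $p_k$ baked into $\gamma_k$, the simulation is a
pure weighted sum: superposition and homogeneity hold exactly, and the
integral of any isolated resonance region is proportional to the
concentration that generated it. That linearity is load-bearing: it is
what makes the cohort simulations below usable as labelled training
data, and it is what the test-suite checks to $10^{-12}$.

Three spectrum types are supported: plain 1D, 2D J-resolved (multiplet
structure separated onto the F1 axis in Hz) and 2D COSY (symmetric
matrices with diagonal and cross peaks). 2D grids are kept on the same
intensity budget as the 1D records: each per-metabolite matrix is
scaled so that the F2 integral of its F1 column sums equals the 1D
proton area, and 2D mixtures are then the same weighted sum.

## Concentrations: biofluid statistics and cohort designs

Concentration metadata follows the HMDB conventions. Sources reporting
a min--max range are converted with the 3-sigma rule — the range is
read as a 99.7% interval, so mean $=(min+max)/2$ and SD
$=(max-min)/6$ — and multiple sources for one metabolite are pooled by
unweighted averaging of means and of SDs (the SD average is over SDs,
not variances; both choices are deliberately simple and documented
here because the upstream curation conventions do not prescribe
weights).

Replicate concentrations are drawn from a normal distribution
truncated below at zero (inverse-CDF sampling, so the draw is exact
and seedable). Two cohort designs are available.

**Discrete (case--control).** Each group has its own (mean, SD) per
metabolite, given directly or derived from the reference group by a
fold change and SD ratio. Optional inter-metabolite correlation is
imposed with a Gaussian copula: draw multivariate normal scores with
the target correlation matrix, rescale to the stated marginals, clamp
at zero. A non-PSD target matrix is repaired by eigenvalue clipping at
$10^{-8}$ and rescaling to unit diagonal (PSD inputs pass through
untouched, and the repair is logged). Clamping — rather than proper
multivariate truncation — slightly distorts marginals and correlations,
but the distortion is negligible whenever mean/SD $\ge 3$, which holds
for the default fixture statistics.

**Continuous.** Metabolites track a biological response $y$ (age,
BMI, ...) through a standardized linear model

$$ z_x = a\, z_y + \varepsilon_x, \qquad
   \varepsilon_x \sim N(0, \sigma_\varepsilon^2), $$

where $z_y$ standardizes the $n$ drawn responses by their *sample*
mean and SD (hence the requirement $n \ge 3$). The user states the
target Pearson correlation $a$ and the error SD. Note the model is
written as a regression of the metabolite on the response: with
$\sigma_\varepsilon = \sqrt{1-a^2}$ the population correlation equals
$a$ exactly, while for any other error SD the realized correlation is
$a/\sqrt{a^2+\sigma_\varepsilon^2}$. The error is placed on the
standardized scale, which is where the model equation lives; whether
the original description intended the raw scale is ambiguous, and this
choice is the documented one. With $a = 0$ and no error SD the
metabolite is simply constant at its mean.

## pH-dependent peak shifting

Resonance positions of ionizable metabolites depend on sample pH. For
a peak cluster with acid-limit position $\delta_L$ and basic-limit
position $\delta_{HL}$, moving the sample from the reference pH
(default 7.4, the pH of the standard reference spectra) to pH$_1$
displaces the cluster by a Henderson--Hasselbalch transform:

$$ \Delta\delta = (\delta_L - \delta_{HL}) \,
   \frac{10^{\,\mathrm{pH}_0 - \mathrm{p}K_a} - 10^{\,\mathrm{pH}_1 - \mathrm{p}K_a}}
        {\left(1 + 10^{\,\mathrm{pH}_0 - \mathrm{p}K_a}\right)
         \left(1 + 10^{\,\mathrm{pH}_1 - \mathrm{p}K_a}\right)} $$

The implementation evaluates the algebraically identical logistic form
$(\delta_L-\delta_{HL})\,[f(\mathrm{pH}_0-\mathrm{p}K_a) -
f(\mathrm{pH}_1-\mathrm{p}K_a)]$ with $f(x) = 1/(1+10^{-x})$, which
cannot overflow however far pH sits from p$K_a$. The formula's
structure gives three free invariants that the tests exercise: the
shift vanishes at pH$_1 =$ pH$_0$, is antisymmetric in (pH$_0$,
pH$_1$), and is bounded by $|\delta_L - \delta_{HL}|$.

Peak clusters are found with a two-threshold run scan: contiguous runs
of points above a cluster threshold (a fraction of the global maximum)
form candidate clusters; local maxima above a higher main threshold
mark apexes; runs without an apex are dropped. Shift-limit pairs are
assigned to detected clusters in order along the ppm axis, and
clusters beyond the list stay in place — simple positional pairing,
chosen over cross-referencing detected peaks against external
multiplet databases, which fails whenever the database entry is
missing or disagrees with the measured spectrum.
Missing p$K_a$ values are imputed from a configurable normal fallback
(default mean 6.8, SD 1.5, clamped to [0, 14] — centred on the
physiological range where a shift matters most), and the same
mechanism can impute limit differences.

Shifts are quantized to whole grid points (round to nearest). At the
default grid of $2^{15}$ points over 10 ppm (~0.0003 ppm/point) the
quantization error is far below a linewidth, and in exchange the
relocation conserves the integral exactly and commutes exactly with
the 2D projections, which turns two approximate checks into exact
ones. On 2D grids, J-Res clusters move as whole F2 column blocks (F1,
i.e. the J structure, untouched); COSY clusters move their column and
row bands together, which preserves matrix symmetry. Cross peaks
therefore ride along with their diagonal blocks — differential
shifting of the two coupled protons is a known limitation. Colliding
relocations are an error by default; `collision = "sum"` superposes
them instead, which is physically sensible for genuinely overlapping
resonances. Within one simulated spectrum a single pH value, drawn per
replicate from the configured normal distribution, is shared by all
metabolites; each metabolite is shifted with its own p$K_a$ and limits
before the weighted sum.

## Blood: the protein background

Real blood spectra sit on a broad envelope of unresolved protein
(chiefly albumin) signal. The fixture background is a mixture of broad
Gaussians (SDs 0.2--0.5 ppm centred near 0.9, 1.3, 2.0, 3.0 and 7.3
ppm), normalized to a stated total area and added as
`protein_scale * background` after the metabolite sum. How large the
background should be relative to the metabolite signal is not a
published number, so the scale is an explicit user parameter; the toy
default (area 5000 at scale 1, against typical fixture mixtures
totalling on the order of $10^4$ area units) makes the baseline
clearly visible without drowning the metabolites. What the envelope
does not model is lipoprotein lineshape structure between 0 and 2 ppm
— typically the largest remaining gap between simulated and measured
blood spectra.

Additive white Gaussian noise, specified as a fraction of the maximum
clean intensity, is added last (the clean spectrum is retained in the
provenance); it is the simplest defensible noise model and every
spectrum records the level used.

## The synthetic fixture library

`make_toy_library()` generates fully synthetic pure-compound records:
1--3 multiplets per metabolite with Lorentzian lines (Pascal-ratio
amplitudes for s/d/t/q patterns), centers uniform on 0.8--9.0 ppm
avoiding the 4.5--5.0 ppm water window, J couplings of 4--12 Hz and
linewidths of 1.5--3 Hz at a default field of 600 MHz; separable
Lorentzian 2D peaks for J-Res and COSY; per-record "normal" statistics
(means 100--800 uM with 10--30% relative SD) plus a derived abnormal
condition. At least half the records carry a p$K_a$ and shift limits
so the pH path is always exercised. Everything is driven by one seeded
RNG stream, so a library is a pure function of its seed.

What the fixtures emulate is the *structure* of the problem — sparse
multiplets on a common grid, proton-area bookkeeping, pH-sensitive
clusters, a broad blood baseline. What they do not emulate is real
spectral crowding (a real urine spectrum has hundreds of overlapping
metabolites), strong-coupling rooftop distortions, quantum-mechanical
multiplet structure, or real lineshape imperfections. Tests passing on
fixtures therefore validate the simulation machinery, not the
chemical fidelity of any particular library; for realistic work the
same I/O layer loads an experimental pure-compound library from disk.

## Numerical and design choices

* **Grids.** ppm axes are uniform and stored descending (display
  convention). The default common grid is 9.995 to -0.005 ppm with
  $2^{15}$ points; the test-suite and the acceptance script run on
  1024--4096-point grids, which keeps runs in seconds while leaving
  every area-based contract intact (normalization pins integrals to
  proton counts regardless of sampling density). Fixture lines are
  rendered no narrower than one grid step for the same reason.
* **Resampling** is linear interpolation with zero fill outside the
  source range; it preserves non-negativity.
* **Seeds.** A master seed spawns named substreams (fixtures,
  concentrations, pH, noise, pKa imputation) by arithmetic derivation
  kept below $2^{31}$. Per-replicate noise gets its own substream, so
  toggling noise or shifting never perturbs the concentration draws,
  and a cohort is bit-reproducible from its master seed. The run
  driver writes a manifest that replays to identical checksums.
* **Degenerate inputs.** Zero spectra cannot be normalized (error);
  an all-zero spectrum yields an empty cluster set (not an error); a
  zero-SD concentration is the constant mean, with an error when the
  mean sits below the truncation bound; noise on an all-zero grid is a
  no-op.
* **Scale of the experiments.** The continuous-outcome check uses 10
  single-resonance metabolites with target correlations
  $\{0.9, 0.7, 0.5, 0.3, 0, -0.3, -0.5, -0.7, -0.9, 0\}$, error SD
  $\sqrt{1-a^2}$, 100 replicates per cohort and 50 seed repetitions in
  the test-suite (25 in the acceptance script); the discrete check
  uses a 2-fold change at 1000 replicates per group. These sizes give
  Monte-Carlo error comfortably below the stated tolerances
  ($\pm 0.05$ on recovered correlations, $\pm 5\%$ on the fold-change
  ratio).

## A worked cohort

```{r example, eval = FALSE}
library(mixnmr)

lib <- make_toy_library(5, seed = 42, biofluid = "blood",
                        axis = default_ppm_axis(4096))

stats <- lapply(lib$records, record_stats, condition = "normal",
                biofluid = "blood")
design <- discrete_design(
  n_per_group = c(normal = 50, `heart transplant` = 50),
  stats = list(normal = stats), reference = "normal",
  fold_change = list(`heart transplant` = list(met02 = 2.0)),
  seed = 7)

cohort <- simulate_cohort(lib, design,
                          mixture_spec(biofluid = "blood", mode = "1d",
                                       noise_sd = 0.005))
X <- cohort_matrix(cohort)          # 100 x 4096 labelled spectra
labels <- cohort$table$labels
```

Each row of `X` is one replicate spectrum; `cohort$table` holds the
concentrations that generated it — the supervised labels a downstream
learning task needs.

## Known limitations

Beyond those already noted (lipoprotein lineshapes, COSY cross-peak
shifting, copula clamping): concentrations are Gaussian-marginal only;
there is no longitudinal design; no FID-domain effects (apodization,
phasing, baseline roll) are modelled; and pure spectra are treated as
fixed templates — no intensity-dependent lineshape or ionic-strength
effects. The on-disk library format is plain TSV; vendor-format
readers are intentionally out of scope.
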