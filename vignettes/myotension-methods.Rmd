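---
title: "Models and methods: from myosin motor activity to tissue contraction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: from myosin motor activity to tissue contraction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myotension)
```

## Scope

Non-muscle myosin II drives apical constriction during epithelial folding,
and its motor output is controlled by phosphorylation of the regulatory
light chain (RLC). An allelic series of RLC point mutants — wild type
(phosphorylatable at both Threonine-20 and Serine-21), single-site mutants,
and glutamate phosphomimetics — spans a range of motor activities, which can
be measured in vitro (steady-state actin-activated ATPase, filament gliding)
and whose tissue-level consequences can be measured in vivo (laser-ablation
recoil, apical constriction rates, tissue folding kinetics).

`myotension` implements the three quantitative analyses that link these
scales, together with a seeded synthetic-data generator that emulates each
input class with known ground truth. Everything downstream of image
segmentation is covered; cell segmentation itself is not.

## Steady-state ATPase kinetics

The actin-activated hydrolysis rate is modeled as

$$ v([A]) = k_\mathrm{basal} + k_\mathrm{cat}\,\frac{[A]}{K_\mathrm{app} + [A]}, $$

fit by unweighted Levenberg–Marquardt least squares over all observations
(`fit_michaelis_menten()`). Initial guesses come from the data: the 0 µM
mean for $k_\mathrm{basal}$, the span of the concentration means for
$k_\mathrm{cat}$, and the concentration nearest half-maximal activation for
$K_\mathrm{app}$; all parameters are bounded below by zero. Replicates
enter as individual points rather than means, which weights concentrations
by their replication.

Weakly activated motors are nearly linear in actin over an assay that stops
at 100 µM; $k_\mathrm{cat}$ and $K_\mathrm{app}$ then trade off freely and
the fit is flagged `identifiable = FALSE` whenever the fitted
$K_\mathrm{app}$ exceeds the largest assayed concentration. For such
variants the meaningful statistic is the endpoint activity $k_{100}$ — the
mean raw rate at exactly 100 µM actin (`k100_summary()`), computed from
observations rather than from the fitted curve, so it stays valid when the
curve does not. Fold activation by phosphorylation and percent-of-reference
activity are ratios of these endpoint statistics. Both denominator
conventions (a variant's own unphosphorylated $k_{100}$, or the wild-type
one) are supported through explicit arguments; the package never guesses
which a summary used.

Gliding speeds in the in vitro motility assay (`track_speeds()`) are mean
step lengths per frame interval. Stage drift is removed by subtracting the
global mean step vector pooled over all tracks — with many tracks of random
heading, that mean is the drift. The estimator is slightly biased upward
for near-stationary filaments (step noise never cancels in a mean of
lengths), which is why drift-corrected stationary tracks read near, not
exactly, zero.

## Laser-ablation recoil

A line cut severs the actomyosin network; the flanking tissue recoils. The
displacement of the wound edge is extracted from a kymograph
(`extract_edges()`): each time row is binarized (Otsu by default, fixed
threshold optionally), runs of foreground or background shorter than
`min_object_px` (default 3) are flipped to suppress specks, and the
background run at the cut position gives the edge separation; displacement
is that distance divided by two. Rows with no detectable wound are recorded
as missing rather than zero — the first post-cut frame typically has a
wound narrower than one pixel, and zeros there would bias the fits.

Displacement is fit to a Kelvin–Voigt response
$$ x(t) = A\left(1 - e^{-t/\tau}\right), \qquad
   A = T/\zeta, \quad \tau = \eta/\zeta, $$
with $T$ the pre-cut tension, $\zeta$ the spring stiffness and $\eta$ the
dashpot viscosity. Only the ratios $A$ and $\tau$ are identifiable from
displacement, so the fit is parameterized in them and $T,\zeta,\eta$ are
never reported individually. The initial recoil velocity
$v_0 = A/\tau = T/\eta$ is the model derivative at $t = 0$ and serves as
the tension readout at constant viscosity; $\tau$ and the exponent
$\alpha$ of a separate power-law fit $x = \beta t^{\alpha}$ describe
viscoelasticity. The power-law fit excludes $t = 0$ (the model is singular
there) and is performed in linear space, consistent with least squares on
displacement. Fits with $R^2 \le 0.5$ (about the mean) are kept but flagged
unaccepted; the velocity accessors refuse unaccepted fits, and cohort
summaries count exclusions per genotype. Initial guesses: $A$ from the
maximum displacement, $\tau$ from the time to reach $(1 - e^{-1})A$,
$\alpha = 0.5$, $\beta$ from the final point.

## Constriction-rate analysis

Myosin accumulation rate varies widely between cells and correlates with
constriction, so comparing genotypes requires conditioning on matched
accumulation. The procedure:

1. **Myosin preprocessing** (`preprocess_myosin_stack()`): per pixel, only
   the two brightest z-values are considered and only those above
   $\mu_\mathrm{cyto} + 2.5\,\sigma_\mathrm{cyto}$ survive; the projection
   is their maximum (zero when none qualifies), then Gaussian-smoothed with
   $\sigma = 0.5$ px. Of the two readings of "projection of the two highest
   values", the max-of-qualifying one is implemented; a two-slice summed
   projection would differ only by a bounded factor of two and not change
   which pixels are retained.
2. **Trace smoothing and rates**: per-cell area and intensity series are
   smoothed with a Gaussian kernel ($\sigma = 2$ frames by default — the
   smoothing scale is a package choice, stated here and configurable, since
   only the fact of smoothing is prescribed) and differentiated by central
   differences, one-sided at the ends. Constriction rate is $-dA/dt$, so
   positive means constricting.
3. **Event detection** (`detect_accumulation_events()`): the mean and SD of
   the accumulation rate pooled over *all* control-genotype time points
   define the normalization; every (cell, time point) with rate in the
   closed window $[\mu + 1\sigma,\ \mu + 2\sigma]$ is an accumulation
   instance. Instances are per-time-point, not merged runs; boundary ties
   are included. On Gaussian rates the flagged fraction is
   $\Phi(2) - \Phi(1) \approx 0.136$, which the tests verify.
4. **Event-conditioned rates**: constriction rates are read off at the
   flagged instances and compared across genotypes with Mann–Whitney tests.
5. **Alignment and half-time**: embryos are aligned at constriction onset —
   the first time the smoothed mean-area derivative stays below
   $-1\ \mu m^2/\mathrm{min}$ for 3 consecutive frames (both artifact
   choices; the source procedure states only "when the tissue begins to
   constrict"). $A_0$ is the mean area 2 min before onset (clamped to the
   start of coverage) and the half-time is the linearly interpolated first
   crossing of $0.5\,A_0$, censored rather than failed when coverage ends
   first.

Gaussian kernel smoothing uses half-sample symmetric boundary reflection,
which preserves the series sum exactly for any symmetric kernel — so
smoothing never creates or destroys signal mass at trace edges, and rates
near boundaries stay unbiased for linear trends.

## The synthetic-data generator

The generator exists so that every stage is testable against known truth.

* **ATPase curves**: Michaelis–Menten values plus Gaussian noise
  (sd 0.02 s⁻¹, 4 replicates, 8 concentrations spanning 0–100 µM by
  default), truncated at zero.
* **Recoil traces**: the Kelvin–Voigt closed form on a regular grid plus
  truncated Gaussian noise; optionally rendered as a kymograph (bright
  tissue, dark wound of width twice the displacement, pixel noise) for
  round-trip testing of the edge extractor.
* **Embryos** (`gen_embryo()`): per cell, myosin intensity is a baseline
  (10 a.u.) plus Poisson-timed pulses (1.5 min⁻¹ per cell) shaped as linear
  ramps — 10 s rise at a slope drawn from N(1.0, 0.3²) a.u./s, 20 s linear
  decay. The coupling rule is the generative contract: instantaneous
  area-loss rate equals `motor_activity_factor × 0.2 µm²/a.u. × ` the
  positive part of the net accumulation rate, floored at 4 µm² from a
  40 µm² start, with pulses beginning after a 120 s quiescent delay.
  Gaussian noise (sd 0.5) is added to both channels. Pulse times,
  amplitudes and noise depend only on the dataset seed and cell index, so
  genotypes generated at the same seed have matched pulse statistics and
  the ratio of event-conditioned constriction rates recovers the factor
  ratio directly.
* **Motility tracks**: constant-speed random-heading walks plus a common
  linear drift plus positional noise.

Reproducibility is strict: one dataset seed, with per-unit substreams
derived as `(seed + 104729·index) mod (2³¹−1)`, so regenerating any one
cell or trace is stable and identical configurations are bit-identical.

Two movie lengths are used as study conditions. Rate comparisons use
600 s movies: long enough for hundreds of accumulation instances per
genotype at 5 s frames, short enough that no cell reaches the area floor,
which would clip event-conditioned rates asymmetrically across genotypes.
Half-time analyses use 1500 s movies. The length matters because pulses
overlap: a rise often coincides with another pulse's decay, cancelling part
of the net accumulation signal, so realized constriction is roughly 1.45×
slower than a no-overlap estimate would suggest, and the slowest genotype
(factor 0.47) needs about 20 min past onset to cross half its initial
area.

What the generator does *not* emulate: spatially correlated noise,
photobleaching, segmentation errors, cell–cell mechanical coupling, myosin
ratcheting (pulses decay fully), or any feedback from area onto myosin.
Passing tests therefore demonstrate that the analysis chain recovers known
generative truth under Gaussian noise — not that these phenomena would
leave real estimates unbiased.

## Statistics and the pipeline driver

Group comparisons use the two-sided Mann–Whitney U test: exact null
distribution when both groups have at most eight tie-free observations,
normal approximation with tie correction otherwise (`mann_whitney()`). No
multiple-testing correction is applied to the pairwise genotype
comparisons. Box summaries report median, quartiles and whiskers at the
most extreme points within 1.5 IQR.

`run_pipeline()` validates a configuration against its schema (unknown keys
are rejected before any computation), generates the configured allelic
series, runs the requested stages and writes tidy CSV/TSV tables, JSON fit
reports and a provenance record containing the seed and an MD5 hash of the
scientific configuration (the output directory is excluded from the hash,
so the same analysis at two locations is recognizably the same run).
Re-running a configuration reproduces every output byte for byte; for that
reason the provenance record carries no timestamp.

```{r example, eval = FALSE}
out <- run_pipeline(list(out_dir = tempfile("demo"), seed = 7))
read.delim(file.path(out$out_dir, "constriction_summary.tsv"))
```

## Numerical choices and degenerate inputs

* Nonlinear fits use Levenberg–Marquardt (`minpack.lm`) with non-negative
  parameter bounds; non-convergence is reported as a flagged failed fit,
  never an exception, so summary tables stay complete.
* A dataset with only one non-zero actin concentration cannot constrain
  $k_\mathrm{cat}$ and $K_\mathrm{app}$ jointly even with
  $k_\mathrm{basal}$ fixed; the singular fit is returned flagged as failed
  and non-identifiable.
* The half-area crossing is interpolated linearly between frames; exact
  touches count as crossings.
* Uncut kymographs yield an all-missing trace plus a warning; missing
  frames propagate as `NA` and fits use the remaining points.
* Displacement noise is truncated at zero to respect the trace invariant;
  at the study noise level (0.05 µm against a 2 µm amplitude) the induced
  bias on fitted parameters is far below the sampling spread.

## Known limitations

* The Kelvin–Voigt and power-law models share the $R^2 > 0.5$ rule with
  $R^2$ defined about the mean in both cases; alternative definitions
  (e.g. about zero for a through-origin model) would shift the acceptance
  boundary for marginal traces.
* Event detection treats consecutive flagged frames as independent
  instances; run-level bookkeeping is available but off by default, and
  the per-instance convention slightly favors genotypes with longer
  accumulation episodes in unbalanced designs.
* The drift-correction estimator assumes drift is common to all tracks and
  constant in time.
* Endpoint statistics at exactly 0 and 100 µM require those concentrations
  to be present verbatim in the dataset.
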