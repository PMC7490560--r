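---
title: "Models and methods behind affinet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind affinet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

affinet quantifies the binary interactome of a transcription-factor hub
(NRF2/NFE2L2) across four evidence layers — live-cell FCCS, DULIP co-IP,
ARE-luciferase reporter screens and Y2H matrix screens — and assembles the
layers into an affinity-weighted interaction network. This vignette is the
package's own account of the models, the defaults and the numerical
choices, including the places where the design was genuinely open and a
choice had to be made.

## 1. Binding equilibrium

Every simulator and the isotherm fitter rest on the 1:1 mass-action
equilibrium. For totals $c_G$, $c_R$ and dissociation constant $K_d$, the
complex concentration is the smaller root of
$c^2 - (c_G + c_R + K_d)c + c_G c_R = 0$. `solve_equilibrium()` evaluates
it in the numerically stable form $2q/(b + \sqrt{b^2-4q})$, which avoids
catastrophic cancellation when $K_d$ dwarfs the totals; mass balance holds
to $10^{-9}$ relative and the $K_d$ relation to $10^{-6}$ relative across
twelve orders of magnitude of inputs (checked on $10^4$ random triples in
the test suite).

## 2. Correlation models and the correlator

Autocorrelations use the two-component 3D-diffusion model with a triplet
(dark-state) factor; cross-correlations use the same diffusion kernel with
the triplet forced to zero, because dark-state blinking is uncorrelated
between spectrally distinct fluorophores. The structure parameter $s$
(axial/lateral ratio of the detection volume, default 5) is supplied by the
calibrated `confocal_volume` and held fixed during fitting — with a single
detection-volume calibration there is no information in one curve to float
it, and floating $s$ trades off almost perfectly against the diffusion
times.

`multitau_correlate()` evaluates
$G(\tau) = \langle\delta a(t)\,\delta b(t+\tau)\rangle / (\langle a\rangle
\langle b\rangle)$ on the standard multi-tau lag ladder (16 lags at base
resolution, then 8 per level with the spacing doubling). One deliberate
deviation from running-average correlator hardware: the estimator at every
ladder lag is computed exactly on the raw trace rather than on
progressively rebinned copies. Progressive rebinning triangularly smooths
the estimate at deep levels; the exact evaluation is unbiased, agrees with
a direct $O(N^2)$ correlator to $10^{-12}$ at every ladder lag, and costs
only $O(N \times n_{\text{lags}})$. Per-lag uncertainties come from
splitting the trace into 5 contiguous segments (mirroring the five
2-second repeat acquisitions of a typical live-cell measurement) and
taking the standard error over segments.

## 3. Curve fitting

`fit_correlation_curve()` minimises weighted squared residuals (weights
$1/\mathrm{sem}^2$ when per-lag uncertainties exist, otherwise unweighted)
with Levenberg–Marquardt (`minpack.lm::nls.lm`) on a transformed parameter
scale: log for positive quantities ($N$, diffusion times, triplet time),
logit for fractions. Initial values are data-driven — amplitude from the
three smallest lags, baseline from the three largest, diffusion time from
the half-amplitude lag — plus a small set of dispersed restarts (component
ratios 0.2/0.5/0.8, diffusion times spread $\times 4$ each way, a
low-triplet variant); the restart with the lowest weighted SSR wins.

Two numerical guards matter in practice:

* the triplet relaxation time is box-constrained to $[0.1, 100]\ \mu s$.
  Unconstrained, noisy fits occasionally drive $\tau_T \to \infty$, which
  turns the triplet factor into a constant $1/(1-T)$ that the amplitude
  absorbs — a local optimum that biases $N$ by up to 20%;
* fitted components are re-ordered so $\tau_{fast} \le \tau_{slow}$
  (swapping $f \leftrightarrow 1-f$), making the labelling canonical.

Non-convergence and singular covariance are *flags* on the returned object,
never exceptions, so population pipelines can QC them out. On noise-free
curves the fitter recovers generating parameters to better than $10^{-4}$
relative (machine precision in practice) for identifiable parameter sets —
component diffusion times at least $\sim 8\times$ apart, fractions away
from 0/1, which is what the property-based tests sample.

## 4. Amplitudes, concentrations, QC, isotherm

Zero-lag *diffusion* amplitudes ($1/N$, excluding triplet and offset)
convert to concentrations via $c = 1/(V_{\mathrm{eff}} N_A G_0)$ and
$c_x = G_{0,\times}/(V_{\mathrm{eff}} N_A G_{0,g} G_{0,r})$; bound
fractions are $G_{0,\times}/G_{0,r}$ (green) and $G_{0,\times}/G_{0,g}$
(red). Noisy fractions outside $[0,1]$ are clipped with a flag rather than
excluded — exclusion would censor the low-binding tail and bias $K_d$
upward. Cells fail QC when counts-per-molecule fall below 0.5 kHz
(instrument practice aims at $\sim$1 kHz), when amplitudes are
non-positive, or when any curve fit did not converge.

The isotherm $f_{bound} = c_{free}/(c_{free} + K_d)$ is fitted separately
in both orientations (bound green vs free red, and vice versa), each cell
contributing its own free-partner coordinate (no pooling or binning — the
per-cell pairing is what makes single-cell FCCS an isotherm at all), and
the reported $K_d$ is the unweighted mean of the two orientation fits.
The one-dimensional least-squares problem is solved by golden-section
search on $\log_{10} K_d \in [-3, 9]$, which is immune to the scaling
pathologies of derivative-based steps across nine decades.

The 95% CI is a nonparametric bootstrap over cells (default 1000
resamples): estimate $\pm 1.96\times$ the bootstrap standard error. The
symmetric SE interval was chosen over the raw percentile interval as the
natural reading of a "CI of the mean" and because it is better calibrated
for this mildly nonlinear estimator at realistic cell counts. Populations
with no detectable bound fraction return a sentinel ($K_d = \infty$,
non-binder) rather than an arbitrary large number. Partners are flagged as
positive binders below 10,000 nM — beyond that the assay's own weak-binder
regime begins and reported constants are no better than bounds.

## 5. What the synthetic data emulate — and what they do not

`simulate_cell_population()` draws per-cell totals log-normally
(default $10^{3\pm0.5}$ nM per channel). The study the package models
transfects tens of nanograms of plasmid per compartment and reports only
that expression varies broadly across cells; the log-normal family and the
defaults are the package's own choice of a realistic transient-transfection
spread, not values taken from any measurement. Curve noise is per-lag
Gaussian with
$\sigma(\tau) = \text{scale} \cdot (G(0)/\sqrt{n_{seg}}) \cdot
(1+\tau/\bar\tau_D)^{-1/2}$ — amplitude-proportional, shrinking with the
number of repeat segments and with lag, which is the standard first-order
FCS noise approximation and keeps fit weights well defined. The same
$\sigma$ fills the `sem` column, so simulated curves are self-describing.

The Brownian-dynamics oracle places free green, free red and
double-labelled complex particles in a periodic box around a 3D-Gaussian
detection profile, with Poisson photon emission per time bin. The box is
deliberately anisotropic — $12 w_0$ laterally and $12 s w_0$ axially —
because a cubic box of $12 w_0$ is only $2.4$ *axial* waists long; the
wrap-around then truncates the axial profile and shortens apparent
diffusion times by $\sim$15%. It is a desk-scale validation tool (at most
200 particles, $2^{20}$ steps), not an instrument model.

Not emulated anywhere: spectral cross-talk, background, photobleaching,
detector afterpulsing, vendor raw formats, anomalous diffusion. Passing
recovery tests therefore demonstrates the correctness of the estimators
under the stated noise model, not robustness to every artefact of real
microscopes.

## 6. DULIP

$\mathrm{NIR} = (FL_{bound}/RL_{bound})/(FL_{input}/RL_{input})$ and
$\mathrm{cNIR} = \mathrm{NIR}/\mathrm{NIR}_{control}$. The underlying
protocol literature defines the ratio only up to such normalisation
conventions, so both formulas are single functions that alternatives can
replace. DULIP $K_d$ estimation is a declared reconstruction (no published
procedure exists): the capture-normalised bound signal
$b = FL_{bound}/(\alpha RL_{bound})$ is fitted as
$b = b_{max} S/(S+K)$ against the free-prey signal
$S = FL_{input} - \beta FL_{bound}$. Because $b_{max}$ is fitted jointly,
$K$ is invariant to the Renilla/capture gain $\alpha$; $\beta$ (default 1)
converts bound firefly signal to the input scale for the depletion
correction. $K$ carries assay units until scaled.

Mutant effects are tested by a two-sided one-sample t-test of log2 cNIR
ratios against zero, after averaging technical triplicates within each
independent experiment — the experiment, not the well, is the independent
unit. A zero-variance sample short-circuits to the degenerate answer
(p = 1 at mean 0, else p = 0 with a flag) instead of dividing by zero.

Cross-platform scaling regresses $\log_{10} K_d^{FCCS}$ (Y) on
$\log_{10} K_d^{DULIP}$ (X) by OLS and reports Pearson's r. The log10
scale and the X/Y orientation are a design decision: a slope/intercept
pair like 0.213/2.110 is physically plausible on log10 (intercept
$\approx$ 129 nM at X = 0) and absurd on raw nM scales. Note the
consequence, visible in `scripts/acceptance.R`: the calibration compresses
fold changes (a raw $r$-fold difference becomes $r^{slope}$-fold after
scaling), so synthetic assays must generate their raw readouts through the
*inverse* calibration if molar fold changes are to survive scaling — just
as the real assay's luminescence units do.

## 7. Reporter screens and the mixed model

Each well's firefly/Renilla ratio is normalised to the geometric mean of
the same-plate, same-cell-line empty-vector wells (geometric, because the
analysis lives on log2 scale) and log2-transformed; plates without a
baseline are excluded with a warning.

`fit_reporter_lmm()` fits $y = X\beta + Zu + e$ with a single random
intercept per plate by REML, maximising the one-dimensional profiled
criterion in $\lambda = \sigma^2_{plate}/\sigma^2_{resid}$ (golden-section
on $\log\lambda \in [-15, 15]$, with the $\lambda = 0$ boundary always
evaluated and winning ties — variances are therefore non-negative by
construction). For fixed $\lambda$ the GLS fixed effects and the residual
variance are closed-form, so each evaluation is one Cholesky solve. The
returned restricted log-likelihood uses the standard
$\beta$-integrated form and matches `lme4::lmer(REML = TRUE)` to machine
precision; the test suite asserts agreement of fixed effects and REML
log-likelihood to $10^{-4}$ on 20 random designs.

The default fixed-effects formula includes the condition $\times$
cell-line interaction. The source analyses list only main effects, but the
questions the classifier asks — is a partner's effect *dampened* in
NRF2-null lines, *enhanced* in derepressed lines? — are interaction
contrasts; without the interaction they are inexpressible. This is
documented as an assumption, not a reproduction.

Satterthwaite degrees of freedom follow
$\mathrm{df} = 2 f(\hat\theta)^2 / (g^\top A g)$ with
$f(\theta) = c^\top (X^\top V^{-1}X)^{-1} c$, $g$ its gradient in
$\theta = (\sigma^2_{plate}, \sigma^2_{resid})$ by central differences
(relative step $10^{-6}$), and $A$ the inverse observed REML information
(Hessian by central differences, relative step $10^{-4}$ — tighter steps
amplify round-off in second differences). At the $\sigma^2_{plate} = 0$
boundary the df collapse analytically to the classical residual $n - p$,
which the implementation returns directly instead of differencing across a
constraint boundary. Under the global null the full contrast pipeline
rejects at 5.5% for a nominal 5% over 2000 simulated screens (6 plates
$\times$ 3 replicates; test suite).

Bonferroni adjustment is the exact clamp $\min(1, m p)$. Partner
classification is a pure function of the adjusted contrast table:
significant WT effect $\Rightarrow$ activator/inhibitor by sign;
significant opposite-sign interaction in *both* NRF2-null lines
$\Rightarrow$ NRF2-dependent; no WT effect but a significant effect in at
least one derepressed line (KEAP1-null or KEAP1-binding-impaired NRF2)
$\Rightarrow$ derepression-dependent; otherwise no-effect. Labels other
than no-effect may coexist.

## 8. Y2H scoring and network assembly

A pair is positive only if growth is seen in at least two independent
assay replicates and neither clone auto-activates; growth on *either*
reporter (ADE2 or HIS3) counts for a replicate. The OR rule is a choice —
the screening protocol names both reporters without an AND/OR rule — made
because requiring both reporters would conflate reporter-specific dropout
with irreproducibility. Pairs assayed once are reported as
`untested_incomplete`, never positive; the rule is monotone (extra growth
can only help).

Conditional affinity between WT and KEAP1-null cells uses the strict rule
on $r = K_d^{KO}/K_d^{WT}$: loss if $r > 1.25$, gain if $r < 1/1.25$, else
unchanged — a ratio of exactly 1.25 is unchanged. Edge weights
operationalise "average normalised binding affinity" as the min–max
normalisation of $\log_{10} K_d$ within each platform, averaged over the
platforms that measured the partner; 0 is the strongest binder, 1 the
weakest, and an all-equal (or single-partner) platform yields the flagged
convention weight 0.5. Gene symbols are upper-cased for matching;
conflicting duplicate records are a hard error naming the offenders, not a
silent overwrite. GraphML export (via igraph) round-trips all node and
edge attributes; absent categorical attributes export as the literal
string `"absent"` so that re-imports are type-stable.

## 9. Validation scale

The test suite validates at sizes chosen to finish in minutes on one CPU
while keeping Monte-Carlo error well inside the asserted margins: $10^4$
equilibria; 50 parameter sets for the zero-noise round trip; 200
simulated 40-cell studies (noise scale 0.02, expression spread 0.5 log10)
for $K_d$ recovery and CI calibration; 2000 null screens plus 200 effect
screens for the mixed model; 20 random designs against the lme4 oracle;
$8 \times 2^{17}$-step Brownian traces for the physics oracle; 1000 pairs
for the Y2H reproducibility rate. `scripts/acceptance.R` re-runs the same
computations at moderately reduced repetition counts and writes the
resulting numbers as JSON.

## 10. Known limitations

* FCCS concentrations assume an ideal 3D-Gaussian detection volume and
  perfect spectral separation; cross-talk and background corrections are
  out of scope and real amplitudes violate them to some degree.
* The DULIP $K_d$ procedure is a reconstruction; its assay units are
  meaningful only after cross-platform scaling, and the scaling itself is
  as good as the partner panel measured on both platforms.
* The mixed model supports a single random intercept (plate). Nested or
  crossed random effects (e.g. experiment/plate) would need the general
  machinery of lme4 and are deliberately not reimplemented.
* The classifier's dampening/enhancement logic inherits the $\alpha = 0.05$
  Bonferroni convention; with few replicates it is conservative, and
  "no_effect" should be read as "not detected", not "absent".
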