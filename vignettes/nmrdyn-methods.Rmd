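---
title: "Models and numerical methods in nmrdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerical methods in nmrdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nmrdyn)
```

nmrdyn implements the quantitative layer of a solution-NMR dynamics and
enzymology study of a small protein domain: per-probe relaxation fitting,
Lipari-Szabo model-free analysis, two-site Bloch-McConnell exchange (CPMG
dispersion and binding lineshapes), methyl cross-correlated relaxation,
chemical-shift analytics, paramagnetic attenuation profiling, monomer-dimer
light-scattering fits, and protease activation kinetics. This vignette
documents the models, the numerical choices, and what the package's
synthetic-data tests do and do not demonstrate.

## Relaxation-rate fitting

Intensity decays are fit to $I(t) = I_0 e^{-Rt}$ by Levenberg-Marquardt
with a log-linear initial guess. When per-point noise estimates are given
the fit minimises $\chi^2$; otherwise unweighted SSE. Uncertainties come
from seeded Monte-Carlo resampling: the model curve at the best fit is
perturbed with Gaussian noise of the stated SD and refit; the SD of the
refit parameters is the quoted error. The default draw count is 200, a
compromise at which the SD estimate itself is stable to a few percent.
Negative fitted rates are flagged, never silently clipped, because a
negative apparent rate usually indicates a mis-referenced intensity rather
than physics.

$R_2$ is derived from the rotating-frame rate via the tilted-frame relation
$R_2 = R_{1\rho}/\sin^2\theta - R_1/\tan^2\theta$ with
$\theta = \arctan(\omega/\Omega)$ at a 2 kHz spin-lock; on resonance the
implementation evaluates $\cos\theta$ exactly as zero so that
$R_2 = R_{1\rho}$ holds to machine precision.

TRACT analysis converts the TROSY/anti-TROSY rate difference into the
DD/CSA cross-correlation rate $\eta_{xy} = (R_{2\beta} - R_{2\alpha})/2$
and solves for $\tau_c$ on the rigid-rotor spectral density. The physical
constants ($r_{NH}$ = 1.02 Å, 15N CSA = -172 ppm, 17° CSA/bond angle) are
standard literature values; they are package defaults, exposed as
arguments, because the analysis is insensitive to them at the level of the
comparisons made here.

## Model-free analysis

Rates are predicted from the standard dipolar + CSA expressions on the
model-free spectral density
$$J(\omega) = \tfrac{2}{5}\Big[\frac{S^2\tau_c}{1+(\omega\tau_c)^2}
 + \frac{(1-S^2)\tau'}{1+(\omega\tau')^2}\Big],\qquad
 \tau'^{-1} = \tau_c^{-1} + \tau_e^{-1},$$
with an axially symmetric variant summing three Lorentzian branches whose
weights depend on the bond-vector angle to the unique axis. A degenerate
axial tensor reproduces the isotropic rates to 1e-10, which the tests
assert.

The fitting pipeline mirrors common practice: probes with $R_2/R_1 > 30$
are removed first (strict inequality; a probe exactly at 30 is retained),
a global $\tau_c$ is seeded from the trimmed-mean $R_2/R_1$ ratio, and each
probe is then assigned one of four models — M1 $\{S^2\}$, M2
$\{S^2, \tau_e\}$, M3 $\{S^2, R_{ex}\}$, M4 $\{S^2, \tau_e, R_{ex}\}$ —
with $R_{ex}$ scaled by $(B_0/B_{0,ref})^2$ at a 16.4 T reference. Model
selection uses AICc where the per-probe observable count supports the
small-sample correction for *every* candidate model, and plain AIC
($\chi^2 + 2k$) for the whole candidate set otherwise — the criterion must
be comparable across models, and mixing corrected with uncorrected
penalties within one probe would systematically favour the richer models.
With a single field a probe contributes only three observables, so the
AICc denominator $n-k-1$ vanishes for two-parameter models and the AIC
path is taken; models with at least as many parameters as observables are
never considered. The global
$\tau_c$ is then re-optimised over probes whose selected model carries no
$R_{ex}$ (exchange-free probes are the ones that constrain tumbling) and
the per-probe stage repeated until $\tau_c$ moves by less than 0.1%.
Extended model-free with two internal timescales is deliberately out of
scope — nothing in the target data class requires it.

## Two-site exchange: CPMG dispersion

The core engine is a numerical two-state Bloch-McConnell propagator.
In-phase SQ magnetisation evolves under the complex 2x2 generator
combining exchange ($k_{AB} = p_B k_{ex}$, $k_{BA} = p_A k_{ex}$) and the
minor-state offset $\Delta\omega$; 180° pulses are ideal and instantaneous
(pulse widths are not modelled). Two echoes compose into the linear cycle
map $U\bar U\bar U U$, and the whole constant-time block is a matrix power
of that cycle, evaluated in closed form (2x2 matrix exponentials via the
Higham formula; bitwise repeated squaring vectorised across the frequency
grid). Both exchange states share one baseline $R_{2,0}$ per probe per
field, which then factorises exactly out of the propagator — the fitters
exploit this by solving for $R_{2,0}$ analytically.

MQ methyl dispersion propagates the (DQ, ZQ) register pair: DQ precesses at
$\Delta\omega_H + \Delta\omega_C$, ZQ at $\Delta\omega_H - \Delta\omega_C$,
and each 13C refocusing pulse swaps the registers. The two-echo cycle is
block diagonal, so the MQ case also reduces to 2x2 algebra. The reported MQ
$R_{2,eff}$ is the mean of the DQ- and ZQ-started decays. With
$\Delta\omega_H = 0$ the MQ propagation is algebraically identical to SQ
carbon dispersion, which the tests assert to machine precision.

Two conventions for $R_{2,eff}$ are exposed. The default, `"intensity"`,
applies the constant-time definition $-\ln(I/I_0)/T$ to the surviving
major-state magnetisation — exactly what the experiment measures. The
alternative, `"cycle"`, returns the asymptotic decay rate of the echo
cycle, which is the quantity closed-form expressions describe: the
package's propagator agrees with Carver-Richards to better than 1e-6 in
this convention across slow, intermediate and fast exchange. The two
conventions differ by a finite-$T$ amplitude term (the projection of the
equilibrium start vector onto the exchange eigenmodes) that is negligible
in fast/intermediate exchange but reaches several percent of $R_{2,eff}$
deep in slow exchange; this is a physical property of constant-time
experiments, not a numerical artefact, and simulation and fitting both use
the intensity convention consistently.

Global dispersion fits share ($p_B$, $k_{ex}$) across probes and fields.
Per-probe shift differences are profiled out by 1-D (SQ) or multi-start
2-D (MQ) inner optimisation with warm starts between outer iterations, and
the outer surface is explored on a 7x4 log-spaced ($k_{ex}$, $p_B$) grid
followed by Nelder-Mead refinement in (logit $p_B$, log $k_{ex}$). The
reported timescale is $\tau_{ex} = 1/k_{ex}$ with
$k_{ex} = k_{AB} + k_{BA}$, the usual convention. Flat datasets (all
dispersion amplitudes below three times the median noise) abort with a
degeneracy error instead of returning uninterpretable parameters.

## Two-site exchange: binding lineshapes

Titration lineshapes are steady-state solutions of the two-site McConnell
equations: at each titration point the free-ligand concentration follows
the exact 1:1 quadratic, populations follow the bound fraction, and
exchange rates are $k_{off}$ and $k_{on} L_{free}$ with
$k_{on} = k_{off}/K_D$. The absorption spectrum is the real part of
$\mathbf{1}^T A^{-1} p$ with the 2x2 complex matrix inverted in closed
form; the integrated intensity is conserved across the titration, which
the tests check to 0.1%. Fitting operates on 1D traces — a deliberate
approximation relative to full 2D lineshape fitting, recorded in the fit
object's metadata — and estimates ($K_D$, $k_{off}$) jointly across all
points with an analytically profiled amplitude scale, multi-start over log
grids and Nelder-Mead refinement in log space. Line positions and widths
of the pure states are taken as known (from the titration endpoints), which
is what keeps the 1D approximation well-posed. Saturated titrations (all
points above 95% bound) raise an identifiability warning.

## Methyl cross-correlated relaxation

SQ/TQ intensity-ratio curves follow
$$\Big|\frac{I_a}{I_b}\Big| = \frac{3}{4}\,
 \frac{\eta\tanh(\sqrt{\eta^2+\delta^2}\,T)}
      {\sqrt{\eta^2+\delta^2} - \delta\tanh(\sqrt{\eta^2+\delta^2}\,T)},$$
fit for ($\eta$, $\delta \ge 0$). The conversion to the
order-parameter/tumbling product uses
$$\eta = \tfrac{9}{10}\Big(\frac{\mu_0}{4\pi}\Big)^{2}
 [P_2(\cos 90^\circ)]^2\,
 \frac{S^2_{axis}\gamma_H^4\hbar^2\tau_c}{r_{HH}^6},\quad
 r_{HH} = 1.813\,\text{Å}.$$
The prefactor carries $(\mu_0/4\pi)$ squared: the first-power form that
sometimes appears in print is dimensionally inconsistent with $\eta$ in
s$^{-1}$, and the squared form reproduces the expected magnitudes
($\eta \approx 15.5$ s$^{-1}$ maps to $S^2_{axis}\tau_c \approx 4.3$ ns).
This choice is recorded here and in the conversion's documentation. Only
the product $S^2_{axis}\tau_c$ is reported; separating it requires an
independent tumbling time, for which a multiplicative D2O-viscosity
correction (default ratio 1.23 at 298 K) is provided.

## Chemical-shift analytics

CSPs are weighted Euclidean distances with the conventional heteronucleus
scalings (15N/5, 13C/4). Significance uses mean + k·SD of the CSP
distribution with k = 1 or 2; the `corrected_to_zero` mode recomputes the
statistic iteratively over not-yet-flagged records until stable, so large
perturbations do not inflate their own threshold. Both single-pass and
iterative modes exist because the trimming procedure is a convention, not
a derivation; likewise the choice of whether broadened residues enter the
SD is left to the caller by simply excluding them from the input.

Combined secondary shifts are
$(\delta_{C\alpha}-\delta_{C\alpha,rc}) - (\delta_{C\beta}-\delta_{C\beta,rc})$
smoothed with 1-2-1 weights over (i-1, i, i+1); missing neighbours drop out
and the weights renormalise, so terminal residues are smoothed over the
available window rather than padded. Random-coil references are an input
table — the package does not predict them.

Methyl rotamer populations invert the linear 13C calibrations
(Met-ε: $\delta = 15.9 + 3.6\,p_{trans}$; Ile-δ1:
$\delta = 9.3 + 5.5\,p_{trans}$) with classes *trans* for
$p_{trans} \in [0.75, 1]$, *gauche(-)* for $[0, 0.25]$, *mixed* otherwise.
Shifts outside the calibration range clamp to [0, 1] with a warning
because real shifts do exceed the calibration endpoints and an error would
discard usable probes.

## Equilibria and kinetics

The SEC-MALS monomer-dimer model
$M_W = 2M - M\frac{-K_D + \sqrt{K_D^2 + 8[M]K_D}}{4[M]}$ is fit on
$\log K_D$ with the endpoint masses constrained (monomer from sequence,
dimer exactly twice). The 95% CI comes from the fit covariance; when its
upper bound exceeds ten times the highest measured concentration the
estimate is flagged as a lower limit — the criterion is a package
convention chosen so that solubility-limited series (data reaching only a
few percent dimer) are flagged and well-spanned series are not.

Fluorescence progress curves are calibrated linearly between the
uncleaved-substrate control and the complete-cleavage plateau; initial
rates are linear fits over the window below 10% conversion (configurable),
widened with a warning when too few points qualify. Michaelis-Menten and
one-site activation fits ($k = k_{max}[A]/(K_{D,app}+[A]) + k_0$,
approximating free activator by total) use Levenberg-Marquardt;
$k_{cat} = v_{max}/[E]_{trimer}$ with the trimer at one third of the
monomeric enzyme concentration, because the trimer is the kinetically
competent unit.

## Paramagnetic attenuation

Corrected ratios multiply $I_{para}/I_{dia}$ by pulse-length, scan-count
and dilution ratios that bring the paramagnetic acquisition onto the
diamagnetic scale; the corrections commute, and ratios above 1 are
reported as negative attenuation rather than clipped. Classes default to
strong < 0.3 ≤ moderate ≤ 0.7 < none — the source data for this analysis
style are colour gradients without numeric cutoffs, so the boundaries are
package defaults, as is the minimum run of three consecutive strongly
attenuated residues for segment reporting. No PRE-to-distance conversion
is attempted.

## The synthetic-data generator

Every generator forward-simulates the corresponding model and adds seeded
Gaussian noise (fractional by default, 2% of signal unless stated), and
attaches its generating parameters as a manifest so recovery tests compare
against recorded truth. Defaults are the study conditions: tumbling 8.2 ns
with order parameters 0.9 ± 0.1 for an ~12 kDa domain at 16.4 T; backbone
exchange at $\tau_{ex}$ = 0.42 ms with a 15.2% minor state at 16.4/21.1 T
(T = 40 ms, 25–1500 Hz); methyl MQ exchange at 1.19 ms / 16.6% at
16.4/18.8 T (25–750 Hz); $S^2_{axis}\tau_c$ = 4.3 ns over thirteen delays
from 2–45 ms; monomer-dimer $K_D$ = 13 mM for a 12.1 kDa monomer over
50–600 µM; activator binding at $K_D$ = 3.18 µM, $k_{off}$ = 48.5 s$^{-1}$
with 250 µM protein over 0–2 equivalents; catalytic efficiency
85 M$^{-1}$s$^{-1}$ at 510 nM monomeric enzyme over the 0.5–30 µM substrate
grid and the 5–300 µM activator grid. Gaussian noise is the only noise
model — spectral noise is approximately Gaussian and nothing in the
analyses is sensitive to heavier tails at these levels.

What passing recovery tests show: that each fitter inverts its forward
model at realistic noise, that the global exchange fits are identifiable
at the study's parameter regimes, and that the analysis chain is free of
unit and convention errors. What they do not show: robustness to peak
overlap, baseline distortions, correlated noise, pulse imperfections, or
assignment errors — none of which the generators emulate. Conclusions
about real spectra still require the usual experimental controls.

## Problem sizes and determinism

The shipped tests and the acceptance script use cohorts of 80 backbone
probes (model-free), 10 SQ and 8 MQ dispersion probes at two fields, 20
CCR methyls, 12 MALS concentrations, and 8 titration points — sizes chosen
to match the study conditions while keeping a full run in minutes on one
core. All stochastic steps (noise injection, Monte-Carlo errors) are
seed-parameterised; reruns with the same seed are bitwise identical.

## Known limitations

Three-state exchange, off-resonance R1rho dispersion, CEST, TROSY/
anti-TROSY differential exchange and full 2D lineshape fitting are out of
scope. The model-free module fits isotropic and axially symmetric tensors
only (no rhombic), and does not implement extended model-free. The MALS
module handles monomer-dimer only, not three-species models. Gel
densitometry and raw spectral processing happen upstream; the package
starts from tables.
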