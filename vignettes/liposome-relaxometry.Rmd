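---
title: "Relaxometry and QC of liposomal co-formulations: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Relaxometry and QC of liposomal co-formulations: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(liporelax)
```

This vignette is the package's account of the science it implements: the
models, their assumptions, the tunable parameters, and the choices made
where the design was genuinely open. The running system is a set of
cationic DOTAP:POPC (2:8) liposomes carrying acteoside (ACT) alone or
co-loaded with cannabidiol (CBD) or naringenin (NG), characterized on a
30.2 MHz proton pulse spectrometer, by dynamic light scattering, and in
MTT viability assays.

## Laboratory-frame relaxometry

Saturation recovery measures the spin-lattice time $T_1$ through
$M(t) = M_0\,(1 - e^{-t/T_1})$. `fit_t1()` estimates $(M_0, T_1)$ by
bounded Levenberg–Marquardt (`minpack.lm::nlsLM`), starting $M_0$ at the
observed plateau and $T_1$ at the time the curve first reaches
$1 - e^{-1} \approx 63\%$ of it; if that fails, $T_1$ is restarted on a
log-spaced grid from the smallest positive sample time to ten times the
last one. A constant curve is a hard error — there is nothing to fit —
and the error names the curve label so batch runs are debuggable.

The transverse decay of these heterogeneous bilayer systems is not a
single exponential: a rigid, ordered population dephases with a Gaussian
kernel $\exp[-(t/T_{2G})^2]$ while a mobile population decays as a simple
exponential $\exp(-t/T_{2L})$ (a Lorentzian line in the spectral domain).
`fit_t2_mixture()` fits

$$M(t) = M_{0G}\,e^{-(t/T_{2G})^2} + M_{0L}\,e^{-t/T_{2L}}$$

with non-negative amplitudes, reported as percentages of
$M_{0G} + M_{0L}$, which therefore sum to exactly 100 by construction.
Percentages make the result invariant to instrument gain: rescaling the
magnetization rescales `m0_total` and nothing else.

Two numerical points matter here:

* **Multi-start.** The objective is multi-modal — the classic failure is
  the Gaussian and Lorentzian components swapping roles. Since the model
  is linear in the amplitudes, we scan the two time constants over a
  log-spaced grid from the smallest sampling interval to ten times the
  sampled span, solve the amplitudes in closed form at each node, and
  refine the best node with all four parameters free. The component
  fitted by the Gaussian kernel is always reported as G, whichever time
  constant is larger.
* **Identifiability tie-break.** If the refined time constants agree
  within 10%, or one amplitude collapses to zero (making its time
  constant undefined), the two-component description is not supported by
  the data; the better single-kernel fit is reported with
  `degenerate = TRUE` rather than pretending four parameters were
  resolved.

Standard errors come from the Jacobian-based covariance at the optimum —
adequate for the smooth, well-conditioned fits here, and consistent with
how nonlinear fit software reports uncertainty. Times are seconds
internally; `relaxation_report()` converts to the conventional reporting
units ($T_1$ in s, $T_2$ in ms).

## Off-resonance rotating-frame analysis

Applying the RF field $B_1$ at an offset $\Delta f$ from resonance creates
an effective field tilted by $\theta = \arctan(B_1/\Delta B)$ with
$\Delta B = 2\pi\Delta f/\gamma$. The equilibrium magnetization locked
along that field satisfies

$$\frac{M_\rho}{M_0} =
  \frac{\Delta f^2}{\Delta f^2 + K\,[(\gamma/2\pi)B_1]^2},$$

a one-parameter saturation curve whose knee sits at
$(\gamma/2\pi)B_1\sqrt{K}$ — about $21.3\sqrt K$ kHz for a 5 G proton
$B_1$. The relaxation enhancement factor

$$K = \frac{10 + 37\,\omega^2\tau_c^2 + 12\,\omega^4\tau_c^4}
           {10 + 16\,\omega^2\tau_c^2}$$

is 1 for fast isotropic motion and strictly increasing in the rotational
correlation time $\tau_c$, so the map is invertible.

Design choices:

* **Which $\omega$.** $\omega$ is taken as the angular Larmor frequency
  $2\pi \times 30.2\,\mathrm{MHz}$. For liposomal lipids
  ($\tau_c$ of a few ns) this puts $\omega\tau_c$ in the 0.3–0.7 range,
  exactly where $K$ is informative (1.2–1.7); any frequency on the scale
  of the effective field ($\gamma B_\mathrm{ef} \sim 10^5$ rad/s) would
  pin $K$ indistinguishably close to 1 for every sample and make the
  measurement meaningless.
* **Inversion.** `invert_k_for_tau()` brackets the root on
  $[0, 1\,\mu s]$ — physical lipid correlation times are far below the
  upper end — and solves with `stats::uniroot` to $10^{-12}$ relative
  tolerance. $K < 1$ is a domain error (only noise can produce it;
  `fit_k()` flags such fits), and $K$ beyond $K(1\,\mu s)$ asks the
  caller to enlarge the bracket rather than silently extrapolating.
* **Regime diagnostic.** The equilibrium-ratio model is stated for the
  fast-motion regime $\omega_e\tau_c \ll 1$. The inversion reports
  $\omega_e\tau_c = \gamma B_1 \tau_c$ and warns above 0.1 instead of
  erroring: the bound describes the experiment, not the algebra.
* **Units.** $B_1$ is accepted in gauss at the interface (the instrument
  convention) and stored in tesla; offsets are Hz; all angular
  frequencies rad/s. $\Delta f$ enters the ratio squared, so only
  $|\Delta f|$ matters there, while $\Delta B$ keeps its sign for the
  tilt-angle geometry.

`fit_k()` requires at least 6 offsets spanning a decade and refuses
profiles that are already fully saturated (all ratios > 0.99): such data
contain no information about the knee position.

## Quality control and encapsulation

`check_stability()` applies the standard injectability criteria —
diameter below 200 nm, PDI at or below 0.3, and zeta-potential
*magnitude* above 30 mV (electrostatic stabilization works for either
sign of surface charge; these DOTAP formulations are cationic). A
formulation passes only if every timepoint passes every criterion, and
loosening any threshold can only turn failures into passes (a property
the tests enforce).

The table loader handles two realities of instrument exports:
`"m ± s"` cells are split into mean and SD, and a missing decimal
separator (e.g. a 127.3 nm entry exported as 1273) is detected by
flagging sizes above five times the formulation's median. The repair —
division by the power of ten that brings the value closest to the
median — is explicit, logged, and recorded in a `size_repaired` column;
with `repair_decimal = FALSE` the value is kept and only warned about.
The packaged reference table contains exactly one such cell.

Encapsulation efficiency is plain arithmetic,
$EE = 100\,C_{en}/C_{in}$, scale-invariant in the concentration unit.
Values above 100% are physically impossible but arise from HPLC assay
noise when encapsulation is near-complete; they are returned unclamped
with a warning, because clamping would hide the very signal (assay
variance) a QC pipeline should surface. The packaged reference set
contains one such value (CBD, 100.26%).

## Dose-response analysis

MTT absorbances are normalized as
$V = 100\,(A - \mathrm{blank})/(A_\mathrm{ctrl} - \mathrm{blank})$, so
the untreated control is exactly 100%. `fit_ic50()` then fits the
two-parameter logistic $V(c) = 100/(1 + (c/IC_{50})^h)$ on
$\log IC_{50}$, which keeps the estimate positive and makes the standard
error multiplicative. The asymptotes are fixed at 100/0 because the data
are already control-normalized and the reported quantity is the absolute
IC50 — the concentration at 50% of control; a four-parameter variant
(`four_parameter = TRUE`) frees the asymptotes and still reports the
absolute IC50 from the fitted curve. Data that never cross 50% yield an
explicit "not estimable" error quoting the nearest observed viability,
rather than an extrapolated number.

Replicates are averaged per concentration before fitting, unweighted by
default. Inverse-variance weighting is applied only when externally
measured per-concentration SDs accompany the data: variances
re-estimated from triplicate wells are so noisy that weighting by them
measurably *worsens* the IC50 estimate (repeated-seed simulation at 5%
noise: 90th-percentile relative error 11.4% weighted vs 8.6%
unweighted), a small-sample effect familiar from meta-analysis.

## Synthetic data: what it emulates and what it does not

No raw decays, saturation profiles, or absorbance plates are published
for studies of this kind, so the generators are first-class pipeline
stages, not test fixtures. Each evaluates the stated functional form and
adds i.i.d. Gaussian noise with SD equal to `sigma_relative` times the
natural amplitude scale (the $t=0$ magnetization, the ratio ceiling 1,
or 100% viability). Gaussian additive noise is the conventional
instrument-noise assumption; a fixed seed (scoped with
`withr::with_seed`, so the session RNG is untouched) makes every draw
bit-reproducible.

Default study conditions, chosen once:

* recovery curves: 40 points log-spaced over $[0.01, 5]\,T_1$
  (equilibrium is reached at about five $T_1$), 1% noise;
* mixture decays: 40 points log-spaced over
  $[0.1\,\min T_2,\ 5\,\max T_2]$ so both decay scales are sampled, 1%
  noise — relaxometry measurement uncertainty is conventionally a few
  percent;
* saturation profiles: 12 offsets log-spaced over
  $[0.05, 20] \times (\gamma/2\pi)B_1$, i.e. a decade and a half around
  the knee, 2% noise;
* dose response: 8 concentrations spanning 0.5–50 µM in triplicate
  (standard MTT practice), 5% noise, Hill slope 1.5;
* characterization tables: 4 formulations × 4 timepoints (days 0, 7,
  14, 21).

What the generators deliberately do **not** emulate: time-domain
evolution under the actual pulse sequence (no Bloch simulation — only
the equilibrium ratio is modeled), multiplicative or correlated noise,
baseline drift and phase errors, DLS autocorrelation functions (tables
carry instrument-reported summary values), HPLC chromatograms, and
plate-position effects in MTT assays. Passing parameter-recovery tests
therefore demonstrates that the fitting machinery is correct and
well-conditioned under the assumed noise model — not that real
instrument artifacts are handled; with real data, residual structure
beyond the reported RMS is the first thing to inspect.

## Problem sizes and runtime

All fits are desk-scale: the full test suite runs a few hundred fits of
40-point curves, the repeated-seed property checks use 40–100 seeds per
scenario, and the end-to-end pipeline (4 materials × 3 NMR experiments,
16 QC rows, 18 dose-response fits) completes in seconds. These sizes
were chosen to match the scale of the emulated experiments — a handful
of materials, tens of points per curve — while keeping the simulations
comfortably reproducible on a laptop.

## Known limitations

* The Gaussian/Lorentzian decomposition assumes exactly two proton
  populations; genuinely multi-modal systems will alias into the two
  reported fractions.
* The $K(\tau_c)$ form assumes a single isotropic rotational mode;
  distributions of correlation times are summarized by one effective
  $\tau_c$.
* Reference $K$ and $\tau_c$ pairs obtained from independent fits of
  measured profiles carry their own rounding and fit error, so forward
  consistency between them holds within the stated $K$ uncertainties,
  not exactly.
* IC50s from the two-parameter logistic are conditional on complete
  efficacy at high dose; compounds with partial maximal effect need the
  4PL variant, at the cost of two more parameters from the same few
  concentrations.
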