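---
title: "Methods: elastoviscoplastic analysis of AFM nanoindentation curves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: elastoviscoplastic analysis of AFM nanoindentation curves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(afmindent)
```

## The problem

Corneocytes — the flat, keratin-filled dead cells of the outermost skin
layer — are stiff enough (hundreds of MPa to GPa in the dry state) that a
sharp AFM tip driven to micro-newton forces deforms them plastically.
Extracting meaningful material parameters from such force curves requires
three things that standard Hertzian cell mechanics does not provide:

1. the *effective* tip geometry, because a nominally 10 nm "sharp" tip is
   in reality blunt and irregular over the 30–200 nm contact depths
   involved;
2. an elastoplastic unloading analysis (Oliver–Pharr style), because the
   loading curve mixes elastic and plastic contributions;
3. a time-dependent (viscoplastic) description, because the force relaxes
   measurably during a constant-position hold.

`afmindent` implements this pipeline and a forward simulator that
generates force curves with the same observable structure, so that every
stage can be validated by parameter recovery.

## Contact model

For a rigid axisymmetric indenter on an elastic half-space the contact
stiffness is $S = dF/dh = 2E^*a$, with $E^* = E/(1-\nu^2)$ the
plane-strain modulus and $a$ the contact radius.  The tip profile is
described locally by a power law $h_c = c\,a^n$; the load then follows
$F = b\,h^m$ with $m = 1 + 1/n$, and total depth and contact depth are
related by $h = \kappa h_c$ with
$\kappa = \sqrt{\pi}\,\Gamma(\tfrac{n+2}{2})/\Gamma(\tfrac{n+1}{2})$
(`depth_scaling_kappa()`; $\kappa = 2$ for a paraboloid, $\pi/2$ for a
cone).  Integrating $dF = 2E^*a\,dh$ for a power-law profile gives the
closed form used throughout
(`power_law_elastic_force()`):
$$F = \frac{2E^*n}{n+1}(\kappa c)^{-1/n} h^{(n+1)/n}.$$
At $n = 2$, $c = 1/(2R)$ this is exactly the Hertz relation
$F = \tfrac{4}{3}E^*\sqrt{R}\,h^{3/2}$; the test suite verifies the
identity on 1000 random draws.

## Tip calibration from a reference elastomer

`calibrate_tip()` inverts the chain on curves measured on a
linear-elastic reference of known $E^*$ (default 3.79 MPa, an
incompressible PDMS elastomer):
average the loading curves, smooth, then per depth compute
$m(h)$, $n = 1/(m-1)$, $a = S/(2E^*)$, $\kappa(n)$ and $h_c = h/\kappa$,
and finally fit the tip radius function $a(h_c)$
(`fit_tip_profile()`): a degree-6 polynomial over $h_c \in [10, 200]$ nm
whose first two terms describe a truncated cone, plus a power-law cap
below 5 nm where the point cloud is too noisy for the polynomial.

**Smoothing choice.**  The load curve is smoothed by a polynomial in
*log–log* coordinates (`smooth_load_loglog()`, default order 3, weights
$\propto F^2$ — the inverse variance of $\ln F$ under additive force
noise).  A zero-intercept polynomial in linear coordinates (also
provided, `smooth_load_curve()`, `method = "linear"`) cannot be used for
the near-contact index: any such polynomial has $m(h) \to 1$ as
$h \to 0$ regardless of the data, which sends $n = 1/(m-1)$ to infinity
at exactly the depths where the cap is anchored.  The log–log basis
represents fractional power laws exactly, so for power-law data the
whole chain is exact to machine precision; this is the package's one
deliberate departure from the "2nd-order polynomial with zero intercept"
description, which remains available and remains the better *physical*
summary of a truncated-cone load curve.

**Local vs global κ.**  κ is applied pointwise with the local $n(h)$.
The alternative (one representative κ) is simple to emulate by passing a
constant to `contact_depth_map()`; for tips whose index varies from ~5
near the apex to ~1.5 at depth the pointwise mapping is the only one
that reproduces both regimes.  For non-power-law tips this pointwise
mapping is itself an approximation (the exact relation is an integral
over the whole profile); on the default truncated-cone truth it leaves a
~3% systematic in $a(h_c)$ at mid depths, which is inherent to the
method, not to this implementation.

**Cap conditioning.**  The cap coefficient $c$ has units
length$^{1-n}$, so its numeric error depends on the unit pivot.  Errors
are quoted in the µm convention of published tip-geometry tables; at an
SI pivot ($a = 1$ m) the $n$-uncertainty is amplified by the lever arm
$\ln(1\,\mathrm{m}/60\,\mathrm{nm}) \approx 16.6$ and the same fit looks
meaninglessly bad.  Under 1% force noise the cap region itself is below
the noise floor; the profile-wide power-law fit (`tip$powerlaw`) is the
estimator to use when a single $(c, n)$ summary is wanted.

## Elastoplastic unloading analysis

Unloading is elastic and follows $F = C_e(h-h_f)^2$
(`fit_unloading()`, force window $F \ge 0.2F_{max}$ by default; a depth
window is available).  From the fit:
$S_0 = 2C_e(h_{max}-h_f)$, sink-in $h_s = \phi F_{max}/S_0$
($\phi = 0.73$ for a near-conical indenter), contact depth
$h_c = h_{max} - h_s$, contact radius from the calibrated tip,
$E = \tfrac{\sqrt{\pi}}{2}(1-\nu^2)S_0/\sqrt{\pi a^2}$ with $\nu = 0.4$
(keratin), hardness $H = F_{max}/(\pi a^2)$ and static yield stress
$\sigma_Y = H/\psi$ with constraint factor $\psi \approx 3$ (fully
yielded contact).

**Errors-in-variables.**  Depth is computed as piezo travel minus
cantilever deflection, so force noise enters depth as $-\eta/k_c$,
anticorrelated with the force noise $\eta$.  A direct quadratic fit in
$(h, F)$ attenuates $S_0$ by ~8% at 1% noise with a 28.5 N/m lever.
When $k_c$ is known the quadratic is therefore refitted against the
noise-free piezo coordinate $u = h + F/k_c$ using the implicit model
$F = C_e(u - F/k_c - h_f)^2$, solved for $F$ in closed form.  This
removes the bias; the plain fit is the fallback when $k_c$ is unknown.

## Contact-point detection

The paper does not state its algorithm; ours is: (1) straight-line
baseline over the leading samples (removes offset and virtual
deflection), re-fitted in a second pass once a provisional contact is
known; (2) threshold at $\max(5\sigma_{noise},$ floor$)$ with a
three-sample sustained-exceedance guard; (3) change-point refinement —
candidate surface positions scanned over ±1 refinement window around the
crossing, each scored by force-space least squares of the piecewise
model $\{0$ before contact, $A(z-z_0)^p$ after$\}$ with $p$ profiled
over a grid in $[0.5, 3]$.  On the simulator's stated world this
recovers $z_0$ within 1–2 sample spacings for stiff contacts and within
a few nm even for soft, low-hardness contacts whose first ~20 nm of
contact force sit below the noise floor — the regime in which surface
detection error is the dominant contributor to modulus error, as the
depth-dependent-modulus artifact reported for PDMS illustrates.

## Relaxation and the Herschel–Bulkley model

During the 4 s hold the force follows a two-term Prony series
$F(t) = B_0 + B_1e^{-t/\tau_1} + B_2e^{-t/\tau_2}$ (`fit_prony()`:
bounded Gauss–Newton, multi-start over log-spaced $(\tau_1, \tau_2)$
guesses with the linear coefficients initialised by least squares;
non-relaxing holds return the degenerate $B_1 = B_2 = 0$ fit with a
warning).  Hardness relaxation coefficients are $C_i = B_i/(\pi a^2)$
with $a$ from the same curve's unloading analysis; instantaneous and
long-term hardness are $H_0 = \sum C_i$ and $H_\infty = C_0$.

Under additive elastic/plastic strain decomposition at constant total
strain, the plastic strain rate is
$\dot\varepsilon_p = \tfrac{3}{E}(C_1/\tau_1\,e^{-t/\tau_1} +
C_2/\tau_2\,e^{-t/\tau_2})$ and the uniaxial stress is
$\sigma(t) = H(t)/\psi$.  Pairing them pointwise on a log-spaced time
grid from $2\,dt$ (avoiding hold-onset transients) to the dwell gives a
monotone $(\dot\varepsilon_p, \sigma)$ locus fitted by
$\sigma = \sigma_Y + k\,\dot\varepsilon_p^{\,j}$
(`fit_herschel_bulkley()`, bounded, $j \in (0.05, 1]$; $j$ fixed at 1
recovers the Bingham special case by linear regression).  As the dwell
grows the fitted $\sigma_Y \to C_0/\psi$, the long-term stress; this
limit is a tested property.  $E$ in the strain-rate formula is taken
per-curve from the unloading analysis (per-cell medians behind a flag).
Curves with Prony $R^2 < 0.95$ or unidentifiable time constants are
excluded from the HB stage — an explicit stand-in for the paper-style
"40–50 of 64 curves" acceptance whose rule is unstated.

## The synthetic world

`generate_dataset()` emulates the acquisition protocol: 3 participants
× 5 cells × an 8×8 grid of loading–pause–unloading curves at 0.5 µm/s,
4 s dwell, 2 µN setpoint, k_c = 28.5 N/m, written as volts with a
20 nm/V sensitivity.  Participant-level medians (E of 1183/424/1105 MPa;
$C_0$ 151/76/92 MPa; $C_1+C_2$ 47/51/67 MPa; $\tau_1$ 0.12–0.16 s,
$\tau_2$ 2–2.4 s) correspond to dry volar-forearm corneocytes on glass;
cell- and curve-level biological scatter is lognormal (sdlog 0.15 and
0.10 — chosen so that 5×64 curves span roughly a factor-2 range, the
order of the spread published for such cells, while keeping H < E
everywhere).  Force noise is Gaussian with sd 0.25% of the setpoint
(5 nN): a ~30 N/m cantilever with ~0.2 nm deflection noise.  The
recovery criteria that specify 1% noise are run at 1% noise; the dataset
default is the instrument-realistic level, chosen also so that the
Prony-fit acceptance gate ($R^2 \ge 0.95$) passes the bulk of curves,
as the 40-50-of-64 acceptance typical of such experiments implies — at
1% noise the gate would reject nearly everything even though the fits
themselves are unbiased.

The loading phase is modelled as a fully yielded contact
$F = \pi a^2 H_0$ with elastic sink-in $\phi F/S$ — the minimal forward
model consistent with the analysis equations, *not* a finite-element
constitutive law.  Consequences to keep in mind:

- the hold is simulated at constant tip depth, with the piezo tracking
  the small cantilever relaxation $F/k_c$, because a literally constant
  piezo position with fixed depth would contradict $z = h + F/k_c$;
- $h_f \to 0$ as $H/E$ approaches a finite validity boundary (elastic
  recovery equal to total depth); beyond it the generator refuses the
  parameters rather than emit a nonphysical curve;
- adhesion, substrate compliance and loading-phase creep are not
  modelled; a green recovery test therefore establishes correctness of
  the inversion, not robustness to those real-world artifacts.

## Numerical choices

- All fitting in scaled units (nm, nN) to control conditioning; the
  degree-6 tip polynomial is fitted in nm and converted to SI.
- Bounded nonlinear fits use `stats::nls(algorithm = "port")` with
  closed-form or linear-least-squares starting values and multi-start
  where the objective is multimodal (Prony).
- Relaxation times are returned ordered ($\tau_1 < \tau_2$); terms with
  $\tau$ outside $(dt/2, 5\times$dwell$)$ are flagged unidentifiable.
- The tip polynomial's monotonicity check tolerates 0.5% endpoint wiggle
  (Runge-type) before erroring.
- Curves whose contact depth exceeds the calibrated tip range are
  evaluated by extrapolation, flagged, and excluded from summary medians
  by default; curves deeper than 10% of a declared sample thickness are
  flagged.

## Known limitations

- The pointwise-κ mapping is approximate for non-power-law tips (~3%
  mid-range radius error on a truncated cone); exact only for power
  laws.
- Contact detection degrades gracefully but measurably for materials
  whose contact onset is below the noise floor; modulus errors on such
  curves reach ~10% at 1% force noise.
- The per-curve hardness uses the post-relaxation unloading force (the
  definition tied to the unloading stiffness), which for strongly
  relaxing materials sits below the setpoint value.
- Substrate compliance (soft-tape mounting) is out of scope; the
  simulator and analysis both assume a stiff support.
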