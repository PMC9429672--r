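---
title: "Methods: protein diffusive dynamics from QENS and DLS"
author: "qensdls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: protein diffusive dynamics from QENS and DLS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qensdls)
```

## The measurement problem

Quasi-elastic neutron scattering (QENS) measures the dynamic structure
factor $S(q, \omega)$ of a sample: diffusive motions broaden the elastic
line into Lorentzians whose half-width at half-maximum (HWHM) encodes the
underlying diffusion. For a protein in solution two windows matter:

* a **time-of-flight** spectrometer (energy resolution of order
  80 µeV FWHM, window of a few meV) resolves picosecond motions —
  solvent diffusion and fast internal/ligand dynamics;
* a **backscattering** spectrometer (0.75 µeV FWHM, window tens of µeV)
  resolves nanosecond motions — the centre-of-mass diffusion of the whole
  protein and the slower internal dynamics, expressed through the elastic
  incoherent structure factor (EISF).

Dynamic light scattering (DLS) complements both with the dilute-limit
*translational* diffusion coefficient at much smaller $q$.

All energies in this package are µeV, momentum transfers Å⁻¹, diffusion
coefficients Å²/ns, times ns. The single conversion constant is
$\hbar = 0.6582119569$ µeV·ns, so a diffusion coefficient $D$ maps to a
Fickian linewidth $\gamma(q) = \hbar D q^2$.

## Spectral models and the resolution convolution

Every fitted model is a sum of Dirac and Lorentzian components convolved
with the instrument resolution $\mathcal{R}(q,\omega)$, which is
represented as a per-$q$ sum of Gaussians (`resolution_model()`). This
closes the convolution analytically: a Dirac line becomes the resolution
profile, and Lorentzian ⊗ Gaussian is a Voigt profile, evaluated from the
real part of the Faddeeva function $w(z)$. `faddeeva_w()` implements
Weideman's 36-term rational approximation, accurate to ~1e−14 and valid
on the upper half-plane; the test suite pins it against frozen reference
values and against brute-force numerical convolution (≤ 1e−5 at the
peak).

The fitting protocol is staged, mirroring a two-instrument experiment:

1. **Solvent (time-of-flight, per q).** `fit_solvent()` fits
   $\mathcal{R} \otimes [I_1 L(\sigma_1) + I_2 L(\sigma_2) +
   I_\delta\,\delta(\omega)] + s\omega + c$: two solvent Lorentzians
   (narrow translational water line with a jump-diffusion $q$-dependence,
   broad rotational/librational line), a container elastic line, and a
   linear background. The background is *not* convolved: it models
   detector/instrument baseline, not scattering. Width ordering
   $\sigma_1 < \sigma_2$ is enforced after the fit (amplitudes swapped
   with the widths; ties keep input order).
2. **Protein solution (time-of-flight, per q).** `fit_protein_tof()`
   fixes the solvent amplitudes and background, rescaled by $(1-\varphi)$
   for the protein volume fraction $\varphi$, and frees an apparent
   elastic line plus two internal Lorentzians: the slower one
   (`gamma_in5`) carrying the jump-diffusion signal, and a broad fast
   component. `fit_jump_diffusion()` then fits
   $\gamma(q) = \hbar D_i q^2 / (1 + D_i q^2 \tau)$, which is linear at
   small $q$ and saturates at $\hbar/\tau$; a fit driven to $\tau \le 0$
   is refit as a Fickian line and flagged.
3. **Backscattering, global in q.** `global_fit()` fits all $(q,\omega)$
   jointly with one global $D$ and per-$q$ amplitude $\beta(q)$ and EISF
   $A_0(q)$:
   $\beta [A_0 L(\hbar D q^2) + (1-A_0) L(\hbar D q^2 + \Gamma)] +
   \beta_{D_2O} L(\gamma_{D_2O})$, everything resolution-convolved. The
   internal width $\Gamma(q)$ is **always fixed externally** (from stage
   2, or an explicit override): freeing it is unstable whenever the
   internal motions are faster than the accessible window — for apo-like
   samples the fit drives $\Gamma \to \infty$ with diverging errors. The
   solvent amplitude is fixed per $q$ and by default also rescaled by
   $(1-\varphi)$ (configurable, `scale_solvent`), keeping the two
   instruments' conventions consistent.
4. **EISF.** `fit_eisf()` fits
   $A_0(q) = a + (1-a)\,[b A_3(q; d) + (1-b) A_{sph}(q; R)]$ with the
   immobile fraction $a$, the three-site methyl jump term
   $A_3 = \tfrac13 (1 + 2 j_0(qd))$ at fixed $d = 1.715$ Å, and a sphere
   term for side-chain motion. Two sphere models are provided: the
   confined-diffusion (Volino–Dianoux) form $[3 j_1(qR)/(qR)]^2$
   (default — it is the canonical EISF in which $j_1$ appears) and the
   surface-of-a-sphere form $[j_0(qR)]^2$ as an option. Box constraints
   $a, b \in [0,1]$, $R \in [1, 50]$ Å; a parameter ending on a box edge
   is flagged unidentifiable.

### Numerical strategy

The global backscattering fit is solved by **variable projection**: at
fixed $D$ the per-$q$ amplitudes $(\beta A_0, \beta(1-A_0))$ solve a
non-negative weighted linear least squares, leaving a one-dimensional
profile objective in $D$ that is scanned on a log grid and polished by
five jittered local starts (fixed jitter seed). This is the same joint
weighted-least-squares objective as a raw 33-parameter optimisation, but
far better conditioned; the reported uncertainties come from the full
joint Jacobian at the optimum. Per-$q$ nonlinear fits use
Levenberg–Marquardt (minpack.lm) with informed starts (background from
window edges, widths from window fractions and a jump-diffusion-shaped
seed) and tight tolerances; a non-converged $q$ is flagged, never fatal,
and downstream fits use the surviving points (at least 4 required).

## Hydrodynamic interpretation

* `viscosity_of()` holds the D₂O viscosity anchors 1.830, 1.175 and
  0.830 mPa·s at 280, 295 and 310 K with log-linear interpolation
  strictly inside [280, 310] K (no extrapolation); the
  "ligand-adjusted" mode multiplies by 1.08 for the viscosity increase of
  a concentrated small-molecule solution.
* `stokes_einstein_D()` / `stokes_einstein_radius()` convert between
  $D_t$ and $R_h$ via $D_t = k_B T / (6\pi\eta R_h)$; they are exact
  inverses (tested to 1e−12). The DLS reproduction default is 295 K
  with these viscosities — the unique combination that reproduces the
  reference radius pair from the reference diffusion pair.
* `effective_volume_fraction()` rescales the dry volume fraction by
  $(R_h/R_{dry})^3$ for crowding models;
  `hs_short_time_factors()` supplies second-order hard-sphere virial
  factors $f_t(\varphi) = 1 - 1.8315\varphi(1 + 0.12\varphi -
  0.70\varphi^2)$ and $f_r(\varphi) = 1 - 0.631\varphi - 0.726\varphi^2$
  for short-time translational and rotational self-diffusion. The
  colloid literature offers several coefficient sets; these standard
  forms are a deliberate, swappable choice.
* `apparent_diffusion_sphere()` combines translation and rotation for a
  rigid sphere via the first cumulant of the incoherent intermediate
  scattering function, using rotational mode weights
  $B_\ell(x) = 3(2\ell+1)\int_0^1 j_\ell(xu)^2 u^2\,du$
  (`sphere_mode_weights()`, completeness $\sum_\ell B_\ell = 1$ checked
  to 1e−6). A useful exact identity falls out:
  $\sum_\ell B_\ell(x)\,\ell(\ell+1) = \tfrac{2}{5}x^2$, so the
  rotational contribution to the apparent $D$ is the *constant*
  $\tfrac25 R^2 D_r$ at every $q > 0$ — it does not vanish as
  $q \to 0$, because the decay of $B_\ell$ exactly cancels the $1/q^2$.
  The expansion is summed explicitly up to $x = 30$ and the closed form
  used beyond.
* `estimate_cluster_size()` inverts the compact-sphere cluster model: a
  cluster of $N$ tetramers is a sphere of radius $R_h N^{1/3}$ with
  Stokes–Einstein(-Debye) diffusion reduced by the hard-sphere factors
  at the effective volume fraction; the predicted apparent $D$
  (averaged over the backscattering $q$ range 0.2–1.9 Å⁻¹, a simple
  arithmetic mean) is matched to the observation by monotone root
  finding. Observed $D$ above the single-tetramer prediction returns
  $N = 1$ with a warning: no sub-tetramer clusters.

## The DLS chain

`fit_g2()` fits the Siegert form $g_2(\tau) = 1 + \beta e^{-2\Gamma\tau}$
per correlogram; `fit_D_from_gamma()` regresses $\Gamma$ on $q^2$ with
zero intercept ($q$ from `q_from_angle()`, defaults $\lambda = 632.8$ nm,
$n = 1.33$), warning when a free-intercept check finds a non-diffusive
component at 3σ; `extrapolate_dilute()` fits
$D_t(c) = D_0 (1 + k_D c)$ across concentrations, falling back to the
weighted mean (flagged "averaged") when the slope is insignificant at
1σ. Only single-exponential analysis is provided; polydisperse cumulant
analysis is out of scope.

## The synthetic-data generator

`ground_truth()` + `simulate_solvent()` / `simulate_protein()` /
`simulate_dls()` generate instrument-realistic data with known truth so
every stage has a parameter-recovery surface. Defaults emulate the
study conditions: volume fraction $\varphi = 0.09$ (135 mg/mL at
0.70 cm³/g), centre-of-mass $D = 3$ Å²/ns, internal jump diffusion
$D_i = 50$ Å²/ns with $\tau = 0.01$ ns (so the fixed $\Gamma$ exceeds
the backscattering window at high $q$, reproducing the identifiability
caveat discussed above), EISF $(a, b, R, d) = (0.4, 0.3, 8.5, 1.715)$ Å,
and a liganded-sample amplitude hierarchy in which the hydrogen-rich
protein + ligand signal sits well above the weak incoherent D₂O
background with a small apparent-elastic container line. Noise is
additive Gaussian with sd $= s\sqrt{\max(\text{model}, 10^{-6}\,
\text{peak})}$, emulating counting statistics on reduced data; seeds are
explicit and mandatory whenever noise is requested. `noise_for_snr()`
converts a desired peak signal-to-noise into the scale $s$.

What the generator does **not** emulate: coherent scattering, multiple
scattering, container Bragg lines, detector efficiency or dead-time,
asymmetric instrument resolution (supported by the contract via
off-centre Gaussians, but the default is a single centred Gaussian), and
the qualitatively different $q$-dependence of a free-ligand reference
line. Passing recovery tests therefore demonstrate correctness of the
estimators under the stated noise model, not robustness to every
instrument artefact in real data.

## What recovery the data can support

Noise-free, every stage recovers its truth essentially to machine
precision (asserted at ≤ 0.1%). At counting noise with peak
signal-to-noise ≈ 30 (16 q × 256 channels backscattering; 18 q × 512
channels time-of-flight — the problem sizes used throughout the tests):

* the global $D$ is recovered to ~1% (asserted ≤ 5% mean over seeds);
* the EISF parameters $(a, b, R)$ to a few percent each (asserted
  ≤ 15% mean over seeds);
* the jump-diffusion pair $(D_i, \tau)$ is the weak spot: the slow
  internal width is strongly correlated with the apparent elastic line
  under an 80 µeV resolution, and a linearised information analysis of
  the extracted widths puts the one-sigma bound on $D_i$ near 25–30% at
  this noise level, with a positive bias from the non-negativity of the
  amplitudes. The test suite asserts what the information content
  supports (estimates consistent with truth within their own reported
  uncertainties, honest error bars with ~68% coverage) rather than a
  tolerance the data cannot deliver; tighter recovery requires higher
  statistics or a narrower-resolution instrument.

## Other deliberate choices

* The ligand-only reference sample runs through the same protein
  machinery with its own (smaller) default volume fraction of 0.03.
* Whether the backscattering background/solvent conventions match the
  time-of-flight $(1-\varphi)$ scaling is not observable from the model
  structure alone; it is a flag, default on.
* Temperatures between viscosity anchors use log-linear interpolation;
  outside [280, 310] K the function errors rather than extrapolates.
* The DLS bath temperature defaults to 295 K for Stokes–Einstein
  conversions (documented prominently in `fit_dls()`); other
  temperatures are supported through the dataset metadata and `eta`
  argument.
* File interchange is plain CSV with a `#` metadata header (long
  format), so synthetic data, fixtures and real reduced data share one
  tested path; instrument-native formats are upstream of this package.
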