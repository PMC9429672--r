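# qensdls

Fitting pipeline for probing how ligand binding changes the diffusive
dynamics of a protein in solution, combining **quasi-elastic neutron
scattering** (QENS) on two complementary spectrometers with **dynamic
light scattering** (DLS).

It is written for neutron/biophysics practitioners who have reduced
S(q, ω) spectra (a protein solution and its matched D₂O buffer) and DLS
correlograms, and want the full analysis chain as tested, scriptable R
functions rather than one-off notebook code:

* **Lineshapes** — unit-area Lorentzian/Gaussian/Voigt densities, the
  Voigt evaluated from the real part of the Faddeeva function w(z)
  (Weideman rational approximation, ~1e−14 accurate), and analytic
  convolution of delta/Lorentzian models with sum-of-Gaussians
  instrument resolutions.
* **Time-of-flight stage** — per-q fits of the solvent model
  ℛ ⊗ [I₁L(σ₁) + I₂L(σ₂) + I_δδ(ω)] + sω + c, then the protein model
  with the solvent fixed and rescaled by (1−φ); the extracted internal
  linewidths are fitted with the jump-diffusion law
  γ(q) = ħD_i q² / (1 + D_i q² τ), which saturates at ħ/τ.
* **Backscattering stage** — a single global fit over all (q, ω) of
  β(q)[A₀(q) L(ħDq²) + (1−A₀(q)) L(ħDq² + Γ(q))] + solvent, all
  resolution-convolved, with one global center-of-mass D and the
  internal width Γ(q) fixed from the time-of-flight result; the per-q
  A₀(q) is the elastic incoherent structure factor (EISF), fitted with
  A₀ = a + (1−a)[b·A₃(q;d) + (1−b)·A_sph(q;R)] (three-site methyl jumps
  at d = 1.715 Å plus diffusion in a sphere).
* **Hydrodynamics** — Stokes–Einstein conversions D_t = k_BT/(6πηR_h)
  with the D₂O viscosity table, effective hard-sphere volume fractions
  φ_t = φ(R_h/R)³, short-time crowding factors, the rigid-sphere
  rotation–translation first cumulant, and inversion of an observed
  apparent D into a compact-cluster size (tetramers per cluster).
* **DLS** — Siegert fits g₂(τ) = 1 + βe^(−2Γτ), Γ-vs-q² regression,
  dilute-limit extrapolation D_t(c) = D₀(1 + k_D c), hydrodynamic radii.
* **Synthetic data** — instrument-realistic spectrum sets (0.75 µeV and
  80 µeV FWHM emulations) and correlograms with known ground truth and
  counting-statistics noise, so the entire chain is testable end to end
  without any experimental download.

## Worked example

Simulate a liganded-sample experiment at peak signal-to-noise ≈ 30 and
run the full chain (seeds fixed for reproducibility):

```r
library(qensdls)
profs  <- default_profiles()
truth0 <- ground_truth()         # D = 3, D_i = 50, tau = 0.01, a = 0.4, b = 0.3, R = 8.5

noise_tof <- noise_for_snr(max(simulate_protein(profs$tof, truth0, "liganded")$intensity), 30)
noise_bs  <- noise_for_snr(max(simulate_protein(profs$backscattering, truth0, "liganded")$intensity), 30)

# -- time-of-flight: solvent fit, protein fit, jump diffusion
truth_tof <- ground_truth(noise = noise_tof, seed = 42)
res_tof   <- profile_resolution(profs$tof)
sf <- fit_solvent(simulate_solvent(profs$tof, truth_tof, seed = 1042), res_tof)
tf <- fit_protein_tof(simulate_protein(profs$tof, truth_tof, "liganded", seed = 2042),
                      res_tof, sf, phi = 0.09)
jd <- fit_jump_diffusion(tf$gamma_in5, tf$q, tf$gamma_in5_se)
jd
#> Jump diffusion: D_i = 75.94 +/- 26 A^2/ns, tau = 0.01284 +/- 0.0023 ns

# -- backscattering: global fit with the internal width fixed from above
truth_bs <- ground_truth(noise = noise_bs, seed = 42)
bs <- simulate_protein(profs$backscattering, truth_bs, "liganded", seed = 3042)
gf <- global_fit(bs, profile_resolution(profs$backscattering),
                 bs_solvent_truth_params(truth_bs, profs$backscattering$q),
                 internal = jd, phi = 0.09)
gf
#> Global backscattering fit: D = 3.17 +/- 0.044 A^2/ns over 16 q points (chi2_red = 1.02)

fit_eisf(gf$per_q$A0, gf$per_q$q, gf$per_q$A0_se)
#> EISF fit (volino sphere): a = 0.441 +/- 0.022, b = 0.271 +/- 0.042, R = 7.704 +/- 0.26 A (d = 1.715 A fixed)

# -- hydrodynamic reading and the parallel DLS branch
eta <- viscosity_of(295, "ligand-adjusted")
stokes_einstein_radius(gf$D, 295, eta)
#> [1] 5.37        # nm: apparent radius, inflated by rotation + crowding
dls <- simulate_dls(4.05, concentrations = 1:5, k_D = -0.002,
                    noise = 0.016, seed = 4042)
fit_dls(dls, eta = eta)
#> DLS: D0 = 4.025 +/- 0.011 A^2/ns (averaged), R_h = 4.23 nm at 295 K
```

Reading the numbers: the jump-diffusion estimate carries a large honest
uncertainty (a ~20–40 µeV internal line under an 80 µeV resolution is
weakly identifiable at this noise — see the methods vignette); because
the true internal width partly overlaps the backscattering window, the
fitted D lands 0.17 Å²/ns above the truth of 3.0, a systematic of the
same order as its sensitivity to the fixed internal dynamics. The DLS
branch recovers its dilute-limit D₀ = 4.05 Å²/ns within error and
converts to R_h ≈ 4.2 nm with the ligand-adjusted viscosity. The same
chain can be driven from files via `run_config()` + `run_pipeline()`
(formats: `write_spectrum_set()` / `read_spectrum_set()`, `write_dls()`
/ `read_dls()`).

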