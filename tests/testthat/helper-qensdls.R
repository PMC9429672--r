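# Shared fixtures, built in code and cached per test run.

.fixture_cache <- new.env(parent = emptyenv())

with_cache <- function(key, expr) {
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# a small instrument for fast simulation-heavy property tests
tiny_tof_profile <- function(n_omega = 64L) {
  instrument_profile("tiny-tof", "tof",
                     q = c(0.5, 1.0, 1.5),
                     omega = seq(-3000, 3000, length.out = n_omega),
                     fwhm = 80)
}

default_bs_setup <- function() {
  with_cache("bs_setup", {
    profs <- default_profiles()
    truth <- ground_truth()
    list(profile = profs$backscattering,
         resolution = profile_resolution(profs$backscattering),
         truth = truth,
         solvent_params = bs_solvent_truth_params(truth,
                                                  profs$backscattering$q))
  })
}

default_tof_setup <- function() {
  with_cache("tof_setup", {
    profs <- default_profiles()
    truth <- ground_truth()
    list(profile = profs$tof,
         resolution = profile_resolution(profs$tof),
         truth = truth)
  })
}

# noise scale giving peak signal-to-noise ~ snr for a sample kind
noise_scale_for <- function(kind = c("bs", "tof"), snr = 30) {
  kind <- match.arg(kind)
  key <- paste0("noise_", kind, "_", snr)
  with_cache(key, {
    profs <- default_profiles()
    truth <- ground_truth()
    sp <- if (kind == "bs")
      simulate_protein(profs$backscattering, truth, "liganded")
    else simulate_protein(profs$tof, truth, "liganded")
    noise_for_snr(max(sp$intensity), snr)
  })
}

rel_err <- function(x, truth) abs(x - truth) / abs(truth)
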