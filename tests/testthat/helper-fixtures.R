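# Shared fixtures: everything is generated in code at test time.

# One cardiac cycle sampled from the standardized model over one period.
v0_cycle <- function(n = 200L) {
  tt <- seq(0, fs_period(v0()), length.out = n)
  cardiac_cycle(tt, fs_evaluate(v0(), tt))
}

# Random eighth-order series with positive offset (so sampled traces are
# valid flow envelopes).
random_series <- function(a0 = 60) {
  fourier8(w = 2 * pi / stats::runif(1, 0.6, 1.0), a0 = a0,
           a = stats::rnorm(8, 0, 2), b = stats::rnorm(8, 0, 2))
}

# Amplitude-renormalized standardized template: the affine image of v0()
# whose extrema are exactly (50, 80) and whose cycle is exactly 0.8 s.
# This is the fixed point the standardize -> fit -> average pipeline
# converges to on noise-free v0-shaped input.
renormalized_template <- function() {
  ex <- fs_extrema(v0())
  s <- 30 / (ex$vmax - ex$vmin)
  base <- v0()
  fourier8(w = 2 * pi / 0.8, a0 = 50 + s * (base$a0 - ex$vmin),
           a = s * base$a, b = s * base$b)
}

# Small noise-free, jitter-free, notch-free cohort for pipeline tests.
clean_cohort <- function(n_patients = 6L, seed = 11L) {
  synth_cohort(cohort_config(n_patients = n_patients, noise_sd = 0,
                             notch_probability = 0, jitter_sd = 0,
                             cycles = 3L, seed = seed))
}
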