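# Shared small fixtures for the suite. Complex frequency grids keep a small
# positive real part: on the pure imaginary axis the lossless aortic LC
# ladder's continued fraction need not converge.
random_s_grid <- function(n, seed, sigma_frac = 0.01) {
  set.seed(seed)
  omega <- stats::runif(n, 0.5, 50) * sample(c(-1, 1), n, replace = TRUE)
  complex(real = sigma_frac * abs(omega), imaginary = omega)
}

aortic_wave <- function(dt = 0.002, n_periods = 4, ...) {
  sample_waveform(pulse_params("aorta", ...), dt = dt, n_periods = n_periods)
}

arteriolar_wave <- function(dt = 0.002, n_periods = 4, ...) {
  sample_waveform(pulse_params("arteriole", ...), dt = dt,
                  n_periods = n_periods)
}
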