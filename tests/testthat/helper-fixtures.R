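# shared fixtures; everything is built in code at test time

uniform_plane <- function(value = 1, n = 10, spacing = 1, quantity = "dose") {
  dose_plane(matrix(value, n, n), spacing, quantity = quantity)
}

# x-ramp plane: value = lo + slope * (x - x_min), independent of y
ramp_plane <- function(n = 50, spacing = 1, lo = 0.5, hi = 2.5) {
  vals <- matrix(rep(seq(lo, hi, length.out = n), each = n), n, byrow = FALSE)
  dose_plane(vals, spacing)
}

with_seed_rnorm <- function(seed, n, sd) {
  set.seed(seed)
  stats::rnorm(n, 0, sd)
}

# a small FFF-like beam pair with noise, the stock gamma test subject
gamma_test_pair <- function(seed) {
  set.seed(seed)
  beam <- beam_model("FFF", field_size = 80, k = 0.004)
  base <- gen_beam_plane(beam, spacing = 2, extent = 98, noise_sd = 0.01,
                         seed = seed)
  gen_plane_pair(base, dose_error = stats::runif(1, -0.03, 0.03),
                 shift = stats::runif(2, -3, 3))
}
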