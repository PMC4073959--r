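## Shared fixtures, all generated in code.

## band-limited random nonnegative image with a cosine-tapered circular
## support (what a linear-interpolation FBP can actually represent)
random_smooth_image <- function(seed, n = 32, passes = 8) {
  set.seed(seed)
  m <- matrix(runif(n * n), n, n)
  for (i in seq_len(passes)) m <- phaseCT:::gaussian3_smooth(m, 0.9)
  d <- sqrt(outer((1:n - (n + 1) / 2)^2, (1:n - (n + 1) / 2)^2, "+"))
  taper <- pmin(1, pmax(0, ((n / 2 - 1) - d) / 4))
  m * (0.5 - 0.5 * cos(pi * taper))
}

## exact logistic edge profile as a line_profile object
sigmoid_profile <- function(k1 = 0, k2 = 50, k3 = 0.1, k4 = 1,
                            length_mm = 0.2, n = 23, noise_sd = 0,
                            seed = NULL) {
  x <- seq(0, length_mm, length.out = n)
  y <- k1 + k4 / (1 + exp(-k2 * (x - k3)))
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    y <- y + rnorm(n, sd = noise_sd)
  }
  structure(list(positions_mm = x, values = y, n_averaged = 1,
                 length_mm = length_mm), class = "line_profile")
}

tiny_beam <- function(photons = Inf) beam_spec(22, photons)

## small homogeneous-gamma phantom for fast propagation tests
tiny_lung_spec <- function(seed = 1, ...) {
  phantom_spec(shape = c(8L, 48L, 48L), vesicle_count = 10L,
               vesicle_radius_range = c(20, 30), bone_rod = FALSE,
               texture_sd = 0, seed = seed, ...)
}
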