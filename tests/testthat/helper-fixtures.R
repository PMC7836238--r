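# Shared in-code fixtures for the test suite.

# Gaussian subject stack with constant true mean/sd on a small 2D grid.
gaussian_stack <- function(n = 20, shape = c(8, 8), mean = 0, sd = 1,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- domain_grid(shape)
  y <- matrix(rnorm(prod(shape) * n, mean = mean, sd = sd), prod(shape), n)
  subject_stack(y, g)
}

# Signal-plus-smoothed-noise stack for a simulation design.
design_stack <- function(signal, noise, n) {
  g <- domain_grid(signal$shape)
  mu <- make_signal(signal)
  st <- make_noise(g, noise, n)
  st$data <- st$data + mu
  list(stack = st, mu = mu, grid = g)
}

# Scalar transcription of the delta-method Cohen's d residuals for one voxel
# (independent of the vectorized implementation). Uses the package-wide N-1
# variance divisor and empirical-mean centering.
scalar_residuals <- function(y) {
  n <- length(y)
  mu <- mean(y)
  sd <- sqrt(sum((y - mu)^2) / (n - 1))
  e <- (y - mu) / sd
  e - (mu / (2 * sd)) * (e^2 - mean(e^2))
}

kernel_sigma <- function(fwhm = 3) fwhm / (2 * sqrt(2 * log(2)))
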