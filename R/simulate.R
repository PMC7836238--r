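#' Synthetic signal specification
#'
#' Describes the deterministic mean fields used in the coverage experiments:
#' a 2D linear ramp rising 0 to 1 along x (no smoothing), a 2D disk of
#' magnitude 1 and radius 30 smoothed with a 3-voxel-FWHM Gaussian kernel,
#' and 3D spherical phantoms (radius 5 or 30, smoothed then rescaled
#' imagewise to a maximum of 1) or four spheres of varying radii whose
#' overlap regions are clipped back to 1 so every sphere centre carries
#' magnitude 1.
#'
#' @param kind one of `"ramp2d"`, `"circle2d"`, `"sphere3d_small"`,
#'   `"sphere3d_large"`, `"multi_sphere3d"`.
#' @param shape grid shape; defaults to 100x100 (2D kinds) or 100x100x100.
#' @param magnitude peak signal intensity (1 in the study designs).
#' @param smoothing_fwhm Gaussian kernel FWHM in voxels applied to the
#'   phantom indicators (ignored by the ramp, which is stated unsmoothed).
#' @param radius sphere/disk radius in voxels; defaults per kind
#'   (30 circle, 5 small sphere, 30 large sphere).
#' @param centers matrix of sphere centres (rows) for `multi_sphere3d`;
#'   defaults to four spheres of radii 4, 6, 8, 10 spread over the volume.
#' @param radii radii for `multi_sphere3d`.
#' @return An object of class `signal_spec`.
#' @export
signal_spec <- function(kind = c("ramp2d", "circle2d", "sphere3d_small",
                                 "sphere3d_large", "multi_sphere3d"),
                        shape = NULL, magnitude = 1, smoothing_fwhm = 3,
                        radius = NULL, centers = NULL, radii = NULL) {
  kind <- match.arg(kind)
  if (is.null(shape))
    shape <- if (kind %in% c("ramp2d", "circle2d")) c(100L, 100L)
             else c(100L, 100L, 100L)
  shape <- as.integer(shape)
  if (is.null(radius))
    radius <- switch(kind, circle2d = 30, sphere3d_small = 5,
                     sphere3d_large = 30, 0)
  if (kind == "multi_sphere3d") {
    if (is.null(radii)) radii <- c(4, 6, 8, 10)
    if (is.null(centers))
      centers <- rbind(c(0.30, 0.30, 0.30), c(0.70, 0.35, 0.30),
                       c(0.35, 0.70, 0.45), c(0.70, 0.70, 0.70)) *
        matrix(shape, 4, length(shape), byrow = TRUE)
    if (nrow(centers) != length(radii))
      stop("centers and radii disagree")
  }
  if (radius > min(shape) / 2 && kind != "multi_sphere3d")
    stop("phantom radius ", radius, " exceeds the grid")
  structure(list(kind = kind, shape = shape, magnitude = magnitude,
                 smoothing_fwhm = smoothing_fwhm, radius = radius,
                 centers = centers, radii = radii),
            class = "signal_spec")
}

#' Noise specification
#'
#' Subject noise is FWHM-smoothed white Gaussian noise standardized to exact
#' pointwise unit variance, then scaled by a standard-deviation field: either
#' homogeneous (sd 1 everywhere) or rising linearly along the last grid axis
#' from `sd_low` to `sd_high` (0.5 to 1.5 in the study designs) while
#' constant along the others.
#'
#' @param smoothing_fwhm kernel FWHM in voxels (3 in the study designs).
#' @param sd `"homogeneous"` or `"linear"`.
#' @param sd_low,sd_high endpoints of the linear sd profile.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(smoothing_fwhm = 3, sd = c("homogeneous", "linear"),
                       sd_low = 0.5, sd_high = 1.5) {
  sd <- match.arg(sd)
  structure(list(smoothing_fwhm = smoothing_fwhm, sd = sd,
                 sd_low = sd_low, sd_high = sd_high),
            class = "noise_spec")
}

# --- Gaussian smoothing -----------------------------------------------------

fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

# Truncated (4 sigma), sum-normalized 1D Gaussian kernel.
gaussian_kernel <- function(fwhm) {
  sigma <- fwhm_to_sigma(fwhm)
  r <- max(1L, ceiling(4 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k / sum(k)
}

# Dense n x n convolution operator for a symmetric kernel, zero padding.
conv_matrix <- function(n, kernel) {
  r <- (length(kernel) - 1L) %/% 2L
  K <- matrix(0, n, n)
  for (off in (-r):r) {
    i <- max(1L, 1L - off):min(n, n - off)
    K[cbind(i, i + off)] <- kernel[off + r + 1L]
  }
  K
}

# Separable Gaussian smoothing of fields stored as columns of x (voxels in
# column-major order for grid shape `shape`); zero padding outside the grid.
# Axis 1 is a dense BLAS product on a free reshape; the remaining axes use
# sparse Kronecker-structured operators, avoiding array permutations.
smooth_fields <- function(x, shape, fwhm) {
  x <- as.matrix(x)
  kern <- gaussian_kernel(fwhm)
  nsub <- ncol(x)
  d <- length(shape)
  v <- prod(shape)

  K1 <- conv_matrix(shape[1L], kern)
  dim(x) <- c(shape[1L], v / shape[1L] * nsub)
  x <- K1 %*% x
  dim(x) <- c(v, nsub)

  for (ax in seq_len(d)[-1L]) {
    K <- methods::as(conv_matrix(shape[ax], kern), "CsparseMatrix")
    before <- prod(shape[seq_len(ax - 1L)])
    after <- prod(shape[seq_len(d) > ax])
    op <- kronecker(K, Matrix::Diagonal(before))
    if (after > 1L) op <- kronecker(Matrix::Diagonal(after), op)
    x <- as.matrix(op %*% x)
  }
  x
}

# Exact pointwise sd of smoothed unit white noise (separable product of
# squared-kernel row sums; handles edge truncation under zero padding).
smoothed_noise_sd <- function(shape, fwhm) {
  kern <- gaussian_kernel(fwhm)
  v <- lapply(shape, function(n) rowSums(conv_matrix(n, kern)^2))
  out <- v[[1L]]
  for (ax in seq_along(shape)[-1L]) out <- outer(out, v[[ax]])
  sqrt(as.vector(out))
}

# Standard-deviation field of a noise_spec on a grid (full-grid vector).
noise_sd_field <- function(grid, noise) {
  shape <- grid$shape
  if (noise$sd == "homogeneous") return(rep(1, prod(shape)))
  last <- shape[length(shape)]
  prof <- noise$sd_low + (seq_len(last) - 1) / (last - 1) *
    (noise$sd_high - noise$sd_low)
  as.vector(array(rep(prof, each = prod(shape[-length(shape)])), dim = shape))
}

# --- Signal and noise generation --------------------------------------------

#' Generate a deterministic signal field
#'
#' @param spec a [signal_spec()].
#' @return Full-grid numeric vector of the mean field mu(s).
#' @export
make_signal <- function(spec) {
  shape <- spec$shape
  coords <- arrayInd(seq_len(prod(shape)), .dim = shape)
  f <- switch(spec$kind,
    ramp2d = {
      spec$magnitude * (coords[, 1L] - 1) / (shape[1L] - 1)
    },
    circle2d = ,
    sphere3d_small = ,
    sphere3d_large = {
      ctr <- (shape + 1) / 2
      dist2 <- rowSums(sweep(coords, 2L, ctr)^2)
      ind <- as.numeric(dist2 <= spec$radius^2)
      sm <- smooth_fields(matrix(ind), shape, spec$smoothing_fwhm)[, 1L]
      if (spec$kind == "circle2d") spec$magnitude * sm
      else spec$magnitude * sm / max(sm)     # imagewise rescale to max 1
    },
    multi_sphere3d = {
      total <- numeric(prod(shape))
      for (j in seq_along(spec$radii)) {
        dist2 <- rowSums(sweep(coords, 2L, spec$centers[j, ])^2)
        ind <- as.numeric(dist2 <= spec$radii[j]^2)
        sm <- smooth_fields(matrix(ind), shape, spec$smoothing_fwhm)[, 1L]
        total <- total + sm / max(sm)        # each phantom peaks at 1
      }
      pmin(total, 1) * spec$magnitude        # clip overlap regions to 1
    })
  f
}

#' Generate a stack of pure-noise subject fields
#'
#' White standard-normal noise per voxel, smoothed with the specified
#' Gaussian kernel, standardized pointwise to exact unit variance (using the
#' analytic sd of smoothed white noise under zero padding) and scaled by the
#' specification's standard-deviation field.
#'
#' @param grid a [domain_grid()].
#' @param noise a [noise_spec()].
#' @param n_subjects number of subject fields N >= 4.
#' @return A [subject_stack()] of noise fields.
#' @export
make_noise <- function(grid, noise, n_subjects) {
  shape <- grid$shape
  v <- prod(shape)
  w <- matrix(stats::rnorm(v * n_subjects), v, n_subjects)
  s <- smooth_fields(w, shape, noise$smoothing_fwhm)
  s <- s / smoothed_noise_sd(shape, noise$smoothing_fwhm)
  sdf <- noise_sd_field(grid, noise)
  if (noise$sd != "homogeneous") s <- s * sdf
  subject_stack(s, grid)
}

#' True excursion set and boundary of a simulation design
#'
#' @param signal full-grid mean field mu(s) (from [make_signal()]).
#' @param grid the [domain_grid()].
#' @param noise the [noise_spec()] (supplies the sd field sigma(s)).
#' @param c Cohen's d threshold.
#' @return An object of class `truth_set`: the true effect field
#'   `d = mu/sigma`, logical excursion set `a_c = {d >= c}`, and the
#'   interpolated true-boundary edges (`a`, `b`, `w`), located on the true d
#'   field at threshold `c`.
#' @export
truth_set <- function(signal, grid, noise, c) {
  d <- signal / noise_sd_field(grid, noise)
  a_c <- grid$mask & d >= c
  cross <- edge_crossings(d, mask_edges(grid), c)
  structure(list(d = d, a_c = a_c, c = c,
                 a = cross$a, b = cross$b, w = cross$w, grid = grid),
            class = "truth_set")
}

#' Did a confidence-set pair cover the truth?
#'
#' A trial covers when (a) the lattice nesting `upper` inside `A_c` inside
#' `lower` holds at every voxel, and (b) at every sub-voxel point of the TRUE
#' boundary (edges where the true d field crosses c, weights from the true
#' field), the linearly interpolated upper-CS decision field is not positive
#' and the lower-CS decision field is not negative — the interpolated
#' assessment that catches violations between lattice points.
#'
#' @param cs a [compute_confidence_sets()] result.
#' @param truth a [truth_set()] on the same grid.
#' @return TRUE/FALSE.
#' @export
assess_coverage_trial <- function(cs, truth) {
  if (!identical(cs$summary$grid$shape, truth$grid$shape))
    stop("confidence sets and truth live on different grids")
  if (any(cs$upper & !truth$a_c)) return(FALSE)
  if (any(truth$a_c & !cs$lower)) return(FALSE)
  if (length(truth$a) > 0L) {
    wu <- (1 - truth$w) * cs$decision_upper[truth$a] +
      truth$w * cs$decision_upper[truth$b]
    wl <- (1 - truth$w) * cs$decision_lower[truth$a] +
      truth$w * cs$decision_lower[truth$b]
    ok <- !is.na(wu) & !is.na(wl)
    if (any(wu[ok] > 0) || any(wl[ok] < 0)) return(FALSE)
  }
  TRUE
}

#' Sensitivity of the upper confidence set
#'
#' Fraction of truly suprathreshold voxels captured by the upper CS,
#' `|upper n A_c| / |A_c|` — the power-like operating characteristic of the
#' method.
#'
#' @inheritParams assess_coverage_trial
#' @return Fraction in `[0, 1]`.
#' @export
upper_cs_sensitivity <- function(cs, truth) {
  n_true <- sum(truth$a_c)
  if (n_true == 0L)
    stop("sensitivity undefined: true excursion set is empty")
  sum(cs$upper & truth$a_c) / n_true
}

# --- Monte-Carlo experiment harness -----------------------------------------

#' Simulation configuration
#'
#' @param n_trials Monte-Carlo repetitions per condition (the full study
#'   design uses 3000; scaled-down counts are supported).
#' @param n_boot bootstrap replicates B per trial (study design 5000).
#' @param sample_sizes vector of N values (study design 30, 60, 120, 240, 480).
#' @param levels confidence levels 1 - alpha (study design 0.80, 0.90, 0.95).
#' @param c Cohen's d threshold.
#' @param algorithms subset of 1:3.
#' @param seed integer RNG seed; the whole experiment is a deterministic
#'   function of it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_trials = 3000, n_boot = 5000,
                       sample_sizes = c(30, 60, 120, 240, 480),
                       levels = c(0.80, 0.90, 0.95), c = 0.8,
                       algorithms = 3, seed = 1) {
  stopifnot(n_trials >= 1, n_boot >= 1, all(sample_sizes >= 4),
            all(levels > 0 & levels < 1), all(algorithms %in% 1:3))
  structure(list(n_trials = n_trials, n_boot = n_boot,
                 sample_sizes = sample_sizes, levels = levels, c = c,
                 algorithms = as.integer(algorithms), seed = seed),
            class = "sim_config")
}

#' Run a Monte-Carlo coverage and sensitivity experiment
#'
#' For every sample size, draws `n_trials` independent samples of
#' signal-plus-noise data, computes confidence sets with each requested
#' algorithm, and assesses coverage (interpolated boundary assessment) and
#' upper-CS sensitivity against the analytic truth. All algorithms and
#' levels are evaluated on the same simulated samples; within a trial and
#' algorithm, the bootstrap supremum distribution is shared across levels
#' (only the percentile changes). Fully deterministic given `config$seed`.
#'
#' @param config a [sim_config()].
#' @param signal a [signal_spec()].
#' @param noise a [noise_spec()].
#' @param mask optional logical mask; defaults to the full grid.
#' @param verbose print a progress line per sample size.
#' @return A data.frame with one row per (algorithm, N, level): columns
#'   `signal`, `noise`, `algorithm`, `n`, `level`, `trials`, `n_boot`,
#'   `coverage`, `coverage_se`, `sensitivity`, `seed`. `coverage_se` is the
#'   binomial Monte-Carlo standard error.
#' @export
run_experiment <- function(config, signal, noise, mask = NULL,
                           verbose = FALSE) {
  grid <- domain_grid(signal$shape, mask)
  mu <- make_signal(signal)
  truth <- truth_set(mu, grid, noise, config$c)
  set.seed(config$seed)

  combos <- expand.grid(level = config$levels, algorithm = config$algorithms,
                        n = config$sample_sizes)
  cover <- matrix(0, nrow(combos), config$n_trials)
  sens <- matrix(NA_real_, nrow(combos), config$n_trials)
  have_truth <- sum(truth$a_c) > 0L

  for (n in config$sample_sizes) {
    if (verbose)
      message("N = ", n, ": ", config$n_trials, " trials, B = ",
              config$n_boot)
    rows_n <- which(combos$n == n)
    for (trial in seq_len(config$n_trials)) {
      stack <- make_noise(grid, noise, n)
      stack$data <- stack$data + mu
      summ <- field_summary(stack)
      for (alg in config$algorithms) {
        rows <- rows_n[combos$algorithm[rows_n] == alg]
        css <- cs_all_levels(stack, summ, config$c, alg,
                             config$levels, config$n_boot)
        for (j in seq_along(config$levels)) {
          row <- rows[combos$level[rows] == config$levels[j]]
          cover[row, trial] <- assess_coverage_trial(css[[j]], truth)
          if (have_truth)
            sens[row, trial] <- upper_cs_sensitivity(css[[j]], truth)
        }
      }
    }
  }

  res <- data.frame(
    signal = signal$kind,
    noise = noise$sd,
    algorithm = combos$algorithm,
    n = combos$n,
    level = combos$level,
    trials = config$n_trials,
    n_boot = config$n_boot,
    coverage = rowMeans(cover),
    sensitivity = if (have_truth) rowMeans(sens) else NA_real_,
    seed = config$seed)
  res$coverage_se <- sqrt(res$coverage * (1 - res$coverage) / res$trials)
  res[, c("signal", "noise", "algorithm", "n", "level", "trials", "n_boot",
          "coverage", "coverage_se", "sensitivity", "seed")]
}

# One trial's confidence sets for a single algorithm at several levels,
# sharing the residuals, boundary and bootstrap supremum distribution.
cs_all_levels <- function(stack, summ, c, algorithm, levels, n_boot) {
  n <- summ$n_subjects
  constants <- vst_constants(n)
  res <- switch(algorithm,
    standardize_limiting(cohens_d_residuals(stack, summ), summ),
    standardize_sample_sd(cohens_d_residuals(stack, summ), summ),
    vst_residuals(stack, summ, constants))
  boundary <- estimate_boundary(summ, c, algorithm)
  degenerate <- length(boundary$a) == 0L
  sup <- NULL
  if (!degenerate) {
    rb <- residuals_on_boundary(res, boundary)
    sup <- wild_t_bootstrap(rb, n_boot = n_boot,
                            alpha = 1 - max(levels))$sup_distribution
  }
  tau <- corrected_threshold(c, n)
  pe <- !is.na(summ$cohens_d) & summ$cohens_d >= tau & summ$grid$mask
  lapply(levels, function(lv) {
    k <- if (degenerate) 0 else boot_percentile(sup, lv)
    cons <- switch(algorithm,
      construct_algorithm1(summ, k, c),
      construct_algorithm2(summ, res$sd_r, k, c),
      construct_algorithm3(summ, constants, k, c))
    if (degenerate) { cons$upper <- pe; cons$lower <- pe }
    structure(list(upper = cons$upper, lower = cons$lower,
                   point_estimate = pe,
                   decision_upper = cons$decision_upper,
                   decision_lower = cons$decision_lower,
                   critical = if (degenerate) NULL else
                     structure(list(k = k, alpha = 1 - lv, n_boot = n_boot,
                                    sup_distribution = sup),
                               class = "critical_value"),
                   c = c, algorithm = algorithm, level = lv, summary = summ,
                   boundary = boundary, degenerate = degenerate, seed = NULL),
              class = "confidence_sets")
  })
}
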