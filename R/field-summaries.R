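#' Pointwise mean, standard deviation and Cohen's d fields
#'
#' Computes the voxelwise sample mean, sample standard deviation and Cohen's d
#' estimate `dhat = mean / sd` of a subject stack. The standard deviation uses
#' divisor N - 1, so that `sqrt(N) * dhat` at a voxel with i.i.d. Gaussian
#' data follows a noncentral t distribution with N - 1 degrees of freedom and
#' noncentrality `sqrt(N) * mu / sigma` exactly, and `dhat = t / sqrt(N)` for
#' the one-sample t statistic.
#'
#' @param stack a [subject_stack()].
#' @param degenerate how to treat voxels where the sample sd is exactly zero
#'   (all subjects identical): `"exclude"` drops them from the mask with a
#'   warning, `"error"` aborts.
#' @return An object of class `field_summary`: full-grid numeric vectors
#'   `mean`, `sd`, `cohens_d` (NA outside the mask), the (possibly reduced)
#'   `grid`, and `n_subjects`.
#' @seealso [bias_factor()], [cohens_d_residuals()]
#' @examples
#' g <- domain_grid(c(5, 5))
#' y <- matrix(rnorm(25 * 20), 25, 20)
#' s <- field_summary(subject_stack(y, g))
#' range(s$cohens_d)
#' @export
field_summary <- function(stack, degenerate = c("exclude", "error")) {
  degenerate <- match.arg(degenerate)
  if (!inherits(stack, "subject_stack")) stop("stack must be a subject_stack")
  grid <- stack$grid
  n <- stack$n_subjects
  full <- all(grid$mask)
  m <- if (full) seq_len(prod(grid$shape)) else mask_which(grid)
  y <- if (full) stack$data else stack$data[m, , drop = FALSE]
  mu <- rowMeans(y)
  ss <- rowSums((y - mu)^2)
  sd <- sqrt(ss / (n - 1))

  bad <- sd == 0
  if (any(bad)) {
    if (degenerate == "error")
      stop("degenerate voxel(s) with zero variance at mask position(s) ",
           paste(utils::head(which(bad), 5L), collapse = ", "))
    warning(sum(bad), " zero-variance voxel(s) excluded from the mask")
    newmask <- grid$mask
    newmask[m[bad]] <- FALSE
    grid <- domain_grid(grid$shape, newmask)
    keep <- !bad
    m <- m[keep]; mu <- mu[keep]; sd <- sd[keep]
  }

  nvox <- prod(grid$shape)
  mean_f <- sd_f <- d_f <- rep(NA_real_, nvox)
  mean_f[m] <- mu
  sd_f[m] <- sd
  d_f[m] <- mu / sd
  structure(list(mean = mean_f, sd = sd_f, cohens_d = d_f,
                 grid = grid, n_subjects = n),
            class = "field_summary")
}

#' @export
print.field_summary <- function(x, ...) {
  m <- x$grid$mask
  cat("<field_summary> N =", x$n_subjects, "; Cohen's d range on mask [",
      sprintf("%.3f", min(x$cohens_d[m])), ",",
      sprintf("%.3f", max(x$cohens_d[m])), "]\n")
  invisible(x)
}

mask_which <- function(grid) which(grid$mask)

check_n <- function(n_subjects) {
  if (length(n_subjects) != 1L || !is.finite(n_subjects) || n_subjects < 4)
    stop("invalid sample size: N must be an integer >= 4, got ", n_subjects)
  as.numeric(n_subjects)
}

#' Small-sample bias factor of the Cohen's d estimator
#'
#' Under Gaussian data, `E[dhat] = C_N * d` where
#' `C_N = sqrt((N-1)/2) * Gamma((N-2)/2) / Gamma((N-1)/2)` — the mean of a
#' chi distribution artefact familiar from Hedges' g. The widely used
#' approximation is `C_N ~ (1 - 3/(4N - 5))^{-1}`. Both exceed 1 for finite N
#' and tend to 1 as N grows; the exact form is evaluated through log-gamma
#' differences so it does not overflow for large N.
#'
#' @param n_subjects sample size N >= 4.
#' @param exact logical; exact gamma-function value (default) or the
#'   `(1 - 3/(4N-5))^{-1}` approximation.
#' @return A positive scalar.
#' @examples
#' bias_factor(30)                  # exact
#' bias_factor(30, exact = FALSE)   # (1 - 3/115)^{-1}
#' @export
bias_factor <- function(n_subjects, exact = TRUE) {
  if (length(n_subjects) == 0L || any(!is.finite(n_subjects) | n_subjects < 4))
    stop("invalid sample size: N must be an integer >= 4")
  n <- as.numeric(n_subjects)
  if (exact) {
    exp(0.5 * log((n - 1) / 2) + lgamma((n - 2) / 2) - lgamma((n - 1) / 2))
  } else {
    1 / (1 - 3 / (4 * n - 5))
  }
}

#' Constants of the arcsinh variance-stabilizing transformation
#'
#' The map `x -> alpha_star * asinh(beta_star * x)` stabilizes the
#' finite-sample variance of the Cohen's d estimator,
#' `N * Var(dhat) = a + b_star^2 * d^2` with `a = (N-1)/(N-3)`, where
#' `b_star = sqrt(N * (8N^2 - 17N + 11) / ((N-3) * (4N-5)^2))`,
#' `alpha_star = 1 / b_star`, and `beta_star = b_star * sqrt((N-3)/(N-1))`.
#' `alpha_star * b_star = 1` holds by construction (they are reciprocal powers
#' of the same expression).
#'
#' @param n_subjects sample size N >= 4.
#' @return An object of class `small_sample_constants` with elements
#'   `n_subjects`, `c_n_exact`, `c_n_approx`, `alpha_star`, `beta_star`,
#'   `b_star`.
#' @seealso [vst_residuals()], [vst_zeta()]
#' @export
vst_constants <- function(n_subjects) {
  n <- check_n(n_subjects)
  bsq <- n * (8 * n^2 - 17 * n + 11) / ((n - 3) * (4 * n - 5)^2)
  b_star <- sqrt(bsq)
  structure(list(n_subjects = n,
                 c_n_exact = bias_factor(n, exact = TRUE),
                 c_n_approx = bias_factor(n, exact = FALSE),
                 alpha_star = 1 / b_star,
                 beta_star = b_star * sqrt((n - 3) / (n - 1)),
                 b_star = b_star),
            class = "small_sample_constants")
}

#' @export
print.small_sample_constants <- function(x, ...) {
  cat(sprintf("<small_sample_constants> N = %d: C_N = %.5f (approx %.5f), alpha* = %.5f, beta* = %.5f, b* = %.5f\n",
              as.integer(x$n_subjects), x$c_n_exact, x$c_n_approx,
              x$alpha_star, x$beta_star, x$b_star))
  invisible(x)
}

#' Convert a one-sample t map to a Cohen's d map
#'
#' For the one-sample t statistic `t = mean / (sd / sqrt(N))`, the Cohen's d
#' estimate is simply `dhat = t / sqrt(N)`; this helper builds d maps from
#' published t maps.
#'
#' @param t_field numeric vector/array of t values (NA allowed outside a mask).
#' @param n_subjects sample size used to compute the t map.
#' @return `t_field / sqrt(n_subjects)`, same shape as the input.
#' @export
t_to_cohens_d <- function(t_field, n_subjects) {
  n <- check_n(n_subjects)
  if (any(is.infinite(t_field)))
    stop("t field contains non-finite values")
  t_field / sqrt(n)
}

#' Variance-stabilizing transformation of the Cohen's d estimator
#'
#' Maps `dhat` to an approximately standard normal deviate given the true
#' effect `d`:
#' `zeta = sqrt(N) * (alpha* asinh(beta* dhat) - alpha* asinh(beta* d Ctilde)
#'  + skew_offset(d, N))`, where `Ctilde = (1 - 3/(4N-5))^{-1}` is the
#' approximate bias factor and the offset is the second-order (skewness)
#' correction
#' `b*^2 d Ctilde / (2N) * ((N-1)/(N-3) + N d^2 (8N^2-17N+11) /
#'  (16 (N-3) (N-2)^2))^{-1/2}`.
#' Used to validate the transform (its 0.9 quantile should sit at
#' `qnorm(0.9)`) and to build the transformed-scale confidence sets.
#'
#' @param dhat observed Cohen's d value(s).
#' @param d true Cohen's d.
#' @param n_subjects sample size N >= 4.
#' @return Numeric vector of stabilized deviates.
#' @export
vst_zeta <- function(dhat, d, n_subjects) {
  n <- check_n(n_subjects)
  k <- vst_constants(n)
  ct <- k$c_n_approx
  sqrt(n) * (k$alpha_star * asinh(k$beta_star * dhat) -
             k$alpha_star * asinh(k$beta_star * ct * d) +
             vst_skew_offset(d, n))
}

# Second-order mean correction of the stabilized transform; also the offset
# entering the transformed-scale CS threshold.
vst_skew_offset <- function(d, n_subjects) {
  n <- n_subjects
  k <- vst_constants(n)
  ct <- k$c_n_approx
  (k$b_star^2 * ct * d / (2 * n)) /
    sqrt((n - 1) / (n - 3) +
         n * d^2 * (8 * n^2 - 17 * n + 11) / (16 * (n - 3) * (n - 2)^2))
}
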