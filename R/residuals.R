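#' Delta-method Cohen's d residuals
#'
#' Builds the first-order (delta-method) residual fields of the Cohen's d
#' estimator,
#' `R_i = (Y_i - Ybar)/sd - (Ybar / (2 sd)) * ((Y_i - Ybar)^2 / sd^2 - kappa)`,
#' the bootstrap fuel for all three confidence-set algorithms. The centering
#' constant `kappa` is the empirical mean of `(Y_i - Ybar)^2 / sd^2` — equal
#' to `(N-1)/N` under the package's N - 1 variance divisor — which makes the
#' pointwise sum of the residuals exactly zero at every voxel for all N.
#'
#' @param stack a [subject_stack()].
#' @param summary the [field_summary()] computed from `stack`.
#' @return Numeric matrix, voxels (full grid, NA off-mask) by subjects, of raw
#'   residual fields.
#' @export
cohens_d_residuals <- function(stack, summary) {
  if (!same_grid(stack$grid, summary$grid)) {
    # summary may have dropped degenerate voxels; require same shape at least
    if (!identical(stack$grid$shape, summary$grid$shape))
      stop("stack and summary grids have different shapes")
  }
  n <- stack$n_subjects
  if (n != summary$n_subjects) stop("stack and summary disagree on N")
  full <- all(summary$grid$mask)
  m <- if (full) seq_len(prod(summary$grid$shape)) else mask_which(summary$grid)
  y <- if (full) stack$data else stack$data[m, , drop = FALSE]
  mu <- summary$mean[m]
  sd <- summary$sd[m]
  e <- (y - mu) / sd                      # standardized subject deviations
  kappa <- (n - 1) / n                    # empirical mean of e^2, exact
  r <- e - (mu / (2 * sd)) * (e^2 - kappa)
  if (!all(is.finite(r)))
    stop("non-finite residual values at mask voxel(s) ",
         paste(utils::head(m[!stats::complete.cases(r)], 5L), collapse = ", "))
  if (full) return(r)
  out <- matrix(NA_real_, prod(summary$grid$shape), n)
  out[m, ] <- r
  out
}

new_residual_set <- function(residuals, flavor, grid, n, sd_r = NULL) {
  structure(list(residuals = residuals, flavor = flavor, grid = grid,
                 n_subjects = n, sd_r = sd_r),
            class = "residual_set")
}

#' @export
print.residual_set <- function(x, ...) {
  cat("<residual_set> flavor =", x$flavor, "; N =", x$n_subjects, "on a",
      paste(x$grid$shape, collapse = " x "), "grid\n")
  invisible(x)
}

#' Standardize residuals by the limiting standard deviation
#'
#' Divides the raw Cohen's d residuals pointwise by `sqrt(1 + dhat^2 / 2)`,
#' the estimated standard deviation of the limiting Gaussian field of the
#' Cohen's d estimator (its asymptotic variance is `1 + d^2/2`). This is the
#' standardization used by the first algorithm.
#'
#' @param raw residual matrix from [cohens_d_residuals()].
#' @param summary the matching [field_summary()].
#' @return A `residual_set` with `flavor = "limiting"`.
#' @export
standardize_limiting <- function(raw, summary) {
  if (all(summary$grid$mask)) {
    out <- raw / sqrt(1 + summary$cohens_d^2 / 2)
  } else {
    m <- mask_which(summary$grid)
    d <- summary$cohens_d[m]
    out <- raw
    out[m, ] <- raw[m, , drop = FALSE] / sqrt(1 + d^2 / 2)
  }
  new_residual_set(out, "limiting", summary$grid, summary$n_subjects)
}

#' Standardize residuals by their sample standard deviation
#'
#' Divides the raw residuals pointwise by
#' `sd_R(s) = sqrt(mean_i R_i(s)^2)` (divisor N, as the residuals are exactly
#' mean-zero), so the pointwise second moment of the standardized residuals is
#' 1 by construction. `sd_R` is retained: it also sets the band width of the
#' second algorithm's confidence sets.
#'
#' @param raw residual matrix from [cohens_d_residuals()].
#' @param summary the matching [field_summary()].
#' @return A `residual_set` with `flavor = "sample_sd"` and field `sd_r`.
#' @export
standardize_sample_sd <- function(raw, summary) {
  full <- all(summary$grid$mask)
  m <- if (full) seq_len(nrow(raw)) else mask_which(summary$grid)
  r <- if (full) raw else raw[m, , drop = FALSE]
  sd_r <- sqrt(rowMeans(r^2))
  if (any(sd_r == 0))
    stop("degenerate voxel(s): residual sample sd is zero at mask position(s) ",
         paste(utils::head(m[sd_r == 0], 5L), collapse = ", "))
  if (full) {
    out <- r / sd_r
  } else {
    out <- raw
    out[m, ] <- r / sd_r
  }
  sd_full <- rep(NA_real_, nrow(raw))
  sd_full[m] <- sd_r
  new_residual_set(out, "sample_sd", summary$grid, summary$n_subjects,
                   sd_r = sd_full)
}

#' Variance-stabilized Cohen's d residuals
#'
#' Residuals for the transformed-scale (third) algorithm: the raw delta-method
#' residuals multiplied by the derivative factor of the arcsinh
#' variance-stabilizing map,
#' `R~_i = alpha* beta* / sqrt(1 + beta*^2 dhat^2) * R_i`.
#'
#' @param stack a [subject_stack()].
#' @param summary the matching [field_summary()].
#' @param constants [vst_constants()] for the stack's N (computed if omitted).
#' @return A `residual_set` with `flavor = "vst"`.
#' @export
vst_residuals <- function(stack, summary, constants = NULL) {
  if (is.null(constants)) constants <- vst_constants(summary$n_subjects)
  raw <- cohens_d_residuals(stack, summary)
  if (all(summary$grid$mask)) {
    fac <- constants$alpha_star * constants$beta_star /
      sqrt(1 + constants$beta_star^2 * summary$cohens_d^2)
    out <- raw * fac
  } else {
    m <- mask_which(summary$grid)
    d <- summary$cohens_d[m]
    fac <- constants$alpha_star * constants$beta_star /
      sqrt(1 + constants$beta_star^2 * d^2)
    out <- raw
    out[m, ] <- raw[m, , drop = FALSE] * fac
  }
  new_residual_set(out, "vst", summary$grid, summary$n_subjects)
}
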