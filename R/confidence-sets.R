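#' @rdname compute_confidence_sets
#' @export
construct_algorithm1 <- function(summary, k, c) {
  n <- summary$n_subjects
  tau <- corrected_threshold(c, n)
  m <- summary$grid$mask
  d <- summary$cohens_d
  band <- (k / sqrt(n)) * sqrt(1 + d^2 / 2)
  finish_construction(d - tau - band, d - tau + band, m)
}

#' @rdname compute_confidence_sets
#' @param sd_r full-grid field of residual sample standard deviations, from
#'   the `sample_sd` residual flavor.
#' @export
construct_algorithm2 <- function(summary, sd_r, k, c) {
  if (is.null(sd_r))
    stop("flavor mismatch: algorithm 2 needs the sd_r field of the ",
         "'sample_sd' residual flavor")
  n <- summary$n_subjects
  tau <- corrected_threshold(c, n)
  m <- summary$grid$mask
  d <- summary$cohens_d
  band <- (k / sqrt(n)) * sd_r
  finish_construction(d - tau - band, d - tau + band, m)
}

#' @rdname compute_confidence_sets
#' @param constants [vst_constants()] for the sample size.
#' @export
construct_algorithm3 <- function(summary, constants, k, c) {
  n <- summary$n_subjects
  tau <- corrected_threshold(c, n)
  m <- summary$grid$mask
  z <- constants$alpha_star * asinh(constants$beta_star * summary$cohens_d)
  thr <- constants$alpha_star * asinh(constants$beta_star * tau) -
    vst_skew_offset(c, n)
  band <- k / sqrt(n)
  finish_construction(z - thr - band, z - thr + band, m)
}

# Assemble masks and retain the signed decision fields (needed for the
# interpolated coverage assessment).
finish_construction <- function(dec_upper, dec_lower, mask) {
  upper <- !is.na(dec_upper) & dec_upper >= 0 & mask
  lower <- !is.na(dec_lower) & dec_lower >= 0 & mask
  list(upper = upper, lower = lower,
       decision_upper = dec_upper, decision_lower = dec_lower)
}

#' Confidence sets for the excursion set of a Cohen's d image
#'
#' The package's main entry point. Given N subject maps, an effect-size
#' threshold `c` and a level `1 - alpha`, produces nested boolean maps
#' `upper` (voxels confidently above `c`), `lower` (voxels not confidently
#' below `c`; its complement is confidently below) and the bias-corrected
#' point-estimate set, such that with probability `1 - alpha` over repeated
#' experiments `upper` is inside the true set `{d >= c}` and the true set is
#' inside `lower`, simultaneously.
#'
#' Three constructions are available. Algorithm 1 standardizes by the
#' limiting standard deviation `sqrt(1 + dhat^2/2)` of the Cohen's d
#' estimator; algorithm 2 by the sample standard deviation of the
#' delta-method residuals (more accurate in small samples); algorithm 3 works
#' on the arcsinh variance-stabilized scale, which also removes the skew of
#' the noncentral-t sampling distribution. In every case the critical value
#' `k` comes from a wild t-bootstrap of the supremum of the studentized
#' residual field over the sub-voxel interpolated, bias-corrected plug-in
#' boundary.
#'
#' @param stack a [subject_stack()] of N >= 4 aligned subject maps.
#' @param c Cohen's d threshold (conventionally 0.5 / 0.8 / 1.2 for medium /
#'   large / very large effects).
#' @param alpha simultaneous error level; the sets have level `1 - alpha`.
#' @param algorithm 1, 2 or 3 (see Details).
#' @param n_boot bootstrap replicates B.
#' @param seed optional integer seed; fixing it makes the output reproducible
#'   bit for bit.
#' @param summary optionally, a precomputed [field_summary()] of `stack`.
#' @return An object of class `confidence_sets`: logical full-grid vectors
#'   `upper`, `lower`, `point_estimate`; the `critical` value object (NULL
#'   when degenerate); signed decision fields `decision_upper`,
#'   `decision_lower`; the `summary`, `boundary`, threshold `c`, `algorithm`,
#'   `level`, and a `degenerate` flag (TRUE when the estimated boundary does
#'   not intersect the mask, in which case both sets equal the point-estimate
#'   set and no `k` can be bootstrapped).
#' @examples
#' g <- domain_grid(c(20, 20))
#' y <- matrix(rnorm(400 * 40, mean = 0.5), 400, 40)
#' cs <- compute_confidence_sets(subject_stack(y, g), c = 0.5, alpha = 0.1,
#'                               algorithm = 3, n_boot = 200, seed = 1)
#' sum(cs$upper); sum(cs$lower)
#' @export
compute_confidence_sets <- function(stack, c, alpha = 0.05, algorithm = 3,
                                    n_boot = 5000, seed = NULL,
                                    summary = NULL) {
  algorithm <- check_algorithm(algorithm)
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(summary)) summary <- field_summary(stack)
  n <- summary$n_subjects
  constants <- vst_constants(n)

  res <- switch(algorithm,
    standardize_limiting(cohens_d_residuals(stack, summary), summary),
    standardize_sample_sd(cohens_d_residuals(stack, summary), summary),
    vst_residuals(stack, summary, constants))

  boundary <- estimate_boundary(summary, c, algorithm)
  degenerate <- length(boundary$a) == 0L
  if (degenerate) {
    warning("degenerate confidence sets: estimated boundary lies outside ",
            "the mask; returning the point-estimate set for both CSs")
    critical <- NULL
    k <- 0
  } else {
    rb <- residuals_on_boundary(res, boundary)
    critical <- wild_t_bootstrap(rb, n_boot = n_boot, alpha = alpha)
    k <- critical$k
  }

  cons <- switch(algorithm,
    construct_algorithm1(summary, k, c),
    construct_algorithm2(summary, res$sd_r, k, c),
    construct_algorithm3(summary, constants, k, c))

  tau <- corrected_threshold(c, n)
  pe <- !is.na(summary$cohens_d) & summary$cohens_d >= tau & summary$grid$mask
  if (degenerate) {
    cons$upper <- pe
    cons$lower <- pe
  }

  structure(list(upper = cons$upper, lower = cons$lower, point_estimate = pe,
                 decision_upper = cons$decision_upper,
                 decision_lower = cons$decision_lower,
                 critical = critical, c = c, algorithm = algorithm,
                 level = 1 - alpha, summary = summary, boundary = boundary,
                 degenerate = degenerate, seed = seed),
            class = "confidence_sets")
}

#' @export
print.confidence_sets <- function(x, ...) {
  cat("<confidence_sets> algorithm", x$algorithm,
      sprintf("; c = %.3g at %.0f%% confidence\n", x$c, 100 * x$level))
  cat(sprintf("  upper %d | point estimate %d | lower %d voxels (mask %d)\n",
              sum(x$upper), sum(x$point_estimate), sum(x$lower),
              sum(x$summary$grid$mask)))
  if (x$degenerate) cat("  DEGENERATE: boundary outside mask, k undefined\n")
  else cat(sprintf("  k = %.4f (B = %d)\n", x$critical$k,
                   as.integer(x$critical$n_boot)))
  invisible(x)
}
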