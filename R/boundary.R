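#' Bias-corrected threshold on the Cohen's d scale
#'
#' The plug-in boundary and point-estimate set are computed at
#' `c * (1 - 3/(4N - 5))^{-1}` rather than at `c`: the Cohen's d estimator is
#' biased upward by approximately this factor, so thresholding the estimate at
#' the inflated level targets the set where the true effect exceeds `c`.
#'
#' @param c effect-size threshold (scalar, >= 0 in typical use).
#' @param n_subjects sample size N >= 4.
#' @return The corrected scalar threshold.
#' @export
corrected_threshold <- function(c, n_subjects) {
  n <- check_n(n_subjects)
  c / (1 - 3 / (4 * n - 5))
}

#' Sub-voxel estimate of the plug-in excursion-set boundary
#'
#' Scans every axis-aligned lattice edge between in-mask voxel neighbours and
#' records those straddling the (bias-corrected) threshold, with a linear
#' interpolation weight locating the crossing. For algorithms 1 and 2 the
#' decision field is `dhat` itself; for algorithm 3, crossings and weights are
#' computed on the arcsinh-transformed field `alpha* asinh(beta* dhat)` with
#' the correspondingly transformed threshold, the scale on which that
#' algorithm's supremum lives (the monotone map preserves which edges cross
#' but changes the weights).
#'
#' @param summary a [field_summary()].
#' @param c effect-size threshold.
#' @param algorithm 1, 2 or 3.
#' @return An object of class `boundary_set`: integer vectors `a`, `b` (linear
#'   voxel indices of edge endpoints), numeric `w` in `[0, 1]` (crossing at
#'   `(1-w) a + w b`), `threshold_corrected` (on the d scale), `scale`
#'   (`"cohens_d"` or `"arcsinh"`), `tau` (threshold on the crossing scale)
#'   and the `grid`. Zero edges is a legitimate result (boundary outside the
#'   mask).
#' @export
estimate_boundary <- function(summary, c, algorithm = 2) {
  algorithm <- check_algorithm(algorithm)
  n <- summary$n_subjects
  tau_d <- corrected_threshold(c, n)
  f <- summary$cohens_d
  if (algorithm == 3L) {
    k <- vst_constants(n)
    f <- k$alpha_star * asinh(k$beta_star * f)
    tau <- k$alpha_star * asinh(k$beta_star * tau_d)
    scale <- "arcsinh"
  } else {
    tau <- tau_d
    scale <- "cohens_d"
  }
  edges <- mask_edges(summary$grid)
  cross <- edge_crossings(f, edges, tau)
  structure(list(a = cross$a, b = cross$b, w = cross$w,
                 threshold_corrected = tau_d, tau = tau, scale = scale,
                 grid = summary$grid),
            class = "boundary_set")
}

#' @export
print.boundary_set <- function(x, ...) {
  cat("<boundary_set>", length(x$a), "edge crossings at corrected threshold",
      sprintf("%.4f", x$threshold_corrected), "on the", x$scale, "scale\n")
  invisible(x)
}

# Locate threshold crossings of field f (full-grid vector) along the supplied
# edges. A crossing exists where f - tau changes sign; a voxel sitting exactly
# at tau emits a crossing with weight at that endpoint.
edge_crossings <- function(f, edges, tau) {
  if (is.null(edges) || nrow(edges) == 0L)
    return(list(a = integer(0), b = integer(0), w = numeric(0)))
  fu <- f[edges[, 1L]] - tau
  fv <- f[edges[, 2L]] - tau
  opp <- fu * fv < 0
  tie_u <- fu == 0
  tie_v <- fv == 0 & !tie_u
  keep <- opp | tie_u | tie_v
  a <- edges[keep, 1L]
  b <- edges[keep, 2L]
  w <- numeric(sum(keep))
  w[opp[keep]] <- fu[keep & opp] / (fu[keep & opp] - fv[keep & opp])
  w[tie_u[keep]] <- 0
  w[tie_v[keep]] <- 1
  list(a = a, b = b, w = w)
}

#' Interpolate residual fields onto boundary points
#'
#' Evaluates each subject's standardized residual field at every sub-voxel
#' boundary point by linear interpolation along the edge:
#' value at a point on edge `(a, b, w)` is `(1-w) R_i(a) + w R_i(b)`.
#'
#' @param residuals a `residual_set`.
#' @param boundary a `boundary_set` on the same grid.
#' @return Numeric matrix, subjects (N) by boundary points (P); P may be 0.
#' @export
residuals_on_boundary <- function(residuals, boundary) {
  if (!identical(residuals$grid$shape, boundary$grid$shape))
    stop("residuals and boundary live on different grids")
  r <- residuals$residuals
  p <- length(boundary$a)
  if (p == 0L)
    return(matrix(numeric(0), nrow = residuals$n_subjects, ncol = 0L))
  vals <- (1 - boundary$w) * r[boundary$a, , drop = FALSE] +
    boundary$w * r[boundary$b, , drop = FALSE]   # P x N
  t(vals)
}

check_algorithm <- function(algorithm) {
  if (!(length(algorithm) == 1L && algorithm %in% 1:3))
    stop("algorithm must be 1, 2 or 3, got ", deparse(algorithm))
  as.integer(algorithm)
}
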