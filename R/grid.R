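#' Domain grid for masked scalar fields
#'
#' A `domain_grid` describes the regular 2D or 3D voxel lattice on which all
#' fields in the package live, together with a boolean mask selecting the
#' in-domain voxels. Fields are stored as numeric vectors in column-major
#' (Fortran) voxel order, i.e. `as.vector()` of an array with `dim = shape`.
#'
#' @param shape integer vector of voxel counts per axis, length 2 or 3.
#' @param mask logical vector or array of length `prod(shape)` marking
#'   in-domain voxels. Defaults to the full grid.
#' @return An object of class `domain_grid` with elements `shape`, `mask`
#'   (logical vector), and `ordering` (`"column-major"`).
#' @examples
#' g <- domain_grid(c(10, 10))
#' sum(g$mask)
#' @export
domain_grid <- function(shape, mask = NULL) {
  shape <- as.integer(shape)
  if (length(shape) < 2L || length(shape) > 3L)
    stop("grid must be 2- or 3-dimensional, got length(shape) = ", length(shape))
  if (any(shape < 1L)) stop("all grid dimensions must be positive")
  nvox <- prod(shape)
  if (is.null(mask)) mask <- rep(TRUE, nvox)
  mask <- as.logical(mask)
  dim(mask) <- NULL
  if (length(mask) != nvox)
    stop("mask length (", length(mask), ") does not match prod(shape) (", nvox, ")")
  if (anyNA(mask)) stop("mask must not contain NA")
  if (!any(mask)) stop("mask is empty")
  structure(list(shape = shape, mask = mask, ordering = "column-major"),
            class = "domain_grid")
}

#' @export
print.domain_grid <- function(x, ...) {
  cat("<domain_grid> ", paste(x$shape, collapse = " x "),
      " (", sum(x$mask), "/", length(x$mask), " voxels in mask)\n", sep = "")
  invisible(x)
}

#' Stack of subject-level scalar fields
#'
#' Bundles N aligned subject maps on a common [domain_grid()] into the input
#' object of the one-sample analysis, where each column of `data` holds one
#' subject's field in column-major voxel order.
#'
#' @param data numeric matrix, `prod(grid$shape)` rows (voxels) by N columns
#'   (subjects), or a 3D/4D array whose last dimension indexes subjects.
#' @param grid a [domain_grid()]; defaults to a fully unmasked grid of the
#'   array's spatial dimensions when `data` is an array.
#' @return An object of class `subject_stack` with elements `data` (voxel x
#'   subject matrix), `grid`, and `n_subjects`.
#' @details At least N = 4 subjects are required: the small-sample constants
#'   of the noncentral-t theory involve the factors N - 3 and 4N - 5, and the
#'   residual variance estimate needs positive degrees of freedom. Subject
#'   fields must be finite on the mask.
#' @export
subject_stack <- function(data, grid = NULL) {
  if (is.array(data) && length(dim(data)) > 2L) {
    dims <- dim(data)
    spatial <- dims[-length(dims)]
    if (is.null(grid)) grid <- domain_grid(spatial)
    data <- matrix(data, nrow = prod(spatial), ncol = dims[length(dims)])
  }
  data <- as.matrix(data)
  if (is.null(grid)) stop("grid must be supplied when data is a matrix")
  if (!inherits(grid, "domain_grid")) stop("grid must be a domain_grid")
  if (nrow(data) != prod(grid$shape))
    stop("data has ", nrow(data), " rows but grid has ", prod(grid$shape), " voxels")
  n <- ncol(data)
  if (n < 4L)
    stop("at least 4 subjects are required (got N = ", n, ")")
  finite_ok <- if (all(grid$mask)) all(is.finite(data))
               else all(is.finite(data[grid$mask, ]))
  if (!finite_ok)
    stop("non-finite subject values inside the mask")
  structure(list(data = data, grid = grid, n_subjects = n),
            class = "subject_stack")
}

#' @export
print.subject_stack <- function(x, ...) {
  cat("<subject_stack> N =", x$n_subjects, "subjects on a",
      paste(x$grid$shape, collapse = " x "), "grid\n")
  invisible(x)
}

# Column-major strides for each axis of a grid.
grid_strides <- function(shape) {
  cumprod(c(1L, shape[-length(shape)]))
}

# All axis-aligned lattice edges (u, v = u + stride) with both endpoints in
# the mask. Returns a 2-column integer matrix of linear voxel indices;
# 4-connectivity in 2D, 6-connectivity in 3D.
mask_edges <- function(grid) {
  shape <- grid$shape
  mask <- grid$mask
  strides <- grid_strides(shape)
  idx <- seq_len(prod(shape))
  coords <- arrayInd(idx, .dim = shape)
  out <- vector("list", length(shape))
  for (ax in seq_along(shape)) {
    ok <- coords[, ax] < shape[ax]           # edge does not wrap the lattice
    u <- idx[ok]
    v <- u + strides[ax]
    keep <- mask[u] & mask[v]
    out[[ax]] <- cbind(u[keep], v[keep])
  }
  do.call(rbind, out)
}

# Check two objects share the same grid geometry.
same_grid <- function(a, b) {
  identical(a$shape, b$shape) && identical(a$mask, b$mask)
}
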