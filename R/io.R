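#' Read a subject stack from NIfTI files
#'
#' Accepts either a single 4D NIfTI volume (subject index on the 4th axis) or
#' a character vector of per-subject 3D volumes stacked in the given order,
#' plus a 3D mask on the same grid.
#'
#' @param path character: one 4D file, or N >= 4 3D files.
#' @param mask_path optional 3D mask file (nonzero = in-mask); defaults to
#'   the full grid.
#' @return A [subject_stack()]; the first input image's NIfTI header is
#'   attached as attribute `"reference"` for output writing.
#' @export
read_subject_stack <- function(path, mask_path = NULL) {
  for (p in c(path, mask_path))
    if (!file.exists(p)) stop("file not found: ", p)
  if (length(path) == 1L) {
    img <- RNifti::readNifti(path[1L])
    dims <- dim(img)
    if (length(dims) != 4L)
      stop("expected a 4D NIfTI volume, got ", length(dims), "D: ", path)
    spatial <- dims[1:3]
    data <- matrix(img, nrow = prod(spatial), ncol = dims[4L])
    ref <- img
  } else {
    imgs <- lapply(path, RNifti::readNifti)
    dims <- lapply(imgs, dim)
    if (any(vapply(dims, length, 1L) != 3L))
      stop("per-subject files must be 3D volumes")
    if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L)
      stop("subject volumes have mismatched dimensions")
    spatial <- dims[[1L]]
    data <- vapply(imgs, as.vector, numeric(prod(spatial)))
    ref <- imgs[[1L]]
  }
  mask <- NULL
  if (!is.null(mask_path)) {
    mimg <- RNifti::readNifti(mask_path)
    if (!identical(as.integer(dim(mimg)), as.integer(spatial)))
      stop("mask dimensions (", paste(dim(mimg), collapse = "x"),
           ") do not match image grid (", paste(spatial, collapse = "x"), ")")
    mask <- as.vector(mimg) != 0
  }
  stack <- subject_stack(data, domain_grid(spatial, mask))
  attr(stack, "reference") <- ref
  stack
}

#' Write confidence sets as NIfTI masks with a JSON sidecar
#'
#' Writes `upper.nii.gz`, `lower.nii.gz` and `point_estimate.nii.gz` as 0/1
#' uint8 masks, the Cohen's d map `cohens_d.nii.gz` as 32-bit float, and
#' `confidence_sets.json` recording the threshold, level, algorithm, critical
#' value, bootstrap size and seed. The reference image's grid and affine are
#' passed through unchanged.
#'
#' @param cs a [compute_confidence_sets()] result.
#' @param reference a NIfTI image (or the attribute attached by
#'   [read_subject_stack()]) supplying header/affine; NULL writes plain
#'   headers.
#' @param outdir output directory, created if missing.
#' @return Invisibly, the paths written.
#' @export
write_confidence_sets <- function(cs, reference = NULL, outdir = ".") {
  if (!inherits(cs, "confidence_sets")) stop("cs must be a confidence_sets")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  shape <- cs$summary$grid$shape
  as_img <- function(v) {
    a <- array(v, dim = shape)
    if (is.null(reference)) a else RNifti::updateNifti(a, reference)
  }
  paths <- file.path(outdir, c("upper.nii.gz", "lower.nii.gz",
                               "point_estimate.nii.gz", "cohens_d.nii.gz"))
  RNifti::writeNifti(as_img(as.integer(cs$upper)), paths[1L], datatype = "uint8")
  RNifti::writeNifti(as_img(as.integer(cs$lower)), paths[2L], datatype = "uint8")
  RNifti::writeNifti(as_img(as.integer(cs$point_estimate)), paths[3L],
                     datatype = "uint8")
  dmap <- cs$summary$cohens_d
  dmap[is.na(dmap)] <- 0
  RNifti::writeNifti(as_img(dmap), paths[4L], datatype = "float")
  sidecar <- file.path(outdir, "confidence_sets.json")
  jsonlite::write_json(
    list(c = cs$c, alpha = 1 - cs$level, level = cs$level,
         algorithm = cs$algorithm,
         k = if (cs$degenerate) NA else cs$critical$k,
         n_boot = if (cs$degenerate) NA else cs$critical$n_boot,
         n_subjects = cs$summary$n_subjects,
         degenerate = cs$degenerate,
         seed = if (is.null(cs$seed)) NA else cs$seed,
         voxels = list(upper = sum(cs$upper), lower = sum(cs$lower),
                       point_estimate = sum(cs$point_estimate),
                       mask = sum(cs$summary$grid$mask))),
    sidecar, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(c(paths, sidecar))
}
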