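# Deformation-based morphometry: voxelwise Jacobian determinants of a
# displacement field, and FWHM-parameterized Gaussian smoothing.
#
# Convention (documented once, used everywhere): the displacement field
# maps template coordinates to subject coordinates, so det(I + grad u) > 1
# means the subject is locally LARGER than the template. Higher DBM
# values therefore read as larger local volumes.

#' Displacement field on a regular 3-D grid
#'
#' @param u numeric 4-D array `c(grid_shape, 3)`: per-voxel displacement
#'   vector in mm. Component `u[,,,k]` displaces along axis `k`.
#' @param spacing_mm voxel spacing in mm, length 3 (recycled from 1).
#' @return an object of class `displacement_field`.
#' @export
displacement_field <- function(u, spacing_mm = c(1, 1, 1)) {
  if (!is.array(u) || length(dim(u)) != 4L || dim(u)[4] != 3L) {
    stop("`u` must be a 4-D array with last dimension 3", call. = FALSE)
  }
  if (any(!is.finite(u))) stop("displacement field contains non-finite values",
                               call. = FALSE)
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 3)
  .check_positive(spacing_mm, "spacing_mm", len = 3L)
  structure(
    list(u = u, grid_shape = dim(u)[1:3], spacing_mm = as.numeric(spacing_mm)),
    class = "displacement_field"
  )
}

#' DBM image: per-voxel scalar local-volume map
#'
#' @param values numeric 3-D array of DBM values (Jacobian determinants,
#'   or any voxelwise scalar map).
#' @param spacing_mm voxel spacing in mm, length 3.
#' @param smoothed_fwhm_mm FWHM of smoothing already applied, or `NULL`.
#' @return an object of class `dbm_image`.
#' @export
dbm_image <- function(values, spacing_mm = c(1, 1, 1), smoothed_fwhm_mm = NULL) {
  if (!is.array(values) || length(dim(values)) != 3L) {
    stop("`values` must be a 3-D array", call. = FALSE)
  }
  if (any(!is.finite(values))) stop("DBM values must be finite", call. = FALSE)
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 3)
  .check_positive(spacing_mm, "spacing_mm", len = 3L)
  if (!is.null(smoothed_fwhm_mm)) .check_positive(smoothed_fwhm_mm, "smoothed_fwhm_mm")
  structure(
    list(values = values, grid_shape = dim(values),
         spacing_mm = as.numeric(spacing_mm), smoothed_fwhm_mm = smoothed_fwhm_mm),
    class = "dbm_image"
  )
}

#' @export
print.dbm_image <- function(x, ...) {
  cat(sprintf("DBM image %s, spacing %s mm, range [%.4g, %.4g]%s\n",
              paste(x$grid_shape, collapse = "x"),
              paste(signif(x$spacing_mm, 3), collapse = "x"),
              min(x$values), max(x$values),
              if (is.null(x$smoothed_fwhm_mm)) ""
              else sprintf(", smoothed %g mm FWHM", x$smoothed_fwhm_mm)))
  invisible(x)
}

# Gradient of a 3-D array along one axis, in 1/mm: central differences
# on interior planes, one-sided at the two boundary planes.
.axis_gradient <- function(a, axis, h) {
  d <- dim(a)
  n <- d[axis]
  if (n < 3L) stop("grid must have at least 3 voxels along every axis",
                   call. = FALSE)
  g <- array(0, dim = d)
  idx <- function(i) {
    args <- list(a, TRUE, TRUE, TRUE)
    args[[axis + 1L]] <- i
    args$drop <- FALSE
    do.call(`[`, args)
  }
  put <- function(i, val) {
    args <- list(TRUE, TRUE, TRUE)
    args[[axis]] <- i
    do.call(`[<-`, c(list(g), args, list(value = val)))
  }
  g <- put(2:(n - 1L), (idx(3:n) - idx(1:(n - 2L))) / (2 * h))
  g <- put(1L, (idx(2L) - idx(1L)) / h)
  g <- put(n, (idx(n) - idx(n - 1L)) / h)
  g
}

#' Jacobian determinant map (DBM values) of a displacement field
#'
#' At each voxel forms `J = I + grad u` (spatial gradient of the
#' displacement in mm per mm, central differences on interior voxels and
#' one-sided differences at the boundary) and returns `det(J)` by
#' cofactor expansion. `det > 1` marks local expansion relative to the
#' template.
#'
#' @param field a [displacement_field].
#' @return a [dbm_image] of determinants.
#' @export
jacobian_determinant_map <- function(field) {
  if (!inherits(field, "displacement_field")) {
    stop("`field` must be a displacement_field", call. = FALSE)
  }
  if (any(field$grid_shape < 3L)) {
    stop("grid must be at least 3 voxels along every axis", call. = FALSE)
  }
  sp <- field$spacing_mm
  # J[a, b] = d u_a / d x_b (+1 on the diagonal)
  J <- vector("list", 9L)
  dim(J) <- c(3L, 3L)
  for (a in 1:3) {
    ua <- field$u[, , , a]
    for (b in 1:3) {
      g <- .axis_gradient(ua, b, sp[b])
      if (a == b) g <- g + 1
      J[[a, b]] <- g
    }
  }
  det <- J[[1, 1]] * (J[[2, 2]] * J[[3, 3]] - J[[2, 3]] * J[[3, 2]]) -
         J[[1, 2]] * (J[[2, 1]] * J[[3, 3]] - J[[2, 3]] * J[[3, 1]]) +
         J[[1, 3]] * (J[[2, 1]] * J[[3, 2]] - J[[2, 2]] * J[[3, 1]])
  dbm_image(det, spacing_mm = sp)
}

# One-axis Gaussian smoothing operator as an n x n row-stochastic
# matrix: kernel truncated at 4 sigma, each row renormalized so its
# weights sum to 1 (boundary rows renormalize over the surviving
# support, avoiding zero-inflation at the edges).
.gauss_operator <- function(n, sigma_vox) {
  radius <- max(0L, as.integer(ceiling(4 * sigma_vox)))
  offsets <- (-radius):radius
  w <- exp(-offsets^2 / (2 * sigma_vox^2))
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- i + offsets
    keep <- j >= 1L & j <= n
    W[i, j[keep]] <- w[keep] / sum(w[keep])
  }
  W
}

#' Gaussian smoothing at a given FWHM
#'
#' Separable Gaussian smoothing with `sigma = fwhm / (2 sqrt(2 log 2))`
#' per axis, converted to voxel units through the image spacing. The
#' kernel is truncated at 4 sigma and renormalized to unit sum; at the
#' boundary the truncated kernel is renormalized over its surviving
#' support, so a constant image is reproduced exactly.
#'
#' @param img a [dbm_image] (or bare 3-D array, taken at unit spacing).
#' @param fwhm_mm full width at half maximum in mm, > 0.
#' @return a smoothed [dbm_image] of the same shape.
#' @export
smooth_fwhm <- function(img, fwhm_mm) {
  if (is.array(img) && length(dim(img)) == 3L) img <- dbm_image(img)
  if (!inherits(img, "dbm_image")) stop("`img` must be a dbm_image",
                                        call. = FALSE)
  .check_positive(fwhm_mm, "fwhm_mm")
  sigma_mm <- fwhm_mm / (2 * sqrt(2 * log(2)))
  v <- img$values
  d <- dim(v)
  for (axis in 1:3) {
    sigma_vox <- sigma_mm / img$spacing_mm[axis]
    if (sigma_vox <= 0) next
    W <- .gauss_operator(d[axis], sigma_vox)
    perm <- c(axis, setdiff(1:3, axis))
    vp <- aperm(v, perm)
    m <- matrix(vp, nrow = d[axis])
    m <- W %*% m
    vp <- array(m, dim = d[perm])
    v <- aperm(vp, order(perm))
  }
  dbm_image(v, spacing_mm = img$spacing_mm, smoothed_fwhm_mm = fwhm_mm)
}

#' Read/write DBM volumes and displacement fields as NIfTI-1
#'
#' Scalar maps are stored as 3-D volumes, displacement fields as 4-D
#' volumes with the three displacement components along the fourth
#' dimension. Voxel spacing is carried in the NIfTI pixdim.
#'
#' @param img a [dbm_image] or [displacement_field].
#' @param path output/input `.nii` or `.nii.gz` path.
#' @return `write_*` returns `path` invisibly; `read_*` returns the object.
#' @name nifti_io
NULL

#' @rdname nifti_io
#' @export
write_dbm_nifti <- function(img, path) {
  stopifnot(inherits(img, "dbm_image"))
  nim <- RNifti::asNifti(img$values)
  RNifti::pixdim(nim) <- img$spacing_mm
  RNifti::writeNifti(nim, path)
  invisible(path)
}

#' @rdname nifti_io
#' @export
read_dbm_nifti <- function(path) {
  nim <- RNifti::readNifti(path)
  dbm_image(array(as.numeric(nim), dim = dim(nim)),
            spacing_mm = RNifti::pixdim(nim)[1:3])
}

#' @rdname nifti_io
#' @export
write_field_nifti <- function(img, path) {
  stopifnot(inherits(img, "displacement_field"))
  nim <- RNifti::asNifti(img$u)
  RNifti::pixdim(nim) <- c(img$spacing_mm, 1)
  RNifti::writeNifti(nim, path)
  invisible(path)
}

#' @rdname nifti_io
#' @export
read_field_nifti <- function(path) {
  nim <- RNifti::readNifti(path)
  displacement_field(array(as.numeric(nim), dim = dim(nim)),
                     spacing_mm = RNifti::pixdim(nim)[1:3])
}
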