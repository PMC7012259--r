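#' 3D density volume
#'
#' Container for a registered gray-matter density map (or any nonnegative 3D
#' scalar field): a 3D array of finite, nonnegative voxel values plus the
#' physical voxel edge lengths in millimetres.
#'
#' @param values 3D numeric array of nonnegative, finite voxel values.
#' @param voxel_size_mm length-3 positive numeric, voxel edge length per axis.
#' @return An object of class `volume3d`.
#' @export
volume3d <- function(values, voxel_size_mm = c(1, 1, 1)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("volume3d: `values` must be a 3D array", call. = FALSE)
  if (any(!is.finite(values)))
    stop("volume3d: voxel values must be finite", call. = FALSE)
  if (any(values < 0))
    stop("volume3d: voxel values must be nonnegative densities", call. = FALSE)
  if (length(voxel_size_mm) != 3L || any(!is.finite(voxel_size_mm)) ||
      any(voxel_size_mm <= 0))
    stop("volume3d: `voxel_size_mm` must be 3 positive numbers", call. = FALSE)
  structure(list(values = values, voxel_size_mm = as.numeric(voxel_size_mm)),
            class = "volume3d")
}

#' @export
print.volume3d <- function(x, ...) {
  cat("volume3d:", paste(dim(x$values), collapse = " x "), "voxels,",
      paste(x$voxel_size_mm, collapse = " x "), "mm\n")
  invisible(x)
}

# 1D Gaussian smoothing matrix, truncated at 4*sigma, rows renormalized so the
# operator preserves constants exactly (the boundary rule).
gauss_band_matrix <- function(n, sigma) {
  r <- ceiling(4 * sigma)
  offs <- -r:r
  w <- exp(-offs^2 / (2 * sigma^2))
  S <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- i + offs
    ok <- j >= 1L & j <= n
    S[i, j[ok]] <- w[ok] / sum(w[ok])
  }
  S
}

#' Gaussian smoothing of a volume
#'
#' Separable Gaussian filter with standard deviation `sigma_vox` voxels per
#' axis, kernel truncated at 4 sigma. Near the boundary the truncated kernel
#' mass is renormalized, so constant volumes are reproduced exactly and an
#' interior impulse keeps unit mass.
#'
#' @param v a [volume3d()].
#' @param sigma_vox Gaussian standard deviation in voxels (> 0).
#' @return A smoothed [volume3d()] of identical shape.
#' @export
smooth_volume <- function(v, sigma_vox) {
  stopifnot(inherits(v, "volume3d"))
  if (length(sigma_vox) != 1L || !is.finite(sigma_vox) || sigma_vox <= 0)
    stop("smooth_volume: `sigma_vox` must be > 0", call. = FALSE)
  d <- dim(v$values)
  x <- v$values
  # axis 1
  x <- array(gauss_band_matrix(d[1], sigma_vox) %*% matrix(x, d[1]), d)
  # axis 2
  x <- aperm(x, c(2, 1, 3))
  x <- array(gauss_band_matrix(d[2], sigma_vox) %*% matrix(x, d[2]),
             c(d[2], d[1], d[3]))
  x <- aperm(x, c(2, 1, 3))
  # axis 3
  x <- aperm(x, c(3, 2, 1))
  x <- array(gauss_band_matrix(d[3], sigma_vox) %*% matrix(x, d[3]),
             c(d[3], d[2], d[1]))
  x <- aperm(x, c(3, 2, 1))
  volume3d(pmax(x, 0), v$voxel_size_mm)
}

#' Downsample a volume by block averaging
#'
#' Each output voxel is the mean of its `factor^3` input block; the voxel
#' size is multiplied by `factor`. Axis extents must be divisible by `factor`
#' (no silent cropping). This is the factor-4 step that reduces a 256^3 map
#' to 64^3.
#'
#' @param v a [volume3d()].
#' @param factor positive integer downsampling factor.
#' @return A [volume3d()] with each axis extent divided by `factor`.
#' @export
downsample <- function(v, factor) {
  stopifnot(inherits(v, "volume3d"))
  if (length(factor) != 1L || !is.finite(factor) || factor != round(factor) ||
      factor < 1)
    stop("downsample: `factor` must be a positive integer", call. = FALSE)
  factor <- as.integer(factor)
  d <- dim(v$values)
  if (any(d %% factor != 0L))
    stop("downsample: axis extents (", paste(d, collapse = "x"),
         ") not divisible by factor ", factor, call. = FALSE)
  if (factor == 1L) return(v)
  d2 <- d %/% factor
  x <- v$values
  # reduce one axis at a time: fold the leading axis into (factor, d2) blocks
  reduce_first <- function(a) {
    da <- dim(a)
    m <- colMeans(matrix(a, factor))          # means over leading factor-blocks
    array(m, c(da[1] %/% factor, da[2], da[3]))
  }
  x <- reduce_first(x)
  x <- aperm(reduce_first(aperm(x, c(2, 3, 1))), c(3, 1, 2))
  x <- aperm(reduce_first(aperm(x, c(3, 1, 2))), c(2, 3, 1))
  volume3d(x, v$voxel_size_mm * factor)
}

#' Vectorize a volume into a feature vector
#'
#' Concatenates voxel densities into a single feature vector in a fixed,
#' documented raster order: R column-major order, i.e. the first axis varies
#' fastest, then the second, then the third. An optional logical mask of the
#' same shape restricts to the `TRUE` voxels (in the same order).
#'
#' @param v a [volume3d()].
#' @param mask optional logical array of `v`'s shape.
#' @return A list with `values` (the feature vector) and `index_map` (an
#'   n x 3 integer matrix of the voxel coordinate of each feature).
#' @seealso [unvectorize()]
#' @export
vectorize <- function(v, mask = NULL) {
  stopifnot(inherits(v, "volume3d"))
  d <- dim(v$values)
  if (is.null(mask)) {
    idx <- arrayInd(seq_len(prod(d)), d)
    vals <- as.vector(v$values)
  } else {
    if (!is.logical(mask) || !identical(dim(mask), d))
      stop("vectorize: `mask` must be a logical array of the volume's shape",
           call. = FALSE)
    sel <- which(mask)                         # column-major order
    idx <- arrayInd(sel, d)
    vals <- v$values[sel]
  }
  colnames(idx) <- c("i", "j", "k")
  list(values = vals, index_map = idx)
}

#' Rebuild a volume from a feature vector and its index map
#'
#' Inverse of [vectorize()]: unmapped voxels are set to `fill`.
#'
#' @param values feature vector.
#' @param index_map n x 3 voxel coordinates, as returned by [vectorize()].
#' @param dim length-3 target volume shape.
#' @param fill value for voxels absent from the map (default 0).
#' @param voxel_size_mm voxel size of the rebuilt volume.
#' @return A [volume3d()].
#' @export
unvectorize <- function(values, index_map, dim, fill = 0,
                        voxel_size_mm = c(1, 1, 1)) {
  if (length(values) != nrow(index_map))
    stop("unvectorize: `values` and `index_map` lengths differ", call. = FALSE)
  a <- array(fill, dim)
  a[as.matrix(index_map)] <- values
  volume3d(a, voxel_size_mm)
}

#' Read a NIfTI volume
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return A [volume3d()] with voxel size taken from the header.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  volume3d(array(as.numeric(img), dim(img)[1:3]), pd[1:3])
}

#' Write a volume to NIfTI
#'
#' @param v a [volume3d()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path) {
  stopifnot(inherits(v, "volume3d"))
  img <- RNifti::asNifti(v$values)
  RNifti::pixdim(img) <- v$voxel_size_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}
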