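#' Define a regular image grid
#'
#' An `image_grid` describes the geometry of a 3D voxel lattice: the number of
#' voxels per axis, the physical voxel spacing in millimetres, and the physical
#' position of the centre of voxel `(0, 0, 0)`. Voxel index `(i, j, k)`
#' (0-based) maps to the physical point `origin + (i * sx, j * sy, k * sz)`;
#' every distance computed by the package uses this centre convention.
#'
#' @param shape Integer vector of length 3, voxels per axis (all >= 1).
#' @param spacing Numeric vector of length 3, mm per voxel (all > 0).
#' @param origin Numeric vector of length 3, mm position of the first voxel
#'   centre. Defaults to the zero vector.
#' @return An object of class `image_grid`.
#' @examples
#' image_grid(c(64, 64, 16), c(2.5, 2.5, 5.0))
#' @export
image_grid <- function(shape, spacing, origin = c(0, 0, 0)) {
  shape <- as.integer(shape)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(shape) != 3L || length(spacing) != 3L || length(origin) != 3L)
    stop("shape, spacing and origin must each have length 3")
  if (any(!is.finite(shape)) || any(shape < 1L))
    stop("all shape entries must be >= 1")
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("all spacing entries must be > 0")
  if (any(!is.finite(origin)))
    stop("origin must be finite")
  structure(list(shape = shape, spacing = spacing, origin = origin),
            class = "image_grid")
}

#' @export
print.image_grid <- function(x, ...) {
  cat(sprintf("image_grid: %d x %d x %d voxels @ %.4g x %.4g x %.4g mm\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' Test two grids for equality
#'
#' @param a,b `image_grid` objects.
#' @param tol Numeric tolerance on spacing and origin (mm).
#' @return Logical scalar.
#' @export
grids_equal <- function(a, b, tol = 1e-6) {
  identical(a$shape, b$shape) &&
    all(abs(a$spacing - b$spacing) <= tol) &&
    all(abs(a$origin - b$origin) <= tol)
}

stop_if_grid_mismatch <- function(a, b, what = "volumes") {
  if (!grids_equal(a, b)) stop("grid mismatch between ", what)
  invisible(TRUE)
}

#' Physical coordinates of voxel centres
#'
#' @param index Matrix (n x 3) of 1-based voxel indices, as returned by
#'   [base::arrayInd()].
#' @param grid An `image_grid`.
#' @return An n x 3 matrix of coordinates in mm.
#' @keywords internal
voxel_centers_mm <- function(index, grid) {
  sweep(sweep(index - 1, 2, grid$spacing, `*`), 2, grid$origin, `+`)
}

#' Construct a multi-b-value diffusion-weighted series
#'
#' Bundles a 4D direction-averaged DWI signal array (x, y, z, b) with its
#' b-value list and grid geometry. The fourth array dimension must match the
#' number of b-values, which must be distinct, non-negative and sorted
#' ascending.
#'
#' @param signal 4D numeric array of non-negative signal (arbitrary units).
#' @param bvalues Numeric vector of b-values (s/mm^2), strictly increasing.
#' @param grid An `image_grid` describing the spatial axes.
#' @return An object of class `dwi_series`.
#' @export
dwi_series <- function(signal, bvalues, grid) {
  if (length(dim(signal)) != 4L)
    stop("signal must be a 4D array (x, y, z, b)")
  bvalues <- as.numeric(bvalues)
  if (dim(signal)[4] != length(bvalues))
    stop("fourth signal dimension (", dim(signal)[4],
         ") does not match number of b-values (", length(bvalues), ")")
  if (any(bvalues < 0)) stop("b-values must be non-negative")
  if (anyDuplicated(bvalues)) stop("b-values must be distinct")
  if (is.unsorted(bvalues, strictly = TRUE))
    stop("b-values must be strictly increasing")
  if (!all(dim(signal)[1:3] == grid$shape))
    stop("signal spatial dimensions do not match grid shape")
  structure(list(signal = signal, bvalues = bvalues, grid = grid),
            class = "dwi_series")
}

#' Construct a binary region-of-interest mask
#'
#' @param mask 3D logical (or 0/1 numeric) array.
#' @param grid An `image_grid`.
#' @param label One of `"cancer"`, `"control"`, `"tumor_containing"`,
#'   `"other"`.
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(mask, grid,
                     label = c("other", "cancer", "control",
                               "tumor_containing")) {
  label <- match.arg(label)
  if (length(dim(mask)) != 3L) stop("mask must be a 3D array")
  if (!all(dim(mask) == grid$shape))
    stop("mask dimensions do not match grid shape")
  storage <- as.logical(mask)
  if (anyNA(storage)) stop("mask must not contain missing values")
  dim(storage) <- dim(mask)
  structure(list(mask = storage, grid = grid, label = label),
            class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("roi_mask [%s]: %d voxels on a %d x %d x %d grid\n",
              x$label, sum(x$mask),
              x$grid$shape[1], x$grid$shape[2], x$grid$shape[3]))
  invisible(x)
}
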