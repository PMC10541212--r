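# NIfTI readers/writers and small geometric plumbing. All file I/O goes
# through RNifti; grids carry spacing via pixdim and a zero origin.

grid_from_nifti <- function(img) {
  d <- dim(img)
  pd <- RNifti::pixdim(img)
  image_grid(d[1:3], pd[1:3])
}

#' Read a multi-b-value DWI series from NIfTI plus a b-value sidecar
#'
#' The volume must be 4D; the sidecar is whitespace-separated text in the FSL
#' `.bval` dialect (one value per 4D sub-volume). Volumes are re-ordered so
#' that b-values are strictly ascending.
#'
#' @param path_volume Path to a 4D NIfTI file.
#' @param path_bvalues Path to the b-value text sidecar.
#' @return A [dwi_series()].
#' @export
read_dwi <- function(path_volume, path_bvalues) {
  if (!file.exists(path_volume)) stop("cannot read volume: ", path_volume)
  if (!file.exists(path_bvalues)) stop("cannot read b-values: ", path_bvalues)
  img <- RNifti::readNifti(path_volume)
  if (length(dim(img)) != 4L)
    stop("expected a 4D volume, got ", length(dim(img)), "D: ", path_volume)
  bvals <- scan(path_bvalues, what = numeric(), quiet = TRUE)
  if (length(bvals) != dim(img)[4])
    stop("b-value sidecar lists ", length(bvals), " values but volume has ",
         dim(img)[4], " sub-volumes")
  if (any(bvals < 0)) stop("negative b-value in sidecar")
  ord <- order(bvals)
  arr <- as.array(img)[, , , ord, drop = FALSE]
  dwi_series(arr, bvals[ord], grid_from_nifti(img))
}

#' Read a 3D volume from NIfTI
#'
#' @param path Path to a 3D NIfTI file.
#' @return List with `volume` (3D array) and `grid` (`image_grid`).
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("cannot read volume: ", path)
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L)
    stop("expected a 3D volume: ", path)
  vol <- as.array(img)
  attributes(vol) <- list(dim = dim(vol))   # drop RNifti image attributes
  list(volume = vol, grid = grid_from_nifti(img))
}

#' Read a binary ROI mask from NIfTI
#'
#' @param path Path to a 3D NIfTI file holding 0/1 values.
#' @param label ROI label, see [roi_mask()].
#' @return A [roi_mask()].
#' @export
read_mask <- function(path, label = "other") {
  v <- read_volume(path)
  roi_mask(v$volume != 0, v$grid, label = label)
}

#' Write a volume (or mask) to NIfTI
#'
#' Masks (logical arrays) are stored as 8-bit unsigned integers with 0/1
#' values; continuous volumes as 64-bit floats so that read-back round-trips
#' within float precision.
#'
#' @param volume 3D or 4D numeric or logical array with finite values.
#' @param grid An `image_grid` supplying the voxel spacing.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return The path, invisibly.
#' @export
write_volume <- function(volume, grid, path) {
  if (is.logical(volume)) {
    v <- array(as.integer(volume), dim = dim(volume))
    datatype <- "uint8"
  } else {
    v <- volume
    datatype <- "double"
  }
  if (!all(is.finite(v))) stop("volume contains non-finite values")
  nd <- length(dim(v))
  if (!nd %in% c(3L, 4L)) stop("volume must be 3D or 4D")
  if (!all(dim(v)[1:3] == grid$shape))
    stop("volume dimensions do not match grid shape")
  img <- RNifti::asNifti(v)
  RNifti::pixdim(img) <- c(grid$spacing, rep(1, nd - 3L))
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Write b-values as an FSL-style sidecar
#'
#' @param bvalues Numeric vector of b-values.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_bvalues <- function(bvalues, path) {
  writeLines(paste(format(bvalues, trim = TRUE, scientific = FALSE),
                   collapse = " "), path)
  invisible(path)
}

#' Average per-direction volumes within each b-value shell
#'
#' Diffusion acquisitions measure several gradient directions per non-zero
#' b-value; the model below uses the direction-averaged signal. Groups are
#' averaged voxel-wise (arithmetic mean) and assembled into a series sorted by
#' b-value.
#'
#' @param stacks Named list, one entry per b-value (name = b-value); each
#'   entry is a list of 3D arrays (one per diffusion direction) or a single
#'   3D array.
#' @param grid An `image_grid` shared by all volumes.
#' @return A [dwi_series()].
#' @export
average_directions <- function(stacks, grid) {
  if (is.null(names(stacks)) || any(!nzchar(names(stacks))))
    stop("stacks must be a named list keyed by b-value")
  bvals <- as.numeric(names(stacks))
  if (anyNA(bvals)) stop("stack names must be numeric b-values")
  means <- lapply(stacks, function(group) {
    if (is.array(group) && length(dim(group)) == 3L) group <- list(group)
    if (length(group) == 0L) stop("empty direction group")
    acc <- array(0, dim = dim(group[[1]]))
    for (g in group) acc <- acc + g
    acc / length(group)
  })
  ord <- order(bvals)
  arr <- array(0, dim = c(dim(means[[1]]), length(means)))
  for (i in seq_along(ord)) arr[, , , i] <- means[[ord[i]]]
  dwi_series(arr, bvals[ord], grid)
}

#' Resample a volume onto another grid
#'
#' Continuous volumes are interpolated trilinearly; label volumes (masks,
#' segmentations) use nearest-neighbour so the output contains only values
#' present in the input. Target voxel centres outside the source extent are
#' clamped to the source border.
#'
#' @param volume 3D numeric array living on `source`.
#' @param source,target `image_grid` objects.
#' @param mode `"continuous"` (trilinear) or `"label"` (nearest-neighbour).
#' @return A 3D array with `target$shape` dimensions.
#' @export
resample_to_grid <- function(volume, source, target,
                             mode = c("continuous", "label")) {
  mode <- match.arg(mode)
  if (!all(dim(volume) == source$shape))
    stop("volume dimensions do not match source grid")
  if (any(target$shape < 1L)) stop("degenerate target grid")
  # continuous index of each target voxel centre in source index space
  axis_index <- function(ax) {
    x <- target$origin[ax] + (seq_len(target$shape[ax]) - 1) *
      target$spacing[ax]
    (x - source$origin[ax]) / source$spacing[ax]
  }
  ci <- axis_index(1); cj <- axis_index(2); ck <- axis_index(3)
  clamp <- function(v, hi) pmin(pmax(v, 0), hi - 1)
  ci <- clamp(ci, source$shape[1])
  cj <- clamp(cj, source$shape[2])
  ck <- clamp(ck, source$shape[3])
  if (mode == "label") {
    ii <- round(ci) + 1; jj <- round(cj) + 1; kk <- round(ck) + 1
    return(array(volume[cbind(rep(ii, times = length(jj) * length(kk)),
                              rep(rep(jj, each = length(ii)),
                                  times = length(kk)),
                              rep(kk, each = length(ii) * length(jj)))],
                 dim = target$shape))
  }
  # lower corner of the interpolation cell, clamped so the +1 neighbour exists
  cell <- function(c, n) pmax(pmin(floor(c), n - 2), 0)
  i0 <- cell(ci, source$shape[1])
  j0 <- cell(cj, source$shape[2])
  k0 <- cell(ck, source$shape[3])
  fi <- if (source$shape[1] == 1L) rep(0, length(ci)) else ci - i0
  fj <- if (source$shape[2] == 1L) rep(0, length(cj)) else cj - j0
  fk <- if (source$shape[3] == 1L) rep(0, length(ck)) else ck - k0
  nt <- prod(target$shape)
  I0 <- rep(i0, times = length(j0) * length(k0))
  J0 <- rep(rep(j0, each = length(i0)), times = length(k0))
  K0 <- rep(k0, each = length(i0) * length(j0))
  FI <- rep(fi, times = length(j0) * length(k0))
  FJ <- rep(rep(fj, each = length(i0)), times = length(k0))
  FK <- rep(fk, each = length(i0) * length(j0))
  out <- numeric(nt)
  at <- function(di, dj, dk) {
    ii <- pmin(I0 + di, source$shape[1] - 1)
    jj <- pmin(J0 + dj, source$shape[2] - 1)
    kk <- pmin(K0 + dk, source$shape[3] - 1)
    volume[cbind(ii + 1, jj + 1, kk + 1)]
  }
  for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
    w <- (if (di == 1) FI else 1 - FI) *
      (if (dj == 1) FJ else 1 - FJ) *
      (if (dk == 1) FK else 1 - FK)
    out <- out + w * at(di, dj, dk)
  }
  array(out, dim = target$shape)
}
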