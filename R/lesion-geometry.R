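# Tumor-containing region construction and automatic lesion sizing. All
# geometry is in physical units (mm) with anisotropic voxel spacing and the
# voxel-centre coordinate convention of image_grid().

neighbour_offsets <- function(connectivity = 26) {
  if (!connectivity %in% c(6, 18, 26))
    stop("connectivity must be 6, 18 or 26")
  g <- expand.grid(di = -1:1, dj = -1:1, dk = -1:1)
  g <- g[!(g$di == 0 & g$dj == 0 & g$dk == 0), ]
  ord <- abs(g$di) + abs(g$dj) + abs(g$dk)
  keep <- switch(as.character(connectivity),
                 "6" = ord == 1, "18" = ord <= 2, "26" = rep(TRUE, nrow(g)))
  as.matrix(g[keep, ])
}

half_offsets <- function(connectivity = 26) {
  o <- neighbour_offsets(connectivity)
  o[o[, 3] > 0 | (o[, 3] == 0 & o[, 2] > 0) |
      (o[, 3] == 0 & o[, 2] == 0 & o[, 1] > 0), , drop = FALSE]
}

#' Label connected components of a binary 3D mask
#'
#' Voxels are connected under the chosen 3D neighbourhood (6 = faces,
#' 18 = faces + edges, 26 = full). Component labels are renumbered so that
#' label 1 contains the smallest linear voxel index, label 2 the next, and so
#' on, giving a deterministic labelling.
#'
#' @param mask 3D logical array.
#' @param connectivity 6, 18 or 26 (default 26).
#' @return 3D integer array; 0 = background, 1..n = components.
#' @export
label_components <- function(mask, connectivity = 26) {
  dm <- dim(mask)
  fg <- which(mask)
  lab <- array(0L, dm)
  if (length(fg) == 0L) return(lab)
  id <- integer(prod(dm))
  id[fg] <- seq_along(fg)
  ijk <- arrayInd(fg, dm)
  offs <- half_offsets(connectivity)
  edges <- vector("list", nrow(offs))
  for (o in seq_len(nrow(offs))) {
    nb <- sweep(ijk, 2, offs[o, ], `+`)
    ok <- nb[, 1] >= 1 & nb[, 1] <= dm[1] &
      nb[, 2] >= 1 & nb[, 2] <= dm[2] &
      nb[, 3] >= 1 & nb[, 3] <= dm[3]
    if (!any(ok)) next
    lin <- (nb[ok, 3] - 1) * dm[1] * dm[2] + (nb[ok, 2] - 1) * dm[1] + nb[ok, 1]
    nbid <- id[lin]
    src <- id[fg[ok]]
    keep <- nbid > 0L
    if (any(keep)) edges[[o]] <- cbind(src[keep], nbid[keep])
  }
  edges <- do.call(rbind, edges)
  if (is.null(edges)) {
    memb <- seq_along(fg)
  } else {
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    extra <- length(fg) - igraph::vcount(g)
    if (extra > 0) g <- igraph::add_vertices(g, extra)
    memb <- igraph::components(g)$membership
  }
  # renumber by first (smallest linear index) appearance: fg is sorted
  memb <- match(memb, unique(memb))
  lab[fg] <- as.integer(memb)
  lab
}

#' Uniformly expand an ROI by a physical distance
#'
#' Returns the mask of voxels whose centre lies within `distance_mm`
#' (Euclidean, in mm, respecting anisotropic spacing) of some input-voxel
#' centre — the "tumor-containing region" when applied to the pre-treatment
#' cancer ROI with the default 10 mm (1 cm) expansion. Always a superset of
#' the input.
#'
#' @param cancer A non-empty [roi_mask()].
#' @param distance_mm Expansion distance in mm (>= 0), default 10.
#' @return A [roi_mask()] labelled `"tumor_containing"`.
#' @export
expand_roi <- function(cancer, distance_mm = 10.0) {
  if (!any(cancer$mask)) stop("cannot expand an empty mask")
  if (distance_mm < 0) stop("distance must be non-negative")
  dm <- cancer$grid$shape
  sp <- cancer$grid$spacing
  r <- pmin(floor(distance_mm / sp + 1e-9), dm - 1L)
  out <- array(FALSE, dm)
  m <- cancer$mask
  for (dk in -r[3]:r[3]) {
    for (dj in -r[2]:r[2]) {
      for (di in -r[1]:r[1]) {
        if (sum((c(di, dj, dk) * sp)^2) > distance_mm^2 + 1e-9) next
        xs <- max(1, 1 + di):min(dm[1], dm[1] + di)
        ys <- max(1, 1 + dj):min(dm[2], dm[2] + dj)
        zs <- max(1, 1 + dk):min(dm[3], dm[3] + dk)
        out[xs, ys, zs] <- out[xs, ys, zs] |
          m[xs - di, ys - dj, zs - dk, drop = FALSE]
      }
    }
  }
  roi_mask(out, cancer$grid, label = "tumor_containing")
}

#' Grow a region by attaching connected classified components
#'
#' Any connected component of the classified mask whose voxel set intersects
#' the region is absorbed in full, accounting for tumor growth extending
#' beyond the initially dilated region.
#'
#' @param region A [roi_mask()] (the tumor-containing region).
#' @param classified 3D logical array of classifier-positive voxels.
#' @param connectivity 6, 18 or 26 (default 26).
#' @param attachment `"intersect"` (default) absorbs components sharing a
#'   voxel with the region; `"adjacent"` also absorbs components merely
#'   face-adjacent to it.
#' @return A [roi_mask()] labelled `"tumor_containing"`.
#' @export
attach_connected_growth <- function(region, classified, connectivity = 26,
                                    attachment = c("intersect", "adjacent")) {
  attachment <- match.arg(attachment)
  if (!all(dim(classified) == region$grid$shape))
    stop("grid mismatch between region and classified mask")
  lab <- label_components(classified, connectivity)
  probe <- region$mask
  if (attachment == "adjacent") {
    dm <- dim(probe)
    for (o in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                   c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))) {
      xs <- max(1, 1 + o[1]):min(dm[1], dm[1] + o[1])
      ys <- max(1, 1 + o[2]):min(dm[2], dm[2] + o[2])
      zs <- max(1, 1 + o[3]):min(dm[3], dm[3] + o[3])
      probe[xs, ys, zs] <- probe[xs, ys, zs] |
        region$mask[xs - o[1], ys - o[2], zs - o[3], drop = FALSE]
    }
  }
  touching <- setdiff(unique(lab[probe]), 0L)
  grown <- region$mask | (lab %in% touching & lab > 0L)
  dim(grown) <- region$grid$shape
  roi_mask(grown, region$grid, label = "tumor_containing")
}

#' Largest connected classified component within a region
#'
#' Intersects the classified mask with the region and returns the connected
#' component of maximum voxel count. Ties are broken deterministically in
#' favour of the component containing the smallest linear voxel index.
#'
#' @param classified 3D logical array of classifier-positive voxels.
#' @param region A [roi_mask()] restricting the search.
#' @param connectivity 6, 18 or 26 (default 26).
#' @return 3D logical array (all `FALSE` when the intersection is empty).
#' @export
largest_component <- function(classified, region, connectivity = 26) {
  if (!all(dim(classified) == region$grid$shape))
    stop("grid mismatch between classified mask and region")
  inter <- classified & region$mask
  lab <- label_components(inter, connectivity)
  if (!any(lab > 0L)) return(array(FALSE, dim = region$grid$shape))
  sizes <- tabulate(lab[lab > 0L])
  # labels are ordered by first appearance, so which.max picks the
  # smallest-min-index component among equal sizes
  best <- which.max(sizes)
  lab == best
}

boundary_voxels <- function(mask) {
  dm <- dim(mask)
  interior <- array(TRUE, dm)
  shift_and <- function(acc, di, dj, dk) {
    shifted <- array(FALSE, dm)
    xs <- max(1, 1 + di):min(dm[1], dm[1] + di)
    ys <- max(1, 1 + dj):min(dm[2], dm[2] + dj)
    zs <- max(1, 1 + dk):min(dm[3], dm[3] + dk)
    shifted[xs, ys, zs] <- mask[xs - di, ys - dj, zs - dk, drop = FALSE]
    acc & shifted
  }
  for (o in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                 c(0, -1, 0), c(0, 0, 1), c(0, 0, -1)))
    interior <- shift_and(interior, o[1], o[2], o[3])
  mask & !interior
}

#' Longest lesion diameter in centimetres
#'
#' The maximum pairwise Euclidean distance between voxel centres of the
#' component, in physical mm, divided by 10. Any 3D chord lies in some plane,
#' so this realizes the longest diameter in any plane. Empty and singleton
#' components measure 0 cm (the centre convention), matching a complete
#' radiological response. For large components the search is restricted to
#' boundary voxels, which carry the extreme points.
#'
#' @param component 3D logical array, or an n x 3 matrix of 1-based voxel
#'   indices.
#' @param grid The `image_grid` supplying voxel spacing.
#' @param plane `"any"` (default) measures the full 3D chord; `"axial"`
#'   restricts candidate pairs to a common axial (xy) slice.
#' @return Non-negative scalar diameter in cm.
#' @export
longest_diameter <- function(component, grid, plane = c("any", "axial")) {
  plane <- match.arg(plane)
  if (is.array(component) && length(dim(component)) == 3L) {
    n_total <- sum(component)
    if (n_total > 600) component <- boundary_voxels(component)
    idx <- which(component)
    if (n_total <= 1L) return(0.0)
    ijk <- arrayInd(idx, dim(component))
  } else {
    ijk <- as.matrix(component)
    if (nrow(ijk) <= 1L) return(0.0)
  }
  if (plane == "axial") {
    best <- 0
    for (k in unique(ijk[, 3])) {
      sl <- ijk[ijk[, 3] == k, , drop = FALSE]
      if (nrow(sl) < 2L) next
      best <- max(best, max(stats::dist(voxel_centers_mm(sl, grid))))
    }
    return(best / 10)
  }
  xyz <- voxel_centers_mm(ijk, grid)
  max(stats::dist(xyz)) / 10
}

#' Measure one timepoint: region construction, component extraction, sizing
#'
#' Composes the full automatic measurement: dilate the pre-treatment cancer
#' ROI by `expand_mm` into the tumor-containing region, absorb classified
#' components connected to it, take the largest classified component inside
#' the grown region, and measure its longest diameter. The pre-treatment ROI
#' is used at every timepoint; only that single manual ROI is ever required.
#'
#' @param prob A `probability_map` from [posterior_map()].
#' @param pre_cancer The pre-treatment cancer [roi_mask()].
#' @param threshold Classification threshold on the probability map
#'   (default 0.5, strict inequality).
#' @param expand_mm ROI expansion in mm (default 10).
#' @param connectivity 6, 18 or 26 (default 26).
#' @return An object of class `lesion_measurement` with fields
#'   `diameter_cm`, `n_voxels`, `component_mask`, `region_mask`.
#' @export
measure_timepoint <- function(prob, pre_cancer, threshold = 0.5,
                              expand_mm = 10.0, connectivity = 26) {
  stop_if_grid_mismatch(prob$grid, pre_cancer$grid,
                        "probability map and cancer ROI")
  region <- expand_roi(pre_cancer, expand_mm)
  classified <- classify_map(prob, threshold)
  region <- attach_connected_growth(region, classified, connectivity)
  comp <- largest_component(classified, region, connectivity)
  structure(list(diameter_cm = longest_diameter(comp, prob$grid),
                 n_voxels = sum(comp),
                 component_mask = comp,
                 region_mask = region$mask),
            class = "lesion_measurement")
}

#' @export
print.lesion_measurement <- function(x, ...) {
  cat(sprintf("lesion_measurement: %.2f cm (%d voxels)\n",
              x$diameter_cm, x$n_voxels))
  invisible(x)
}
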