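#' Build ROI-restricted searchlight spheres
#'
#' One searchlight per ROI voxel: the set of ROI voxels whose integer-lattice
#' Euclidean distance from the centre voxel is at most \code{radius_voxels}.
#' Spheres are clipped by the ROI border, so member counts shrink near edges;
#' an interior sphere of radius 3 contains 123 lattice points.  Searchlights
#' are ordered by the centre voxel's linear (column-major) index, which also
#' fixes the deterministic tie-break used during feature selection.
#'
#' @param mask a [roi_mask()] or a pattern set's \code{voxel_coords} matrix.
#' @param radius_voxels sphere radius in voxel units (default 3).
#' @return list of searchlights; each has \code{centre} (1-based voxel index
#'   triple), \code{centre_col} (column in the ROI voxel ordering) and
#'   \code{members} (ROI voxel column indices inside the sphere).
#' @export
build_searchlights <- function(mask, radius_voxels = 3) {
  stopifnot(radius_voxels > 0)
  if (inherits(mask, "roi_mask")) {
    coords <- which(mask$mask, arr.ind = TRUE)
  } else {
    coords <- as.matrix(mask)
    stopifnot(ncol(coords) == 3)
  }
  nv <- nrow(coords)
  if (nv == 0) stop("empty ROI")
  # which() returns coordinates in column-major order already; keep it
  d2 <- outer(coords[, 1], coords[, 1], `-`)^2 +
        outer(coords[, 2], coords[, 2], `-`)^2 +
        outer(coords[, 3], coords[, 3], `-`)^2
  r2 <- radius_voxels^2
  lapply(seq_len(nv), function(i) {
    list(centre = coords[i, ], centre_col = i,
         members = which(d2[i, ] <= r2), radius_voxels = radius_voxels)
  })
}
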