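# 3D shape descriptors of the binary lesion mask. Surface area and mesh
# volume come from a triangulated iso-surface (marching tetrahedra at level
# 0.5 of the lightly smoothed binary mask - smoothing anti-aliases the
# voxel staircase so digitized spheres mesh at near-unit sphericity).

mask_mesh <- function(mask, smooth_sigma_vox = 0.6) {
  d <- dim(mask$voxels)
  pad <- array(0, dim = d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- as.numeric(mask$voxels)
  field <- smooth_gaussian(pad, smooth_sigma_vox)
  if (max(field) <= 0.5) field <- pad # tiny mask: smoothing undershoots 0.5
  av <- cpp_mesh_area_volume(as.numeric(field), as.integer(dim(pad)),
                             mask$spacing_mm, 0.5)
  list(area = av[1], volume = av[2])
}

boundary_coords_mm <- function(mask) {
  m <- mask$voxels
  d <- dim(m)
  pad <- array(FALSE, dim = d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- m
  inner <- pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] &
    pad[1:d[1], 2:(d[2] + 1), 2:(d[3] + 1)] &
    pad[3:(d[1] + 2), 2:(d[2] + 1), 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 1:d[2], 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 3:(d[2] + 2), 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 2:(d[2] + 1), 1:d[3]] &
    pad[2:(d[1] + 1), 2:(d[2] + 1), 3:(d[3] + 2)]
  surf <- which(m & !inner, arr.ind = TRUE)
  sweep(surf - 1, 2, mask$spacing_mm, `*`)
}

#' 3D shape features of a segmentation mask
#'
#' The 14 standard shape descriptors: mesh/voxel volume, surface area and
#' derived ratios, maximum 3D and in-plane diameters (from boundary voxel
#' centres), and principal-axis lengths from the eigenvalues of the voxel
#' coordinate covariance (`4*sqrt(lambda)`). Degenerate masks (single
#' voxel, flat slabs) report zero axis lengths rather than failing.
#'
#' @param mask a [segmentation_mask] with known spacing.
#' @return Named numeric vector of length 14.
#' @export
shape_features <- function(mask) {
  stop_if_not(mask_count(mask) > 0, "empty mask")
  sp <- mask$spacing_mm
  mesh <- mask_mesh(mask)
  vvol <- mask_count(mask) * prod(sp)
  bc <- boundary_coords_mm(mask)
  idx <- which(mask$voxels, arr.ind = TRUE)
  pts <- sweep(idx - 1, 2, sp, `*`)
  n <- nrow(pts)
  if (n > 1) {
    cc <- sweep(pts, 2, colMeans(pts))
    ev <- sort(eigen(crossprod(cc) / n, symmetric = TRUE,
                     only.values = TRUE)$values, decreasing = TRUE)
    ev <- pmax(ev, 0)
  } else {
    ev <- c(0, 0, 0)
  }
  axes <- 4 * sqrt(ev)
  surf <- max(mesh$area, .Machine$double.eps)
  c(MeshVolume = mesh$volume,
    VoxelVolume = vvol,
    SurfaceArea = mesh$area,
    SurfaceVolumeRatio = mesh$area / max(mesh$volume, .Machine$double.eps),
    Sphericity = pi^(1 / 3) * (6 * mesh$volume)^(2 / 3) / surf,
    Maximum3DDiameter = cpp_max_pairwise(bc, 0L),
    Maximum2DDiameterSlice = cpp_max_pairwise(bc, 3L),
    Maximum2DDiameterColumn = cpp_max_pairwise(bc, 2L),
    Maximum2DDiameterRow = cpp_max_pairwise(bc, 1L),
    MajorAxisLength = axes[1],
    MinorAxisLength = axes[2],
    LeastAxisLength = axes[3],
    Elongation = if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 0,
    Flatness = if (ev[1] > 0) sqrt(ev[3] / ev[1]) else 0)
}
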