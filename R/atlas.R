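#' Region table of the synthetic label atlas
#'
#' Integer label ids of the parametric head geometry. Id 0 is background;
#' ids 1-9 are brain regions and 10/11 the two external reference phantoms.
#' "Whole brain" is the union of ids 1-9 and is reported by
#' [regional_means()] as a derived region.
#'
#' @return named integer vector mapping region name to label id.
#' @export
atlas_regions <- function() {
  c(frontal = 1L, parietal = 2L, temporal = 3L, occipital = 4L,
    cerebellum = 5L, thalamus = 6L, caudate = 7L, putamen = 8L,
    brain_stem = 9L, phantom_low = 10L, phantom_high = 11L)
}

#' Geometry configuration of the synthetic atlas
#'
#' Centers and radii in normalised coordinates (each axis spans [-1, 1]
#' across the grid). The geometry is deliberately parametric, not anatomical:
#' an ellipsoidal brain carved into wedge-like lobes, spherical deep-gray
#' nuclei, a posterior-inferior cerebellum, an inferior brain stem, and two
#' phantom spheres outside the brain.
#'
#' @param brain_radius brain ellipsoid radius.
#' @param cerebellum_center,cerebellum_radius cerebellum sphere.
#' @param thalamus_radius,caudate_radius,putamen_radius nuclei sphere radii.
#' @param brain_stem_center,brain_stem_radius brain-stem sphere.
#' @param phantom_radius phantom sphere radius (centers are fixed corners).
#' @return list of class `atlas_geometry`.
#' @export
atlas_geometry <- function(brain_radius = 0.80,
                           cerebellum_center = c(0, -0.45, -0.45),
                           cerebellum_radius = 0.28,
                           thalamus_radius = 0.18,
                           caudate_radius = 0.14,
                           putamen_radius = 0.14,
                           brain_stem_center = c(0, -0.05, -0.62),
                           brain_stem_radius = 0.16,
                           phantom_radius = 0.16) {
  stopifnot(brain_radius > 0, cerebellum_radius > 0, thalamus_radius > 0,
            caudate_radius > 0, putamen_radius > 0, brain_stem_radius > 0,
            phantom_radius > 0)
  structure(list(brain_radius = brain_radius,
                 cerebellum_center = cerebellum_center,
                 cerebellum_radius = cerebellum_radius,
                 thalamus_radius = thalamus_radius,
                 caudate_radius = caudate_radius,
                 putamen_radius = putamen_radius,
                 brain_stem_center = brain_stem_center,
                 brain_stem_radius = brain_stem_radius,
                 phantom_radius = phantom_radius),
            class = "atlas_geometry")
}

# voxel-center coordinates normalised to [-1, 1] per axis
norm_coords <- function(grid_shape) {
  ax <- lapply(grid_shape, function(n) (2 * (seq_len(n) - 0.5) / n) - 1)
  list(x = ax[[1]], y = ax[[2]], z = ax[[3]])
}

#' Build the synthetic label atlas
#'
#' Places every required region (four lobes, cerebellum, thalamus, caudate,
#' putamen, brain stem, two phantoms) as a simple parametric shape on the
#' CSI grid. Non-background voxels carry exactly one label. On coarse grids
#' a region whose parametric shape captures no voxel center is assigned its
#' single nearest eligible voxel so that every region is non-empty.
#'
#' @param grid_shape integer length-3 matrix size (each >= 6).
#' @param geometry an [atlas_geometry()].
#' @param fov_mm field of view, used only to record the voxel size.
#' @return object of class `label_atlas`: list with integer 3D `labels`,
#'   `region_names` (named id vector), and `voxel_size_mm`.
#' @export
make_atlas <- function(grid_shape = c(10L, 10L, 10L),
                       geometry = atlas_geometry(),
                       fov_mm = c(240, 240, 240)) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L)
  if (any(grid_shape < 6L)) {
    stop("grid too small: at least 6 voxels per axis are needed to place ",
         "all regions")
  }
  g <- geometry
  co <- norm_coords(grid_shape)
  xg <- array(co$x, grid_shape)
  yg <- array(rep(co$y, each = grid_shape[1]), grid_shape)
  zg <- array(rep(co$z, each = grid_shape[1] * grid_shape[2]), grid_shape)
  r2 <- function(cx, cy, cz) (xg - cx)^2 + (yg - cy)^2 + (zg - cz)^2

  ids <- atlas_regions()
  labels <- array(0L, grid_shape)
  brain <- r2(0, 0, 0) <= g$brain_radius^2

  # lobes fill the remaining cerebrum by anterior/posterior and height
  labels[brain & yg > 0.1] <- ids[["frontal"]]
  labels[brain & yg <= 0.1 & yg > -0.35 & zg > 0] <- ids[["parietal"]]
  labels[brain & yg <= 0.1 & zg <= 0] <- ids[["temporal"]]
  labels[brain & yg <= -0.35 & zg > 0] <- ids[["occipital"]]

  assign_sphere <- function(labels, center, radius, id, inside = brain) {
    hit <- inside & r2(center[1], center[2], center[3]) <= radius^2
    labels[hit] <- id
    labels
  }
  labels <- assign_sphere(labels, g$cerebellum_center, g$cerebellum_radius,
                          ids[["cerebellum"]])
  labels <- assign_sphere(labels, g$brain_stem_center, g$brain_stem_radius,
                          ids[["brain_stem"]])
  labels <- assign_sphere(labels, c(0, 0, 0.05), g$thalamus_radius,
                          ids[["thalamus"]])
  labels <- assign_sphere(labels, c(0.30, 0.25, 0.15), g$caudate_radius,
                          ids[["caudate"]])
  labels <- assign_sphere(labels, c(-0.30, 0.25, 0.15), g$caudate_radius,
                          ids[["caudate"]])
  labels <- assign_sphere(labels, c(0.42, 0.05, 0), g$putamen_radius,
                          ids[["putamen"]])
  labels <- assign_sphere(labels, c(-0.42, 0.05, 0), g$putamen_radius,
                          ids[["putamen"]])

  phantom_centers <- list(phantom_low = c(0.75, 0.75, -0.55),
                          phantom_high = c(-0.75, 0.75, -0.55))
  for (nm in names(phantom_centers)) {
    cc <- phantom_centers[[nm]]
    labels <- assign_sphere(labels, cc, g$phantom_radius, ids[[nm]],
                            inside = !brain)
  }

  # coarse-grid fallback: claim the nearest eligible voxel for empty regions
  centers <- list(
    frontal = c(0, 0.45, 0.1), parietal = c(0, -0.1, 0.45),
    temporal = c(0.4, -0.1, -0.25), occipital = c(0, -0.55, 0.25),
    cerebellum = g$cerebellum_center, thalamus = c(0, 0, 0.05),
    caudate = c(0.30, 0.25, 0.15), putamen = c(0.42, 0.05, 0),
    brain_stem = g$brain_stem_center,
    phantom_low = phantom_centers$phantom_low,
    phantom_high = phantom_centers$phantom_high
  )
  for (nm in names(ids)) {
    id <- ids[[nm]]
    if (any(labels == id)) next
    cc <- centers[[nm]]
    eligible <- if (grepl("^phantom", nm)) !brain & labels == 0L else brain
    if (!any(eligible)) stop("grid too small to place region ", nm)
    d2 <- r2(cc[1], cc[2], cc[3])
    d2[!eligible] <- Inf
    labels[which.min(d2)] <- id
  }

  structure(list(labels = labels, region_names = ids,
                 voxel_size_mm = fov_mm / grid_shape),
            class = "label_atlas")
}

#' @export
print.label_atlas <- function(x, ...) {
  counts <- table(factor(x$labels[x$labels != 0L],
                         levels = x$region_names,
                         labels = names(x$region_names)))
  cat("label_atlas ", paste(dim(x$labels), collapse = "x"), " voxels\n",
      sep = "")
  print(counts)
  invisible(x)
}

#' Logical mask of all brain voxels (labels 1-9)
#' @param atlas a `label_atlas`.
#' @export
brain_mask <- function(atlas) {
  ids <- atlas$region_names
  brain_ids <- ids[!grepl("^phantom", names(ids))]
  array(atlas$labels %in% brain_ids, dim(atlas$labels))
}

#' Write an atlas or a 3D map as a NIfTI volume
#'
#' @param x a `label_atlas`, a `metabolite_map`, or a plain 3D array.
#' @param path output file path (`.nii` or `.nii.gz`).
#' @param voxel_size_mm voxel size, taken from the object when available.
#' @return the path, invisibly.
#' @export
write_nifti_volume <- function(x, path, voxel_size_mm = c(1, 1, 1)) {
  if (inherits(x, "label_atlas")) {
    vol <- x$labels
    voxel_size_mm <- x$voxel_size_mm
  } else if (inherits(x, "metabolite_map")) {
    vol <- x$values
  } else {
    vol <- x
  }
  img <- RNifti::asNifti(vol, pixdim = voxel_size_mm)
  RNifti::writeNifti(img, path)
  invisible(path)
}
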