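#' Seeded region growing on a scalar image
#'
#' Segments a connected region of similar intensity (or T1) around a seed
#' voxel, as used to delineate the hydrogel on gradient-echo images in vitro
#' and on T1 maps in vivo. The acceptance band is relative: a voxel is a
#' candidate when its value lies within `tolerance` times the current
#' reference value of that reference. The reference starts as the mean over
#' the seed and its face neighbours and is refined to the mean of the grown
#' region; reference update and regrowth iterate to a fixed point. Every
#' iteration is a whole-image threshold followed by a connected-component
#' extraction, so the result does not depend on any voxel visiting order.
#'
#' @param image Numeric 3D array (image intensities or a T1/R1 map).
#' @param seed Integer vector of length 3: voxel index of the seed, placed
#'   in the centre of the gel.
#' @param tolerance Relative half-width of the acceptance band (fraction of
#'   the reference value). Defaults of 0.20 for raw intensities and 0.15 for
#'   T1 maps are suggested; the default here is 0.20.
#' @param connectivity Neighbourhood used for region connectivity: 6 (face
#'   neighbours, default) or 26.
#' @param max_iter Cap on reference-refinement iterations.
#' @return Logical 3D array (the grown mask) with attribute `provenance`,
#'   a tibble recording seed, tolerance, connectivity, final reference value
#'   and iteration count. If the seed itself falls outside the acceptance
#'   band of its own neighbourhood (a background seed), a single-voxel mask
#'   is returned with a warning.
#' @export
region_grow <- function(image, seed, tolerance = 0.2, connectivity = 6L,
                        max_iter = 20L) {
  stopifnot(is.numeric(image), length(dim(image)) == 3L)
  seed <- as.integer(seed)
  if (length(seed) != 3L || any(seed < 1L) || any(seed > dim(image)))
    abort("`seed` must be a voxel index inside the image grid.")
  if (!is.numeric(tolerance) || tolerance <= 0)
    abort("`tolerance` must be a positive fraction.")
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(6L, 26L))
    abort("`connectivity` must be 6 or 26.")

  seed_mask <- array(FALSE, dim = dim(image))
  seed_mask[seed[1], seed[2], seed[3]] <- TRUE
  nbhd <- dilate_step(seed_mask, 6L)
  ref <- mean(image[nbhd])

  single <- function(ref, iters) {
    warn("Seed lies outside its own acceptance band; returning a single-voxel mask.")
    structure(seed_mask, provenance = region_grow_provenance(
      seed, tolerance, connectivity, ref, iters, 1L))
  }

  region <- seed_mask
  iters <- 0L
  repeat {
    iters <- iters + 1L
    cand <- abs(image - ref) <= tolerance * abs(ref)
    if (!cand[seed[1], seed[2], seed[3]]) return(single(ref, iters))
    grown <- flood_fill(cand, seed, connectivity)
    new_ref <- mean(image[grown])
    if (all(grown == region) || iters >= max_iter) {
      region <- grown
      ref <- new_ref
      break
    }
    region <- grown
    ref <- new_ref
  }
  structure(region, provenance = region_grow_provenance(
    seed, tolerance, connectivity, ref, iters, sum(region)))
}

region_grow_provenance <- function(seed, tolerance, connectivity, ref,
                                   iters, n_voxels) {
  tibble(
    seed_x = seed[1], seed_y = seed[2], seed_z = seed[3],
    tolerance = tolerance, connectivity = connectivity,
    reference_value = ref, iterations = iters, n_voxels = n_voxels
  )
}

#' Volume of a voxel mask in microlitres
#'
#' Voxel count times voxel volume; 1 mm^3 corresponds to 1 uL.
#'
#' @param mask Logical array.
#' @param voxel_mm Voxel edge lengths in mm (length 1 for isotropic or 3).
#' @return Volume in uL (numeric scalar). An empty mask gives 0 with a
#'   warning.
#' @export
volume_from_mask <- function(mask, voxel_mm) {
  stopifnot(is.logical(mask))
  voxel_mm <- rep_len(as.numeric(voxel_mm), 3L)
  if (any(voxel_mm <= 0)) abort("Voxel dimensions must be positive.")
  n <- sum(mask)
  if (n == 0L) warn("Empty mask: volume is 0 uL.")
  n * prod(voxel_mm)
}

#' Build the ROI system around a segmented gel mask
#'
#' Constructs the analysis ROIs used for serial release quantification:
#' a rim-excluded gel core (the gel eroded by `rim_depth` voxels, keeping
#' the ROI border away from the partial-volume rim), the rim band itself,
#' an adjacent-tissue shell at `tissue_offset` voxels beyond the gel rim,
#' and contralateral mirrors of core and adjacent-tissue ROIs obtained by
#' reflection across the image midline. Erosion and dilation use the
#' city-block structuring element, so "n voxels distance" means n iterations.
#'
#' @param gel_mask Logical 3D array, the segmented gel.
#' @param rim_depth Erosion depth in voxels for the gel core (default 2).
#' @param tissue_offset Distance in voxels from the gel rim to the
#'   adjacent-tissue shell (default 10).
#' @param mirror_axis Axis perpendicular to the midline plane used for
#'   contralateral mirroring (default 1). Set to `NA` to skip mirroring
#'   (tube geometry).
#' @param tissue_mask Optional logical array restricting the adjacent-tissue
#'   shell (e.g. a brain mask).
#' @return An object of class `roi_set`: a named list of logical masks
#'   (`gel`, `core`, `rim`, `adjacent`, and when mirrored `core_mirror`,
#'   `adjacent_mirror`) plus a `provenance` tibble.
#' @export
build_roi_set <- function(gel_mask, rim_depth = 2L, tissue_offset = 10L,
                          mirror_axis = 1L, tissue_mask = NULL) {
  stopifnot(is.logical(gel_mask), length(dim(gel_mask)) == 3L)
  if (!any(gel_mask)) abort("Gel mask is empty.")
  rim_depth <- as.integer(rim_depth)
  tissue_offset <- as.integer(tissue_offset)
  if (rim_depth < 0L || tissue_offset < 1L)
    abort("`rim_depth` must be >= 0 and `tissue_offset` >= 1.")

  core <- mask_erode(gel_mask, rim_depth)
  if (!any(core))
    abort(sprintf(paste0(
      "Eroding by %d voxels empties the gel core; the gel must span more ",
      "than %d voxels across its narrowest axis."), rim_depth, 2L * rim_depth))
  rim <- gel_mask & !core

  adjacent <- mask_dilate(gel_mask, tissue_offset) &
    !mask_dilate(gel_mask, tissue_offset - 1L)
  if (!is.null(tissue_mask)) adjacent <- adjacent & tissue_mask

  rois <- list(gel = gel_mask, core = core, rim = rim, adjacent = adjacent)
  if (!is.na(mirror_axis)) {
    rois$core_mirror <- mask_mirror(core, mirror_axis)
    rois$adjacent_mirror <- mask_mirror(adjacent, mirror_axis)
  }
  structure(
    rois,
    provenance = tibble(
      rim_depth = rim_depth, tissue_offset = tissue_offset,
      mirror_axis = if (is.na(mirror_axis)) NA_integer_ else as.integer(mirror_axis),
      n_gel = sum(gel_mask), n_core = sum(core), n_rim = sum(rim),
      n_adjacent = sum(adjacent)
    ),
    class = "roi_set"
  )
}

#' @export
print.roi_set <- function(x, ...) {
  cat("<roi_set>\n")
  print(attr(x, "provenance"))
  invisible(x)
}
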