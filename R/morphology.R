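# Vectorised 3D binary morphology and flood fill on logical arrays.
#
# All operations use index-shift logic on the full array, so results are
# deterministic and independent of any voxel visiting order. The structuring
# element is the 3D cross (city-block metric) for 6-connectivity and the full
# 3x3x3 box for 26-connectivity.

# Shift a 3D logical array by one voxel along `axis` in direction `dir`
# (+1 or -1), padding with FALSE.
shift_mask <- function(m, axis, dir) {
  d <- dim(m)
  out <- array(FALSE, dim = d)
  idx_src <- lapply(d, seq_len)
  idx_dst <- idx_src
  n <- d[axis]
  if (n < 2L) return(out)
  if (dir > 0) {
    idx_dst[[axis]] <- 2:n
    idx_src[[axis]] <- 1:(n - 1L)
  } else {
    idx_dst[[axis]] <- 1:(n - 1L)
    idx_src[[axis]] <- 2:n
  }
  out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
    m[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
  out
}

# One dilation step. 6-connectivity: union of the six face-neighbour shifts.
# 26-connectivity: sequential box dilation along each axis.
dilate_step <- function(m, connectivity = 6L) {
  if (connectivity == 26L) {
    for (ax in 1:3) m <- m | shift_mask(m, ax, 1L) | shift_mask(m, ax, -1L)
    return(m)
  }
  out <- m
  for (ax in 1:3) out <- out | shift_mask(m, ax, 1L) | shift_mask(m, ax, -1L)
  out
}

erode_step <- function(m, connectivity = 6L) {
  if (connectivity == 26L) {
    for (ax in 1:3) m <- m & shift_mask(m, ax, 1L) & shift_mask(m, ax, -1L)
    return(m)
  }
  out <- m
  for (ax in 1:3) out <- out & shift_mask(m, ax, 1L) & shift_mask(m, ax, -1L)
  out
}

#' Binary dilation of a 3D mask
#'
#' City-block (face-neighbour) dilation iterated `n` times, so `n` is a
#' distance in voxels along the image axes.
#'
#' @param mask Logical 3D array.
#' @param n Number of dilation iterations (non-negative integer).
#' @param connectivity 6 (face neighbours) or 26 (full box).
#' @return Logical array of the same dimensions.
#' @export
mask_dilate <- function(mask, n = 1L, connectivity = 6L) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L, n >= 0)
  for (i in seq_len(n)) mask <- dilate_step(mask, connectivity)
  mask
}

#' Binary erosion of a 3D mask
#'
#' @inheritParams mask_dilate
#' @return Logical array of the same dimensions.
#' @export
mask_erode <- function(mask, n = 1L, connectivity = 6L) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L, n >= 0)
  for (i in seq_len(n)) mask <- erode_step(mask, connectivity)
  mask
}

# Connected component of `candidate` containing `seed` (length-3 index).
# Frontier expansion to a fixed point; each step is a whole-array operation.
flood_fill <- function(candidate, seed, connectivity = 6L) {
  stopifnot(is.logical(candidate), length(seed) == 3L)
  region <- array(FALSE, dim = dim(candidate))
  region[seed[1], seed[2], seed[3]] <- TRUE
  if (!candidate[seed[1], seed[2], seed[3]]) return(region)
  repeat {
    grown <- dilate_step(region, connectivity) & candidate
    if (all(grown == region)) break
    region <- grown
  }
  region
}

#' Mirror a mask across the image midline
#'
#' Reflects a 3D mask across the centre plane perpendicular to `axis`
#' (default the first, left-right, axis), as used to transfer ROIs to the
#' contralateral hemisphere. The reflection is an involution: mirroring twice
#' returns the original mask.
#'
#' @param mask Logical 3D array.
#' @param axis Axis perpendicular to the mirror plane (1, 2 or 3).
#' @return Logical array of the same dimensions and voxel count.
#' @export
mask_mirror <- function(mask, axis = 1L) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L, axis %in% 1:3)
  d <- dim(mask)
  idx <- lapply(d, seq_len)
  idx[[axis]] <- rev(idx[[axis]])
  out <- mask[idx[[1]], idx[[2]], idx[[3]]]
  dim(out) <- d
  out
}
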