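#' Downsample a volume in x and y
#'
#' Block-mean downsampling of density and block-majority of labels over
#' `factor x factor x 1` blocks (ties broken toward the lowest label id),
#' mirroring the in-plane reduction applied to high-resolution microCT
#' before model building.  Trailing voxels that do not fill a block are
#' cropped with a warning.  Spacing in x/y is multiplied by `factor`; the
#' origin moves to the centre of the new voxel `(0, 0, 0)` (the centroid of
#' its source block).
#'
#' @param volume a [labeled_volume].
#' @param factor positive integer reduction factor.
#' @return the downsampled [labeled_volume].
#' @export
downsample_xy <- function(volume, factor) {
  validate_volume(volume)
  if (!is.numeric(factor) || length(factor) != 1L || factor < 1 ||
      factor != round(factor))
    stop("`factor` must be a positive integer", call. = FALSE)
  factor <- as.integer(factor)
  if (factor == 1L) return(volume)
  d <- volume$dims
  nx <- d[1] %/% factor; ny <- d[2] %/% factor
  if (nx < 1L || ny < 1L)
    stop("factor larger than volume extent", call. = FALSE)
  cx <- nx * factor; cy <- ny * factor
  if (cx < d[1] || cy < d[2])
    warning(sprintf("cropping %d x / %d y trailing voxels not filling a block",
                    d[1] - cx, d[2] - cy))
  den <- volume$density[seq_len(cx), seq_len(cy), , drop = FALSE]
  lab <- volume$label[seq_len(cx), seq_len(cy), , drop = FALSE]
  nz <- d[3]
  # fold each factor x factor x 1 block onto its own slot
  dim(den) <- c(factor, nx, factor, ny, nz)
  newden <- apply(den, c(2, 4, 5), mean)
  dim(lab) <- c(factor, nx, factor, ny, nz)
  lab <- aperm(lab, c(1, 3, 2, 4, 5))
  dim(lab) <- c(factor * factor, nx * ny * nz)
  newlab <- apply(lab, 2, function(b) {
    tb <- tabulate(b + 1L)
    which.max(tb) - 1L   # which.max takes the first (= lowest id) on ties
  })
  labs <- sort(unique(as.vector(newlab)))
  labeled_volume(array(newden, c(nx, ny, nz)),
                 label = array(as.integer(newlab), c(nx, ny, nz)),
                 spacing = volume$spacing * c(factor, factor, 1),
                 origin = volume$origin +
                   c((factor - 1) / 2 * volume$spacing[1],
                     (factor - 1) / 2 * volume$spacing[2], 0))
}

#' Threshold-based bone segmentation
#'
#' Labels every voxel whose density lies inside the closed HU window
#' `[hu_low, hu_high]`; all other voxels keep label 0 in the returned pass,
#' so interior void spaces (mastoid air cells) below the window are
#' retained as drained/void space rather than being filled.
#'
#' @param volume a [labeled_volume].
#' @param hu_low,hu_high window bounds, `hu_low <= hu_high`.
#' @param label positive label id to assign.
#' @return a [labeled_volume] whose label grid is `label` inside the
#'   window and 0 elsewhere (density unchanged).
#' @export
threshold_segment <- function(volume, hu_low, hu_high, label) {
  validate_volume(volume)
  if (hu_low > hu_high)
    stop("`hu_low` must not exceed `hu_high`", call. = FALSE)
  label <- as.integer(label)
  if (label <= 0L) stop("`label` must be positive", call. = FALSE)
  sel <- volume$density >= hu_low & volume$density <= hu_high
  lab <- array(0L, volume$dims)
  lab[sel] <- label
  labeled_volume(volume$density, label = lab, spacing = volume$spacing,
                 origin = volume$origin)
}

# boundary (non-2-manifold) edge count; 0 for a watertight mesh
mesh_boundary_edges <- function(mesh) {
  E <- mesh_edges(mesh)
  if (!nrow(E)) return(0L)
  ukey <- paste(pmin(E[, 1], E[, 2]), pmax(E[, 1], E[, 2]))
  sum(table(ukey) != 2L)
}

#' Voxelize a watertight mesh onto a grid
#'
#' A voxel is occupied iff its centre lies inside the mesh, decided by a
#' ray-casting parity (winding) test.  Deterministic; structures entirely
#' outside the grid produce an empty mask.
#'
#' @param mesh a watertight [triangle_mesh] (closed; an explicit error
#'   reporting the boundary-edge count is raised otherwise).
#' @param dims,spacing,origin target grid geometry (see [labeled_volume]).
#' @return logical 3D occupancy array.
#' @export
voxelize_mesh <- function(mesh, dims, spacing, origin = c(0, 0, 0)) {
  nb <- mesh_boundary_edges(mesh)
  if (nb > 0L)
    stop("mesh is not watertight: ", nb, " boundary edges", call. = FALSE)
  occ <- .voxelize_core(mesh$vertices, mesh$triangles, as.integer(dims),
                        as.numeric(spacing), as.numeric(origin))
  array(occ, as.integer(dims))
}

#' Combine structure masks into one labeled model
#'
#' Paints an ordered list of occupancy masks onto a base volume; later
#' entries overwrite earlier labels where masks overlap (so soft-tissue
#' structures listed after bone take priority).  Voxels newly labeled out
#' of void space (density 0) receive `fill_density` so the model surface
#' encloses them.
#'
#' @param masks list of `list(mask = <logical array>, label = <id>)`
#'   entries sharing the base grid dims.
#' @param base a [labeled_volume].
#' @param fill_density representative density for newly labeled void
#'   voxels (default 1000, roughly a soft-tissue/bone-window midpoint).
#' @return the combined [labeled_volume].
#' @export
combine_structures <- function(masks, base, fill_density = 1000) {
  validate_volume(base)
  lab <- base$label
  den <- base$density
  for (entry in masks) {
    m <- entry$mask
    if (!identical(dim(m), dim(lab)))
      stop("mask dims do not match base volume grid", call. = FALSE)
    lab[m] <- as.integer(entry$label)
    den[m & den == 0] <- fill_density
  }
  labeled_volume(den, label = lab, spacing = base$spacing,
                 origin = base$origin)
}
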