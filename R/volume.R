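#' Labeled voxel volume
#'
#' The central container of the engine: a density grid (HU-like scalars or
#' occupancy in `[0, 1]`) plus an integer anatomic-label grid on the same
#' lattice, with voxel spacing and world origin.  Label 0 is reserved for
#' void/air; any voxel with a nonzero label is "occupied" for collision and
#' drilling purposes.  The world position of voxel `(i, j, k)` (0-based) is
#' `origin + (i, j, k) * spacing`, all distances in millimetres.
#'
#' @param density numeric 3D array of per-voxel densities (finite).
#' @param label integer 3D array of the same dimensions, non-negative;
#'   `NULL` means all-zero (no labeled structures).
#' @param spacing positive numeric length-3, mm per voxel along x, y, z.
#' @param origin numeric length-3, world-mm centre of voxel `(0, 0, 0)`.
#' @return an object of class `labeled_volume` with fields `dims`,
#'   `spacing`, `origin`, `density`, `label`.
#' @export
labeled_volume <- function(density, label = NULL, spacing = c(1, 1, 1),
                           origin = c(0, 0, 0)) {
  density <- as.array(density)
  if (length(dim(density)) != 3L)
    stop("`density` must be a 3D array", call. = FALSE)
  dims <- dim(density)
  if (is.null(label)) {
    label <- array(0L, dims)
  } else {
    label <- as.array(label)
    storage.mode(label) <- "integer"
  }
  v <- structure(list(dims = as.integer(dims),
                      spacing = as.numeric(spacing),
                      origin = as.numeric(origin),
                      density = density,
                      label = label),
                 class = "labeled_volume")
  validate_volume(v)
  v
}

#' Validate a labeled volume's invariants
#'
#' Checks dimensions, positive spacing, finite density, matching label grid
#' and non-negative labels; stops with an informative error on violation.
#'
#' @param v a `labeled_volume`.
#' @return `v`, invisibly.
#' @export
validate_volume <- function(v) {
  stopifnot(inherits(v, "labeled_volume"))
  if (length(v$dims) != 3L || any(v$dims < 1L))
    stop("volume dims must be three integers >= 1", call. = FALSE)
  if (length(v$spacing) != 3L || any(!is.finite(v$spacing)) ||
      any(v$spacing <= 0))
    stop("volume spacing must be three positive finite numbers",
         call. = FALSE)
  if (length(v$origin) != 3L || any(!is.finite(v$origin)))
    stop("volume origin must be three finite numbers", call. = FALSE)
  if (!identical(dim(v$density), dim(v$label)) ||
      !identical(as.integer(dim(v$density)), v$dims))
    stop("density/label grids must both match dims", call. = FALSE)
  if (any(!is.finite(v$density)))
    stop("density must be finite everywhere", call. = FALSE)
  if (any(v$label < 0L))
    stop("labels must be non-negative", call. = FALSE)
  invisible(v)
}

#' @export
print.labeled_volume <- function(x, ...) {
  occ <- sum(x$label != 0L)
  cat(sprintf("<labeled_volume %dx%dx%d, spacing %s mm, %d occupied voxels, labels {%s}>\n",
              x$dims[1], x$dims[2], x$dims[3],
              paste(signif(x$spacing, 4), collapse = "x"),
              occ,
              paste(sort(unique(as.vector(x$label[x$label != 0L]))),
                    collapse = ",")))
  invisible(x)
}

#' World coordinates of voxel centres
#'
#' @param v a `labeled_volume`.
#' @param ijk integer matrix (n x 3) of 0-based voxel indices.
#' @return n x 3 matrix of world-mm positions.
#' @export
voxel_to_world <- function(v, ijk) {
  ijk <- matrix(as.numeric(ijk), ncol = 3)
  sweep(sweep(ijk, 2, v$spacing, `*`), 2, v$origin, `+`)
}

#' Continuous voxel coordinates of world points
#'
#' @param v a `labeled_volume`.
#' @param p numeric matrix (n x 3) of world-mm positions.
#' @return n x 3 matrix of continuous 0-based voxel coordinates.
#' @export
world_to_voxel <- function(v, p) {
  p <- matrix(as.numeric(p), ncol = 3)
  sweep(sweep(p, 2, v$origin, `-`), 2, v$spacing, `/`)
}

# nearest 0-based voxel index of a single world point, or NULL if the point
# rounds outside the grid
nearest_voxel <- function(v, p) {
  ijk <- round(as.numeric((p - v$origin) / v$spacing))
  if (any(ijk < 0) || any(ijk >= v$dims)) return(NULL)
  as.integer(ijk)
}

# occupancy test at a world point: TRUE iff the nearest voxel exists and
# carries a nonzero label
point_occupied <- function(v, p) {
  ijk <- nearest_voxel(v, p)
  if (is.null(ijk)) return(FALSE)
  v$label[ijk[1] + 1L, ijk[2] + 1L, ijk[3] + 1L] != 0L
}

# label of the nearest voxel at a world point (0 outside the grid)
point_label <- function(v, p) {
  ijk <- nearest_voxel(v, p)
  if (is.null(ijk)) return(0L)
  v$label[ijk[1] + 1L, ijk[2] + 1L, ijk[3] + 1L]
}

# linear (1-based) <-> 0-based ijk index conversion
ijk_to_linear <- function(dims, ijk) {
  ijk <- matrix(as.integer(ijk), ncol = 3)
  1L + ijk[, 1] + dims[1] * (ijk[, 2] + dims[2] * ijk[, 3])
}

linear_to_ijk <- function(dims, lin) {
  lin0 <- as.integer(lin) - 1L
  i <- lin0 %% dims[1]
  rest <- lin0 %/% dims[1]
  cbind(i, rest %% dims[2], rest %/% dims[2])
}

#' Occupancy field of a labeled volume
#'
#' @param v a `labeled_volume`.
#' @return numeric 3D array, 1 where `label != 0`, else 0.
#' @export
occupancy <- function(v) {
  array(as.numeric(v$label != 0L), v$dims)
}

#' Content hash of a labeled volume
#'
#' MD5 over a canonical binary serialization of dims, spacing, origin,
#' density and label.  Used to enforce model identity when replaying
#' recorded sessions on their matching (isomorphic) model.
#'
#' @param v a `labeled_volume`.
#' @return a 32-character hex string.
#' @export
volume_hash <- function(v) {
  tf <- tempfile(fileext = ".bin")
  on.exit(unlink(tf), add = TRUE)
  con <- file(tf, "wb")
  writeBin(as.integer(v$dims), con, size = 4, endian = "little")
  writeBin(as.numeric(v$spacing), con, size = 8, endian = "little")
  writeBin(as.numeric(v$origin), con, size = 8, endian = "little")
  writeBin(as.numeric(v$density), con, size = 8, endian = "little")
  writeBin(as.integer(v$label), con, size = 4, endian = "little")
  close(con)
  unname(tools::md5sum(tf))
}
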