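#' Marching-cubes surface extraction
#'
#' Standard 256-case lookup with linear edge interpolation at `iso`,
#' applied to the volume's binary occupancy (label != 0, surfaced at 0.5)
#' or to the raw density field at an HU iso.  Vertices are emitted in
#' world mm; each vertex carries the label of the solid-side voxel of its
#' crossing edge.  An iso outside the field's range simply yields an empty
#' mesh.  Ambiguous-face cases are resolved by a fixed rule without an
#' asymptotic decider (see the methods vignette), so adjacent cells always
#' agree and the surface of an interior solid is closed.
#'
#' @param volume a [labeled_volume].
#' @param iso iso value (default 0.5, matching occupancy).
#' @param region optional list with 0-based inclusive cell bounds
#'   `lo`, `hi` (a cell is the cube spanned by voxels `(i..i+1, ...)`);
#'   default the whole volume.
#' @param field `"occupancy"` or `"density"`.
#' @return a [triangle_mesh].
#' @export
marching_cubes <- function(volume, iso = 0.5, region = NULL,
                           field = c("occupancy", "density")) {
  validate_volume(volume)
  field <- match.arg(field)
  d <- volume$dims
  if (any(d < 2L)) return(empty_mesh())
  lo <- c(0L, 0L, 0L); hi <- d - 2L
  if (!is.null(region)) {
    lo <- pmax(lo, as.integer(region$lo))
    hi <- pmin(hi, as.integer(region$hi))
    if (any(hi < lo)) return(empty_mesh())
  }
  f <- if (field == "occupancy") as.numeric(volume$label != 0L)
       else as.numeric(volume$density)
  tab <- mc_table()
  res <- .mc_core(f, d, iso, lo, hi, as.integer(volume$label),
                  tab$offsets, tab$edges)
  if (!nrow(res$vertices)) return(empty_mesh())
  V <- sweep(sweep(res$vertices, 2, volume$spacing, `*`), 2,
             volume$origin, `+`)
  mesh <- triangle_mesh(V, res$faces, vertex_labels = res$vertex_labels)
  drop_degenerate(mesh)
}

# remove exact-zero-area triangles (possible only when a corner value
# equals iso exactly, collapsing interpolated vertices)
drop_degenerate <- function(mesh) {
  if (!nrow(mesh$triangles)) return(mesh)
  area2 <- rowSums(face_cross(mesh)^2)
  keep <- area2 > 0
  if (all(keep)) return(mesh)
  triangle_mesh(mesh$vertices, mesh$triangles[keep, , drop = FALSE],
                mesh$vertex_labels)
}

#' Chunked surface cache with incremental (dirty-region) updates
#'
#' Partitions the cell lattice into cubic chunks (default 16 cells per
#' side), extracts one mesh fragment per chunk, and re-extracts only
#' chunks marked dirty by voxel edits.  Each cell is owned by exactly one
#' chunk, so no seam triangle is emitted twice; chunk recomputation is
#' order-independent and side-effect-free (the "multicore" contract: any
#' schedule, including parallel, yields the same surface).
#'
#' @param volume a [labeled_volume].
#' @param chunk_size cells per chunk side (default 16).
#' @param iso iso value passed to [marching_cubes].
#' @param field `"occupancy"` or `"density"`.
#' @return a `chunk_grid` object (environment).
#' @export
chunk_grid <- function(volume, chunk_size = 16L, iso = 0.5,
                       field = "occupancy") {
  validate_volume(volume)
  cg <- new.env(parent = emptyenv())
  cg$chunk_size <- as.integer(chunk_size)
  cg$iso <- iso
  cg$field <- field
  cg$cell_dims <- pmax(volume$dims - 1L, 0L)
  cg$nchunks <- pmax(ceiling(cg$cell_dims / cg$chunk_size), 1L)
  nc <- prod(cg$nchunks)
  cg$fragments <- vector("list", nc)
  cg$dirty <- rep(TRUE, nc)
  cg$revision <- integer(nc)
  class(cg) <- "chunk_grid"
  update_dirty(cg, volume)
  cg
}

chunk_linear <- function(cg, cxyz) {
  1L + cxyz[, 1] + cg$nchunks[1] * (cxyz[, 2] + cg$nchunks[2] * cxyz[, 3])
}

chunk_region <- function(cg, lin) {
  lin0 <- lin - 1L
  cx <- lin0 %% cg$nchunks[1]
  rest <- lin0 %/% cg$nchunks[1]
  cy <- rest %% cg$nchunks[2]
  cz <- rest %/% cg$nchunks[2]
  lo <- c(cx, cy, cz) * cg$chunk_size
  hi <- pmin(lo + cg$chunk_size - 1L, cg$cell_dims - 1L)
  list(lo = lo, hi = hi)
}

#' Mark chunks dirty for a set of voxel edits
#'
#' A voxel edit invalidates every cell that uses the voxel as a corner
#' (up to 8), and hence the chunk owning each such cell; chunks adjacent
#' across a face/edge/corner shared with the affected cells are marked
#' through that same cell-ownership rule.
#'
#' @param cg a [chunk_grid].
#' @param edits integer matrix (n x 3) of 0-based voxel indices.
#' @return `cg`, invisibly.
#' @export
mark_dirty <- function(cg, edits) {
  edits <- matrix(as.integer(edits), ncol = 3)
  if (!nrow(edits)) return(invisible(cg))
  offs <- as.matrix(expand.grid(0:-1, 0:-1, 0:-1))
  cells <- do.call(rbind, lapply(seq_len(nrow(offs)), function(i)
    sweep(edits, 2, -offs[i, ], `-`)))
  keep <- cells[, 1] >= 0L & cells[, 2] >= 0L & cells[, 3] >= 0L &
    cells[, 1] < cg$cell_dims[1] & cells[, 2] < cg$cell_dims[2] &
    cells[, 3] < cg$cell_dims[3]
  cells <- cells[keep, , drop = FALSE]
  if (!nrow(cells)) return(invisible(cg))
  ch <- unique(chunk_linear(cg, cells %/% cg$chunk_size))
  cg$dirty[ch] <- TRUE
  invisible(cg)
}

#' Recompute dirty chunks and return the assembled surface
#'
#' Re-extracts only chunks currently flagged dirty (optionally flagging
#' `edits` first), clears the flags, bumps per-chunk revisions and
#' concatenates all cached fragments.  The result is triangle-set
#' identical to a full-volume [marching_cubes] call.
#'
#' @param cg a [chunk_grid].
#' @param volume the [labeled_volume] (edits already applied).
#' @param edits optional integer matrix (n x 3) of 0-based voxel indices
#'   to mark before updating.
#' @return the assembled [triangle_mesh].
#' @export
update_dirty <- function(cg, volume, edits = NULL) {
  if (!is.null(edits)) mark_dirty(cg, edits)
  for (lin in which(cg$dirty)) {
    reg <- chunk_region(cg, lin)
    cg$fragments[[lin]] <- marching_cubes(volume, iso = cg$iso,
                                          region = reg, field = cg$field)
    cg$revision[lin] <- cg$revision[lin] + 1L
    cg$dirty[lin] <- FALSE
  }
  assemble_chunks(cg)
}

assemble_chunks <- function(cg) {
  frags <- Filter(function(m) !is.null(m) && nrow(m$triangles) > 0,
                  cg$fragments)
  if (!length(frags)) return(empty_mesh())
  nv <- vapply(frags, function(m) nrow(m$vertices), integer(1))
  off <- cumsum(c(0L, head(nv, -1L)))
  V <- do.call(rbind, lapply(frags, `[[`, "vertices"))
  TRm <- do.call(rbind, lapply(seq_along(frags), function(i)
    frags[[i]]$triangles + off[i]))
  lab <- unlist(lapply(frags, `[[`, "vertex_labels"))
  triangle_mesh(V, TRm, vertex_labels = lab)
}
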