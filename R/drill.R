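#' Spherical drill bit
#'
#' @param radius burr radius in mm (> 0, modifiable between strokes).
#' @param removal_rate exposure units delivered per second of contact.
#' @return a `drill_bit` list.
#' @export
drill_bit <- function(radius, removal_rate = 1) {
  if (!is.numeric(radius) || radius <= 0)
    stop("bit radius must be positive", call. = FALSE)
  if (!is.numeric(removal_rate) || removal_rate <= 0)
    stop("removal rate must be positive", call. = FALSE)
  structure(list(radius = radius, removal_rate = removal_rate),
            class = "drill_bit")
}

#' Sparse per-voxel drill-exposure accumulator
#'
#' Maps (linear) voxel indices to accumulated exposure
#' (`seconds * rate * ease`); entries exist only for voxels ever touched
#' by an active bit.  A voxel is removed once its exposure reaches the
#' material's resistance (resistance 0 means instantaneous carving).
#'
#' @return an `exposure_field` environment.
#' @export
exposure_field <- function() {
  e <- new.env(parent = emptyenv())
  e$map <- new.env(hash = TRUE, parent = emptyenv())
  class(e) <- "exposure_field"
  e
}

exposure_get <- function(ef, keys) {
  vapply(keys, function(k) get0(k, envir = ef$map, ifnotfound = 0),
         numeric(1))
}

exposure_clear <- function(ef, keys) {
  keys <- keys[vapply(keys, exists, logical(1), envir = ef$map)]
  if (length(keys)) rm(list = keys, envir = ef$map)
  invisible(ef)
}

#' Apply one drill increment
#'
#' Every voxel whose centre lies within `bit$radius` of `center` and whose
#' label is drillable accrues `removal_rate * dt * ease(label)` exposure;
#' voxels whose accumulated exposure reaches the material's resistance are
#' carved (density and label set to 0).  Undrillable labels never change,
#' void voxels are ignored, and a centre outside the volume is a no-op.
#'
#' @param volume a [labeled_volume].
#' @param materials a [material_table]; every touched nonzero label must
#'   be present.
#' @param bit a [drill_bit].
#' @param center world-mm bit centre.
#' @param dt contact duration in seconds (> 0).
#' @param exposure an [exposure_field], updated in place.
#' @return list with `volume` (updated), `removed` (integer matrix of
#'   0-based voxel indices) and `delta` (data.frame `linear`, `density`,
#'   `label` of prior states, the undo fragment for this increment).
#' @export
apply_drill <- function(volume, materials, bit, center, dt, exposure) {
  if (!is.numeric(dt) || dt <= 0) stop("`dt` must be positive", call. = FALSE)
  d <- volume$dims
  lo <- pmax(ceiling((center - bit$radius - volume$origin) / volume$spacing), 0)
  hi <- pmin(floor((center + bit$radius - volume$origin) / volume$spacing),
             d - 1)
  empty <- list(volume = volume,
                removed = matrix(integer(0), ncol = 3),
                delta = data.frame(linear = integer(0), density = numeric(0),
                                   label = integer(0)))
  if (any(hi < lo)) return(empty)
  ii <- lo[1]:hi[1]; jj <- lo[2]:hi[2]; kk <- lo[3]:hi[3]
  ijk <- as.matrix(expand.grid(i = ii, j = jj, k = kk))
  w <- voxel_to_world(volume, ijk)
  inside <- rowSums(sweep(w, 2, center, `-`)^2) <= bit$radius^2
  ijk <- ijk[inside, , drop = FALSE]
  if (!nrow(ijk)) return(empty)
  lin <- ijk_to_linear(d, ijk)
  lab <- volume$label[lin]
  touched <- lab != 0L
  if (!any(touched)) return(empty)
  lin <- lin[touched]; ijk <- ijk[touched, , drop = FALSE]
  lab <- lab[touched]
  mi <- match(lab, materials$label)
  if (anyNA(mi))
    stop("volume labels absent from material table: ",
         paste(unique(lab[is.na(mi)]), collapse = ", "), call. = FALSE)
  drl <- materials$drillable[mi]
  if (!any(drl)) return(empty)
  lin <- lin[drl]; ijk <- ijk[drl, , drop = FALSE]
  mi <- mi[drl]
  keys <- as.character(lin)
  acc <- exposure_get(exposure, keys) +
    bit$removal_rate * dt * materials$ease[mi]
  gone <- acc >= materials$resistance[mi]
  for (q in seq_along(keys))
    assign(keys[q], acc[q], envir = exposure$map)
  if (!any(gone)) {
    return(list(volume = volume, removed = matrix(integer(0), ncol = 3),
                delta = data.frame(linear = integer(0),
                                   density = numeric(0),
                                   label = integer(0))))
  }
  rlin <- lin[gone]
  delta <- data.frame(linear = rlin,
                      density = volume$density[rlin],
                      label = volume$label[rlin])
  volume$density[rlin] <- 0
  volume$label[rlin] <- 0L
  exposure_clear(exposure, as.character(rlin))
  list(volume = volume, removed = ijk[gone, , drop = FALSE], delta = delta)
}

#' Stroke undo stack
#'
#' One stroke = one maximal pedal-on interval; undo is strictly LIFO.
#'
#' @return an `undo_stack` environment.
#' @export
undo_stack <- function() {
  s <- new.env(parent = emptyenv())
  s$strokes <- list()
  s$next_id <- 1L
  class(s) <- "undo_stack"
  s
}

#' @rdname undo_stack
#' @param stack an `undo_stack`.
#' @param delta data.frame (`linear`, `density`, `label`) of prior voxel
#'   states removed during the stroke; voxel indices unique per stroke.
#' @param t0,t1 stroke time span in seconds.
#' @return `push_stroke` returns the stored record (with its stroke id).
#' @export
push_stroke <- function(stack, delta, t0 = NA_real_, t1 = NA_real_) {
  delta <- delta[!duplicated(delta$linear), , drop = FALSE]
  rec <- structure(list(id = stack$next_id, delta = delta, t0 = t0, t1 = t1),
                   class = "undo_record")
  stack$strokes[[length(stack$strokes) + 1L]] <- rec
  stack$next_id <- stack$next_id + 1L
  rec
}

#' Undo the most recent stroke
#'
#' Restores density and label bitwise for every voxel in the record,
#' clears their exposure entries, pops the record off the stack and,
#' when a [chunk_grid] is supplied, marks the affected chunks dirty.
#' Only the most recent un-reverted stroke may be undone (LIFO).
#'
#' @param volume a [labeled_volume].
#' @param record the `undo_record` to revert; must be the stack top.
#' @param exposure an [exposure_field].
#' @param stack the `undo_stack` the record came from (LIFO enforced);
#'   `NULL` skips stack bookkeeping.
#' @param chunks optional [chunk_grid] to invalidate.
#' @return the restored [labeled_volume].
#' @export
undo_stroke <- function(volume, record, exposure, stack = NULL,
                        chunks = NULL) {
  if (!is.null(stack)) {
    n <- length(stack$strokes)
    if (n == 0L) stop("undo stack is empty", call. = FALSE)
    top <- stack$strokes[[n]]
    if (!identical(top$id, record$id))
      stop("out-of-order undo: stroke ", record$id,
           " is not the most recent (top is ", top$id, ")", call. = FALSE)
    stack$strokes[[n]] <- NULL
  }
  dlt <- record$delta
  if (nrow(dlt)) {
    volume$density[dlt$linear] <- dlt$density
    volume$label[dlt$linear] <- as.integer(dlt$label)
    exposure_clear(exposure, as.character(dlt$linear))
    if (!is.null(chunks))
      mark_dirty(chunks, linear_to_ijk(volume$dims, dlt$linear))
  }
  volume
}
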