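#' Haptic state
#'
#' Device pose, surface-locked proxy position, pedal state, simulated
#' time, last output force and the device force clamp.
#'
#' @param device_pos world-mm device (drill-tip) position.
#' @param proxy_pos world-mm proxy position (defaults to the device
#'   position; must start in free space).
#' @param pedal logical foot-pedal state.
#' @param t simulated time, s.
#' @param max_force device force clamp in N (default 3.3, a typical
#'   entry-level device limit; configurable, not a measured value).
#' @return a `haptic_state` list.
#' @export
haptic_state <- function(device_pos, proxy_pos = device_pos,
                         pedal = FALSE, t = 0, max_force = 3.3) {
  structure(list(device_pos = as.numeric(device_pos),
                 proxy_pos = as.numeric(proxy_pos),
                 pedal = isTRUE(pedal), t = t,
                 force = c(0, 0, 0), contact_label = 0L,
                 max_force = max_force),
            class = "haptic_state")
}

# outward surface normal from central differences of the 3^3-box-smoothed
# occupancy field around world point p; zero-gradient fallback = direction
# from the nearest occupied voxel centre to p
surface_normal <- function(volume, p) {
  ijk <- round((p - volume$origin) / volume$spacing)
  s_at <- function(q) {
    lo <- pmax(q - 1, 0); hi <- pmin(q + 1, volume$dims - 1)
    if (any(hi < lo)) return(0)
    blk <- volume$label[(lo[1]:hi[1]) + 1L, (lo[2]:hi[2]) + 1L,
                        (lo[3]:hi[3]) + 1L]
    sum(blk != 0L) / 27   # voxels clipped off the grid count as void
  }
  g <- numeric(3)
  for (ax in 1:3) {
    e <- c(0, 0, 0); e[ax] <- 1
    g[ax] <- (s_at(ijk + e) - s_at(ijk - e)) / 2
  }
  len <- sqrt(sum(g^2))
  if (len > 1e-12) return(-g / len)
  nb <- nearest_voxel(volume, p)
  if (!is.null(nb) &&
      volume$label[nb[1] + 1L, nb[2] + 1L, nb[3] + 1L] != 0L) {
    d <- p - voxel_to_world(volume, matrix(nb, 1))[1, ]
    if (sqrt(sum(d^2)) > 1e-12) return(d / sqrt(sum(d^2)))
  }
  c(0, 0, 1)
}

#' Position-locking proxy update
#'
#' Marches the proxy from its previous position toward the device in
#' steps of at most a quarter voxel; on striking an occupied voxel it
#' stops at the last free sample, estimates the local surface normal,
#' projects the residual motion onto the tangent plane and re-marches
#' (at most `max_slides` slide iterations).  The returned proxy is always
#' in free space; in fully free space it equals the device position.
#' A previous proxy found inside occupied space (normally unreachable) is
#' recovered by snapping to the nearest free voxel centre, with a warning.
#'
#' @param volume a [labeled_volume].
#' @param prev_proxy world-mm proxy from the previous tick (free space).
#' @param device_pos world-mm device position.
#' @param max_slides maximum tangential re-march iterations (default 3).
#' @return list with `proxy` (world mm), `contact_label` (label of the
#'   first blocking voxel, 0 in free space) and `normal` (outward surface
#'   normal at the contact, or `NULL`).
#' @export
update_proxy <- function(volume, prev_proxy, device_pos, max_slides = 3L) {
  step <- min(volume$spacing) / 4
  proxy <- as.numeric(prev_proxy)
  if (point_occupied(volume, proxy)) {
    warning("proxy found inside occupied space; snapping to nearest free voxel")
    ijk <- nearest_voxel(volume, proxy)
    nf <- .nearest_free_voxel(as.integer(volume$label), volume$dims,
                              ijk[1], ijk[2], ijk[3])
    if (nf[1] >= 0L) proxy <- voxel_to_world(volume, matrix(nf, 1))[1, ]
  }
  target <- as.numeric(device_pos)
  contact_label <- 0L
  normal <- NULL
  for (slide in 0:max_slides) {
    dir <- target - proxy
    len <- sqrt(sum(dir^2))
    if (len < 1e-12) break
    u <- dir / len
    nsteps <- ceiling(len / step)
    hit <- FALSE
    start <- proxy
    for (s in seq_len(nsteps)) {
      cand <- start + u * min(s * step, len)
      if (point_occupied(volume, cand)) {
        hit <- TRUE
        if (contact_label == 0L)
          contact_label <- point_label(volume, cand)
        break
      }
      proxy <- cand
    }
    if (!hit) break
    normal <- surface_normal(volume, proxy)
    residual <- target - proxy
    target <- proxy + (residual - sum(residual * normal) * normal)
  }
  list(proxy = proxy, contact_label = contact_label, normal = normal)
}

clamp_force <- function(f, max_force) {
  len <- sqrt(sum(f^2))
  if (len > max_force) f * (max_force / len) else f
}

#' Proxy-spring contact force
#'
#' Zero when the proxy coincides with the device; otherwise
#' `k * (proxy - device)` with the contacting material's stiffness,
#' magnitude clamped to the device limit with direction preserved.
#'
#' @param state a [haptic_state].
#' @param materials a [material_table].
#' @param contact_label label of the contacting material (0/`NULL` for no
#'   contact); must exist in the table when nonzero.
#' @return force vector in N.
#' @export
compute_force <- function(state, materials, contact_label) {
  sep <- state$proxy_pos - state$device_pos
  if (is.null(contact_label) || contact_label == 0L ||
      sqrt(sum(sep^2)) < 1e-12)
    return(c(0, 0, 0))
  k <- material_row(materials, contact_label)$stiffness
  clamp_force(k * sep, state$max_force)
}

#' Virtual-spring (penalty) force baseline
#'
#' The classical alternative to position locking: force equals
#' `k * penetration_depth` along the direction to the nearest free space,
#' where depth is measured from the device position.  Provided solely as
#' the comparison baseline; on thin walls it exhibits pop-through (the
#' force flips to push the device out the far side once past the
#' midplane), which the proxy method avoids.
#'
#' @param volume a [labeled_volume].
#' @param device_pos world-mm device position.
#' @param materials a [material_table].
#' @param max_force clamp in N.
#' @return force vector in N (zero in free space).
#' @export
spring_force_baseline <- function(volume, device_pos, materials,
                                  max_force = 3.3) {
  if (!point_occupied(volume, device_pos)) return(c(0, 0, 0))
  ijk <- nearest_voxel(volume, device_pos)
  lab <- volume$label[ijk[1] + 1L, ijk[2] + 1L, ijk[3] + 1L]
  k <- material_row(materials, lab)$stiffness
  nf <- .nearest_free_voxel(as.integer(volume$label), volume$dims,
                            ijk[1], ijk[2], ijk[3])
  if (nf[1] < 0L) return(c(0, 0, 0))   # fully solid volume
  out <- voxel_to_world(volume, matrix(nf, 1))[1, ] - device_pos
  depth <- sqrt(sum(out^2))
  if (depth < 1e-12) return(c(0, 0, 0))
  clamp_force(k * depth * (out / depth), max_force)
}

#' One simulated haptic tick
#'
#' Composes position locking with drilling: updates the proxy toward the
#' new device pose, computes the contact force and, with the pedal on,
#' carves along the proxy path (sub-sampled at a quarter voxel so fast
#' sweeps cannot tunnel through thin structures).  Fully deterministic
#' given its inputs.
#'
#' @param state a [haptic_state].
#' @param volume a [labeled_volume].
#' @param materials a [material_table].
#' @param bit a [drill_bit].
#' @param new_device_pos world-mm device pose for this tick.
#' @param pedal pedal state this tick.
#' @param dt tick duration in s (default 1 ms).
#' @param exposure an [exposure_field].
#' @param chunks optional [chunk_grid]; removed voxels mark it dirty.
#' @return list with `state`, `volume`, `force`, `removed` (0-based voxel
#'   index matrix) and `delta` (undo fragment).
#' @export
haptic_step <- function(state, volume, materials, bit, new_device_pos,
                        pedal, dt = 1e-3, exposure = exposure_field(),
                        chunks = NULL) {
  if (!is.numeric(dt) || dt <= 0) stop("`dt` must be positive", call. = FALSE)
  prev_proxy <- state$proxy_pos
  up <- update_proxy(volume, prev_proxy, new_device_pos)
  removed <- matrix(integer(0), ncol = 3)
  delta <- data.frame(linear = integer(0), density = numeric(0),
                      label = integer(0))
  if (isTRUE(pedal)) {
    seg <- up$proxy - prev_proxy
    seglen <- sqrt(sum(seg^2))
    nsub <- max(1L, ceiling(seglen / (min(volume$spacing) / 4)))
    for (s in seq_len(nsub)) {
      ctr <- prev_proxy + seg * (s / nsub)
      res <- apply_drill(volume, materials, bit, ctr, dt / nsub, exposure)
      volume <- res$volume
      if (nrow(res$removed)) {
        removed <- rbind(removed, res$removed)
        delta <- rbind(delta, res$delta)
      }
    }
    if (!is.null(chunks) && nrow(removed)) mark_dirty(chunks, removed)
  }
  state$device_pos <- as.numeric(new_device_pos)
  state$proxy_pos <- up$proxy
  state$pedal <- isTRUE(pedal)
  state$t <- state$t + dt
  state$contact_label <- up$contact_label
  state$force <- compute_force(state, materials, up$contact_label)
  list(state = state, volume = volume, force = state$force,
       removed = removed, delta = delta)
}

#' Run a scripted device trajectory through the simulator
#'
#' Drives [haptic_step] over a pose/pedal schedule, keeping stroke
#' bookkeeping (a stroke is one maximal pedal-on interval) and recording
#' a session log plus a per-tick force/pose trace.  This is the engine
#' behind both interactive-style simulation and expert-session replay.
#'
#' @param volume a [labeled_volume].
#' @param materials a [material_table].
#' @param bit a [drill_bit].
#' @param poses n x 3 matrix of device positions (world mm), one per tick.
#' @param pedal logical vector of length n.
#' @param dt tick duration, s.
#' @param max_force device clamp, N.
#' @param record keep a [session_log] (default TRUE).
#' @param chunks optional [chunk_grid] kept in sync.
#' @param seed integer recorded in the session header (provenance only;
#'   the simulation itself is deterministic).
#' @return list with `volume`, `trace` (data.frame), `log`, `stack`
#'   (undo stack), `exposure`, `state`.
#' @export
simulate_trajectory <- function(volume, materials, bit, poses, pedal,
                                dt = 1e-3, max_force = 3.3, record = TRUE,
                                chunks = NULL, seed = 0L) {
  poses <- matrix(as.numeric(poses), ncol = 3)
  n <- nrow(poses)
  stopifnot(length(pedal) == n)
  if (n == 0L) {
    return(list(volume = volume, trace = empty_trace(),
                log = if (record)
                  session_log(volume_hash(volume),
                              materials_hash(materials), dt, bit$radius,
                              seed),
                stack = undo_stack(), exposure = exposure_field(),
                state = NULL))
  }
  state <- haptic_state(poses[1, ], max_force = max_force)
  exposure <- exposure_field()
  stack <- undo_stack()
  log <- if (record)
    session_log(volume_hash(volume), materials_hash(materials), dt,
                bit$radius, seed)
  trace <- vector("list", n)
  stroke_delta <- NULL
  stroke_t0 <- NA_real_
  for (i in seq_len(n)) {
    ped <- isTRUE(pedal[i])
    if (ped && is.null(stroke_delta)) {        # pedal rising edge
      stroke_delta <- data.frame(linear = integer(0), density = numeric(0),
                                 label = integer(0))
      stroke_t0 <- state$t
    }
    res <- haptic_step(state, volume, materials, bit, poses[i, ], ped,
                       dt, exposure, chunks)
    state <- res$state
    volume <- res$volume
    if (ped) stroke_delta <- rbind(stroke_delta, res$delta)
    if (!ped && !is.null(stroke_delta)) {      # pedal falling edge
      push_stroke(stack, stroke_delta, stroke_t0, state$t)
      stroke_delta <- NULL
    }
    if (record) record_step(log, state$t, poses[i, ], ped, bit$radius)
    trace[[i]] <- c(state$t, poses[i, ], state$proxy_pos, state$force,
                    as.numeric(ped), state$contact_label)
  }
  if (!is.null(stroke_delta))
    push_stroke(stack, stroke_delta, stroke_t0, state$t)
  trace <- as.data.frame(do.call(rbind, trace))
  names(trace) <- c("t", "dx", "dy", "dz", "px", "py", "pz",
                    "fx", "fy", "fz", "pedal", "contact")
  list(volume = volume, trace = trace, log = if (record) log,
       stack = stack, exposure = exposure, state = state)
}

empty_trace <- function() {
  structure(as.data.frame(matrix(numeric(0), 0, 12)),
            names = c("t", "dx", "dy", "dz", "px", "py", "pz",
                      "fx", "fy", "fz", "pedal", "contact"))
}

#' Write a force/pose trace as CSV
#'
#' @param trace the trace data.frame from [simulate_trajectory].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(trace, path, row.names = FALSE)
  invisible(path)
}
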