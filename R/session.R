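#' Drilling session log
#'
#' Timestamped device trajectory with pedal state and bit radius, plus a
#' header binding the log to a specific model/material pairing by content
#' hash, so an expert session can only be replayed on its matching
#' (isomorphic) model.
#'
#' @param model_hash hash of the starting [labeled_volume]
#'   (see [volume_hash]).
#' @param materials_hash hash of the [material_table].
#' @param dt tick duration, s.
#' @param bit_radius initial bit radius, mm.
#' @param seed integer recorded for provenance.
#' @return a `session_log` environment.
#' @export
session_log <- function(model_hash, materials_hash, dt, bit_radius,
                        seed = 0L) {
  sl <- new.env(parent = emptyenv())
  sl$header <- list(model_hash = model_hash,
                    materials_hash = materials_hash,
                    dt = dt, bit_radius = bit_radius,
                    seed = as.integer(seed))
  sl$t <- numeric(0)
  sl$pose <- list()
  sl$pedal <- logical(0)
  sl$radius <- numeric(0)
  sl$strokes <- list()        # list of c(start_record, end_record)
  sl$open_stroke <- NA_integer_
  class(sl) <- "session_log"
  sl
}

#' Append one tick to a session log
#'
#' Timestamps must advance by exactly the header `dt`; pedal edges open
#' and close stroke boundary records.
#'
#' @param sl a [session_log].
#' @param t tick timestamp, s.
#' @param pose device position, world mm.
#' @param pedal pedal state.
#' @param radius bit radius this tick (> 0).
#' @return `sl`, invisibly.
#' @export
record_step <- function(sl, t, pose, pedal, radius) {
  n <- length(sl$t)
  if (n > 0L && t <= sl$t[n] + 1e-12)
    stop("non-monotone session timestamp", call. = FALSE)
  if (n > 0L && abs((t - sl$t[n]) - sl$header$dt) > 1e-9)
    stop("session timestamps must advance by dt", call. = FALSE)
  if (radius <= 0) stop("bit radius must be positive", call. = FALSE)
  i <- n + 1L
  sl$t[i] <- t
  sl$pose[[i]] <- as.numeric(pose)
  sl$pedal[i] <- isTRUE(pedal)
  sl$radius[i] <- radius
  prev <- if (n > 0L) sl$pedal[n] else FALSE
  if (isTRUE(pedal) && !prev) sl$open_stroke <- i
  if (!isTRUE(pedal) && prev) {
    sl$strokes[[length(sl$strokes) + 1L]] <- c(sl$open_stroke, n)
    sl$open_stroke <- NA_integer_
  }
  invisible(sl)
}

session_length <- function(sl) length(sl$t)

session_poses <- function(sl) {
  if (!length(sl$pose)) return(matrix(numeric(0), ncol = 3))
  do.call(rbind, sl$pose)
}

#' Session JSON Lines serialization
#'
#' One header object followed by one object per tick; streamable,
#' diffable and append-safe.  `read_session_jsonl(write_session_jsonl(s))`
#' round-trips losslessly.
#'
#' @param sl a [session_log].
#' @param path file path.
#' @return `write_session_jsonl` returns `path` invisibly;
#'   `read_session_jsonl` returns a [session_log].
#' @export
write_session_jsonl <- function(sl, path) {
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  writeLines(jsonlite::toJSON(c(list(type = "header"), sl$header),
                              auto_unbox = TRUE, digits = I(17)), con)
  for (i in seq_len(session_length(sl))) {
    writeLines(jsonlite::toJSON(list(t = sl$t[i], pose = sl$pose[[i]],
                                     pedal = sl$pedal[i],
                                     radius = sl$radius[i]),
                                auto_unbox = TRUE, digits = I(17)), con)
  }
  invisible(path)
}

#' @rdname write_session_jsonl
#' @export
read_session_jsonl <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) stop("empty session file", call. = FALSE)
  hdr <- jsonlite::fromJSON(lines[1])
  if (!identical(hdr$type, "header"))
    stop("session file does not start with a header record", call. = FALSE)
  sl <- session_log(hdr$model_hash, hdr$materials_hash, hdr$dt,
                    hdr$bit_radius, hdr$seed)
  for (ln in lines[-1]) {
    rec <- jsonlite::fromJSON(ln)
    record_step(sl, rec$t, rec$pose, rec$pedal, rec$radius)
  }
  sl
}

session_equal <- function(a, b) {
  identical(a$header, b$header) &&
    isTRUE(all.equal(a$t, b$t, tolerance = 0)) &&
    identical(a$pedal, b$pedal) &&
    isTRUE(all.equal(a$radius, b$radius, tolerance = 0)) &&
    isTRUE(all.equal(session_poses(a), session_poses(b), tolerance = 0)) &&
    identical(a$strokes, b$strokes)
}

#' Passive hand-motion training: exact replay
#'
#' Re-executes every recorded tick on the given model, reproducing the
#' expert's drill movements exactly: the final volume and force trace are
#' bit-identical to the original session's.  Refuses to run when the
#' model or material hash does not match the header (wrong isomorphic
#' model).
#'
#' @param log a [session_log].
#' @param volume the starting [labeled_volume].
#' @param materials a [material_table].
#' @param removal_rate bit removal rate (exposure units/s).
#' @param max_force device clamp, N.
#' @return list with `volume` (final) and `trace`.
#' @export
replay_passive <- function(log, volume, materials, removal_rate = 1,
                           max_force = 3.3) {
  if (!identical(log$header$model_hash, volume_hash(volume)))
    stop("session/model hash mismatch: refusing to replay on a different model",
         call. = FALSE)
  if (!identical(log$header$materials_hash, materials_hash(materials)))
    stop("session/material hash mismatch", call. = FALSE)
  n <- session_length(log)
  bit <- drill_bit(log$header$bit_radius, removal_rate)
  if (n == 0L)
    return(list(volume = volume, trace = empty_trace()))
  res <- simulate_trajectory(volume, materials, bit, session_poses(log),
                             log$pedal, dt = log$header$dt,
                             max_force = max_force, record = FALSE)
  list(volume = res$volume, trace = res$trace)
}

#' Active hand-motion training: guidance cue
#'
#' Matches the trainee's pose to the expert trajectory by monotonic
#' nearest-point search (the matched index never decreases over a
#' session) and points toward the expert pose `lookahead` ticks ahead,
#' emulating the on-screen guidance arrows of active training.
#'
#' @param expert a [session_log] (non-empty).
#' @param lookahead look-ahead in records (default 50 ticks).
#' @return a `guidance_tracker` environment; pass it to [guidance].
#' @export
guidance_tracker <- function(expert, lookahead = 50L) {
  if (session_length(expert) == 0L)
    stop("expert log is empty", call. = FALSE)
  if (lookahead < 1L) stop("lookahead must be >= 1", call. = FALSE)
  g <- new.env(parent = emptyenv())
  g$poses <- session_poses(expert)
  g$h <- as.integer(lookahead)
  g$index <- 1L
  class(g) <- "guidance_tracker"
  g
}

#' @rdname guidance_tracker
#' @param tracker a `guidance_tracker`.
#' @param pose current trainee device position, world mm.
#' @return `guidance` returns a list: `direction` (unit vector, or zero
#'   when the target has been reached), `distance` (mm) and `index` (the
#'   matched expert record).
#' @export
guidance <- function(tracker, pose) {
  P <- tracker$poses
  n <- nrow(P)
  cand <- tracker$index:n
  d2 <- rowSums(sweep(P[cand, , drop = FALSE], 2, as.numeric(pose), `-`)^2)
  i <- cand[which.min(d2)]
  tracker$index <- i
  target <- P[min(i + tracker$h, n), ]
  delta <- target - as.numeric(pose)
  dist <- sqrt(sum(delta^2))
  dir <- if (dist > 1e-12) delta / dist else c(0, 0, 0)
  list(direction = dir, distance = dist, index = i)
}

#' Session summary report
#'
#' Per-label removed-voxel counts, stroke count and session duration, as
#' a plain list suitable for JSON export.
#'
#' @param stack an [undo_stack] after simulation.
#' @param log the matching [session_log] (or `NULL`).
#' @return a list.
#' @export
session_summary <- function(stack, log = NULL) {
  labs <- integer(0)
  for (rec in stack$strokes) labs <- c(labs, rec$delta$label)
  tab <- table(labs)
  list(strokes = length(stack$strokes),
       voxels_removed = length(labs),
       removed_by_label = as.list(structure(as.integer(tab),
                                            names = names(tab))),
       duration_s = if (!is.null(log) && session_length(log))
         max(log$t) - min(log$t) + log$header$dt else 0)
}
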