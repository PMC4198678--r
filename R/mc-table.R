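# Marching-cubes case table, generated once at first use.
#
# Cube corners 0..7 sit at offsets (c & 1, (c >> 1) & 1, (c >> 2) & 1) from
# the cell's lower voxel.  Edges 0..11: x-edges based at corners {0,2,4,6},
# y-edges at {0,1,4,5}, z-edges at {0,1,2,3} (same enumeration as src/core.cpp).
#
# The table is built constructively rather than transcribed: on every cube
# face the corner signs determine the contour segments joining edge
# crossings, with the ambiguous checkerboard face resolved by a fixed rule
# (always cut off the above-iso corners).  Both cells sharing a face see the
# same corner signs and hence emit the same segments, so the assembled
# surface is crack-free by construction; segments chain into closed loops
# which are fan-triangulated and oriented with normals pointing away from
# the solid (above-iso) region.  No asymptotic decider is applied: on
# ambiguous configurations the rule may pick a topology the true field does
# not have, the classic marching-cubes limitation.

# 8x8 matrix mapping a corner pair to its cube-edge id (0-based), NA if the
# corners are not edge-adjacent.
mc_edge_lookup <- function() {
  base <- c(0L, 2L, 4L, 6L, 0L, 1L, 4L, 5L, 0L, 1L, 2L, 3L)
  axis <- c(0L, 0L, 0L, 0L, 1L, 1L, 1L, 1L, 2L, 2L, 2L, 2L)
  m <- matrix(NA_integer_, 8, 8)
  for (e in seq_len(12)) {
    a <- base[e]
    b <- bitwOr(a, bitwShiftL(1L, axis[e]))
    m[a + 1L, b + 1L] <- e - 1L
    m[b + 1L, a + 1L] <- e - 1L
  }
  m
}

# Directed contour segments (source -> target cube-edge ids) on one face.
# `corners` is the face's corner cycle, counter-clockwise as seen from
# OUTSIDE the cube, so the right-hand rule over a chained loop yields
# triangle normals pointing away from the solid (above-iso) region.  Each
# crossing cycle-edge is "entering" (outside -> inside corner) or
# "exiting"; every entering crossing is paired with the next crossing
# around the cycle (necessarily exiting), which on the 4-crossing
# checkerboard face cuts off each inside corner — the fixed ambiguity
# rule.  Both cells sharing a face walk its cycle in opposite senses and
# therefore emit the same segments with opposite directions: the surface
# is crack-free and globally consistently oriented by construction.
mc_face_segments <- function(corners, inside, elookup) {
  n <- 4L
  nxt_c <- function(i) if (i == n) 1L else i + 1L
  entering <- exiting <- logical(n)
  for (i in seq_len(n)) {
    a <- inside[corners[i] + 1L]
    b <- inside[corners[nxt_c(i)] + 1L]
    entering[i] <- !a && b
    exiting[i] <- a && !b
  }
  edge_id <- function(i)
    elookup[corners[i] + 1L, corners[nxt_c(i)] + 1L]
  segs <- list()
  for (i in which(entering)) {
    j <- nxt_c(i)
    while (!entering[j] && !exiting[j]) j <- nxt_c(j)
    segs[[length(segs) + 1L]] <- c(edge_id(i), edge_id(j))
  }
  segs
}

# which of the 6 faces each cube edge lies on (12 x 2)
mc_edge_faces <- function(faces, elookup) {
  ef <- vector("list", 12L)
  for (fi in seq_along(faces)) {
    f <- faces[[fi]]
    for (i in 1:4) {
      e <- elookup[f[i] + 1L, f[if (i == 4) 1 else i + 1] + 1L]
      ef[[e + 1L]] <- c(ef[[e + 1L]], fi)
    }
  }
  ef
}

# Fan-triangulate a loop from a root chosen so that no fan diagonal lies
# inside a cube face: mesh edges shared between adjacent cells are then
# exactly the face contour segments, and every interior fan diagonal is
# private to its cell — the assembled surface is 2-manifold.
mc_fan <- function(loop, edge_faces) {
  k <- length(loop)
  for (r in seq_len(k)) {
    rot <- c(loop[r:k], loop[seq_len(r - 1L)])
    ok <- TRUE
    if (k > 3L) {
      for (i in 3:(k - 1L)) {
        if (length(intersect(edge_faces[[rot[1L] + 1L]],
                             edge_faces[[rot[i] + 1L]]))) {
          ok <- FALSE
          break
        }
      }
    }
    if (ok) {
      tris <- integer(0)
      for (i in 2:(k - 1L))
        tris <- c(tris, rot[1L], rot[i], rot[i + 1L])
      return(tris)
    }
  }
  stop("no face-free fan root for loop: ", paste(loop, collapse = ","))
}

mc_case_triangles <- function(config, faces, elookup, edge_faces) {
  inside <- bitwAnd(bitwShiftR(config, 0:7), 1L) == 1L
  if (!any(inside) || all(inside)) return(integer(0))
  segs <- list()
  for (f in faces) segs <- c(segs, mc_face_segments(f, inside, elookup))
  if (!length(segs)) return(integer(0))
  segmat <- do.call(rbind, segs)
  nxt_of <- integer(12)
  nxt_of[segmat[, 1L] + 1L] <- segmat[, 2L]
  used <- rep(FALSE, nrow(segmat))
  tris <- integer(0)
  repeat {
    s0 <- which(!used)[1L]
    if (is.na(s0)) break
    loop <- segmat[s0, 1L]
    cur <- loop
    repeat {
      used[segmat[, 1L] == cur] <- TRUE
      nx <- nxt_of[cur + 1L]
      if (nx == loop[1L]) break
      loop <- c(loop, nx)
      cur <- nx
    }
    tris <- c(tris, mc_fan(loop, edge_faces))
  }
  tris
}

# Returns list(offsets = int[257] 0-based into edges, edges = int vector of
# cube-edge ids, flattened triangle triples).
mc_table <- function() {
  tab <- get0("mc_table_cache", envir = .otodrill_env)
  if (!is.null(tab)) return(tab)
  # corner cycles counter-clockwise as seen from outside the cube
  faces <- list(c(0L, 4L, 6L, 2L),   # x = 0 (outward -x)
                c(1L, 3L, 7L, 5L),   # x = 1 (outward +x)
                c(0L, 1L, 5L, 4L),   # y = 0 (outward -y)
                c(2L, 6L, 7L, 3L),   # y = 1 (outward +y)
                c(0L, 2L, 3L, 1L),   # z = 0 (outward -z)
                c(4L, 5L, 7L, 6L))   # z = 1 (outward +z)
  elookup <- mc_edge_lookup()
  edge_faces <- mc_edge_faces(faces, elookup)
  cases <- lapply(0:255, mc_case_triangles, faces = faces,
                  elookup = elookup, edge_faces = edge_faces)
  lens <- vapply(cases, length, integer(1))
  tab <- list(offsets = c(0L, cumsum(lens)),
              edges = as.integer(unlist(cases)))
  assign("mc_table_cache", tab, envir = .otodrill_env)
  tab
}
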