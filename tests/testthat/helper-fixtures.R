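# Shared fixtures and independent oracles.  Everything is generated in
# code; no binary fixtures are stored.

# tiny all-void volume
tiny_volume <- function(n = 4, spacing = 1) {
  labeled_volume(array(0, rep(n, 3)), spacing = rep(spacing, 3))
}

# binary random volume with empty boundary shell (closed occupied set)
random_binary_volume <- function(n = 10, p = 0.4) {
  lab <- array(as.integer(stats::runif(n^3) < p), rep(n, 3))
  lab[c(1, n), , ] <- 0L
  lab[, c(1, n), ] <- 0L
  lab[, , c(1, n)] <- 0L
  labeled_volume(array(as.numeric(lab), rep(n, 3)), label = lab)
}

# volumes-identical check (the carrier of every "bitwise" assertion)
volumes_identical <- function(a, b) {
  identical(a$density, b$density) && identical(a$label, b$label) &&
    identical(a$spacing, b$spacing) && identical(a$origin, b$origin)
}

# 0-based ijk <-> linear helpers mirroring the package's layout
lin_of <- function(dims, ijk) {
  ijk <- matrix(as.integer(ijk), ncol = 3)
  1L + ijk[, 1] + dims[1] * (ijk[, 2] + dims[2] * ijk[, 3])
}

# Independent point-in-mesh oracle: generalized winding number via summed
# solid angles (van Oosterom & Strackee), entirely separate from the
# package's ray-parity voxelizer.
winding_inside <- function(mesh, pts) {
  V <- mesh$vertices
  TRm <- mesh$triangles
  total <- numeric(nrow(pts))
  for (t in seq_len(nrow(TRm))) {
    A <- matrix(V[TRm[t, 1], ], nrow(pts), 3, byrow = TRUE) - pts
    B <- matrix(V[TRm[t, 2], ], nrow(pts), 3, byrow = TRUE) - pts
    C <- matrix(V[TRm[t, 3], ], nrow(pts), 3, byrow = TRUE) - pts
    la <- sqrt(rowSums(A^2)); lb <- sqrt(rowSums(B^2)); lc <- sqrt(rowSums(C^2))
    num <- rowSums(A * cbind(B[, 2] * C[, 3] - B[, 3] * C[, 2],
                             B[, 3] * C[, 1] - B[, 1] * C[, 3],
                             B[, 1] * C[, 2] - B[, 2] * C[, 1]))
    den <- la * lb * lc + rowSums(A * B) * lc + rowSums(A * C) * lb +
      rowSums(B * C) * la
    total <- total + 2 * atan2(num, den)
  }
  abs(total) > 2 * pi
}

# Brute-force drilled set: union over trajectory samples of drillable
# voxel centres within the bit radius (exhaustive distance test).
brute_drill_set <- function(volume, materials, centers, radius) {
  d <- volume$dims
  ijk <- as.matrix(expand.grid(i = 0:(d[1] - 1), j = 0:(d[2] - 1),
                               k = 0:(d[3] - 1)))
  w <- voxel_to_world(volume, ijk)
  lin <- lin_of(d, ijk)
  lab <- volume$label[lin]
  drl_labels <- materials$label[materials$drillable]
  hit <- rep(FALSE, nrow(ijk))
  centers <- matrix(centers, ncol = 3)
  for (s in seq_len(nrow(centers))) {
    hit <- hit | rowSums(sweep(w, 2, centers[s, ], `-`)^2) <= radius^2
  }
  sort(lin[hit & lab %in% drl_labels])
}

# hand-built closed axis-aligned cuboid mesh [lo, hi] with outward normals
box_mesh <- function(lo, hi) {
  g <- as.matrix(expand.grid(x = c(lo[1], hi[1]), y = c(lo[2], hi[2]),
                             z = c(lo[3], hi[3])))
  quad <- function(a, b, c, d) rbind(c(a, b, c), c(a, c, d))
  TRm <- rbind(quad(1, 3, 4, 2),   # z = lo
               quad(5, 6, 8, 7),   # z = hi
               quad(1, 2, 6, 5),   # y = lo
               quad(3, 7, 8, 4),   # y = hi
               quad(1, 5, 7, 3),   # x = lo
               quad(2, 4, 8, 6))   # x = hi
  triangle_mesh(g, TRm)
}

# JSONL trajectory file for the CLI `simulate` subcommand
write_cli_trajectory <- function(path, poses, pedal, dt = 1e-3) {
  con <- file(path, "w")
  writeLines(sprintf('{"type":"header","dt":%.17g}', dt), con)
  for (i in seq_len(nrow(poses))) {
    writeLines(sprintf('{"pose":[%.17g,%.17g,%.17g],"pedal":%s}',
                       poses[i, 1], poses[i, 2], poses[i, 3],
                       if (pedal[i]) "true" else "false"), con)
  }
  close(con)
  invisible(path)
}

file_identical <- function(a, b) {
  identical(readBin(a, "raw", file.size(a)),
            readBin(b, "raw", file.size(b)))
}

# run a proxy-only (no drilling) device sweep; returns per-tick proxy
# positions and forces
sweep_proxy <- function(volume, materials, poses, max_force = 3.3) {
  n <- nrow(poses)
  P <- matrix(NA_real_, n, 3)
  FF <- matrix(NA_real_, n, 3)
  contact <- integer(n)
  state <- haptic_state(poses[1, ], max_force = max_force)
  for (i in seq_len(n)) {
    up <- update_proxy(volume, state$proxy_pos, poses[i, ])
    state$proxy_pos <- up$proxy
    state$device_pos <- poses[i, ]
    P[i, ] <- up$proxy
    contact[i] <- up$contact_label
    FF[i, ] <- compute_force(state, materials, up$contact_label)
  }
  list(proxy = P, force = FF, contact = contact)
}
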