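# Synthetic temporal-bone-like phantoms with analytic ground truth.  The
# paper's microCT specimens are not deposited, so tests and examples run on
# generated volumes that reproduce the features the engine cares about: a
# cortical shell, trabecular interior honeycombed with air-cell voids,
# tubular vessel/nerve analogues, a thin dural-plate analogue and small
# ossicle-like ellipsoids.

with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Phantom specification
#'
#' Stated-world defaults: a 64^3 grid at 0.5 mm spacing (the fast-CI
#' size; pass `dims = rep(128L, 3)` for the showcase variant), an
#' ellipsoidal cortical shell 2 mm thick at 1900 HU around a 700 HU
#' trabecular interior, 40 air cells of 0.5-1.2 mm radius, one curved
#' vessel-analogue tube, one thin dural-plate analogue and two
#' ossicle-like ellipsoids.
#'
#' @param dims grid dimensions (voxels).
#' @param spacing isotropic voxel spacing, mm.
#' @param seed integer RNG seed (air-cell placement).
#' @param shell_thickness cortical shell thickness, mm.
#' @param shell_density,trabecular_density HU-like densities.
#' @param n_air_cells number of non-overlapping air-cell voids.
#' @param air_cell_radius radius range, mm.
#' @param with_structures include tube/plate/ossicle analogues.
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(dims = rep(64L, 3), spacing = 0.5, seed = 1L,
                         shell_thickness = 2, shell_density = 1900,
                         trabecular_density = 700, n_air_cells = 40L,
                         air_cell_radius = c(0.5, 1.2),
                         with_structures = TRUE) {
  structure(list(dims = as.integer(dims), spacing = rep(spacing, 3),
                 seed = as.integer(seed),
                 shell_thickness = shell_thickness,
                 shell_density = shell_density,
                 trabecular_density = trabecular_density,
                 n_air_cells = as.integer(n_air_cells),
                 air_cell_radius = air_cell_radius,
                 with_structures = isTRUE(with_structures)),
            class = "phantom_spec")
}

phantom_grid_coords <- function(dims, spacing) {
  list(x = (seq_len(dims[1]) - 1) * spacing[1],
       y = (seq_len(dims[2]) - 1) * spacing[2],
       z = (seq_len(dims[3]) - 1) * spacing[3])
}

# normalized ellipsoid radius field rho(x): rho = 1 on the outer surface
ellipsoid_rho <- function(g, centre, semi) {
  X <- outer(((g$x - centre[1]) / semi[1])^2,
             ((g$y - centre[2]) / semi[2])^2, `+`)
  outer(X, ((g$z - centre[3]) / semi[3])^2, `+`) |> sqrt()
}

#' Generate a temporal-bone-like phantom
#'
#' Deterministic for a given spec/seed.  Returns the labeled volume, a
#' matching material table and a ground-truth list holding exact
#' per-label voxel counts, per-air-cell centre counts and the analytic
#' volumes of every primitive.  Air cells are placed by seeded
#' dart-throwing with overlap rejection (bounded retries; an error names
#' the cell that could not be placed), so per-cell counts add exactly.
#'
#' @param spec a [phantom_spec].
#' @return list with `volume` ([labeled_volume]), `materials`
#'   ([material_table]) and `truth`.
#' @export
make_phantom <- function(spec = phantom_spec()) {
  d <- spec$dims; h <- spec$spacing
  g <- phantom_grid_coords(d, h)
  centre <- (d - 1) / 2 * h
  semi <- (d - 1) / 2 * h * 0.9
  rho <- ellipsoid_rho(g, centre, semi)
  rho_in <- 1 - spec$shell_thickness / mean(semi)
  density <- array(0, d)
  label <- array(0L, d)
  shell <- rho <= 1 & rho > rho_in
  interior <- rho <= rho_in
  label[shell] <- 1L
  density[shell] <- spec$shell_density
  label[interior] <- 2L
  density[interior] <- spec$trabecular_density
  truth <- list(shell_voxels = sum(shell),
                interior_voxels_initial = sum(interior),
                centre = centre, semi_axes = semi, rho_inner = rho_in,
                analytic = list(
                  shell_volume_mm3 = 4 / 3 * pi *
                    (prod(semi) - prod(semi) * rho_in^3)))

  xg <- array(rep(g$x, times = d[2] * d[3]), d)
  yg <- array(rep(rep(g$y, each = d[1]), times = d[3]), d)
  zg <- array(rep(g$z, each = d[1] * d[2]), d)

  structures <- list()
  if (spec$with_structures) {
    # vessel-analogue tube: vertical helix-ish polyline through the interior
    tpath <- cbind(centre[1] + 0.25 * semi[1] *
                     cos(seq(0, pi, length.out = 24)),
                   centre[2] + 0.25 * semi[2] *
                     sin(seq(0, pi, length.out = 24)),
                   seq(centre[3] - 0.55 * semi[3],
                       centre[3] + 0.55 * semi[3], length.out = 24))
    tube_r <- 1.2
    dmin <- array(Inf, d)
    for (s in seq_len(nrow(tpath) - 1L)) {
      a <- tpath[s, ]; b <- tpath[s + 1L, ]
      ab <- b - a; ab2 <- sum(ab^2)
      tpar <- ((xg - a[1]) * ab[1] + (yg - a[2]) * ab[2] +
                 (zg - a[3]) * ab[3]) / ab2
      tpar[tpar < 0] <- 0; tpar[tpar > 1] <- 1
      dd <- (xg - a[1] - tpar * ab[1])^2 + (yg - a[2] - tpar * ab[2])^2 +
        (zg - a[3] - tpar * ab[3])^2
      dmin <- pmin(dmin, dd)
    }
    tube <- dmin <= tube_r^2 & interior
    label[tube] <- 3L
    density[tube] <- 300
    structures$tube <- list(radius = tube_r, path = tpath,
                            voxels = sum(tube))

    # dural-plate analogue: one-voxel-thick plate in the upper interior
    kz <- round(centre[3] / h[3] + 0.35 * semi[3] / h[3])
    plate <- array(FALSE, d)
    plate[, , kz + 1L] <- rho[, , kz + 1L] <= (rho_in - 0.15) &
      label[, , kz + 1L] == 2L
    label[plate] <- 5L
    density[plate] <- 400
    structures$plate <- list(k = kz, voxels = sum(plate))

    # ossicle analogues: two small ellipsoids
    oss <- list(list(c(-0.3, 0.25, 0.1), c(1.2, 0.8, 0.8)),
                list(c(-0.25, -0.3, 0.0), c(0.9, 0.9, 1.3)))
    ovox <- 0L
    for (o in oss) {
      oc <- centre + o[[1]] * semi
      os <- o[[2]]
      sel <- ((xg - oc[1]) / os[1])^2 + ((yg - oc[2]) / os[2])^2 +
        ((zg - oc[3]) / os[3])^2 <= 1
      sel <- sel & label == 2L
      label[sel] <- 6L
      density[sel] <- 1800
      ovox <- ovox + sum(sel)
    }
    structures$ossicles <- list(n = length(oss), voxels = ovox)
  }

  # air cells: seeded dart throwing, rejected unless the whole ball plus a
  # one-voxel margin sits in still-trabecular space
  cells <- NULL
  if (spec$n_air_cells > 0L) {
    cells <- with_local_seed(spec$seed, {
      placed <- list()
      for (ci in seq_len(spec$n_air_cells)) {
        ok <- FALSE
        for (try in seq_len(500L)) {
          r <- runif(1, spec$air_cell_radius[1], spec$air_cell_radius[2])
          cc <- centre + (runif(3, -1, 1) * (rho_in - 0.1)) * semi
          if (sqrt(sum(((cc - centre) / semi)^2)) > rho_in - r / min(semi) - 0.05)
            next
          clash <- FALSE
          for (p in placed) {
            if (sqrt(sum((cc - p$centre)^2)) < r + p$r + min(h)) {
              clash <- TRUE; break
            }
          }
          if (clash) next
          # every voxel centre within r + one voxel must still be trabecular
          lo <- pmax(floor((cc - r - min(h)) / h), 0)
          hi <- pmin(ceiling((cc + r + min(h)) / h), d - 1)
          sub <- expand.grid(i = lo[1]:hi[1], j = lo[2]:hi[2],
                             k = lo[3]:hi[3])
          w <- cbind(sub$i * h[1], sub$j * h[2], sub$k * h[3])
          d2 <- rowSums(sweep(w, 2, cc, `-`)^2)
          near <- d2 <= (r + min(h))^2
          lin <- ijk_to_linear(d, as.matrix(sub)[near, , drop = FALSE])
          if (any(label[lin] != 2L)) next
          inside <- d2[near] <= r^2
          placed[[ci]] <- list(centre = cc, r = r,
                               lin = lin[inside],
                               count = sum(inside))
          ok <- TRUE
          break
        }
        if (!ok)
          stop("could not place air cell #", ci,
               " without collision after 500 tries", call. = FALSE)
      }
      placed
    })
    for (p in cells) {
      label[p$lin] <- 0L
      density[p$lin] <- 0
    }
  }

  vol <- labeled_volume(density, label = label, spacing = h,
                        origin = c(0, 0, 0))
  truth$structures <- structures
  truth$air_cells <- if (!is.null(cells))
    data.frame(x = vapply(cells, function(p) p$centre[1], 1),
               y = vapply(cells, function(p) p$centre[2], 1),
               z = vapply(cells, function(p) p$centre[3], 1),
               r = vapply(cells, function(p) p$r, 1),
               count = vapply(cells, function(p) p$count, 1))
  truth$air_cell_voxels <- if (!is.null(cells))
    sum(truth$air_cells$count) else 0L
  truth$label_counts <- table(label[label != 0L])
  list(volume = vol, materials = default_materials(), truth = truth)
}

#' Anti-aliased solid sphere phantom
#'
#' Boundary voxels carry partial-volume densities (as a CT scan of a
#' smooth object would), so surfacing the density field at
#' `density / 2` recovers the sphere with sub-voxel accuracy.  The label
#' grid is the exact centre-in-sphere digitization.
#'
#' @param radius sphere radius, mm.
#' @param spacing voxel spacing, mm.
#' @param density material density (HU-like).
#' @param label label id.
#' @param margin empty border, voxels.
#' @return list with `volume`, `truth` (centre, analytic volume, exact
#'   occupied-voxel count).
#' @export
make_sphere_phantom <- function(radius = 20, spacing = 0.5,
                                density = 1500, label = 1L, margin = 3L) {
  n <- ceiling(2 * radius / spacing) + 2L * margin + 1L
  d <- rep(as.integer(n), 3)
  h <- rep(spacing, 3)
  g <- phantom_grid_coords(d, h)
  centre <- (d - 1) / 2 * h
  r2 <- outer(outer((g$x - centre[1])^2, (g$y - centre[2])^2, `+`),
              (g$z - centre[3])^2, `+`)
  dist <- sqrt(r2)
  frac <- pmin(pmax(0.5 + (radius - dist) / spacing, 0), 1)
  lab <- array(0L, d)
  lab[dist <= radius] <- as.integer(label)
  vol <- labeled_volume(array(density * frac, d), label = lab,
                        spacing = h, origin = c(0, 0, 0))
  list(volume = vol,
       truth = list(centre = centre, radius = radius,
                    analytic_volume = 4 / 3 * pi * radius^3,
                    occupied_voxels = sum(lab != 0L)))
}

#' Anti-aliased solid torus phantom (genus 1)
#'
#' @param R major (ring) radius, mm.
#' @param r minor (tube) radius, mm.
#' @param spacing voxel spacing, mm.
#' @param density material density.
#' @param label label id.
#' @param margin empty border, voxels.
#' @return list with `volume`, `truth` (analytic volume
#'   `2 pi^2 R r^2`, exact occupied count).
#' @export
make_torus_phantom <- function(R = 9, r = 4, spacing = 0.5,
                               density = 1500, label = 1L, margin = 3L) {
  nxy <- ceiling(2 * (R + r) / spacing) + 2L * margin + 1L
  nz <- ceiling(2 * r / spacing) + 2L * margin + 1L
  d <- as.integer(c(nxy, nxy, nz))
  h <- rep(spacing, 3)
  g <- phantom_grid_coords(d, h)
  centre <- (d - 1) / 2 * h
  ring <- sqrt(outer((g$x - centre[1])^2, (g$y - centre[2])^2, `+`)) - R
  dist <- sqrt(outer(ring^2, (g$z - centre[3])^2, `+`))
  frac <- pmin(pmax(0.5 + (r - dist) / spacing, 0), 1)
  lab <- array(0L, d)
  lab[dist <= r] <- as.integer(label)
  vol <- labeled_volume(array(density * frac, d), label = lab,
                        spacing = h, origin = c(0, 0, 0))
  list(volume = vol,
       truth = list(analytic_volume = 2 * pi^2 * R * r^2,
                    occupied_voxels = sum(lab != 0L)))
}

#' Flat-wall phantom (with optional pre-drilled channel)
#'
#' A slab of the given voxel thickness spanning the full x/y extent,
#' centred in z; the fixture behind the thin-wall pop-through and
#' constrained-channel haptics tests.  With `channel_width` set, a
#' straight channel of that many voxels (in x) is carved through the
#' whole slab depth, running the full y length.
#'
#' @param thickness slab thickness, voxels (>= 1).
#' @param nx,ny,nz grid dimensions.
#' @param spacing voxel spacing, mm.
#' @param density slab density.
#' @param label slab label id.
#' @param channel_width optional channel width in voxels.
#' @return list with `volume`, `truth` (occupied count, slab z-range,
#'   channel voxel count and x-range if carved).
#' @export
make_wall_phantom <- function(thickness = 2L, nx = 32L, ny = 32L,
                              nz = 24L, spacing = 0.5, density = 1500,
                              label = 1L, channel_width = NULL) {
  if (thickness < 1L) stop("thickness must be >= 1 voxel", call. = FALSE)
  d <- as.integer(c(nx, ny, nz))
  h <- rep(spacing, 3)
  lab <- array(0L, d)
  thickness <- as.integer(thickness)
  k0 <- (d[3] - thickness) %/% 2L        # 0-based first slab layer
  kk <- (k0 + 1L):(k0 + thickness)
  lab[, , kk] <- as.integer(label)
  truth <- list(occupied_voxels = thickness * d[1] * d[2],
                slab_k = c(k0, k0 + thickness - 1L))
  if (!is.null(channel_width)) {
    w <- as.integer(channel_width)
    i0 <- (d[1] - w) %/% 2L
    ii <- (i0 + 1L):(i0 + w)
    lab[ii, , kk] <- 0L
    truth$channel_voxels <- w * thickness * d[2]
    truth$channel_i <- c(i0, i0 + w - 1L)
    truth$occupied_voxels <- truth$occupied_voxels - truth$channel_voxels
  }
  den <- array(0, d)
  den[lab != 0L] <- density
  list(volume = labeled_volume(den, label = lab, spacing = h,
                               origin = c(0, 0, 0)),
       truth = truth)
}
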