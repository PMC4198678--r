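test_that("marching_cubes handles trivial and topological base cases", {
  expect_identical(nrow(marching_cubes(tiny_volume(4))$triangles), 0L)

  # iso outside the field range is an empty mesh, not an error
  u <- labeled_volume(array(1, c(4, 4, 4)),
                      label = array(1L, c(4, 4, 4)))
  expect_identical(nrow(marching_cubes(u, iso = 5,
                                       field = "density")$triangles), 0L)

  # single occupied voxel: closed surface with Euler characteristic 2
  lab <- array(0L, c(3, 3, 3)); lab[2, 2, 2] <- 1L
  v <- labeled_volume(array(as.numeric(lab), c(3, 3, 3)), label = lab)
  m <- marching_cubes(v)
  expect_true(mesh_is_closed(m))
  expect_identical(mesh_euler(m), 2L)
  expect_true(all(m$vertex_labels == 1L))
})

test_that("extracted surfaces of interior solids are closed oriented 2-manifolds", {
  set.seed(11)
  for (rep in 1:10) {
    v <- random_binary_volume(n = sample(7:11, 1),
                              p = stats::runif(1, 0.2, 0.7))
    m <- marching_cubes(v)
    if (nrow(m$triangles)) expect_true(mesh_is_closed(m))
  }
  # genus from the phantom family: sphere g=0, torus g=1
  sp <- make_sphere_phantom(8, 0.5)
  ms <- marching_cubes(sp$volume, iso = 750, field = "density")
  expect_true(mesh_is_closed(ms))
  expect_identical(mesh_euler(ms), 2L)
  to <- make_torus_phantom(6, 2.5, 0.5)
  mt <- marching_cubes(to$volume, iso = 750, field = "density")
  expect_true(mesh_is_closed(mt))
  expect_identical(mesh_euler(mt), 0L)
})

test_that("mesh volumes track analytic phantom volumes", {
  sp <- make_sphere_phantom(8, 0.5)
  m <- marching_cubes(sp$volume, iso = 750, field = "density")
  expect_lt(abs(mesh_volume(m) - sp$truth$analytic_volume),
            0.01 * sp$truth$analytic_volume)
  # vertex normals are unit length
  nl <- sqrt(rowSums(m$vertex_normals^2))
  expect_lt(max(abs(nl - 1)), 1e-6)
})

test_that("incremental update equals full recompute (oracle equivalence)", {
  set.seed(21)
  ph <- make_phantom(phantom_spec(dims = rep(40L, 3), n_air_cells = 10L))
  v <- ph$volume
  cg <- chunk_grid(v)
  expect_true(mesh_sets_equal(update_dirty(cg, v), marching_cubes(v)))

  # empty edit set: no recomputation, identical mesh
  rev0 <- cg$revision
  m <- update_dirty(cg, v)
  expect_identical(cg$revision, rev0)
  expect_true(mesh_sets_equal(m, marching_cubes(v)))

  # one interior removal
  occ <- which(v$label != 0L)
  e <- occ[[1000]]
  v$density[e] <- 0; v$label[e] <- 0L
  ijk <- matrix(c((e - 1L) %% 40L,
                  ((e - 1L) %/% 40L) %% 40L,
                  (e - 1L) %/% 1600L), 1)
  m1 <- update_dirty(cg, v, ijk)
  expect_true(mesh_sets_equal(m1, marching_cubes(v), tol = 1e-12))

  # interleaved random removals
  eds <- sample(which(v$label != 0L), 60)
  for (e in eds) {
    v$density[e] <- 0; v$label[e] <- 0L
    ijk <- matrix(c((e - 1L) %% 40L, ((e - 1L) %/% 40L) %% 40L,
                    (e - 1L) %/% 1600L), 1)
    update_dirty(cg, v, ijk)
  }
  expect_true(mesh_sets_equal(update_dirty(cg, v), marching_cubes(v),
                              tol = 1e-12))
})

test_that("voxel edits dirty the owning chunk and cell-sharing neighbours", {
  lab <- array(1L, c(34, 34, 34))
  v <- labeled_volume(array(1, c(34, 34, 34)), label = lab)
  cg <- chunk_grid(v, chunk_size = 16L)
  expect_true(all(!cg$dirty))
  # a voxel on the chunk boundary (cell 15|16 seam) touches two chunks in x
  mark_dirty(cg, matrix(c(16L, 3L, 3L), 1))
  expect_identical(sum(cg$dirty), 2L)
})

test_that("HC smoothing is identity-safe, shape-preserving and anti-shrink", {
  sp <- make_sphere_phantom(6, 0.5)
  m <- marching_cubes(sp$volume)   # voxellated (staircase) sphere

  expect_identical(hc_smooth(m, smoothing_params(iterations = 0L)), m)

  hc <- hc_smooth(m, smoothing_params(0, 0.5, 10L))
  lap <- laplacian_smooth(m, 10L)
  # connectivity and vertex count unchanged
  expect_identical(hc$triangles, m$triangles)
  expect_identical(nrow(hc$vertices), nrow(m$vertices))
  # HC shrinks strictly less than plain Laplacian
  v0 <- abs(mesh_volume(m))
  expect_lt(v0 - abs(mesh_volume(hc)), v0 - abs(mesh_volume(lap)))
  # smoothing reduces mean dihedral roughness
  expect_lt(mesh_dihedral_roughness(hc), mesh_dihedral_roughness(m))

  # planar grid is a Laplacian fixed point: interior vertices do not move
  g <- expand.grid(x = 0:5, y = 0:5)
  V <- cbind(g$x, g$y, 0)
  tri <- list()
  for (i in 0:4) for (j in 0:4) {
    a <- i + j * 6 + 1
    tri[[length(tri) + 1]] <- c(a, a + 1, a + 7)
    tri[[length(tri) + 1]] <- c(a, a + 7, a + 6)
  }
  pm <- triangle_mesh(V, do.call(rbind, tri))
  ps <- hc_smooth(pm, smoothing_params(0, 0.5, 10L))
  expect_lt(max(abs(ps$vertices[, 3])), 1e-9)

  # isolated vertices are left unmoved
  iso_m <- triangle_mesh(rbind(V, c(99, 99, 99)), do.call(rbind, tri))
  iso_s <- hc_smooth(iso_m, smoothing_params(0, 0.5, 5L))
  expect_identical(iso_s$vertices[37, ], c(99, 99, 99))

  expect_error(smoothing_params(alpha = 2), "\\[0, 1\\]")
})
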