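test_that("volume files round-trip bit-identically in every dialect", {
  set.seed(101)
  d <- c(9L, 7L, 5L)
  # dyadic spacing/origin so even NIfTI-1 (whose header stores geometry
  # as float32) round-trips bit-exactly; the NRRD dialect additionally
  # proves exact non-dyadic geometry in the hand-written-header test
  vol <- labeled_volume(array(rnorm(prod(d), 500, 300), d),
                        label = array(sample(0:3, prod(d), TRUE), d),
                        spacing = c(0.25, 0.5, 0.125),
                        origin = c(-1.25, 3, 0.5))
  paths <- c(nrrd = "v.nrrd", nifti = "v.nii", nifti_gz = "v.nii.gz",
             rawjson = "v.json")
  for (p in paths) {
    fp <- file.path(withr::local_tempdir(), p)
    write_volume(vol, fp)
    back <- read_volume(fp)
    expect_true(volumes_identical(back, vol), label = p)
    expect_identical(tabulate(back$label + 1L), tabulate(vol$label + 1L))
  }
  # gzip-encoded NRRD
  fp <- file.path(withr::local_tempdir(), "v.nrrd")
  write_volume(vol, fp, gzip = TRUE)
  expect_true(volumes_identical(read_volume(fp), vol))
  # all-zero label grid: companion omitted, round trip still exact
  v0 <- labeled_volume(vol$density, spacing = vol$spacing,
                       origin = vol$origin)
  fp0 <- file.path(withr::local_tempdir(), "z.nrrd")
  write_volume(v0, fp0)
  expect_false(file.exists(sub("\\.nrrd$", "-labels.nrrd", fp0)))
  expect_true(volumes_identical(read_volume(fp0), v0))
})

test_that("read_volume reports header geometry exactly and rejects bad headers", {
  # hand-written NRRD fixture, independent of write_volume
  fp <- file.path(withr::local_tempdir(), "hand.nrrd")
  con <- file(fp, "wb")
  writeLines(c("NRRD0004", "type: double", "dimension: 3",
               "sizes: 2 2 2",
               "spacings: 0.14 0.14 0.035",
               "encoding: raw", "endian: little", ""), con)
  writeBin(as.numeric(1:8), con, size = 8, endian = "little")
  close(con)
  v <- read_volume(fp)
  expect_identical(v$dims, c(2L, 2L, 2L))
  expect_identical(v$spacing, c(0.14, 0.14, 0.035))
  expect_identical(as.vector(v$density), as.numeric(1:8))
  expect_true(all(v$label == 0L))

  # negative spacing -> format error
  bad <- file.path(withr::local_tempdir(), "bad.nrrd")
  con <- file(bad, "wb")
  writeLines(c("NRRD0004", "type: double", "dimension: 3", "sizes: 2 2 2",
               "spacings: -1 1 1", "encoding: raw", "endian: little", ""),
             con)
  writeBin(as.numeric(1:8), con, size = 8, endian = "little")
  close(con)
  expect_error(read_volume(bad), "spacing")

  # payload shorter than promised by sizes -> format error
  short <- file.path(withr::local_tempdir(), "short.nrrd")
  con <- file(short, "wb")
  writeLines(c("NRRD0004", "type: double", "dimension: 3", "sizes: 3 3 3",
               "spacings: 1 1 1", "encoding: raw", "endian: little", ""),
             con)
  writeBin(as.numeric(1:8), con, size = 8, endian = "little")
  close(con)
  expect_error(read_volume(short), "match")
})

test_that("downsample_xy block-averages density and majority-votes labels", {
  # factor 1 is the identity
  v <- random_binary_volume(8)
  expect_true(volumes_identical(downsample_xy(v, 1), v))

  # uniform volume: block mean of constants
  u <- labeled_volume(array(1, c(8, 8, 8)), spacing = c(1, 1, 1))
  du <- downsample_xy(u, 4)
  expect_identical(du$dims, c(2L, 2L, 8L))
  expect_true(all(du$density == 1))
  expect_identical(du$spacing, c(4, 4, 1))

  # hand-computed block mean: one 4x4 tile with densities {0,0,...,4}
  den <- array(0, c(4, 4, 1))
  den[2, 3, 1] <- 4
  dv <- downsample_xy(labeled_volume(den, spacing = c(1, 1, 1)), 4)
  expect_identical(dv$dims, c(1L, 1L, 1L))
  expect_equal(as.vector(dv$density), 0.25)
  # origin moves to the block centroid
  expect_equal(dv$origin, c(1.5, 1.5, 0))

  # label majority with ties broken toward the lowest id
  lab <- array(0L, c(2, 2, 1))
  lab[1, 1, 1] <- 3L; lab[2, 1, 1] <- 3L
  lab[1, 2, 1] <- 1L; lab[2, 2, 1] <- 1L
  lv <- labeled_volume(array(1, c(2, 2, 1)), label = lab,
                       spacing = c(1, 1, 1))
  expect_identical(as.vector(downsample_xy(lv, 2)$label), 1L)

  # trailing voxels are cropped with a warning
  odd <- labeled_volume(array(1, c(5, 5, 2)), spacing = c(1, 1, 1))
  expect_warning(downsample_xy(odd, 2), "cropping")

  expect_error(downsample_xy(v, 0), "positive integer")
})

test_that("downsample_xy conserves total density mass", {
  set.seed(77)
  v <- labeled_volume(array(runif(16 * 12 * 5, 0, 2000), c(16, 12, 5)),
                      spacing = c(0.25, 0.5, 1))
  for (f in c(2, 4)) {
    dv <- downsample_xy(v, f)
    mass0 <- sum(v$density) * prod(v$spacing)
    mass1 <- sum(dv$density) * prod(dv$spacing)
    expect_equal(mass1, mass0, tolerance = 1e-9)
  }
})

test_that("threshold_segment labels exactly the HU window", {
  z <- tiny_volume(4)
  expect_identical(sum(threshold_segment(z, 500, 3000, 1L)$label), 0L)

  ph <- make_phantom(phantom_spec(n_air_cells = 12L,
                                  with_structures = FALSE))
  seg <- threshold_segment(ph$volume, 500, 3000, 7L)
  # shell (1900) + trabecular (700) fall in window; carved air cells do not
  expect_identical(sum(seg$label == 7L), sum(ph$volume$label != 0L))
  # air-cell voids stay label 0
  expect_identical(sum(seg$label[ph$volume$density == 0]), 0L)

  all_in <- threshold_segment(ph$volume, -Inf, Inf, 2L)
  expect_true(all(all_in$label == 2L))

  # never labels a voxel outside the window (random property)
  set.seed(3)
  for (rep in 1:5) {
    v <- labeled_volume(array(runif(125, -100, 100), c(5, 5, 5)))
    lohi <- sort(runif(2, -100, 100))
    s <- threshold_segment(v, lohi[1], lohi[2], 1L)
    expect_true(all(v$density[s$label == 1L] >= lohi[1]))
    expect_true(all(v$density[s$label == 1L] <= lohi[2]))
    expect_true(all(s$label[v$density < lohi[1] |
                              v$density > lohi[2]] == 0L))
  }
  expect_error(threshold_segment(z, 10, 5, 1L), "hu_low")
})

test_that("voxelize_mesh matches forced geometry and the winding oracle", {
  # axis-aligned cube spanning exactly 3^3 voxel centres
  m <- box_mesh(c(0.5, 0.5, 0.5), c(3.5, 3.5, 3.5))
  occ <- voxelize_mesh(m, c(5, 5, 5), c(1, 1, 1))
  expect_identical(sum(occ), 27L)

  # sphere mesh: occupied count within 2% of the analytic ball volume
  sp <- make_sphere_phantom(10, 0.5)
  sm <- marching_cubes(sp$volume, iso = 750, field = "density")
  occ <- voxelize_mesh(sm, sp$volume$dims, sp$volume$spacing,
                       sp$volume$origin)
  expect_lt(abs(sum(occ) - (4 / 3) * pi * 10^3 / 0.5^3),
            0.02 * (4 / 3) * pi * 10^3 / 0.5^3)

  # exact agreement with the independent winding-number oracle over every
  # voxel centre of a small grid
  sp2 <- make_sphere_phantom(4, 1)
  sm2 <- marching_cubes(sp2$volume, iso = 750, field = "density")
  d <- c(16L, 16L, 16L)
  occ2 <- voxelize_mesh(sm2, d, c(0.75, 0.75, 0.75), c(0, 0, 0))
  ijk <- as.matrix(expand.grid(0:15, 0:15, 0:15))
  pts <- sweep(ijk * 0.75, 2, c(0, 0, 0), `+`)
  oracle <- winding_inside(sm2, pts)
  expect_identical(as.vector(occ2)[lin_of(d, ijk)], oracle)

  # mesh entirely outside the grid -> empty mask
  far <- box_mesh(c(100, 100, 100), c(103, 103, 103))
  expect_identical(sum(voxelize_mesh(far, c(5, 5, 5), c(1, 1, 1))), 0L)

  # non-watertight mesh -> error naming the boundary edge count
  open <- triangle_mesh(m$vertices, m$triangles[-1, , drop = FALSE])
  expect_error(voxelize_mesh(open, c(5, 5, 5), c(1, 1, 1)),
               "boundary edges")
})

test_that("combine_structures respects priority and is idempotent", {
  base <- tiny_volume(6)
  expect_true(volumes_identical(combine_structures(list(), base), base))

  m1 <- array(FALSE, c(6, 6, 6)); m1[1:4, 1:4, 1:4] <- TRUE
  m2 <- array(FALSE, c(6, 6, 6)); m2[3:6, 3:6, 3:6] <- TRUE
  out <- combine_structures(list(list(mask = m1, label = 1L),
                                 list(mask = m2, label = 3L)), base)
  # later mask wins on the overlap
  expect_true(all(out$label[m2] == 3L))
  expect_true(all(out$label[m1 & !m2] == 1L))
  # newly labeled void voxels get the representative fill density
  expect_true(all(out$density[out$label != 0L] == 1000))

  # disjoint masks add exactly
  mA <- array(FALSE, c(6, 6, 6)); mA[1:2, , ] <- TRUE
  mB <- array(FALSE, c(6, 6, 6)); mB[5:6, , ] <- TRUE
  out2 <- combine_structures(list(list(mask = mA, label = 1L),
                                  list(mask = mB, label = 2L)), base)
  expect_identical(sum(out2$label != 0L), sum(mA) + sum(mB))

  # idempotent under re-application of the same list
  lst <- list(list(mask = m1, label = 1L), list(mask = m2, label = 3L))
  once <- combine_structures(lst, base)
  twice <- combine_structures(lst, once)
  expect_true(volumes_identical(once, twice))

  bad <- array(FALSE, c(3, 3, 3))
  expect_error(combine_structures(list(list(mask = bad, label = 1L)), base),
               "dims")
})

test_that("mesh files round-trip through PLY, STL and OBJ", {
  sp <- make_sphere_phantom(4, 0.5)
  m <- marching_cubes(sp$volume)
  for (ext in c("ply", "stl", "obj")) {
    fp <- file.path(withr::local_tempdir(), paste0("m.", ext))
    write_mesh(m, fp)
    back <- read_mesh(fp)
    expect_identical(nrow(back$triangles), nrow(m$triangles))
    expect_equal(abs(mesh_volume(back)), abs(mesh_volume(m)),
                 tolerance = 1e-5)
  }
  # binary dialects
  for (ext in c("ply", "stl")) {
    fp <- file.path(withr::local_tempdir(), paste0("b.", ext))
    write_mesh(m, fp, binary = TRUE)
    back <- read_mesh(fp)
    expect_identical(nrow(back$triangles), nrow(m$triangles))
  }
  # PLY with per-vertex material colour parses back
  fp <- file.path(withr::local_tempdir(), "c.ply")
  write_mesh(m, fp, materials = default_materials())
  expect_identical(nrow(read_mesh(fp)$triangles), nrow(m$triangles))
})

test_that("material tables validate, serialize and support ease changes", {
  mat <- default_materials()
  fp <- file.path(withr::local_tempdir(), "mat.json")
  write_materials(mat, fp)
  back <- read_materials(fp)
  expect_equal(back$stiffness, mat$stiffness)
  expect_identical(back$drillable, mat$drillable)

  expect_error(material_table(data.frame(label = c(1, 1), name = "x",
                                         r = 0, g = 0, b = 0,
                                         stiffness = 1, drillable = TRUE)),
               "unique")
  expect_error(material_table(data.frame(label = 0, name = "void",
                                         r = 0, g = 0, b = 0,
                                         stiffness = 1, drillable = TRUE)),
               "reserved")
  expect_error(set_ease(mat, 1, -2), "positive")
  expect_error(set_ease(mat, 99, 1), "not in table")
  m2 <- set_ease(mat, 2, 4)
  expect_equal(m2$ease[m2$label == 2], 4)
})
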