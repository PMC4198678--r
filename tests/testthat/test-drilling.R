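test_that("apply_drill matches the brute-force sphere oracle", {
  wall <- make_wall_phantom(8, 24, 24, 20, 0.5)
  v <- wall$volume
  mat <- default_materials()
  bit <- drill_bit(1.6)
  ef <- exposure_field()

  # bit fully inside void space: zero removals
  res0 <- apply_drill(v, mat, bit, c(6, 6, 0.2), 0.01, ef)
  expect_identical(nrow(res0$removed), 0L)
  # centre outside the volume: no-op
  resF <- apply_drill(v, mat, bit, c(-50, -50, -50), 0.01, ef)
  expect_identical(nrow(resF$removed), 0L)

  # instantaneous carving equals the exhaustive distance test
  ctr <- c(6, 6, (wall$truth$slab_k[1]) * 0.5)
  res <- apply_drill(v, mat, bit, ctr, 0.01, ef)
  oracle <- brute_drill_set(v, mat, ctr, 1.6)
  expect_identical(sort(res$delta$linear), oracle)
  # mass conservation: removed + remaining = before
  expect_identical(nrow(res$removed) + sum(res$volume$label != 0L),
                   sum(v$label != 0L))
})

test_that("undrillable materials are never carved", {
  ph <- make_phantom(phantom_spec(dims = rep(48L, 3), n_air_cells = 5L))
  v <- ph$volume
  mat <- ph$materials           # vessel/nerve/plate are undrillable
  protected <- mat$label[!mat$drillable]
  before <- sum(v$label %in% protected)
  ef <- exposure_field()
  bit <- drill_bit(2.5)
  # sweep straight through the vessel-analogue tube region
  ctr0 <- ph$truth$structures$tube$path[12, ]
  vol <- v
  for (s in seq(-3, 3, by = 0.4)) {
    res <- apply_drill(vol, mat, bit, ctr0 + c(s, 0, 0), 0.01, ef)
    vol <- res$volume
  }
  expect_identical(sum(vol$label %in% protected), before)
  expect_gt(sum(v$label != 0L) - sum(vol$label != 0L), 0L)
})

test_that("exposure/resistance dynamics follow t = R / (rate * ease)", {
  lab <- array(0L, c(3, 3, 3)); lab[2, 2, 2] <- 2L
  v <- labeled_volume(array(700 * (lab != 0), c(3, 3, 3)), label = lab,
                      spacing = c(1, 1, 1))
  mat <- default_materials()
  mat$resistance[mat$label == 2] <- 2          # R = 2 exposure units
  mat <- set_ease(mat, 2L, 2)                  # ease 2, rate 1 -> t = 1 s
  bit <- drill_bit(0.6, removal_rate = 1)
  ef <- exposure_field()
  ctr <- c(1, 1, 1)
  vol <- v
  # three ticks of 0.25 s: exposure 1.5 < 2, voxel must survive
  # (0.25 is exactly representable, so the closed form is exact)
  for (i in 1:3) {
    res <- apply_drill(vol, mat, bit, ctr, 0.25, ef)
    vol <- res$volume
  }
  expect_identical(sum(vol$label != 0L), 1L)
  # the fourth tick reaches R at t = 1 s = R / (rate * ease) and removes it
  res <- apply_drill(vol, mat, bit, ctr, 0.25, ef)
  expect_identical(nrow(res$removed), 1L)

  # ease on an undrillable label is accepted but removal stays blocked
  mat2 <- set_ease(default_materials(), 3L, 10)
  lab3 <- array(0L, c(3, 3, 3)); lab3[2, 2, 2] <- 3L
  v3 <- labeled_volume(array(300 * (lab3 != 0), c(3, 3, 3)), label = lab3,
                       spacing = c(1, 1, 1))
  r3 <- apply_drill(v3, mat2, drill_bit(0.6), ctr, 10, exposure_field())
  expect_identical(nrow(r3$removed), 0L)

  # unknown label in the volume is an explicit error
  lab9 <- array(0L, c(3, 3, 3)); lab9[2, 2, 2] <- 9L
  v9 <- labeled_volume(array(1, c(3, 3, 3)), label = lab9,
                       spacing = c(1, 1, 1))
  expect_error(apply_drill(v9, mat, bit, ctr, 0.1, exposure_field()),
               "absent from material table")
})

test_that("stroke undo restores the volume bitwise in LIFO order", {
  set.seed(33)
  ph <- make_phantom(phantom_spec(dims = rep(40L, 3), n_air_cells = 5L))
  v0 <- ph$volume
  mat <- ph$materials
  bit <- drill_bit(1.4)
  ef <- exposure_field()
  stack <- undo_stack()
  vol <- v0
  snapshots <- list(vol)
  centre <- (v0$dims - 1) / 2 * v0$spacing
  for (s in 1:6) {
    delta <- data.frame(linear = integer(0), density = numeric(0),
                        label = integer(0))
    for (step in 1:10) {
      ctr <- centre + runif(3, -6, 6)
      res <- apply_drill(vol, mat, bit, ctr, 0.01, ef)
      vol <- res$volume
      delta <- rbind(delta, res$delta)
    }
    push_stroke(stack, delta)
    snapshots[[s + 1L]] <- vol
  }
  # out-of-order undo is refused
  expect_error(undo_stroke(vol, stack$strokes[[2]], ef, stack),
               "out-of-order")
  # LIFO undo walks back through every snapshot bitwise
  for (s in 6:1) {
    rec <- stack$strokes[[length(stack$strokes)]]
    vol <- undo_stroke(vol, rec, ef, stack)
    expect_true(volumes_identical(vol, snapshots[[s]]))
  }
  expect_error(undo_stroke(vol, list(id = 1L), ef, stack), "empty")
})

test_that("undo then replay of the same stroke restores the post-stroke state", {
  wall <- make_wall_phantom(6, 20, 20, 16, 0.5)
  v <- wall$volume
  mat <- default_materials()
  bit <- drill_bit(1.2)
  ef <- exposure_field()
  stack <- undo_stack()
  ctrs <- cbind(seq(3, 6, by = 0.5), 5, wall$truth$slab_k[1] * 0.5)
  vol <- v
  delta <- data.frame(linear = integer(0), density = numeric(0),
                      label = integer(0))
  for (i in seq_len(nrow(ctrs))) {
    res <- apply_drill(vol, mat, bit, ctrs[i, ], 0.01, ef)
    vol <- res$volume
    delta <- rbind(delta, res$delta)
  }
  post <- vol
  rec <- push_stroke(stack, delta)
  vol <- undo_stroke(vol, rec, ef, stack)
  expect_true(volumes_identical(vol, v))
  # replaying the identical stroke reproduces the post-stroke volume
  for (i in seq_len(nrow(ctrs))) {
    res <- apply_drill(vol, mat, bit, ctrs[i, ], 0.01, ef)
    vol <- res$volume
  }
  expect_true(volumes_identical(vol, post))
})

test_that("drill_bit and exposure invariants hold", {
  expect_error(drill_bit(0), "positive")
  expect_error(drill_bit(1, -1), "positive")
  ef <- exposure_field()
  expect_identical(otodrill:::exposure_get(ef, "123"), c(`123` = 0))
})
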