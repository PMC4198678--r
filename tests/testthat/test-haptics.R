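test_that("proxy equals device in free space and forces vanish", {
  v <- tiny_volume(10)
  mat <- default_materials()
  up <- update_proxy(v, c(1, 1, 1), c(7, 6, 5))
  expect_equal(up$proxy, c(7, 6, 5))
  expect_identical(up$contact_label, 0L)
  st <- haptic_state(c(7, 6, 5))
  expect_identical(compute_force(st, mat, 0L), c(0, 0, 0))
  expect_identical(spring_force_baseline(v, c(5, 5, 5), mat), c(0, 0, 0))
})

test_that("proxy locks onto a flat wall and slides along it", {
  wall <- make_wall_phantom(6, 32, 32, 24, 0.5)
  v <- wall$volume
  h <- 0.5
  zsurf <- (wall$truth$slab_k[1] - 0.5) * h   # lower wall face, world mm
  # push 2 mm straight into the wall from below
  start <- c(8, 8, zsurf - 2)
  target <- c(8, 8, zsurf + 2)
  up <- update_proxy(v, start, target)
  expect_false(otodrill:::point_occupied(v, up$proxy))
  expect_equal(up$proxy[1:2], c(8, 8))
  # proxy rests on the wall: separation ~2 mm along the wall normal
  expect_lt(abs((target[3] - up$proxy[3]) - 2), h / 2)
  expect_gt(up$contact_label, 0L)

  # drag parallel to the wall while pressed in: lateral tracking within
  # half a voxel of the analytic closest point on the plane
  poses <- cbind(seq(8, 12, by = 0.1), 8, zsurf + 1)
  sw <- sweep_proxy(v, default_materials(), rbind(c(8, 8, zsurf - 2), poses))
  for (i in 2:nrow(poses)) {
    p <- sw$proxy[i + 1, ]
    expect_false(otodrill:::point_occupied(v, p))
    expect_lt(abs(p[1] - poses[i, 1]), h / 2)     # tracks laterally
    expect_lt(abs(p[3] - zsurf), h)               # stays on the surface
  }
})

test_that("compute_force applies the linear law with a direction-preserving clamp", {
  mat <- default_materials()
  mat$stiffness[mat$label == 2] <- 0.5
  st <- haptic_state(c(0, 0, 0), proxy_pos = c(2, 0, 0))
  f <- compute_force(st, mat, 2L)
  expect_equal(f, c(1, 0, 0))                    # 0.5 N/mm * 2 mm
  st2 <- haptic_state(c(0, 0, 0), proxy_pos = c(60, 80, 0))
  f2 <- compute_force(st2, mat, 2L)
  expect_equal(sqrt(sum(f2^2)), 3.3)
  expect_equal(f2 / sqrt(sum(f2^2)), c(0.6, 0.8, 0))
  expect_error(compute_force(st, mat, 99L), "not present")
})

test_that("virtual-spring baseline pops through a thin wall, proxy does not", {
  thin <- make_wall_phantom(2, 32, 32, 24, 0.5)
  v <- thin$volume
  mat <- default_materials()
  h <- 0.5
  k0 <- thin$truth$slab_k[1]
  zsurf <- (k0 - 0.5) * h
  wall_thickness <- 2 * h

  # simple penalty sanity: 1 mm inside a thick wall -> k * 1 mm outward
  thick <- make_wall_phantom(12, 24, 24, 24, 0.5)
  ztop <- (thick$truth$slab_k[1] - 0.5) * 0.5
  sf <- spring_force_baseline(thick$volume, c(6, 6, ztop + 1),
                              default_materials())
  expect_equal(sf[3], -default_materials()$stiffness[1] * 1,
               tolerance = 0.3)  # within a voxel-centre quantization

  # drive the device 3 wall-thicknesses deep; entry from below (-z side)
  entry_normal <- c(0, 0, -1)
  zs <- seq(zsurf - 2, zsurf + 3 * wall_thickness, by = h / 5)
  proxy <- c(8, 8, zs[1])
  popped <- FALSE
  for (z in zs) {
    dev <- c(8, 8, z)
    up <- update_proxy(v, proxy, dev)
    proxy <- up$proxy
    expect_false(otodrill:::point_occupied(v, proxy))
    expect_lt(proxy[3], zsurf + h / 2)   # proxy stays on the entry side
    st <- haptic_state(dev, proxy_pos = proxy)
    f <- compute_force(st, mat, up$contact_label)
    # contact force never reverses against the entry normal
    expect_gte(sum(f * entry_normal), 0)
    sfz <- spring_force_baseline(v, dev, mat)[3]
    if (sfz > 1e-9) popped <- TRUE       # penalty force pushes through
  }
  expect_true(popped)
})

test_that("the proxy traverses a 3-voxel channel without wall-jumping", {
  ch <- make_wall_phantom(10, 24, 24, 20, 0.5, channel_width = 3L)
  v <- ch$volume
  i0 <- ch$truth$channel_i[1]
  ichan <- (ch$truth$channel_i + c(0, 0)) * 0.5
  xmid <- mean(ch$truth$channel_i) * 0.5
  kk <- ch$truth$slab_k
  zmid <- mean(kk) * 0.5
  # wobbling descent along the channel axis (y), pressing toward the walls
  n <- 120
  poses <- cbind(xmid + 0.9 * sin(seq(0, 6 * pi, length.out = n)),
                 seq(1, 10, length.out = n),
                 zmid)
  proxy <- c(xmid, 0.5, zmid)
  for (i in seq_len(n)) {
    up <- update_proxy(v, proxy, poses[i, ])
    proxy <- up$proxy
    expect_false(otodrill:::point_occupied(v, proxy))
    # stays within the channel's free-space slab (never jumps a wall)
    expect_gt(proxy[1], (i0 - 0.5) * 0.5 - 1e-9)
    expect_lt(proxy[1], (ch$truth$channel_i[2] + 0.5) * 0.5 + 1e-9)
  }
})

test_that("haptic_step is deterministic and composes drilling at the proxy", {
  wall <- make_wall_phantom(6, 20, 20, 16, 0.5)
  mat <- default_materials()
  bit <- drill_bit(1.2)
  zsurf <- (wall$truth$slab_k[1] - 0.5) * 0.5
  n <- 60
  # hover just below the lower wall face; the 1.2 mm burr reaches 0.6 mm
  # into the slab while the proxy stays in free space
  poses <- cbind(5, seq(4, 6, length.out = n), zsurf - 0.6)
  pedal <- rep(TRUE, n)
  r1 <- simulate_trajectory(wall$volume, mat, bit, poses, pedal,
                            record = FALSE)
  r2 <- simulate_trajectory(wall$volume, mat, bit, poses, pedal,
                            record = FALSE)
  expect_identical(r1$trace, r2$trace)
  expect_true(volumes_identical(r1$volume, r2$volume))
  expect_gt(sum(wall$volume$label != 0L) - sum(r1$volume$label != 0L), 0L)

  # pedal off: volume immutable
  r3 <- simulate_trajectory(wall$volume, mat, bit, poses, rep(FALSE, n),
                            record = FALSE)
  expect_true(volumes_identical(r3$volume, wall$volume))
  expect_identical(length(r3$stack$strokes), 0L)
})

test_that("force change per tick is bounded along a continuous path", {
  wall <- make_wall_phantom(8, 24, 24, 20, 0.5)
  mat <- default_materials()
  zsurf <- (wall$truth$slab_k[1] - 0.5) * 0.5
  h <- 0.5
  step <- h / 4
  # approach, press and slide, never moving more than a quarter voxel
  path <- rbind(
    cbind(6, 6, seq(1, zsurf + 1.2, by = step)),
    cbind(seq(6, 9, by = step), 6, zsurf + 1.2))
  sw <- sweep_proxy(wall$volume, mat, path)
  kmax <- max(mat$stiffness)
  df <- sqrt(rowSums(diff(sw$force)^2))
  # k * (device step + proxy step) plus slack for one clamp transition
  expect_lt(max(df), 4 * kmax * step + 1e-6)
})
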