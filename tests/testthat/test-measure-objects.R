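test_that("rectangular crop keeps exactly the enclosed points", {
  xyz <- cbind(x = c(0, 1, 2, 3, 4, 5, 6, 7, 8, 9),
               y = c(0, 2, 4, 6, 8, 1, 3, 5, 7, 9), z = 1:10)
  pc <- point_cloud(xyz)
  got <- crop_rectangle(pc, 1, 6, 1, 5)
  # linear-scan oracle
  keep <- xyz[, 1] >= 1 & xyz[, 1] <= 6 & xyz[, 2] >= 1 & xyz[, 2] <= 5
  expect_equal(got$xyz, xyz[keep, , drop = FALSE])
  expect_equal(npoints(got), 4L)
  # full bounding box returns the identical cloud
  all_pc <- crop_rectangle(pc, min(xyz[, 1]), max(xyz[, 1]),
                           min(xyz[, 2]), max(xyz[, 2]))
  expect_equal(all_pc$xyz, pc$xyz)
  expect_error(crop_rectangle(pc, 100, 200, 100, 200), "no points inside")
  expect_error(crop_rectangle(pc, 5, 1, 0, 1), "x_min < x_max")
  # permutation invariance (up to row order of the kept set)
  perm <- sample(nrow(xyz))
  got2 <- crop_rectangle(point_cloud(xyz[perm, ]), 1, 6, 1, 5)
  expect_equal(got2$xyz[order(got2$xyz[, 1]), ],
               got$xyz[order(got$xyz[, 1]), ])
})

test_that("bottom zeroing subtracts a robust floor", {
  pc <- point_cloud(cbind(0, 0, 5:10))
  z0 <- zero_bottom(pc, bottom_percentile = 0)
  expect_equal(range(z0$xyz[, 3]), c(0, 5))
  expect_equal(zero_bottom(z0, 0)$xyz, z0$xyz)  # idempotent
  # 1000 bed points at 50 plus 10 under-floor noise points at 45:
  # the 1st percentile ignores the noise, quantile oracle agrees
  z <- c(rep(50, 1000), rep(45, 10))
  noisy <- point_cloud(cbind(0, 0, z))
  shifted <- zero_bottom(noisy, 1)
  expect_lt(abs(stats::median(shifted$xyz[, 3])), 0.5)
  expect_equal(shifted$xyz[, 3], z - stats::quantile(z, 0.01, names = FALSE))
  expect_error(zero_bottom(point_cloud(matrix(0, 0, 3))), "empty")
})

test_that("trimmed histogram mean drops extreme bins, never the bulk", {
  # one value per bin: bins 1-5 and 16-20 trimmed, mean of the middle ten
  expect_equal(trimmed_histogram_mean(seq(0.5, 19.5, by = 1)), 10.0)
  # constant sample: degenerate guard returns the value
  expect_equal(trimmed_histogram_mean(rep(3.3, 7)), 3.3)
  # bulk at 150 with a one-sided outlier cluster: outliers occupy the top
  # bins and are trimmed, the bulk survives the mass cap
  set.seed(21)
  vals <- c(150 + runif(100, -0.5, 0.5), rep(200, 3))
  expect_lt(abs(trimmed_histogram_mean(vals) - 150), 0.5)
  # result always within data range; plain mean when trim guard collapses
  for (i in 1:20) {
    v <- rnorm(50, sd = 10)
    tm <- trimmed_histogram_mean(v)
    expect_gte(tm, min(v)); expect_lte(tm, max(v))
  }
  expect_error(trimmed_histogram_mean(numeric(0)), "empty")
  expect_error(trim_spec(10, 5, 5), "at least one bin")
})

test_that("height extraction matches construction on generator clouds", {
  sp <- object_spec("cuboid", width_x = 100, depth_y = 100, height_z = 150)
  pc <- make_object_cloud(sp, quiet_noise(), seed = 31)
  expect_equal(measure_height(pc), 150, tolerance = 1e-6)
  # jittered top: trimmed mean concentrates (cloud bottom is exact zero
  # by construction, so no zeroing error enters)
  errs <- vapply(1:20, function(s) {
    pcj <- make_object_cloud(sp, quiet_noise(0.5, jitter = 0.5), seed = s)
    abs(measure_height(pcj) - 150)
  }, 1.0)
  expect_lt(max(errs), 0.5)
  # a 2% layer of floating outliers at z = 200, spread over the object
  # footprint, barely moves the estimate
  pcj <- make_object_cloud(sp, quiet_noise(0.5, jitter = 0.5), seed = 99)
  n_out <- round(0.02 * npoints(pcj))
  blob <- cbind(runif(n_out, -50, 50), runif(n_out, -50, 50),
                200 + rnorm(n_out, 0, 0.5))
  spiked <- point_cloud(rbind(pcj$xyz, blob))
  expect_lt(abs(measure_height(spiked) - measure_height(pcj)), 1)
  expect_error(measure_height(pc, center_fraction = 0), "\\(0, 1\\]")
})

test_that("slice extents equal the brute-force oracle on random clouds", {
  set.seed(41)
  for (i in 1:100) {
    n <- sample(20:500, 1)
    xyz <- cbind(runif(n, -50, 50), runif(n, -50, 50), runif(n, 0, 30))
    w <- sample(c(0.5, 1, 2), 1)
    want <- oracle_slice_extents(xyz, w, 3)
    if (nrow(want) == 0) {
      # too sparse for any slice to qualify: implementation must refuse
      expect_error(slice_extents(point_cloud(xyz), w,
                                 min_points_per_slice = 3), "at least")
      next
    }
    got <- slice_extents(point_cloud(xyz), slice_width_mm = w,
                         min_points_per_slice = 3)
    expect_equal(got$n, want$n)
    expect_equal(got$dim_x, want$dim_x)
    expect_equal(got$dim_y, want$dim_y)
  }
})

test_that("slice extents recover closed-form shapes", {
  # axis-aligned noise-free cuboid: every full lateral slice is 100 x 80
  pc <- make_object_cloud(object_spec("cuboid", width_x = 100, depth_y = 80,
                                      height_z = 150),
                          quiet_noise(), seed = 42, bed_margin_mm = 0)
  sl <- slice_extents(pc)
  body <- sl[sl$z_mid > 5 & sl$z_mid < 145, ]
  expect_true(all(abs(body$dim_x - 100) < 1))
  expect_true(all(abs(body$dim_y - 80) < 1))
  # hemisphere: slice extent tracks the chord 2*sqrt(r^2 - h^2)
  hemi <- make_object_cloud(
    object_spec("mushroom", stem_radius = 10, stem_height = 1,
                cap_radius = 50),
    quiet_noise(density = 8), seed = 43, bed_margin_mm = 0)
  cap <- subset(as.data.frame(hemi), label == "top")
  sl <- slice_extents(point_cloud(cap[, 1:3]), slice_width_mm = 1)
  h <- sl$z_mid - 1 - 0.5  # slice lower edge height above cap equator
  ok <- h > 0 & h < 40
  expect_true(all(abs(sl$dim_x[ok] - 2 * sqrt(50^2 - h[ok]^2)) <= 2))
  expect_error(slice_extents(pc, slice_width_mm = -1), "positive")
  expect_error(slice_extents(pc, min_points_per_slice = 1e6), "at least")
})

test_that("x/y measurement reduces slices faithfully", {
  pc <- make_object_cloud(object_spec("cuboid", width_x = 100, depth_y = 80,
                                      height_z = 150),
                          quiet_noise(), seed = 51, bed_margin_mm = 0)
  xy <- measure_xy(pc)
  expect_equal(unname(xy), c(100, 80), tolerance = 1e-3)
  cyl <- make_object_cloud(object_spec("cylinder", radius = 50, height = 150),
                           quiet_noise(), seed = 52, bed_margin_mm = 0)
  xy <- measure_xy(cyl)
  expect_equal(unname(xy), c(100, 100), tolerance = 1e-2)
  # hemispherical cap shrinks toward the apex: trimmed mean under-reads
  mush <- make_object_cloud(object_spec("mushroom"), quiet_noise(), seed = 53)
  xy <- measure_xy(mush)
  expect_lt(xy[["dim_x"]], 2 * object_spec("mushroom")$dims$cap_radius)
  # max-of-retained reduction is never below the trimmed mean here
  xy_max <- measure_xy(mush, reduction = "max_retained")
  expect_gte(xy_max[["dim_x"]], xy[["dim_x"]])
})

test_that("the composite measurement pipeline is exact on clean clouds", {
  sp <- object_spec("cuboid", width_x = 100, depth_y = 80, height_z = 150)
  pc <- make_object_cloud(sp, quiet_noise(), seed = 61)
  m <- measure_object(pc)
  expect_equal(m$dim_x_mm, 100, tolerance = 1e-3)
  expect_equal(m$dim_y_mm, 80, tolerance = 1e-3)
  expect_equal(m$dim_z_mm, 150, tolerance = 1e-6)
  expect_invisible(print(m))
  expect_error(measure_object(point_cloud(matrix(0, 0, 3))), "empty")
  # translation invariance in x and y
  moved <- point_cloud(sweep(pc$xyz, 2, c(500, -300, 0), "+"),
                       label = pc$label)
  m2 <- measure_object(moved)
  expect_equal(m2$dim_x_mm, m$dim_x_mm)
  expect_equal(m2$dim_y_mm, m$dim_y_mm)
  expect_equal(m2$dim_z_mm, m$dim_z_mm)
})

test_that("degraded clouds lose accuracy as POU falls", {
  deg <- pou_degradation()
  pous <- c(17, 111, 556)
  errs <- sapply(pous, function(p) {
    rowMeans(vapply(1:6, function(s) {
      pr <- make_object_cloud(object_spec("cuboid"), quiet_noise(0.4),
                              seed = s)
      m <- measure_object(degrade_for_pou(pr, p, deg, seed = 100 + s))
      abs(c(m$dim_x_mm, m$dim_y_mm, m$dim_z_mm) - c(100, 100, 150))
    }, numeric(3)))
  })
  expect_true(all(diff(errs[1, ]) < 0))  # x error falls with POU
  expect_true(all(diff(errs[2, ]) < 0))  # y error falls with POU
  expect_true(all(errs[3, ] < errs[1, ]))  # z error stays below x
})

test_that("scene-level measurement flags failures per object", {
  sc <- simulate_scene(list(A = object_spec("cuboid"),
                            B = object_spec("cylinder")),
                       dir = withr::local_tempdir(), seed = 3,
                       noise = quiet_noise(0.5))
  regions <- rbind(sc$regions,
                   data.frame(object_id = "ghost", x_min = 5000,
                              x_max = 6000, y_min = 5000, y_max = 6000))
  res <- measure_objects(sc$cloud, regions)
  expect_equal(res$status[1:2], c("ok", "ok"))
  expect_match(res$status[3], "no points inside")
  expect_equal(res$dim_z[1], 150, tolerance = 0.1)
})
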