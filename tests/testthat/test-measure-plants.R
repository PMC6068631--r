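test_that("TGI matches hand arithmetic and its algebraic identities", {
  expect_equal(tgi(100, 100, 100), 0)
  expect_equal(tgi(50, 150, 50), 9.5)
  expect_equal(tgi(150, 50, 100), -6.5)
  expect_error(tgi(-1, 0, 0), "\\[0, 255\\]")
  expect_error(tgi(0, 300, 0), "\\[0, 255\\]")
  # shift invariance: adding a constant to all channels changes nothing
  set.seed(7)
  for (i in 1:50) {
    ch <- runif(3, 0, 200)
    d <- runif(1, 0, 55)
    expect_equal(tgi(ch[1] + d, ch[2] + d, ch[3] + d),
                 tgi(ch[1], ch[2], ch[3]))
  }
})

test_that("two-cluster k-means is exact in one dimension", {
  km <- kmeans_two(c(rep(0, 50), rep(10, 50)))
  expect_equal(sort(unique(km$labels[1:50])), 1L)
  expect_equal(sort(unique(km$labels[51:100])), 2L)
  expect_equal(km$centers, c(0, 10))
  expect_equal(km$withinss, 0)
  # {1, 2, 9}: enumerating both cuts puts {1,2} together
  km <- kmeans_two(c(1, 2, 9))
  expect_equal(km$labels, c(1L, 1L, 2L))
  # a case where Lloyd from extreme centers stalls in a local optimum
  # (WSS 100 at the cut {0,10}|{11,21}): the exact scan must still find
  # the global best cut (WSS 74, attained by two tied partitions)
  km <- kmeans_two(c(0, 10, 11, 21))
  expect_equal(km$withinss, oracle_best_cut_wss(c(0, 10, 11, 21)))
  expect_equal(km$withinss, 74)
  # exhaustive-search equivalence on random small sets
  set.seed(8)
  for (i in 1:300) {
    v <- round(runif(sample(2:12, 1), 0, 100), 1)
    if (max(v) - min(v) == 0) next
    expect_equal(kmeans_two(v)$withinss, oracle_best_cut_wss(v),
                 tolerance = 1e-9)
  }
  # WSS trace never increases and iteration cap holds
  set.seed(9)
  v <- c(rnorm(100, 0), rnorm(100, 6))
  km <- kmeans_two(v)
  expect_true(all(diff(km$wss_trace) <= 1e-9))
  expect_lte(km$iterations, 100L)
  expect_error(kmeans_two(rep(2, 5)), "distinct")
})

test_that("plant segmentation recovers the generator labels", {
  recs <- vapply(1:10, function(s) {
    pc <- make_plant_cloud(plant_spec(), seed = s)
    seg <- segment_plant(pc)
    truth <- which(pc$label == "plant")
    c(recall = length(intersect(seg$plant_idx, truth)) / length(truth),
      precision = mean(seg$plant_idx %in% truth))
  }, numeric(2))
  expect_true(all(recs["recall", ] >= 0.99))
  expect_true(all(recs["precision", ] >= 0.99))
  # deterministic: same cloud, same segmentation
  pc <- make_plant_cloud(plant_spec(), seed = 3)
  expect_identical(segment_plant(pc)$plant_idx, segment_plant(pc)$plant_idx)
  # plant set always within the strictly-green set
  seg <- segment_plant(pc)
  expect_true(all(seg$tgi[seg$plant_idx] > 0))
})

test_that("segmentation degenerate cases follow the sign rule", {
  gray <- point_cloud(cbind(runif(50), runif(50), runif(50)),
                      rgb = matrix(80, 50, 3))
  expect_error(segment_plant(gray), "no plant detected")
  pure <- point_cloud(cbind(runif(50), runif(50), runif(50)),
                      rgb = matrix(rep(c(50, 150, 50), each = 50), ncol = 3))
  seg <- segment_plant(pure)  # constant TGI > 0: all points are plant
  expect_equal(length(seg$plant_idx), 50L)
  nocol <- point_cloud(cbind(1, 1, 1))
  expect_error(segment_plant(nocol), "RGB")
})

test_that("plant height reads the top histogram bin", {
  expect_equal(plant_height(rep(300, 40)), 300)
  # canopy plus a low cotyledon layer: only the top bin matters
  z <- c(rep(80, 500), seq(280, 300, length.out = 200))
  expect_gt(plant_height(z), 295)
  # monotone: raising the top canopy raises the estimate
  z2 <- z; z2[z2 > 295] <- z2[z2 > 295] + 10
  expect_gt(plant_height(z2), plant_height(z))
  # generator recovery within one bin width
  pc <- make_plant_cloud(plant_spec(plant_height_mm = 300,
                                    noise = quiet_noise(0.3)), seed = 5)
  zp <- pc$xyz[pc$label == "plant", 3]
  expect_lt(abs(plant_height(zp) - 300), diff(range(zp)) / 50 + 1e-9)
  expect_error(plant_height(numeric(0)), "no plant points")
})

test_that("height recovery regression over synthetic plants is tight", {
  set.seed(12)
  heights <- runif(20, 100, 400)
  est <- vapply(seq_along(heights), function(i) {
    sp <- plant_spec(plant_height_mm = heights[i], canopy_radius_mm = 100,
                     noise = noise_model(jitter_sd_mm = 0.5,
                                         density_pts_per_mm2 = 0.3))
    pc <- make_plant_cloud(sp, seed = 1000 + i)
    seg <- segment_plant(pc)
    zb <- stats::quantile(pc$xyz[seg$background_idx, 3], 0.01,
                          names = FALSE)
    plant_height(pc$xyz[seg$plant_idx, 3] - zb)
  }, 1.0)
  ag <- agreement_stats(est, heights)
  expect_gte(ag$r_squared, 0.95)
})

test_that("tray-level measurement reports per-plant status", {
  specs <- lapply(c(100, 200, 300), function(h)
    plant_spec(plant_height_mm = h, canopy_radius_mm = 80,
               noise = noise_model(density_pts_per_mm2 = 0.4)))
  clouds <- lapply(1:3, function(i) {
    s <- specs[[i]]; s$center <- c((i - 1) * 400, 0)
    make_plant_cloud(s, seed = i)
  })
  scene <- point_cloud(do.call(rbind, lapply(clouds, `[[`, "xyz")),
                       rgb = do.call(rbind, lapply(clouds, `[[`, "rgb")),
                       label = unlist(lapply(clouds, `[[`, "label")))
  regions <- data.frame(plant_id = c("P1", "P2", "P3", "empty"),
                        x_min = c(-200, 200, 600, 5000),
                        x_max = c(200, 600, 1000, 6000),
                        y_min = -200, y_max = 200)
  res <- measure_plants(scene, regions)
  expect_equal(res$status, c("ok", "ok", "ok", "no_plant"))
  for (i in 1:3)
    expect_lt(abs(res$height_mm[i] - c(100, 200, 300)[i]), 8)
  # determinism: identical call, identical table
  expect_identical(res, measure_plants(scene, regions))
})
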