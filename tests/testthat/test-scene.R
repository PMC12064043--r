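test_that("watersheds partition the grid and areas close", {
  cfg <- toy_config(grid = c(20, 20), seed = 3L)
  sc <- generate_scene(cfg)
  expect_false(anyNA(sc$watersheds))
  expect_setequal(unique(as.vector(sc$watersheds)), 1:4)
  areas <- table(sc$watersheds) * cfg$pixel_area
  expect_equal(sum(areas), 400 * cfg$pixel_area)
  # pairwise disjoint by construction of a label raster: every pixel exactly
  # one id, so the intersection of any two watershed masks is empty
  for (i in 1:3) for (j in (i + 1):4) {
    expect_equal(sum(sc$watersheds == i & sc$watersheds == j), 0)
  }
})

test_that("generation is deterministic for a fixed seed", {
  cfg <- toy_config(seed = 99L)
  a <- generate_scene(cfg)
  b <- generate_scene(cfg)
  expect_identical(a$opening, b$opening)
  expect_identical(a$watersheds, b$watersheds)
  expect_identical(a$rivers, b$rivers)
  expect_identical(a$line_items, b$line_items)
})

test_that("every generated class is in the palette; degenerate palette works", {
  sc <- generate_scene(toy_config(seed = 5L))
  expect_true(all(sc$opening %in% toy_palette()$class_id))
  one <- generate_scene(toy_config(ids = 51L, seed = 5L))
  expect_equal(sum(one$truth$transitions > 0), 1)
  expect_equal(one$truth$transitions["51", "51"], 400)
})

test_that("invalid configurations are rejected", {
  expect_error(scene_config(grid_shape = c(1, 5)), "grid_shape")
  expect_error(scene_config(pixel_area = 0), "pixel_area")
  expect_error(scene_config(palette = default_palette()[0, ]), "palette")
  bad <- default_class_params()
  bad$greenness[1] <- 120
  expect_error(scene_config(class_params = bad), "greenness")
})

test_that("change scenarios construct the requested ground truth", {
  sc <- generate_scene(toy_config(grid = c(30, 30), seed = 21L))
  n61 <- sum(sc$opening == 61)
  expect_gt(n61, 0)
  k <- min(50L, n61)
  sc2 <- apply_change_scenario(sc, data.frame(from = 61, to = 41,
                                              n_pixels = k))
  expect_equal(sc2$truth$transitions["61", "41"], k)
  expect_equal(sum(sc2$opening != sc2$closing), k)
  # empty scenario is the identity
  sc3 <- apply_change_scenario(sc, data.frame(from = integer(),
                                              to = integer(),
                                              n_pixels = integer()))
  expect_identical(sc3$closing, sc3$opening)
  # moving every pixel of a class empties its closing stock
  sc4 <- apply_change_scenario(sc, data.frame(from = 61, to = 51,
                                              n_pixels = n61))
  expect_equal(sum(sc4$closing == 61), 0)
  tm <- cross_tabulate(sc4$opening, sc4$closing, sc$config$pixel_area,
                       sc$config$palette)
  expect_equal(unname(colSums(tm$counts)["61"]), 0)
})

test_that("oversubscribed scenarios fail with the shortfall", {
  sc <- generate_scene(toy_config(seed = 2L))
  n <- sum(sc$opening == 131)
  expect_error(
    apply_change_scenario(sc, data.frame(from = 131, to = 51,
                                         n_pixels = n + 10)),
    "short by 10"
  )
})

test_that("truth flow totals conserve the changed area", {
  sc <- generate_scene(toy_config(seed = 13L))
  sc <- apply_change_scenario(sc, data.frame(from = c(61, 51),
                                             to = c(41, 131),
                                             n_pixels = c(30, 20)))
  changed <- sum(sc$truth$transitions) - sum(diag(sc$truth$transitions))
  expect_equal(sum(sc$truth$flow_totals),
               changed * sc$config$pixel_area)
})

test_that("scene write/read round-trips, including nodata masks", {
  sc <- generate_scene(toy_config(seed = 8L))
  sc <- apply_change_scenario(sc, data.frame(from = 61, to = 41,
                                             n_pixels = 10))
  # inject nodata at both dates
  sc$opening[1, 1:3] <- NA
  sc$closing[1, 1:3] <- NA
  dir <- withr::local_tempdir()
  manifest <- write_scene(sc, dir)
  expect_gte(nrow(manifest), 5)
  expect_true(all(file.exists(file.path(dir, manifest$file))))
  back <- read_scene(dir)
  expect_equal(back$opening, sc$opening, ignore_attr = TRUE)
  expect_equal(back$closing, sc$closing, ignore_attr = TRUE)
  expect_identical(is.na(back$opening), is.na(sc$opening))
  expect_equal(back$watersheds, sc$watersheds, ignore_attr = TRUE)
  expect_equal(back$rivers$discharge, sc$rivers$discharge)
  expect_equal(back$line_items$water$closing$value,
               sc$line_items$water$closing$value)
  # truth is recomputed on read from the (nodata-masked) rasters
  tm <- cross_tabulate(sc$opening, sc$closing, sc$config$pixel_area,
                       sc$config$palette)
  expect_equal(back$truth$transitions, tm$counts)
})
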