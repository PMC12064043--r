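test_that("GBLI is the per-pixel mean greenness", {
  ws <- matrix(1L, 10, 10)
  w <- c(`61` = 100, `51` = 40, `41` = 80)
  expect_equal(unname(gbli(matrix(61, 10, 10), ws, w)), 100)
  r <- matrix(c(rep(51, 50), rep(41, 50)), 10, 10)
  expect_equal(unname(gbli(r, ws, w)), 60)
  # random raster: equals the brute-force per-pixel mean
  set.seed(3)
  r2 <- matrix(sample(c(61, 51, 41), 100, TRUE), 10, 10)
  expect_equal(unname(gbli(r2, ws, w)), mean(w[as.character(r2)]))
  expect_error(gbli(matrix(62, 2, 2), matrix(1L, 2, 2), w), "62")
  expect_error(gbli(matrix(61, 2, 2), matrix(1L, 2, 2), c(`61` = 150)),
               "\\[0, 100\\]")
})

test_that("effective mesh size obeys its closed forms", {
  expect_equal(effective_mesh_size(100, 100), 100)   # single patch
  for (n in c(1, 2, 4, 5, 10)) {
    expect_equal(effective_mesh_size(rep(60 / n, n), 60), 60 / n)
  }
  expect_equal(effective_mesh_size(c(4, 1), 10), 1.7)
  expect_error(effective_mesh_size(c(1, 2), 0), "total_area")
  expect_error(effective_mesh_size(c(5, 6), 10), "exceed")
})

test_that("splitting a patch never increases the effective mesh size", {
  set.seed(9)
  for (trial in 1:50) {
    areas <- runif(5, 0.5, 10)
    A <- sum(areas) + 5
    m0 <- effective_mesh_size(areas, A)
    i <- sample(5, 1)
    f <- runif(1)
    split <- c(areas[-i], areas[i] * f, areas[i] * (1 - f))
    expect_lte(effective_mesh_size(split, A), m0 + 1e-12)
  }
})

test_that("patch labelling finds rook-connected components", {
  m <- matrix(FALSE, 4, 4)
  m[1, 1:2] <- TRUE           # one 2-cell patch
  m[3:4, 4] <- TRUE           # one 2-cell patch
  m[4, 1] <- TRUE             # singleton
  lab <- label_patches(m)
  expect_equal(max(lab, na.rm = TRUE), 3)
  expect_equal(sum(!is.na(lab)), 5)
  # diagonal cells are not connected under rook adjacency
  d <- diag(3) == 1
  expect_equal(max(label_patches(d), na.rm = TRUE), 3)
  expect_true(all(is.na(label_patches(matrix(FALSE, 2, 2)))))
})

test_that("the fragmentation index averages its three components", {
  expect_equal(fragmentation_index(1, 1, 1), 1)
  expect_equal(fragmentation_index(1, 0.5, 0), 0.5)
  expect_error(fragmentation_index(1.2, 0.5, 0.5), "\\[0, 1\\]")
  # fully fragmented toy grid: 8x8 checkerboard of habitat singles inside
  # one watershed, enumerated by hand: 32 patches of 1 px (1 ha each),
  # A = 64, meff = 32/64 = 0.5, meff_norm = 1/128, pcn = 1/32, tr = 0.5
  hab <- outer(1:8, 1:8, function(i, j) (i + j) %% 2 == 0)
  r <- matrix(51, 8, 8); r[hab] <- 61
  f <- selu_fragmentation(r, matrix(1L, 8, 8), 1, tree_classes = 61,
                          pixel_area = 1)
  expect_equal(f$meff_norm, (32 * 1^2 / 64) / 64)
  expect_equal(f$patch_count_norm, 1 / 32)
  expect_equal(f$tree_ratio, 0.5)
  expect_equal(f$FI, mean(c(1 / 128, 1 / 32, 0.5)))
  # intact landscape scores 1
  fi1 <- selu_fragmentation(matrix(61, 8, 8), matrix(1L, 8, 8), 1, 61, 1)
  expect_equal(fi1$FI, 1)
})

test_that("river accessibility weights length by log discharge", {
  expect_equal(rawi(data.frame(length_km = 10, discharge = 100)), 20)
  expect_equal(rawi(data.frame(length_km = 5, discharge = 1)), 0)
  expect_equal(rawi(data.frame(length_km = numeric(),
                               discharge = numeric())), 0)
  expect_error(rawi(data.frame(length_km = 1, discharge = c(2, 0))),
               "segment\\(s\\): 2")
  expect_equal(river_fragmentation(0), 1)
  expect_equal(river_fragmentation(3), 0.25)
})

test_that("LEP composites multiply and EISU caps and rescales", {
  ln <- lep_nlep(59.91, 1.00, 0.62, 6241)
  expect_equal(round(ln$LEP, 2), 37.14)
  expect_equal(ln$NLEP, ln$LEP / 100 * 6241)
  expect_equal(lep_nlep(80, 1.1, 0, 100)$NLEP, 0)
  expect_equal(infra_use_intensity(200, 100), 0.5)
  expect_equal(infra_use_intensity(100, 150), 1)
  expect_true(is.na(infra_use_intensity(0, 10)))
  # common rescaling leaves EISU unchanged
  expect_equal(infra_use_intensity(3 * 200, 3 * 100),
               infra_use_intensity(200, 100))
})

test_that("the published infrastructure account reproduces printed indices", {
  acc <- mkc_infra_account()
  # TEIP additivity within 1 rounding unit of the printed stocks
  printed_teip1 <- c(12713, 42312, 226391, 215273, 91334, 288217, 48130)
  expect_true(all(abs(acc["TEIP1", 1:7] - printed_teip1) <= 1))
  expect_equal(round(acc["EISU", 1:7], 2),
               c(`Human footprint` = 0.49, `Agricultural landscape` = 1.00,
                 Shrubland = 0.94, `Forest landscape` = 0.70,
                 `Mangrove Landscape` = 0.84, Wetland = 0.73,
                 Estuary = 0.92))
  expect_equal(round(acc["EIIUV", 1:7], 2),
               c(`Human footprint` = 0.71, `Agricultural landscape` = 0.97,
                 Shrubland = 0.93, `Forest landscape` = 0.81,
                 `Mangrove Landscape` = 0.90, Wetland = 0.83,
                 Estuary = 0.93))
  # composite worked example: LEP of the Human footprint column
  expect_equal(round(acc["LEP1", "Human footprint"], 2), 37.14)
})
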