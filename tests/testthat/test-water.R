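test_that("evapotranspiration scaling handles both orientations", {
  # equal long-run averages: ratio 1 either way
  expect_equal(estimate_etr(123, 1000, 1000, "inverted"), 123)
  expect_equal(estimate_etr(123, 1000, 1000, "as_printed"), 123)
  expect_equal(estimate_etr(0, 1554, 777, "inverted"), 0)
  # direct arithmetic, both orientations
  expect_equal(estimate_etr(100, 1554, 777, "as_printed"), 200)
  expect_equal(estimate_etr(100, 1554, 777, "inverted"), 50)
  expect_message(estimate_etr(100, 1554, 777), "inverted")
  expect_error(estimate_etr(100, 0, 777, "inverted"), "positive")
})

test_that("the water use index is a clamped, capped ratio", {
  expect_equal(water_use_index(53983, 68974), 53983 / 68974)
  expect_equal(water_use_index(200, 100), 1)   # cap
  expect_equal(water_use_index(0, 100), 0)     # floor
  expect_equal(water_use_index(-5, 100), 0)    # negative resource clamps
  expect_equal(water_use_index(5, 0), 1)       # no use = no pressure
  expect_error(water_use_index(1, -1), "W9")
})

test_that("the internal unit value combines use and health indices", {
  expect_equal(water_internal_value(0.5, 0.95), 0.725)
  expect_equal(water_internal_value(1, 1), 1)
  expect_equal(water_internal_value(0.5, 0.8, combiner = "product"), 0.4)
  expect_error(water_internal_value(1.2, 0.5), "\\[0, 1\\]")
})

test_that("derived rows are exact on a hand-built integer fixture", {
  items <- rbind(
    data.frame(selu_id = "A", code = c("W2_1", "W2_2", "W2_3", "W2_4",
                                       "W2_5", "W2_6", "W3_1", "W3_3",
                                       "W3_4", "W14"),
               value = c(100, -20, 50, 10, 2, 8, 60, 30, 40, 0.9)),
    data.frame(selu_id = "B", code = c("W2_1", "W3_1", "W3_4", "W14"),
               value = c(10, 5, 0, 1))
  )
  acc <- assemble_water_account(items)
  expect_equal(acc["W2a", "A"], 130)           # 100 - 20 + 50
  expect_equal(acc["W2b", "A"], 20)            # 10 + 2 + 8
  expect_equal(acc["W2", "A"], 150)
  expect_equal(acc["W3", "A"], 130)            # 60 + 30 + 40
  expect_equal(acc["W4", "A"], 20)
  expect_equal(acc["W4a", "A"], 40)
  expect_equal(acc["W6", "A"], 120)            # 130 + 20 - 0 - 30
  expect_equal(acc["W9", "A"], 100)
  expect_equal(acc["W13", "A"], 1)
  expect_equal(acc["W15", "A"], 0.95)
  # SELU B: unsupplied codes default to zero; W9 = 5, W6 = 10
  expect_equal(acc["W6", "B"], 10)
  expect_equal(acc["W13", "B"], 1)
  # totals: volumes sum, indices average
  expect_equal(acc["W2", "Total"], acc["W2", "A"] + acc["W2", "B"])
  expect_equal(acc["W13", "Total"], mean(c(1, 1)))
  # degenerate: all-zero items give all-zero derived volumes
  z <- data.frame(selu_id = "Z", code = c("W2_1", "W3_1", "W3_4", "W14"),
                  value = 0)
  az <- assemble_water_account(z)
  expect_equal(unname(az[c("W2", "W3", "W4", "W6", "W9"), "Z"]),
               rep(0, 5))
})

test_that("schema violations name the SELU and code", {
  items <- data.frame(selu_id = "X", code = c("W2_1", "W3_1"), value = 1)
  expect_error(assemble_water_account(items), "X")
  expect_error(assemble_water_account(items), "W3_4")
  neg <- data.frame(selu_id = "X",
                    code = c("W2_1", "W3_1", "W3_4", "W14", "W1_1"),
                    value = c(1, 1, 1, 0.9, -5))
  expect_error(assemble_water_account(neg), ">= 0")
})

test_that("published water accounts reproduce their printed derived rows", {
  for (yr in c(2013, 2018)) {
    acc <- assemble_water_account(mkc_water_items(yr))
    expect_equal(colnames(acc)[5], "Mangrove Landscape")
    if (yr == 2013) {
      # worked examples: total use and net resource of the Human footprint
      expect_equal(acc["W9", "Human footprint"], 13261 + 35872)
      expect_lte(abs(acc["W6", "Human footprint"] - 24456), 3)
      expect_lte(abs(acc["W6", "Mangrove Landscape"] - 53983), 0)
      expect_equal(round(acc["W13", ],
                         2)[c("Human footprint", "Agricultural landscape",
                              "Shrubland", "Forest landscape",
                              "Mangrove Landscape", "Wetland", "Estuary")],
                   c(`Human footprint` = 0.50,
                     `Agricultural landscape` = 0.53, Shrubland = 1,
                     `Forest landscape` = 1, `Mangrove Landscape` = 0.78,
                     Wetland = 0.50, Estuary = 0.98))
      expect_equal(round(acc["W13", "Total"], 2), 0.76)
      expect_equal(round(acc["W15", "Agricultural landscape"], 2), 0.74)
    } else {
      expect_equal(round(acc["W13", "Human footprint"], 2), 0.33)
      expect_equal(round(acc["W15", "Human footprint"], 2), 0.64)
    }
    # balance identity holds exactly in every column
    expect_equal(acc["W4", ], acc["W2", ] - acc["W3", ])
  }
})

test_that("W13 and W15 are monotone in resource and health", {
  w9 <- 120
  w6 <- seq(-10, 200, by = 10)
  w13 <- water_use_index(w6, w9)
  expect_true(all(diff(w13) >= 0))
  w14 <- seq(0, 1, by = 0.05)
  expect_true(all(diff(water_internal_value(0.4, w14)) >= 0))
})

test_that("index totals average and volume totals sum", {
  expect_equal(round(totals_row(c(0.50, 0.53, 1.00, 1.00, 0.78, 0.50, 0.98),
                                "index"), 2), 0.76)
  expect_equal(totals_row(5, "index"), 5)
  expect_equal(totals_row(c(1, 2, 3), "volume"), 6)
  expect_error(totals_row(numeric(0)), "at least one")
})
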