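test_that("cross-tabulation counts pixels by class pair", {
  # identical rasters give a purely diagonal matrix
  r <- matrix(c(61, 61, 51, 51), 2, 2)
  tm <- cross_tabulate(r, r, pixel_area = 1)
  expect_equal(sum(tm$counts) - sum(diag(tm$counts)), 0)
  # 2x2 worked example, enumerated by hand: [[A,A],[B,B]] -> [[A,C],[B,B]]
  op <- matrix(c(61, 62, 61, 62), 2, 2) # col-major: A,B / A,B
  cl <- matrix(c(61, 62, 41, 62), 2, 2) # A,B / C,B
  tm <- cross_tabulate(op, cl, pixel_area = 1)
  expect_equal(tm$counts["61", "41"], 1L)
  expect_equal(tm$counts["61", "61"], 1L)
  expect_equal(tm$counts["62", "62"], 2L)
  expect_equal(sum(tm$counts), 4L)
})

test_that("cross-tabulation rejects misaligned or off-palette rasters", {
  expect_error(cross_tabulate(matrix(61, 2, 2), matrix(61, 2, 3), 1),
               "not aligned")
  expect_error(cross_tabulate(matrix(9999, 2, 2), matrix(61, 2, 2), 1),
               "outside the nomenclature")
})

test_that("a pixel nodata at either date is excluded at both", {
  op <- matrix(61, 3, 3); cl <- matrix(41, 3, 3)
  op[1, 1] <- NA
  cl[3, 3] <- NA
  tm <- cross_tabulate(op, cl, pixel_area = 1)
  expect_equal(sum(tm$counts), 7L)
  expect_equal(unname(rowSums(tm$counts)["61"]), 7)
  expect_equal(unname(colSums(tm$counts)["41"]), 7)
})

test_that("default flow rules are total with lf0 on the diagonal", {
  rules <- default_flow_rules()
  expect_true(all(rules %in% paste0("lf", 0:7)))
  expect_true(all(diag(rules) == "lf0"))
  # causal reading: to village lf1, savannah to rice lf2, within-family
  # density change lf3, forest to savannah lf4, savannah to forest lf5,
  # forest to water lf6
  expect_equal(rules["51", "11"], "lf1")
  expect_equal(rules["51", "21"], "lf2")
  expect_equal(rules["61", "62"], "lf3")
  expect_equal(rules["61", "51"], "lf4")
  expect_equal(rules["51", "61"], "lf5")
  expect_equal(rules["61", "131"], "lf6")
})

test_that("single-cell bookkeeping: one transition is one formation and one consumption", {
  op <- matrix(51, 10, 10)
  cl <- op; cl[1:25] <- 21 # savannah -> rice on 25 px of 1 ha
  tm <- cross_tabulate(op, cl, pixel_area = 4)
  fa <- classify_flows(tm)
  expect_equal(fa$formation["lf2", "21"], 100)
  expect_equal(fa$consumption["lf2", "51"], 100)
  expect_equal(sum(fa$formation), 100)
  expect_equal(sum(fa$consumption), 100)
  # all-diagonal matrix: no flows at all
  fa0 <- classify_flows(cross_tabulate(op, op, 4))
  expect_equal(sum(fa0$formation) + sum(fa0$consumption), 0)
})

test_that("formation/consumption conservation holds on random matrices", {
  set.seed(42)
  pal <- toy_palette(c(11L, 21L, 51L, 61L, 131L))
  rules <- default_flow_rules(pal)
  for (trial in 1:200) {
    counts <- matrix(rpois(25, 20), 5, 5,
                     dimnames = list(pal$class_id, pal$class_id))
    tm <- structure(list(classes = pal$class_id, counts = counts,
                         pixel_area = 0.5),
                    class = "transition_matrix")
    fa <- classify_flows(tm, rules)
    off_diag <- (sum(counts) - sum(diag(counts))) * 0.5
    expect_equal(sum(fa$formation), off_diag)
    expect_equal(sum(fa$consumption), off_diag)
    # stock closure per class, exactly
    expect_equal(fa$closing_stock,
                 fa$opening_stock + fa$total_formation - fa$total_consumption)
    expect_equal(sum(fa$net_change), 0)
  }
})

test_that("account equals the per-pixel brute-force enumeration", {
  set.seed(7)
  pal <- toy_palette(c(21L, 51L, 61L, 62L, 131L))
  rules <- default_flow_rules(pal)
  for (trial in 1:5) {
    nr <- sample(8:32, 1); nc <- sample(8:32, 1)
    op <- matrix(sample(pal$class_id, nr * nc, TRUE), nr, nc)
    cl <- matrix(sample(pal$class_id, nr * nc, TRUE), nr, nc)
    op[sample(nr * nc, 5)] <- NA
    cl[sample(nr * nc, 5)] <- NA
    mask <- is.na(op) | is.na(cl)
    op[mask] <- NA; cl[mask] <- NA
    fa <- classify_flows(cross_tabulate(op, cl, 0.0225, pal), rules)
    bf <- brute_force_account(op, cl, 0.0225, rules)
    expect_equal(fa$opening_stock[names(bf$opening)], bf$opening)
    expect_equal(fa$closing_stock[names(bf$closing)], bf$closing)
    expect_equal(fa$formation[, colnames(bf$formation)], bf$formation)
    expect_equal(fa$consumption[, colnames(bf$consumption)], bf$consumption)
  }
})

test_that("area is conserved between opening and closing", {
  sc <- generate_scene(toy_config(seed = 31L))
  sc <- apply_change_scenario(sc, data.frame(from = 61, to = 41,
                                             n_pixels = 40))
  fa <- classify_flows(cross_tabulate(sc$opening, sc$closing,
                                      sc$config$pixel_area,
                                      sc$config$palette),
                       default_flow_rules(sc$config$palette))
  expect_equal(sum(fa$opening_stock), sum(fa$closing_stock))
})

test_that("the assembled account has the standard layout", {
  fa <- mkc_landcover_account()
  acct <- assemble_account(fa)
  expect_equal(rownames(acct)[1], "Opening stock")
  expect_equal(rownames(acct)[19], "Closing stock")
  expect_equal(nrow(acct), 19) # opening, 2x7 flows, 2 totals, net, closing
  expect_equal(ncol(acct), 17) # 16 classes + Total
  expect_equal(acct["Opening stock", "Total"], 350762)
  # closure row-by-row
  expect_equal(
    unlist(acct["Closing stock", ]),
    unlist(acct["Opening stock", ] + acct["Total formation", ] -
             acct["Total consumption", ])
  )
})
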