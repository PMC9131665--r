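test_that("hexagon grid cells are regular, exact and tiling", {
  extent <- c(0, 0, 2000, 1500)
  grid <- hex_grid(extent)
  expect_error(hex_grid(extent, side_m = 0), "positive")

  # closed-form area and circumradius for every cell
  for (k in sample(nrow(grid), 5)) {
    ring <- grid$geometry[[k]]
    expect_equal(shoelace_oracle(ring), 3 * sqrt(3) / 2 * 300^2,
                 tolerance = 1e-6)
    rad <- sqrt((ring[, 1] - grid$cx[k])^2 + (ring[, 2] - grid$cy[k])^2)
    expect_equal(rad, rep(300, 6))
  }
  expect_equal(grid$area_m2[1], 233826.859, tolerance = 1e-6)

  # the grid covers the extent with no overlaps: clipped areas of all
  # cells against the extent rectangle sum to the extent area
  rect <- rect_ring_test(extent[1], extent[2], extent[3], extent[4])
  covered <- 0
  for (k in seq_len(nrow(grid))) {
    ls1 <- landscape("h", "forest", list(grid$geometry[[k]]))
    pt_area <- suppressWarnings(tryCatch({
      # clip hexagon against extent via the package's composition path
      comp <- populate_cells(hex_grid(extent)[k, ],
                             landscape("r", "paddy", list(rect)))
      if (nrow(comp) > 0) comp$paddy_km2 * 1e6 else 0
    }, error = function(e) 0))
    covered <- covered + pt_area
  }
  expect_equal(covered, (extent[3] - extent[1]) * (extent[4] - extent[2]),
               tolerance = 1e-6)

  # neighboring cells do not overlap
  d <- as.matrix(dist(cbind(grid$cx, grid$cy)))
  diag(d) <- Inf
  nb <- which(d < 2 * 300, arr.ind = TRUE)[1, ]
  inter <- 0
  ring_a <- grid$geometry[[nb[1]]]
  ring_b <- grid$geometry[[nb[2]]]
  cellb <- landscape("b", "paddy", list(ring_b))
  # intersect hexagon b with hexagon a through the public cell machinery
  g1 <- hex_grid(extent)[nb[1], , drop = FALSE]
  ov <- populate_cells(g1, cellb)
  if (nrow(ov) > 0) inter <- ov$paddy_km2 * 1e6
  expect_lt(inter, 1e-6)
})

test_that("cell population conserves area and drops non-agricultural cells", {
  spec <- small_spec()
  w <- small_world()
  grid <- hex_grid(w$extent)
  cells <- populate_cells(grid, w$fields, include_margin = FALSE)
  expect_true(all(cells$contains_agriculture))
  # conservation per category between mosaic and cell decomposition
  for (cat in c("paddy", "source_habitat", "soybean")) {
    total_fields <- sum(w$fields$area_m2[w$fields$category == cat]) / 1e6
    total_cells <- sum(cells[[paste0(cat, "_km2")]])
    expect_equal(total_cells, total_fields, tolerance = 1e-6)
  }
  # forest-only landscape yields no cells
  forest <- landscape("f", "forest", list(rect_ring_test(0, 0, 500, 500)))
  expect_equal(nrow(populate_cells(hex_grid(c(0, 0, 500, 500)), forest)), 0)

  # one paddy fully inside one cell: that cell carries its whole area
  grid2 <- hex_grid(c(0, 0, 2000, 2000))
  host <- which(grid2$cx > 600 & grid2$cx < 1400 &
                  grid2$cy > 600 & grid2$cy < 1400)[1]
  cxy <- c(grid2$cx[host], grid2$cy[host])
  pad <- landscape("p", "paddy",
                   list(rect_ring_test(cxy[1] - 50, cxy[2] - 50,
                                       cxy[1] + 50, cxy[2] + 50)))
  cells2 <- populate_cells(grid2, pad, include_margin = FALSE)
  expect_equal(nrow(cells2), 1)
  expect_equal(cells2$id, grid2$id[host])
  expect_equal(cells2$paddy_km2, 1e4 / 1e6)
})

test_that("map prediction grades cells and counts priority areas", {
  em <- extended_model()
  # engineered 2x2-cell scene: exactly one cell has enough source habitat
  # to exceed the first-grade boundary (0.1% back-transformed = 1.8122
  # arcsine degrees; 0.06 km2 of source habitat gives eta = 1.9542)
  grid <- hex_grid(c(0, 0, 1200, 600))
  grid <- grid[1:4, ]
  mk <- function(k, side_m) {
    cx <- grid$cx[k]; cy <- grid$cy[k]
    rect_ring_test(cx - side_m / 2, cy - side_m / 2,
                   cx + side_m / 2, cy + side_m / 2)
  }
  fields <- landscape(
    c("s1", "p1", "p2", "p3"),
    c("source_habitat", "paddy", "paddy", "paddy"),
    list(mk(1, sqrt(60000)), mk(2, 100), mk(3, 100), mk(4, 100))
  )
  cells <- populate_cells(grid, fields, include_margin = FALSE)
  cells <- map_predict(cells, em)
  expect_equal(attr(cells, "summary")$n_total, 4)
  expect_equal(attr(cells, "summary")$n_priority, 1)
  hot <- cells[cells$priority, ]
  expect_equal(hot$predicted_arcsine, 0.03 + 32.07 * 0.06, tolerance = 1e-9)
  expect_equal(as.character(hot$grade), "second")

  # zero-area cell predicts the fixed intercept; adding source habitat
  # never lowers the prediction
  cold <- cells[!cells$priority, ][1, ]
  more <- cold
  more$source_habitat_km2 <- more$source_habitat_km2 + 0.01
  expect_gt(predict(em, more), predict(em, cold))
})

test_that("scenario table reproduces the published sensitivity analysis", {
  em <- extended_model()
  tab <- scenario_table(em)
  expect_equal(nrow(tab), 18)  # 2 cases x 3 source x 3 soybean
  avgavg <- tab[tab$case == "lowest" & tab$source_level == "avg" &
                  tab$soybean_level == "avg", ]
  expect_equal(avgavg$arcsine, 1.4224, tolerance = 1e-3)
  expect_equal(avgavg$source_km2, 0.0312)
  expect_equal(avgavg$soybean_km2, 0.0033)
  expect_equal(avgavg$paddy_km2, 0.0942)

  # monotone nondecreasing in source and soybean levels
  for (cs in unique(tab$case)) {
    for (sl in c("min", "avg", "max")) {
      sub <- tab[tab$case == cs & tab$soybean_level == sl, ]
      expect_true(all(diff(sub$arcsine[match(c("min", "avg", "max"),
                                             sub$source_level)]) >= 0))
    }
  }
  # a high-risk intercept shifts predictions up; max source habitat drops
  # the grade below first in both cases
  tab2 <- scenario_table(em, intercept_cases = c(lowest = -0.2,
                                                 highest = 0.6))
  maxmax <- tab2[tab2$source_level == "max", ]
  expect_true(all(maxmax$grade != "first"))

  expect_warning(expect_warning(risk_case_offset(em, "Nowhere", 1999),
                                "using 0"))
})

test_that("predicted maps round trip through GeoJSON", {
  w <- small_world()
  grid <- hex_grid(w$extent)
  cells <- map_predict(populate_cells(grid, w$fields), extended_model())
  path <- withr::local_tempfile(fileext = ".geojson")
  write_map(cells, path)
  back <- read_map(path)
  expect_equal(nrow(back), nrow(cells))
  expect_true(all(unlist(back$grade) %in%
                    c("first", "second", "third", "substandard")))
  expect_equal(unlist(back$predicted_pct), cells$predicted_pct,
               tolerance = 1e-12)
  expect_equal(unlist(back$source_habitat_km2), cells$source_habitat_km2,
               tolerance = 1e-12)
})
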