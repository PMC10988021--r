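test_that("a blank image yields an empty segmentation, not an error", {
  seg <- segment_cells(matrix(0, 64, 64))
  expect_identical(nrow(seg$cells), 0L)
  expect_true(all(seg$mask == 0L))
})

test_that("non-touching cells are segmented one label each with high overlap", {
  r <- render_cells(twenty_cell_scene())
  seg <- segment_cells(r$image)
  expect_identical(nrow(seg$cells), 20L)
  for (i in 1:20) {
    tm <- r$truth$mask == i
    best <- max(vapply(seq_len(20), function(j) mask_iou(tm, seg$mask == j),
                       numeric(1)))
    expect_gte(best, 0.9)
  }
})

test_that("touching cells are split by the watershed", {
  cells <- list(synth_cell(5, 5, angle = 0, length = 2.5, width = 0.8),
                synth_cell(7.6, 5, angle = 0, length = 2.5, width = 0.8))
  r <- render_cells(cell_scene(cells))
  seg <- segment_cells(r$image)
  expect_identical(nrow(seg$cells), 2L)
})

test_that("recovered cell geometry matches the planted rods", {
  cells <- list(synth_cell(3, 3, angle = 0.5, length = 2.6, width = 0.8),
                synth_cell(8, 8, angle = -1.1, length = 2, width = 0.7))
  r <- render_cells(cell_scene(cells, nx = 220, ny = 220))
  seg <- segment_cells(r$image)
  expect_identical(nrow(seg$cells), 2L)
  for (j in 1:2) {
    ti <- r$truth$mask[round(seg$cells$x[j]), round(seg$cells$y[j])]
    expect_equal(seg$cells$length[j], cells[[ti]]$length, tolerance = 0.1)
    expect_equal(seg$cells$width[j], cells[[ti]]$width, tolerance = 0.15)
    # angles agree modulo pi
    da <- abs(seg$cells$angle[j] - cells[[ti]]$angle) %% pi
    expect_lt(min(da, pi - da), 0.1)
  }
})

test_that("per-cell intensity closes on the planted values without blur", {
  sc <- twenty_cell_scene(background = 0, psf_sigma = 0)
  r <- render_cells(sc)
  seg <- segment_cells(r$image)
  pci <- per_cell_intensity(seg$mask, r$image)
  for (j in seq_len(nrow(seg$cells))) {
    ti <- r$truth$mask[round(seg$cells$x[j]), round(seg$cells$y[j])]
    planted <- sc$cells[[ti]]$cyto
    expect_lt(abs(pci$mean_intensity[j] - planted) / planted, 0.01)
  }
})

test_that("a CCCP-like half-intensity scene halves the measured means", {
  base <- twenty_cell_scene()
  half <- base
  half$cells <- lapply(half$cells, function(cl) { cl$cyto <- cl$cyto / 2; cl })
  r1 <- render_cells(base); r2 <- render_cells(half)
  s1 <- segment_cells(r1$image); s2 <- segment_cells(r2$image)
  m1 <- mean(per_cell_intensity(s1$mask, r1$image)$mean_intensity)
  m2 <- mean(per_cell_intensity(s2$mask, r2$image)$mean_intensity)
  expect_lt(abs(m2 / m1 - 0.5), 0.05)
})

test_that("uniform cells contain no spots and bright planted spots are recovered", {
  u <- render_cells(cell_scene(list(synth_cell(3, 3)), nx = 128, ny = 128))
  su <- segment_cells(u$image)
  expect_identical(nrow(detect_maxima(u$image, su$mask)), 0L)

  cells <- list(synth_cell(3, 3, angle = 0.4, length = 2.8, width = 0.9,
                           cyto = 100,
                           spots = list(c(-1, 0, 500, 0.1), c(0, 0.1, 500, 0.1),
                                        c(1, -0.1, 500, 0.1))))
  r <- render_cells(cell_scene(cells, nx = 128, ny = 128))
  seg <- segment_cells(r$image)
  sp <- detect_maxima(r$image, seg$mask)
  expect_identical(nrow(sp), 3L)
  for (k in seq_len(3)) {
    d <- sqrt((r$truth$spots$x - sp$x[k])^2 + (r$truth$spots$y - sp$y[k])^2)
    expect_lt(min(d), 2)
  }
})

test_that("spot count is non-increasing in the prominence threshold", {
  cells <- list(synth_cell(3, 3, angle = 0, length = 2.8, width = 0.9,
                           cyto = 100,
                           spots = list(c(-0.9, 0, 150, 0.1), c(0, 0, 400, 0.1),
                                        c(0.9, 0, 800, 0.1))))
  r <- render_cells(cell_scene(cells, nx = 128, ny = 128))
  seg <- segment_cells(r$image)
  counts <- vapply(c(0.2, 0.8, 1.5, 3, 6),
                   function(p) nrow(detect_maxima(r$image, seg$mask,
                                                  min_prominence = p)),
                   integer(1))
  expect_true(all(diff(counts) <= 0))
  expect_error(detect_maxima(r$image, seg$mask, min_prominence = 0), "> 0")
})

test_that("cell-frame mapping sends a centroid spot to the origin and poles to half-length", {
  cells <- list(synth_cell(4, 4, angle = 0.7, length = 3, width = 0.9,
                           cyto = 100,
                           spots = list(c(0, 0, 600, 0.1), c(1.3, 0, 600, 0.1))))
  r <- render_cells(cell_scene(cells, nx = 180, ny = 180))
  seg <- segment_cells(r$image)
  sp <- map_to_cell_frame(detect_maxima(r$image, seg$mask), seg$cells)
  expect_identical(nrow(sp), 2L)
  sp <- sp[order(abs(sp$dlong)), ]
  expect_lt(abs(sp$dlong[1]), 0.1)      # centroid spot ~ (0, 0)
  expect_lt(abs(sp$dtrans[1]), 0.1)
  expect_equal(abs(sp$dlong[2]), 1.3, tolerance = 0.12) # near-pole spot
  expect_lte(sp$fold_long[2], 1.2)
})

test_that("spots per cell averages planted counts", {
  cells <- list(synth_cell(3, 3, length = 2.8, width = 0.9, cyto = 100,
                           spots = list(c(-0.9, 0, 500, 0.1), c(0.9, 0, 500, 0.1))),
                synth_cell(8, 8, length = 2.8, width = 0.9, cyto = 100,
                           spots = list(c(0, 0, 500, 0.1), c(-0.9, 0, 500, 0.1))))
  r <- render_cells(cell_scene(cells, nx = 240, ny = 240))
  seg <- segment_cells(r$image)
  sp <- detect_maxima(r$image, seg$mask)
  res <- spots_per_cell(sp, seg$cells)
  expect_equal(res$mean_spots_per_cell, 2)
  expect_identical(res$per_cell$n_spots, c(2, 2))
})
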