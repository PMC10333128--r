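# Data model, I/O layouts and preprocessing.

test_that("dataset construction validates panel, schema and coordinates", {
  ds <- tiny_dataset()
  expect_s3_class(ds, "MultiplexedDataset")
  expect_equal(n_channels(ds), 3)
  expect_error(
    cell_record("c", "w", list(perturbation = "control"),
                rbind(c(0, 0), c(0, 0)), matrix(1, 2, 3)),
    "unique")
  expect_error(
    multiplexed_dataset(list(square_cell(conditions =
                                           list(perturbation = "nope"))),
                        channel_panel(paste0("ch", 1:3)),
                        condition_schema(list(perturbation = "control"))),
    "not in schema")
})

test_that("condition one-hot blocks sum to one per field", {
  schema <- condition_schema(list(perturbation = c("a", "b"),
                                  stage = c("g1", "s", "g2")))
  oh <- condition_onehot(schema,
                         data.frame(perturbation = c("a", "b", "b"),
                                    stage = c("s", "g2", "g1")))
  expect_equal(dim(oh), c(3, 5))
  expect_equal(rowSums(oh[, 1:2]), rep(1, 3))
  expect_equal(rowSums(oh[, 3:5]), rep(1, 3))
  expect_error(condition_onehot(schema, data.frame(perturbation = "x",
                                                   stage = "s")),
               "unknown level")
})

test_that("csv_dir round trip preserves coords exactly and intensities closely", {
  ds <- tiny_dataset()
  root <- withr::local_tempdir()
  write_dataset(ds, file.path(root, "d"))
  ds2 <- load_dataset(file.path(root, "d"))
  expect_equal(cell_ids(ds2), cell_ids(ds))
  for (id in cell_ids(ds)) {
    expect_identical(ds2$cells[[id]]$coords, ds$cells[[id]]$coords)
    expect_equal(ds2$cells[[id]]$intensities, ds$cells[[id]]$intensities,
                 tolerance = 1e-6, ignore_attr = TRUE)
    expect_identical(ds2$cells[[id]]$conditions$perturbation,
                     ds$cells[[id]]$conditions$perturbation)
  }
})

test_that("tiff_csv layout round-trips pixels through stacks and masks", {
  out <- generate_synth_small(seed = 3, n_cells_per_condition = 2)
  ds <- out$dataset
  # raw intensities can be slightly negative from additive noise; clamp for
  # the raw-image layout
  ds$cells <- lapply(ds$cells, function(cell) {
    cell$intensities <- pmax(cell$intensities, 0)
    cell
  })
  root <- withr::local_tempdir()
  write_dataset(ds, file.path(root, "t"), layout = "tiff_csv")
  ds2 <- load_dataset(file.path(root, "t"), layout = "tiff_csv")
  expect_setequal(cell_ids(ds2), cell_ids(ds))
  for (id in cell_ids(ds)) {
    a <- ds$cells[[id]]; b <- ds2$cells[[id]]
    oa <- order(a$coords[, 1], a$coords[, 2])
    ob <- order(b$coords[, 1], b$coords[, 2])
    expect_identical(unname(b$coords[ob, ]), unname(a$coords[oa, ]))
    scale <- apply(dataset_pixels(ds)$intensities, 2, max)
    expect_lt(max(abs(b$intensities[ob, ] - a$intensities[oa, ]) /
                    rep(scale, each = nrow(a$coords))), 1e-6)
  }
  expect_error(load_dataset(file.path(root, "missing")), "does not exist")
})

test_that("empty metadata and missing files are fatal with clear messages", {
  root <- withr::local_tempdir()
  dir.create(file.path(root, "d"))
  write.csv(data.frame(index = 0, name = "ch1", background = 0),
            file.path(root, "d", "channels.csv"), row.names = FALSE)
  write.csv(data.frame(cell_id = character(), well_id = character(),
                       perturbation = character()),
            file.path(root, "d", "cells.csv"), row.names = FALSE)
  expect_error(load_dataset(file.path(root, "d")), "no cells")
  expect_error(load_dataset(root), "missing required file")
})

test_that("background subtraction shifts without clamping", {
  ds <- tiny_dataset()
  ds$panel$background <- c(5, 0, 20)
  before <- ds$cells$c1$intensities
  ds2 <- background_subtract(ds)
  expect_equal(ds2$cells$c1$intensities[, 1], before[, 1] - 5)
  expect_equal(ds2$cells$c1$intensities[, 2], before[, 2])
  # channel 3 has values far below 20: negatives preserved
  expect_true(any(ds2$cells$c1$intensities[, 3] < 0))
  ds$panel$background <- rep(0, 3)
  expect_equal(background_subtract(ds)$cells$c1$intensities, before)
  ds$panel$background <- c(1, 2)
  expect_error(background_subtract(ds), "length")
})

test_that("quantile normalization matches a sort-and-interpolate oracle", {
  # channel with values 1..100: type-7 interpolated 98th percentile
  coords <- as.matrix(expand.grid(row = 0:9, col = 0:9))
  cell <- make_cell(coords = coords,
                    intensities = cbind(1:100, rep(7, 100)))
  ds <- multiplexed_dataset(list(cell), channel_panel(c("a", "b")),
                            condition_schema(list(perturbation = "control")))
  # independent oracle: linear interpolation on the sorted values
  x <- sort(1:100)
  h <- (100 - 1) * 0.98 + 1
  oracle <- x[floor(h)] + (h - floor(h)) * (x[floor(h) + 1] - x[floor(h)])
  ds2 <- fit_and_apply_quantile_norm(ds)
  expect_equal(ds2$panel$quantiles[1], oracle)
  expect_equal(max(abs(quantile(ds2$cells[[1]]$intensities[, 1], 0.98) - 1)),
               0, tolerance = 1e-9)
  # constant channel normalizes to exactly 1
  expect_equal(unique(ds2$cells[[1]]$intensities[, 2]), 1)
  # idempotent up to interpolation: second application divides by ~1
  ds3 <- fit_and_apply_quantile_norm(ds2)
  expect_equal(ds3$panel$quantiles, c(1, 1), tolerance = 1e-9,
               ignore_attr = TRUE)
  # nonpositive quantile is fatal and names the channel
  neg <- ds
  neg$cells[[1]]$intensities[, 2] <- -1
  expect_error(fit_and_apply_quantile_norm(neg), "b")
})

test_that("cell split is a seeded partition with the requested proportions", {
  ds <- tiny_dataset(n_cells = 10)
  ds1 <- split_cells(ds, seed = 4)
  expect_equal(as.vector(table(ds1$split)[c("train", "val", "test")]),
               c(8, 1, 1))
  ds2 <- split_cells(ds, seed = 4)
  expect_identical(ds1$split, ds2$split)
  ds3 <- split_cells(ds, c(1, 0, 0), seed = 4)
  expect_true(all(ds3$split == "train"))
  expect_error(split_cells(ds, c(0.5, 0.4, 0.2), seed = 1), "sum to 1")
})

test_that("patch extraction fills out-of-cell neighbours with the window mean", {
  # interior pixel of a dense square: patch equals the raw window
  cell <- square_cell(side = 4, n_channels = 2)
  b <- extract_patches(cell)
  interior <- which(cell$coords[, 1] == 1 & cell$coords[, 2] == 1)
  # all 9 neighbours valid: no NA fill, and center equals the pixel profile
  expect_equal(b$patches[interior, 5, ], cell$intensities[interior, ])
  expect_equal(b$centers, cell$intensities, ignore_attr = TRUE)

  # corner pixel with specified valid-window values {1,2,3,6}: missing
  # entries filled with their mean 3.0
  coords <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  ints <- matrix(c(1, 2, 3, 6), 4, 1)
  cell2 <- make_cell(coords = coords, intensities = ints)
  b2 <- extract_patches(cell2)
  p <- b2$patches[1, , 1]  # corner pixel (0,0)
  expect_equal(sort(unique(p)), c(1, 2, 3, 6))
  expect_equal(p[is.na(match(p, c(1, 2, 3, 6)))], numeric(0))
  expect_equal(sum(p == 3), 5 + 1)  # five filled positions plus the real 3
  expect_equal(mean(c(1, 2, 3, 6)), 3)

  # neighborhood 1 degenerates to the profiles themselves
  b3 <- extract_patches(cell2, neighborhood = 1)
  expect_equal(dim(b3$patches), c(4, 1, 1))
  expect_equal(b3$patches[, 1, ], ints[, 1])

  # single-pixel cell: patch is 9 copies of the profile
  b4 <- extract_patches(make_cell(coords = rbind(c(0, 0)),
                                  intensities = matrix(c(2, 5), 1, 2)))
  expect_equal(unique(b4$patches[1, , 1]), 2)
  expect_equal(unique(b4$patches[1, , 2]), 5)
})

test_that("training-pixel sampling is per-cell, seeded and ceiling-sized", {
  out <- small_synth()
  ds <- split_cells(out$dataset, seed = 1)
  b <- sample_training_pixels(ds, 0.005, seed = 2)
  counts <- table(b$provenance$cell_id)
  cells <- cells_in_split(ds, "train")
  for (id in names(counts))
    expect_equal(as.integer(counts[[id]]),
                 as.integer(ceiling(0.005 * nrow(ds$cells[[id]]$coords))))
  # fraction 1 returns every pixel of the split
  b1 <- sample_training_pixels(ds, 1, seed = 2)
  expect_equal(n_patches(b1), sum(vapply(cells, function(x) nrow(x$coords), 1L)))
  # determinism and seed sensitivity (same per-cell counts, different sets)
  b2 <- sample_training_pixels(ds, 0.005, seed = 2)
  b3 <- sample_training_pixels(ds, 0.005, seed = 3)
  expect_identical(b$provenance, b2$provenance)
  expect_false(identical(b$provenance, b3$provenance))
  expect_equal(table(b3$provenance$cell_id), counts)
  expect_error(sample_training_pixels(ds, 0, seed = 1), "fraction")
})

test_that("patch centers equal the pixel profiles and one-hots are valid", {
  out <- small_synth()
  ds <- split_cells(out$dataset, seed = 1)
  b <- sample_training_pixels(ds, 0.01, seed = 5)
  center <- (dim(b$patches)[2] + 1) %/% 2
  expect_equal(b$patches[, center, ], b$centers, ignore_attr = TRUE)
  expect_equal(rowSums(b$onehot), rep(1, n_patches(b)))
})
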