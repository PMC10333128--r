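# Object morphology, size filters, co-occurrence and curve comparisons.

# build a cell whose label mask contains specified rectangular objects
rect_cell <- function(rects, side = 40, label = "A") {
  coords <- as.matrix(expand.grid(row = 0:(side - 1), col = 0:(side - 1)))
  labels <- rep("bg", nrow(coords))
  for (r in rects)
    labels[coords[, 1] >= r[1] & coords[, 1] < r[1] + r[3] &
             coords[, 2] >= r[2] & coords[, 2] < r[2] + r[4]] <- label
  list(cell = make_cell(coords = coords,
                        intensities = matrix(1, nrow(coords), 2)),
       labels = labels)
}

test_that("component size filters reproduce the hand-traced cases", {
  mk <- function(areas) data.frame(area = areas, perimeter = 4 * areas)
  # {5, 20, 30}: the >10 filter drops 5; smallest survivor is 40% of total,
  # not < 10%, so nothing else is removed
  f1 <- sublandmarks:::filter_components(mk(c(5, 20, 30)))
  expect_setequal(f1$area, c(20, 30))
  # {11, 200}: 11 survives the >10 filter but is 5.2% < 10% cumulative
  f2 <- sublandmarks:::filter_components(mk(c(11, 200)))
  expect_equal(f2$area, 200)
  # {100, 100}: neither is < 10% of 200, none removed
  f3 <- sublandmarks:::filter_components(mk(c(100, 100)))
  expect_setequal(f3$area, c(100, 100))
})

test_that("connected components use 8-connectivity and edge-count perimeter", {
  # two diagonal pixels are one 8-connected component
  cc <- sublandmarks:::connected_components(rbind(c(0, 0), c(1, 1)))
  expect_equal(nrow(cc$stats), 1)
  expect_equal(cc$stats$area, 2)
  expect_equal(cc$stats$perimeter, 8)  # no shared 4-edges
  # two separated pixels are two components
  cc2 <- sublandmarks:::connected_components(rbind(c(0, 0), c(0, 2)))
  expect_equal(nrow(cc2$stats), 2)
})

test_that("circularity closed forms: squares, bars, elongation monotonicity", {
  rc <- rect_cell(list(c(5, 5, 6, 6)))  # 6x6 square
  obj <- csl_objects(rc$cell, rc$labels, "A")
  expect_equal(obj$area, 36)
  expect_equal(obj$perimeter, 24)
  expect_equal(obj$circularity, pi / 4)
  # 1 x 10 bar: c = 4*pi*10 / 22^2
  rc2 <- rect_cell(list(c(5, 5, 1, 10)))
  # the bar has 10 <= 10 pixels: passes only with min_area lowered
  obj2 <- csl_objects(rc2$cell, rc2$labels, "A", min_area = 5)
  expect_equal(obj2$area, 10)
  expect_equal(obj2$circularity, 4 * pi * 10 / 22^2, tolerance = 1e-12)
  expect_equal(round(obj2$circularity, 4), 0.2596)
  # fixed area 36, increasing elongation decreases circularity
  circs <- vapply(list(c(6, 6), c(4, 9), c(3, 12), c(2, 18), c(1, 36)),
                  function(d) {
                    rc3 <- rect_cell(list(c(1, 1, d[1], d[2])), side = 45)
                    csl_objects(rc3$cell, rc3$labels, "A")$circularity
                  }, 1)
  expect_true(all(diff(circs) < 0))
})

test_that("object stats aggregate and degenerate cases", {
  rc <- rect_cell(list(c(2, 2, 5, 5), c(20, 20, 7, 7)))
  st <- object_stats(csl_objects(rc$cell, rc$labels, "A"))
  expect_equal(st$count, 2)
  expect_equal(st$mean_area, (25 + 49) / 2)
  expect_equal(st$median_circularity, pi / 4)
  empty <- object_stats(csl_objects(rc$cell, rc$labels, "missing"))
  expect_equal(empty$count, 0)
  expect_true(is.na(empty$mean_area))
})

test_that("per-landmark mean intensities respect the weighted-mean identity", {
  set.seed(4)
  coords <- as.matrix(expand.grid(row = 0:9, col = 0:9))
  ints <- matrix(rnorm(200, 10), 100, 2)
  cell <- make_cell(coords = coords, intensities = ints)
  labels <- rep(c("A", "B"), c(30, 70))
  ft <- per_csl_mean_intensity(cell, labels)
  expect_equal(ft$n_pixels, c(30, 70))
  # size-weighted average of per-landmark means = whole-cell mean
  w <- ft$n_pixels / sum(ft$n_pixels)
  expect_equal(colSums(as.matrix(ft[, 4:5]) * w), colMeans(ints),
               ignore_attr = TRUE)
  # single-landmark cell: row equals the whole-cell mean
  ft1 <- per_csl_mean_intensity(cell, rep("A", 100))
  expect_equal(as.numeric(ft1[1, 4:5]), colMeans(ints), ignore_attr = TRUE)
  # absent landmark: count 0, missing intensity
  ft2 <- per_csl_mean_intensity(cell, labels, all_csls = c("A", "B", "C"))
  expect_equal(ft2$n_pixels[ft2$csl == "C"], 0)
  expect_true(all(is.na(ft2[ft2$csl == "C", 4:5])))
})

test_that("log-spaced intervals are geometric and strictly increasing", {
  iv <- log_spaced_intervals(19, 2, 80)
  expect_equal(nrow(iv), 19)
  expect_equal(iv$d_a[1], 2)
  expect_equal(iv$d_b[19], 80)
  ratios <- iv$d_b / iv$d_a
  expect_equal(ratios, rep(ratios[1], 19), tolerance = 1e-12)
  expect_true(all(iv$d_b > iv$d_a))
})

test_that("co-occurrence matches the O(n^2) brute-force oracle", {
  set.seed(7)
  # toy cell: ~200 pixels, 3 labels with spatial structure
  coords <- as.matrix(expand.grid(row = 0:13, col = 0:13))
  labels <- rep("bg", nrow(coords))
  labels[coords[, 1] < 5 & coords[, 2] < 5] <- "X"
  labels[coords[, 1] > 9 & coords[, 2] > 9] <- "Y"
  iv <- log_spaced_intervals(6, 2, 15)
  for (variant in c("conditional_over_marginal", "as_printed")) {
    fast <- co_occurrence(coords, labels, iv, variant = variant)
    slow <- sublandmarks:::co_occurrence_bruteforce(coords, labels, iv,
                                                    variant = variant)
    expect_equal(fast, slow, tolerance = 1e-12)
  }
})

test_that("single-label cell has unit co-occurrence wherever defined", {
  coords <- as.matrix(expand.grid(row = 0:9, col = 0:9))
  cc <- co_occurrence(coords, rep("A", 100), log_spaced_intervals(5, 2, 12))
  vals <- cc["A", "A", ]
  expect_true(all(vals[!is.na(vals)] == 1))
})

test_that("co-occurrence is ~1 under label permutation and >1 for blobs", {
  set.seed(8)
  coords <- as.matrix(expand.grid(row = 0:69, col = 0:69))
  iv <- log_spaced_intervals(8, 2, 40)
  # blob labels: disk of radius 9 at the center
  ctr <- c(35, 35)
  blob <- sqrt((coords[, 1] - ctr[1])^2 + (coords[, 2] - ctr[2])^2) < 9
  labels <- ifelse(blob, "blob", "bg")
  cc <- co_occurrence(coords, labels, iv)
  expect_gt(cc["blob", "blob", 1], 1)
  # permutation null: mean score ~ 1 at all intervals
  perm_vals <- replicate(60, {
    cc_p <- co_occurrence(coords, sample(labels), iv)
    cc_p["blob", "blob", ]
  })
  expect_true(all(abs(rowMeans(perm_vals, na.rm = TRUE) - 1) < 0.05))
})

test_that("mean log2 curves and curve areas behave as closed forms", {
  iv <- log_spaced_intervals(5, 2, 12)
  flat <- array(1, c(2, 2, 5), dimnames = list(c("A", "B"), c("A", "B"), NULL))
  attr(flat, "intervals") <- iv
  curves <- list(c1 = flat, c2 = flat)
  m <- mean_log2_cooccurrence(curves, "A", "B")
  expect_equal(m$mean_log2, rep(0, 5))
  expect_equal(m$hi - m$lo, rep(0, 5))
  # identical curves: area 0; doubling: area = log-x range; symmetric
  a <- c(1, 2, 4, 2, 1)
  expect_equal(curve_area_difference(a, a, iv), 0)
  xr <- log2(sqrt(iv$d_a * iv$d_b))
  expect_equal(curve_area_difference(a, 2 * a, iv), max(xr) - min(xr))
  b <- c(2, 1, 3, 1, 2)
  expect_equal(curve_area_difference(a, b, iv),
               curve_area_difference(b, a, iv))
  expect_error(curve_area_difference(a, b[1:4], iv), "mismatch")
})

test_that("feature table conserves the per-cell pixel partition", {
  out <- small_synth()
  ds <- out$dataset
  labels <- ground_truth_labels(out$ground_truth, ds)
  ft <- feature_table(ds, labels)
  tot <- tapply(ft$n_pixels, ft$cell_id, sum)
  for (id in cell_ids(ds))
    expect_equal(unname(tot[id]), nrow(ds$cells[[id]]$coords))
})
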