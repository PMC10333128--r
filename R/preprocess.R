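# Preprocessing: background subtraction, quantile normalization, cell-level
# splitting, 3x3 neighborhood patch extraction and training-pixel sampling.

#' Subtract per-channel background levels
#'
#' Background offsets stored in the panel are subtracted from every pixel.
#' Values are deliberately not clamped at zero: subtraction preserves the
#' linear structure of the data and downstream normalization and modelling
#' tolerate negative values.
#'
#' @param ds a `MultiplexedDataset` whose panel has background levels set
#' @return the dataset with background-subtracted intensities
#' @export
background_subtract <- function(ds) {
  bg <- ds$panel$background
  if (length(bg) != n_channels(ds))
    stop("background_levels length does not match channel count")
  ds$cells <- lapply(ds$cells, function(cell) {
    cell$intensities <- sweep(cell$intensities, 2, bg, "-")
    cell
  })
  ds
}

#' Fit and apply per-channel quantile normalization
#'
#' Each channel is divided by its `q`-quantile (linear-interpolation
#' definition, type 7) computed over the union of all pixels of the dataset
#' (optionally restricted to some splits). The fitted divisors are stored in
#' the panel so that inference on new data is reproducible.
#'
#' @param ds a `MultiplexedDataset`
#' @param q quantile level, default 0.98
#' @param fit_split optional split restriction for fitting the quantiles
#'   (default NULL: all pixels)
#' @return the normalized dataset, with `panel$quantiles` filled
#' @export
fit_and_apply_quantile_norm <- function(ds, q = 0.98, fit_split = NULL) {
  px <- dataset_pixels(ds, fit_split)
  qs <- apply(px$intensities, 2, quantile, probs = q, names = FALSE, type = 7)
  bad <- which(qs <= 0)
  if (length(bad))
    stop(sprintf("q-quantile is not positive for channel(s): %s",
                 paste(ds$panel$names[bad], collapse = ", ")))
  ds$cells <- lapply(ds$cells, function(cell) {
    cell$intensities <- sweep(cell$intensities, 2, qs, "/")
    cell
  })
  ds$panel$quantiles <- qs
  ds
}

#' Split cells into train/validation/test sets
#'
#' The split is made at the cell level so that all pixels of a cell share a
#' split (no pixel-level leakage). Deterministic given the seed.
#'
#' @param ds a `MultiplexedDataset`
#' @param fractions numeric length-3 vector (train, val, test) summing to 1
#' @param seed integer seed
#' @return the dataset with `$split` set
#' @export
split_cells <- function(ds, fractions = c(0.8, 0.1, 0.1), seed = 0L) {
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")
  n <- length(ds$cells)
  if (n < sum(fractions > 0)) stop("fewer cells than requested splits")
  set.seed(seed)
  ord <- sample.int(n)
  n_train <- round(fractions[1] * n)
  n_val <- round(fractions[2] * n)
  if (n_train + n_val > n) n_val <- n - n_train
  lab <- rep(c("train", "val", "test"),
             c(n_train, n_val, n - n_train - n_val))
  split <- setNames(lab[order(ord)], cell_ids(ds))
  ds$split <- split
  ds
}

patch_offsets <- function(neighborhood) {
  h <- (neighborhood - 1L) %/% 2L
  expand.grid(dc = -h:h, dr = -h:h)[, c("dr", "dc")]
}

#' Extract local neighborhood patches for every pixel of a cell
#'
#' Each pixel yields one `neighborhood x neighborhood` patch of multiplexed
#' profiles. Neighbor positions falling outside the segmented cell are filled,
#' per channel, with the mean over the valid pixels of that window (the center
#' is always valid). Patches are stored as an n x neighborhood^2 x C array;
#' positions are ordered row-major, so the center is position
#' `(neighborhood^2 + 1) / 2`.
#'
#' @param cell a `CellRecord`
#' @param neighborhood odd window size >= 1 (default 3)
#' @return a `PixelPatchBatch` without condition encodings (see
#'   [patch_batch()]); fields: `patches`, `centers`, `provenance`
#' @export
extract_patches <- function(cell, neighborhood = 3L) {
  if (neighborhood < 1L || neighborhood %% 2L != 1L)
    stop("neighborhood must be odd and >= 1")
  h <- (neighborhood - 1L) %/% 2L
  co <- cell$coords
  n <- nrow(co)
  C <- ncol(cell$intensities)
  r0 <- co[, 1] - min(co[, 1]) + 1L
  c0 <- co[, 2] - min(co[, 2]) + 1L
  grid <- matrix(0L, max(r0) + 2L * h, max(c0) + 2L * h)
  grid[cbind(r0 + h, c0 + h)] <- seq_len(n)
  P <- array(NA_real_, c(n, neighborhood^2, C))
  off <- patch_offsets(neighborhood)
  for (pos in seq_len(nrow(off))) {
    nb <- grid[cbind(r0 + h + off$dr[pos], c0 + h + off$dc[pos])]
    ok <- nb > 0L
    if (any(ok)) P[ok, pos, ] <- cell$intensities[nb[ok], , drop = FALSE]
  }
  if (neighborhood > 1L) {
    for (ch in seq_len(C)) {
      M <- P[, , ch, drop = FALSE]
      dim(M) <- c(n, neighborhood^2)
      nas <- is.na(M)
      if (any(nas)) {
        fill <- rowMeans(M, na.rm = TRUE)
        M[nas] <- fill[row(M)[nas]]
        P[, , ch] <- M
      }
    }
  }
  center <- (neighborhood^2 + 1L) %/% 2L
  centers <- P[, center, , drop = FALSE]
  dim(centers) <- c(n, C)
  structure(list(patches = P, centers = centers, onehot = NULL,
                 provenance = data.frame(cell_id = rep(cell$cell_id, n),
                                         pixel = seq_len(n),
                                         stringsAsFactors = FALSE)),
            class = "PixelPatchBatch")
}

#' Assemble a patch batch with condition one-hot encodings
#'
#' @param batches list of per-cell batches from [extract_patches()]
#' @param schema a [condition_schema()]
#' @param conditions_by_cell named list cell_id -> named condition vector
#' @return a `PixelPatchBatch` with `onehot` filled
#' @export
patch_batch <- function(batches, schema, conditions_by_cell) {
  n <- vapply(batches, function(b) nrow(b$centers), 1L)
  C <- dim(batches[[1]]$patches)[3]
  P9 <- dim(batches[[1]]$patches)[2]
  P <- array(NA_real_, c(sum(n), P9, C))
  at <- 0L
  for (b in batches) {
    P[at + seq_len(nrow(b$centers)), , ] <- b$patches
    at <- at + nrow(b$centers)
  }
  centers <- do.call(rbind, lapply(batches, function(b) b$centers))
  prov <- do.call(rbind, lapply(batches, function(b) b$provenance))
  rownames(prov) <- NULL
  cond <- do.call(rbind, lapply(batches, function(b) {
    cv <- conditions_by_cell[[b$provenance$cell_id[1]]]
    as.data.frame(as.list(cv), stringsAsFactors = FALSE)[
      rep(1, nrow(b$centers)), , drop = FALSE]
  }))
  structure(list(patches = P, centers = centers,
                 onehot = condition_onehot(schema, cond),
                 provenance = prov),
            class = "PixelPatchBatch")
}

#' Number of patches in a batch
#' @param batch a `PixelPatchBatch`
#' @return integer
#' @export
n_patches <- function(batch) nrow(batch$centers)

conditions_by_cell <- function(ds) {
  lapply(ds$cells, function(cell) unlist(cell$conditions))
}

#' Sample training pixels and build their patch batch
#'
#' Per cell, `ceiling(fraction * n_pixels)` pixels are drawn without
#' replacement (ceiling so every cell contributes at least one pixel), patches
#' extracted and condition one-hots attached. Deterministic given the seed.
#'
#' @param ds a `MultiplexedDataset` with a split assigned
#' @param fraction_per_cell fraction of pixels per cell, in (0, 1]
#' @param seed integer seed
#' @param split character vector of splits to draw from (default "train")
#' @param neighborhood patch window size (default 3)
#' @return a `PixelPatchBatch`
#' @export
sample_training_pixels <- function(ds, fraction_per_cell, seed = 0L,
                                   split = "train", neighborhood = 3L) {
  if (fraction_per_cell <= 0 || fraction_per_cell > 1)
    stop("fraction_per_cell must be in (0, 1]")
  cells <- cells_in_split(ds, split)
  if (length(cells) == 0) stop(sprintf("empty split: %s",
                                       paste(split, collapse = "+")))
  set.seed(seed)
  batches <- lapply(cells, function(cell) {
    n <- nrow(cell$coords)
    take <- sort(sample.int(n, ceiling(fraction_per_cell * n)))
    b <- extract_patches(cell, neighborhood)
    b$patches <- b$patches[take, , , drop = FALSE]
    b$centers <- b$centers[take, , drop = FALSE]
    b$provenance <- b$provenance[take, , drop = FALSE]
    b
  })
  patch_batch(batches, ds$schema, conditions_by_cell(ds))
}

#' Patch batch covering every pixel of the given cells
#'
#' @param ds a `MultiplexedDataset`
#' @param split optional split restriction (default NULL: all cells)
#' @param neighborhood patch window size (default 3)
#' @return a `PixelPatchBatch`
#' @export
all_pixel_patches <- function(ds, split = NULL, neighborhood = 3L) {
  cells <- cells_in_split(ds, split)
  batches <- lapply(cells, extract_patches, neighborhood = neighborhood)
  patch_batch(batches, ds$schema, conditions_by_cell(ds))
}
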