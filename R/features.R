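# Per-cell landmark quantification: mean intensities, object morphology
# (8-connected components with size filters, circularity), and spatial
# co-occurrence curves over log-spaced distance intervals.

#' Per-landmark per-channel mean intensities of one cell
#'
#' Landmarks absent from the cell are recorded with pixel count 0 and missing
#' intensities (dropped before statistics downstream).
#'
#' @param cell a `CellRecord`
#' @param labels per-pixel landmark labels for this cell
#' @param all_csls optional full landmark alphabet (so absent landmarks get a
#'   zero-count row)
#' @return data.frame: cell_id, csl, n_pixels, one mean-intensity column per
#'   channel
#' @export
per_csl_mean_intensity <- function(cell, labels, all_csls = NULL) {
  if (length(labels) != nrow(cell$coords))
    stop("labels not aligned with the cell's pixels")
  csls <- as.character(all_csls %||% sort(unique(as.character(labels))))
  counts <- table(factor(as.character(labels), levels = csls))
  means <- rowsum(cell$intensities, group = factor(as.character(labels),
                                                   levels = csls))
  means <- means / pmax(as.vector(counts[rownames(means)]), 1)
  out <- data.frame(cell_id = cell$cell_id, csl = csls,
                    n_pixels = as.vector(counts), stringsAsFactors = FALSE)
  im <- matrix(NA_real_, length(csls), ncol(cell$intensities))
  im[match(rownames(means), csls), ] <- means
  im[out$n_pixels == 0, ] <- NA_real_
  colnames(im) <- colnames(cell$intensities) %||%
    paste0("ch", seq_len(ncol(cell$intensities)))
  cbind(out, as.data.frame(im))
}

# 8-connected components of a pixel coordinate set; returns per component a
# row of (area, perimeter) with perimeter = count of exposed 4-neighbour unit
# edges, plus the component id of every pixel.
connected_components <- function(coords) {
  n <- nrow(coords)
  if (n == 0) return(list(stats = data.frame(area = integer(0),
                                             perimeter = integer(0)),
                          membership = integer(0)))
  width <- max(coords[, 2]) - min(coords[, 2]) + 3L
  key <- (coords[, 1] - min(coords[, 1]) + 1L) * width +
    (coords[, 2] - min(coords[, 2]) + 1L)
  idx_of <- new.env(hash = TRUE, size = n)
  for (i in seq_len(n)) assign(as.character(key[i]), i, envir = idx_of)
  off8 <- cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
                dc = c(-1, 0, 1, -1, 1, -1, 0, 1))
  edges <- list()
  for (o in seq_len(8)) {
    nb_key <- key + off8[o, 1] * width + off8[o, 2]
    hit <- vapply(as.character(nb_key), function(kk)
      if (exists(kk, envir = idx_of, inherits = FALSE))
        get(kk, envir = idx_of) else 0L, 0L)
    sel <- hit > 0L
    if (any(sel)) edges[[length(edges) + 1L]] <- cbind(which(sel), hit[sel])
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (length(edges))
    g <- igraph::add_edges(g, t(do.call(rbind, edges)))
  comp <- igraph::components(g)$membership
  # perimeter: 4-neighbour exposure
  off4 <- off8[c(2, 4, 5, 7), , drop = FALSE]
  exposure <- rep(4L, n)
  for (o in seq_len(4)) {
    nb_key <- key + off4[o, 1] * width + off4[o, 2]
    inside <- vapply(as.character(nb_key), function(kk)
      exists(kk, envir = idx_of, inherits = FALSE), TRUE)
    exposure <- exposure - as.integer(inside)
  }
  stats <- data.frame(area = as.vector(table(comp)),
                      perimeter = as.vector(rowsum(exposure, comp)))
  list(stats = stats, membership = comp)
}

#' Landmark objects of one cell after size filtering
#'
#' 8-connected components of the pixels carrying the given landmark label.
#' Two filters: components of 10 or fewer pixels are dropped; then, with the
#' survivors sorted by increasing area, the smallest are removed while the
#' cumulative removed area stays below 10% of the survivors' total area (if no
#' component is smaller than 10% of the total, none is removed).
#'
#' @param cell a `CellRecord`
#' @param labels per-pixel landmark labels for this cell
#' @param csl the landmark to extract
#' @param min_area components with area <= `min_area` are dropped (default 10)
#' @param cum_frac cumulative small-component removal fraction (default 0.1)
#' @return data.frame of surviving components: `area`, `perimeter`,
#'   `circularity`
#' @export
csl_objects <- function(cell, labels, csl, min_area = 10L, cum_frac = 0.1) {
  sel <- as.character(labels) == as.character(csl)
  comps <- connected_components(cell$coords[sel, , drop = FALSE])$stats
  filter_components(comps, min_area, cum_frac)
}

# The two object filters, exposed separately so they can be tested on bare
# area lists.
filter_components <- function(comps, min_area = 10L, cum_frac = 0.1) {
  comps <- comps[comps$area > min_area, , drop = FALSE]
  if (nrow(comps) == 0) return(add_circularity(comps))
  comps <- comps[order(comps$area), , drop = FALSE]
  total <- sum(comps$area)
  cum <- cumsum(comps$area)
  drop <- cum < cum_frac * total
  comps <- comps[!drop, , drop = FALSE]
  add_circularity(comps[order(comps$area, decreasing = TRUE), , drop = FALSE])
}

add_circularity <- function(comps) {
  comps$circularity <- if (nrow(comps)) 4 * pi * comps$area / comps$perimeter^2
  else numeric(0)
  rownames(comps) <- NULL
  comps
}

#' Aggregate object statistics
#'
#' Circularity c = 4*pi*a / p^2 with the perimeter p counted as exposed unit
#' pixel edges (exact for axis-aligned rectangles: an s x s square scores
#' pi/4). Cross-cell aggregation downstream uses per-condition medians.
#'
#' @param components data.frame from [csl_objects()]
#' @return list: `count`, `mean_area`, `median_area`, `mean_circularity`,
#'   `median_circularity` (NA when no components survive)
#' @export
object_stats <- function(components) {
  if (nrow(components) == 0)
    return(list(count = 0L, mean_area = NA_real_, median_area = NA_real_,
                mean_circularity = NA_real_, median_circularity = NA_real_))
  list(count = nrow(components),
       mean_area = mean(components$area),
       median_area = median(components$area),
       mean_circularity = mean(components$circularity),
       median_circularity = median(components$circularity))
}

#' Log-spaced distance intervals
#'
#' `n` half-open intervals `[d_a, d_b)` with geometrically spaced endpoints
#' between `d_min` and `d_max`, in pixel units.
#'
#' @param n number of intervals (default 19)
#' @param d_min smallest distance (default 2)
#' @param d_max largest distance (default 80)
#' @return data.frame with `d_a`, `d_b` (strictly increasing)
#' @export
log_spaced_intervals <- function(n = 19L, d_min = 2, d_max = 80) {
  breaks <- exp(seq(log(d_min), log(d_max), length.out = n + 1L))
  data.frame(d_a = breaks[-(n + 1L)], d_b = breaks[-1L])
}

#' Spatial co-occurrence curves of one cell
#'
#' For landmarks (i, j) and a distance annulus, the score is the conditional
#' probability of finding label j at that distance from a label-i pixel,
#' relative to a reference probability: `variant = "conditional_over_marginal"`
#' (default) divides by the overall label-j pixel fraction p(j) of the cell, so
#' the score is 1 under spatial randomness; `variant = "as_printed"` divides by
#' p(i) instead. Ordered pixel pairs are counted; self-pairs are excluded;
#' annuli are half-open `[d_a, d_b)` between pixel centers. Entries with an
#' empty annulus or an absent label are missing.
#'
#' @param cell a `CellRecord` (or an n x 2 coordinate matrix)
#' @param labels per-pixel landmark labels
#' @param intervals data.frame from [log_spaced_intervals()]
#' @param all_csls optional full landmark alphabet for the curve dimensions
#' @param variant denominator convention (see above)
#' @return numeric array csl x csl x interval (dimnames set); attribute
#'   `intervals` carries the interval table
#' @export
co_occurrence <- function(cell, labels, intervals = log_spaced_intervals(),
                          all_csls = NULL,
                          variant = c("conditional_over_marginal",
                                      "as_printed")) {
  variant <- match.arg(variant)
  coords <- if (is.matrix(cell)) cell else cell$coords
  if (nrow(coords) < 2) stop("need at least 2 pixels")
  if (any(diff(intervals$d_a) <= 0) || any(intervals$d_b <= intervals$d_a))
    stop("intervals must be strictly increasing")
  labels <- as.character(labels)
  csls <- as.character(all_csls %||% sort(unique(labels)))
  L <- length(csls)
  B <- nrow(intervals)
  li <- match(labels, csls)
  n <- length(labels)
  D <- as.matrix(stats::dist(coords))
  diag(D) <- -1  # exclude self-pairs from every annulus
  breaks <- c(intervals$d_a, intervals$d_b[B])
  bin <- findInterval(D, breaks, rightmost.closed = FALSE)
  bin[bin == B + 1L] <- 0L  # beyond the last interval
  sel <- bin > 0L
  code <- (bin[sel] - 1L) * L * L + (li[row(D)[sel]] - 1L) * L + li[col(D)[sel]]
  counts <- array(tabulate(code, nbins = B * L * L), c(L, L, B))
  # counts[j, i, b] = ordered pairs (u labeled i, v labeled j) in annulus b
  pj <- as.vector(table(factor(labels, levels = csls))) / n
  out <- array(NA_real_, c(L, L, B), dimnames = list(csls, csls, NULL))
  for (b in seq_len(B)) {
    counts_b <- matrix(counts[, , b], L, L)
    tot_i <- colSums(counts_b)                # pairs from label i, any j
    pj_given_i <- sweep(t(counts_b), 1, tot_i, "/")       # i x j
    pj_given_i[tot_i == 0, ] <- NA_real_
    out[, , b] <- switch(variant,
      conditional_over_marginal = sweep(pj_given_i, 2, pj, "/"),
      as_printed = sweep(pj_given_i, 1, pj, "/"))
    out[pj == 0, , b] <- NA_real_
    out[, pj == 0, b] <- NA_real_
  }
  attr(out, "intervals") <- intervals
  out
}

# O(n^2) reference implementation used as the test oracle.
co_occurrence_bruteforce <- function(coords, labels,
                                     intervals = log_spaced_intervals(),
                                     all_csls = NULL,
                                     variant = "conditional_over_marginal") {
  labels <- as.character(labels)
  csls <- as.character(all_csls %||% sort(unique(labels)))
  L <- length(csls); B <- nrow(intervals)
  counts <- array(0, c(L, L, B))
  n <- nrow(coords)
  for (u in seq_len(n)) for (v in seq_len(n)) {
    if (u == v) next
    d <- sqrt(sum((coords[u, ] - coords[v, ])^2))
    for (b in seq_len(B)) {
      if (d >= intervals$d_a[b] && d < intervals$d_b[b]) {
        i <- match(labels[u], csls); j <- match(labels[v], csls)
        counts[j, i, b] <- counts[j, i, b] + 1
      }
    }
  }
  pj <- as.vector(table(factor(labels, levels = csls))) / n
  out <- array(NA_real_, c(L, L, B), dimnames = list(csls, csls, NULL))
  for (b in seq_len(B)) {
    tot_i <- colSums(counts[, , b])
    for (i in seq_len(L)) for (j in seq_len(L)) {
      if (tot_i[i] == 0 || pj[j] == 0 || pj[i] == 0) next
      pji <- counts[j, i, b] / tot_i[i]
      out[i, j, b] <- if (variant == "conditional_over_marginal")
        pji / pj[j] else pji / pj[i]
    }
  }
  attr(out, "intervals") <- intervals
  out
}

#' Mean log2 co-occurrence across cells with a normal-approximation 95% CI
#'
#' @param curves list of per-cell co-occurrence arrays (same dimensions)
#' @param from,to landmark names selecting the curve
#' @return data.frame: interval index, `d_a`, `d_b`, `mean_log2`, `lo`, `hi`,
#'   `n_cells` (missing per-cell values are ignored; intervals with no defined
#'   cell are NA)
#' @export
mean_log2_cooccurrence <- function(curves, from, to) {
  intervals <- attr(curves[[1]], "intervals")
  vals <- vapply(curves, function(a) log2(a[from, to, ]),
                 numeric(dim(curves[[1]])[3]))
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = 1)
  vals[!is.finite(vals)] <- NA_real_
  m <- rowMeans(vals, na.rm = TRUE)
  nn <- rowSums(!is.na(vals))
  se <- apply(vals, 1, sd, na.rm = TRUE) / sqrt(pmax(nn, 1))
  m[nn == 0] <- NA_real_
  data.frame(interval = seq_along(m), d_a = intervals$d_a, d_b = intervals$d_b,
             mean_log2 = m, lo = m - 1.96 * se, hi = m + 1.96 * se,
             n_cells = nn)
}

#' Area between two co-occurrence curves
#'
#' Trapezoidal integral of |log2 A - log2 B| over log-transformed interval
#' midpoints; symmetric in its arguments. Intervals where either curve is
#' missing are dropped.
#'
#' @param curveA,curveB numeric vectors of co-occurrence scores on the same
#'   intervals
#' @param intervals data.frame from [log_spaced_intervals()]
#' @return nonnegative real
#' @export
curve_area_difference <- function(curveA, curveB,
                                  intervals = log_spaced_intervals()) {
  if (length(curveA) != length(curveB) || length(curveA) != nrow(intervals))
    stop("curves and intervals have mismatched lengths")
  x <- log2(sqrt(intervals$d_a * intervals$d_b))
  y <- abs(log2(curveA) - log2(curveB))
  ok <- is.finite(y)
  if (sum(ok) < 2) return(NA_real_)
  x <- x[ok]; y <- y[ok]
  sum(diff(x) * (head(y, -1) + y[-1]) / 2)
}

#' Per-cell feature table over annotated landmarks
#'
#' One row per (cell, landmark): pixel count, per-channel mean intensities and
#' object morphology (after the standard size filters).
#'
#' @param ds a `MultiplexedDataset`
#' @param labels per-pixel landmark labels aligned with [dataset_pixels()]
#'   order (cells in dataset order)
#' @param min_area,cum_frac object filter parameters (see [csl_objects()])
#' @return data.frame (`FeatureTable`)
#' @export
feature_table <- function(ds, labels, min_area = 10L, cum_frac = 0.1) {
  labs_by_cell <- split_labels_by_cell(ds, labels)
  csls <- sort(unique(as.character(labels)))
  rows <- lapply(ds$cells, function(cell) {
    lab <- labs_by_cell[[cell$cell_id]]
    ft <- per_csl_mean_intensity(cell, lab, all_csls = csls)
    names(ft)[-(1:3)] <- ds$panel$names
    morph <- do.call(rbind, lapply(csls, function(cs) {
      if (!any(lab == cs)) return(data.frame(object_count = 0L,
                                             mean_area = NA_real_,
                                             median_area = NA_real_,
                                             mean_circularity = NA_real_,
                                             median_circularity = NA_real_))
      st <- object_stats(csl_objects(cell, lab, cs, min_area, cum_frac))
      data.frame(object_count = st$count, mean_area = st$mean_area,
                 median_area = st$median_area,
                 mean_circularity = st$mean_circularity,
                 median_circularity = st$median_circularity)
    }))
    cbind(ft, morph)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Split a dataset-aligned label vector into per-cell label vectors
#' @param ds a `MultiplexedDataset`
#' @param labels per-pixel labels in [dataset_pixels()] order
#' @return named list cell_id -> label vector
#' @export
split_labels_by_cell <- function(ds, labels) {
  n <- vapply(ds$cells, function(x) nrow(x$coords), 1L)
  if (length(labels) != sum(n))
    stop("labels length does not match the dataset pixel count")
  split(as.character(labels), rep(cell_ids(ds), n))[cell_ids(ds)]
}

#' Co-occurrence curves for every cell of a dataset
#'
#' @param ds a `MultiplexedDataset`
#' @param labels per-pixel landmark labels in dataset order
#' @param intervals interval table (default [log_spaced_intervals()])
#' @param variant see [co_occurrence()]
#' @return named list cell_id -> co-occurrence array
#' @export
cooccurrence_curves <- function(ds, labels,
                                intervals = log_spaced_intervals(),
                                variant = "conditional_over_marginal") {
  labs_by_cell <- split_labels_by_cell(ds, labels)
  csls <- sort(unique(as.character(labels)))
  lapply(ds$cells, function(cell)
    co_occurrence(cell, labs_by_cell[[cell$cell_id]], intervals,
                  all_csls = csls, variant = variant))
}
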