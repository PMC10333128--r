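# Synthetic multiplexed cell images with ground-truth structure labels.
#
# Each cell is a digitized axis-aligned ellipse ("nucleus") containing
# non-overlapping disk-shaped organelle objects. Every structure has a
# characteristic per-channel enrichment profile relative to the background
# compartment; conditions act multiplicatively on a subset of channels and can
# optionally relocate part of a channel's intensity between structures.

#' Describe a synthetic subcellular structure class
#'
#' @param name structure label
#' @param count_range integer interval (min, max) of objects per cell
#' @param radius_range disk radius interval in pixels (radii >= 1)
#' @param enrichment positive per-channel multiplicative factors relative to
#'   the background compartment
#' @return a `StructureSpec`
#' @export
structure_spec <- function(name, count_range, radius_range, enrichment) {
  if (any(radius_range < 1)) stop("radii must be >= 1")
  if (any(enrichment <= 0)) stop("enrichment factors must be positive")
  structure(list(name = name, count_range = count_range,
                 radius_range = radius_range,
                 enrichment = as.numeric(enrichment)),
            class = "StructureSpec")
}

#' Describe the effect of one condition level
#'
#' @param condition_level the level this effect applies to
#' @param channel_scales positive per-channel multiplicative factors
#' @param relocalization optional list of moves, each a list with elements
#'   `channel` (index), `from`/`to` (structure names, `"background"` allowed)
#'   and `fraction` in \[0, 1\]: the given fraction of the cell-total intensity
#'   of that channel in the `from` structure is moved (uniformly per pixel) to
#'   the `to` structure, conserving the cell total
#' @return a `ConditionEffect`
#' @export
condition_effect <- function(condition_level, channel_scales,
                             relocalization = NULL) {
  if (any(channel_scales <= 0)) stop("channel scales must be positive")
  for (m in relocalization)
    if (m$fraction < 0 || m$fraction > 1)
      stop("relocalization fraction must be in [0, 1]")
  structure(list(condition_level = condition_level,
                 channel_scales = as.numeric(channel_scales),
                 relocalization = relocalization),
            class = "ConditionEffect")
}

digitized_ellipse <- function(a, b) {
  r <- as.integer(round(a)); cc <- as.integer(round(b))
  g <- expand.grid(row = -r:r, col = -cc:cc)
  keep <- (g$row / a)^2 + (g$col / b)^2 <= 1
  as.matrix(g[keep, ])
}

place_objects <- function(coords, structures, seed_state_unused = NULL,
                          max_attempts = 1000L) {
  # rejection sampling of non-overlapping disks fully inside the nucleus
  key <- paste(coords[, 1], coords[, 2])
  inside <- new.env(hash = TRUE, size = length(key))
  for (k in key) assign(k, TRUE, envir = inside)
  labels <- rep("background", nrow(coords))
  for (s in structures) {
    count <- if (s$count_range[1] == s$count_range[2]) s$count_range[1] else
      sample(s$count_range[1]:s$count_range[2], 1)
    for (obj in seq_len(count)) {
      placed <- FALSE
      for (attempt in seq_len(max_attempts)) {
        radius <- runif(1, s$radius_range[1], s$radius_range[2])
        ctr <- coords[sample.int(nrow(coords), 1), ]
        rr <- as.integer(ceiling(radius))
        g <- expand.grid(row = -rr:rr, col = -rr:rr)
        g <- g[g$row^2 + g$col^2 <= radius^2, , drop = FALSE]
        pr <- g$row + ctr[1]; pc <- g$col + ctr[2]
        pk <- paste(pr, pc)
        if (!all(vapply(pk, exists, TRUE, envir = inside, inherits = FALSE)))
          next
        idx <- match(pk, key)
        if (any(labels[idx] != "background")) next
        labels[idx] <- s$name
        placed <- TRUE
        break
      }
      if (!placed)
        stop(sprintf("could not place a '%s' object after %d attempts; %s",
                     s$name, max_attempts,
                     "structures do not fit in the nucleus"))
    }
  }
  labels
}

#' Generate a synthetic multiplexed dataset with ground truth
#'
#' Pixel intensity is `base_level * structure enrichment * condition scale`
#' (times a per-well log-normal factor when `well_sd > 0`), optionally
#' redistributed by relocalization moves, then Poisson-resampled (optional)
#' and finally perturbed by additive Gaussian noise. Negative values are
#' allowed, mirroring background-subtracted real data. Deterministic given
#' the seed.
#'
#' @param n_cells_per_condition cells per condition level
#' @param structures list of [structure_spec()] (background is implicit)
#' @param effects list of [condition_effect()], one per condition level; the
#'   level set of the "perturbation" field is taken from these
#' @param channels character vector of channel names
#' @param base_level background-compartment intensity (default 100)
#' @param noise list with `gaussian_sd` (additive noise sd) and `poisson`
#'   (logical; resample the pre-noise mean)
#' @param nucleus_radius_range semi-axis interval in pixels (default 20-26)
#' @param n_wells_per_condition wells per condition (default 4)
#' @param well_sd sd of the per-well log-normal intensity factor (default 0)
#' @param seed integer seed
#' @return list with `dataset` (a `MultiplexedDataset`) and `ground_truth`
#'   (class `GroundTruth`: per-cell pixel labels plus the generating
#'   parameters)
#' @export
generate_dataset <- function(n_cells_per_condition = 100L,
                             structures,
                             effects,
                             channels = paste0("ch", 1:8),
                             base_level = 100,
                             noise = list(gaussian_sd = 10, poisson = FALSE),
                             nucleus_radius_range = c(20, 26),
                             n_wells_per_condition = 4L,
                             well_sd = 0,
                             seed = 0L) {
  if (length(structures) < 1) stop("need at least one structure")
  if (length(effects) < 1) stop("need at least one condition level")
  C <- length(channels)
  for (s in structures)
    if (length(s$enrichment) != C) stop("enrichment length != channel count")
  for (e in effects)
    if (length(e$channel_scales) != C) stop("channel_scales length != channels")
  levels <- vapply(effects, function(e) e$condition_level, "")
  schema <- condition_schema(list(perturbation = levels))
  panel <- channel_panel(channels)
  enr <- rbind(background = rep(1, C),
               do.call(rbind, lapply(structures, function(s) s$enrichment)))
  rownames(enr) <- c("background", vapply(structures, function(s) s$name, ""))

  set.seed(seed)
  cells <- list()
  gt <- list()
  for (ci in seq_along(effects)) {
    eff <- effects[[ci]]
    wells <- sprintf("%s_w%d", eff$condition_level,
                     seq_len(n_wells_per_condition))
    well_factor <- matrix(exp(rnorm(n_wells_per_condition * C, 0, well_sd)),
                          n_wells_per_condition, C)
    for (j in seq_len(n_cells_per_condition)) {
      a <- runif(1, nucleus_radius_range[1], nucleus_radius_range[2])
      b <- runif(1, nucleus_radius_range[1], nucleus_radius_range[2])
      coords <- digitized_ellipse(a, b)
      coords <- sweep(coords, 2, apply(coords, 2, min))
      labels <- place_objects(coords, structures)
      E <- base_level * enr[labels, , drop = FALSE] *
        rep(eff$channel_scales, each = nrow(coords))
      wi <- ((j - 1L) %% n_wells_per_condition) + 1L
      if (well_sd > 0) E <- E * rep(well_factor[wi, ], each = nrow(coords))
      for (m in eff$relocalization) {
        from <- labels == m$from; to <- labels == m$to
        if (!any(from) || !any(to)) next
        moved <- m$fraction * sum(E[from, m$channel])
        E[from, m$channel] <- E[from, m$channel] * (1 - m$fraction)
        E[to, m$channel] <- E[to, m$channel] + moved / sum(to)
      }
      if (isTRUE(noise$poisson))
        E[] <- rpois(length(E), lambda = pmax(E, 0))
      if (noise$gaussian_sd > 0)
        E <- E + matrix(rnorm(length(E), 0, noise$gaussian_sd), nrow(E))
      id <- sprintf("%s_c%03d", eff$condition_level, j)
      cells[[id]] <- cell_record(id, wells[wi],
                                 list(perturbation = eff$condition_level),
                                 coords, E)
      gt[[id]] <- labels
    }
  }
  ds <- multiplexed_dataset(cells, panel, schema)
  truth <- structure(list(labels = gt,
                          params = list(structures = structures,
                                        effects = effects,
                                        channels = channels,
                                        base_level = base_level,
                                        noise = noise,
                                        nucleus_radius_range = nucleus_radius_range,
                                        n_wells_per_condition = n_wells_per_condition,
                                        well_sd = well_sd, seed = seed)),
                     class = "GroundTruth")
  list(dataset = ds, ground_truth = truth)
}

#' Per-cell ground-truth structure fractions
#'
#' @param gt a `GroundTruth`
#' @return data.frame (cell_id, label, fraction); fractions sum to 1 per cell
#' @export
ground_truth_fractions <- function(gt) {
  out <- lapply(names(gt$labels), function(id) {
    tab <- table(gt$labels[[id]])
    data.frame(cell_id = id, label = names(tab),
               fraction = as.numeric(tab) / sum(tab),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Ground-truth labels stacked in dataset pixel order
#'
#' @param gt a `GroundTruth`
#' @param ds the matching `MultiplexedDataset` (defines cell order); if NULL,
#'   the generator's own cell order is used
#' @return character vector, one label per pixel
#' @export
ground_truth_labels <- function(gt, ds = NULL) {
  ids <- if (is.null(ds)) names(gt$labels) else cell_ids(ds)
  unlist(gt$labels[ids], use.names = FALSE)
}

#' Default small synthetic study configuration
#'
#' Two conditions ("control", "treated") of 100 cells each; 8 channels;
#' nuclei with semi-axes 20-26 px; three structures (one or two large blobs,
#' a few medium speckles, many small dots) plus background, each structure
#' enriched sixfold in two dedicated channels and depleted (x0.4) in the other
#' structures' marker channels; the treated condition scales channels 7 and 8
#' twofold; additive Gaussian noise with sd 10 on a base level of 100.
#' Chosen so the full pipeline runs in minutes on one CPU.
#'
#' @return a named list of [generate_dataset()] arguments
#' @export
synth_small_config <- function() {
  list(
    n_cells_per_condition = 100L,
    structures = list(
      structure_spec("large", c(1, 2), c(5, 8),
                     c(6, 6, 0.4, 0.4, 0.4, 0.4, 1, 1)),
      structure_spec("speckles", c(3, 8), c(2, 4),
                     c(0.4, 0.4, 6, 6, 0.4, 0.4, 1, 1)),
      structure_spec("dots", c(5, 15), c(1, 2),
                     c(0.4, 0.4, 0.4, 0.4, 6, 6, 1, 1))),
    effects = list(
      condition_effect("control", rep(1, 8)),
      condition_effect("treated", c(1, 1, 1, 1, 1, 1, 2, 2))),
    channels = paste0("ch", 1:8),
    base_level = 100,
    noise = list(gaussian_sd = 10, poisson = FALSE),
    nucleus_radius_range = c(20, 26),
    n_wells_per_condition = 4L,
    well_sd = 0)
}

#' Generate the default small synthetic study
#'
#' @param seed integer seed
#' @param ... overrides for [synth_small_config()] entries
#' @return list with `dataset` and `ground_truth` (see [generate_dataset()])
#' @export
generate_synth_small <- function(seed = 0L, ...) {
  cfg <- synth_small_config()
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad))
    stop(sprintf("unknown generator argument(s): %s", paste(bad, collapse = ", ")))
  cfg[names(dots)] <- dots  # wholesale replacement, including list values
  do.call(generate_dataset, c(cfg, list(seed = seed)))
}
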