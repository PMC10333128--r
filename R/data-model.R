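# Core data model: channel panel, condition schema, per-cell pixel records and
# the dataset container shared by all pipeline stages.

#' Channel panel
#'
#' Describes the ordered channel set of a multiplexed dataset, together with
#' per-channel background intensity offsets and (once fitted) the per-channel
#' quantile divisors used for normalization.
#'
#' @param names character vector of unique channel identifiers
#' @param background nonnegative per-channel background intensity offsets
#' @param quantiles optional positive per-channel normalization divisors
#'   (filled by [fit_and_apply_quantile_norm()])
#' @return an object of class `ChannelPanel`
#' @export
channel_panel <- function(names, background = rep(0, length(names)),
                          quantiles = NULL) {
  names <- as.character(names)
  if (anyDuplicated(names)) stop("channel names must be unique")
  if (length(background) != length(names))
    stop("background_levels length must equal number of channels")
  if (any(background < 0)) stop("background levels must be nonnegative")
  if (!is.null(quantiles)) {
    if (length(quantiles) != length(names) || any(quantiles <= 0))
      stop("normalization quantiles must be positive, one per channel")
  }
  structure(list(names = names, background = as.numeric(background),
                 quantiles = quantiles),
            class = "ChannelPanel")
}

#' Condition schema
#'
#' Ordered categorical condition fields (e.g. perturbation, cell cycle stage)
#' with their level sets. Cells carry one level per field; levels are one-hot
#' encoded per field and concatenated when fed to the conditional model.
#'
#' @param levels named list mapping each condition field to its ordered
#'   character vector of levels
#' @return an object of class `ConditionSchema`
#' @export
condition_schema <- function(levels) {
  if (is.null(names(levels)) || any(names(levels) == ""))
    stop("levels must be a named list (one entry per condition field)")
  if (any(vapply(levels, length, 1L) == 0))
    stop("every condition field needs at least one level")
  structure(list(fields = names(levels),
                 levels = lapply(levels, as.character)),
            class = "ConditionSchema")
}

#' Single segmented cell with per-pixel multiplexed intensities
#'
#' @param cell_id cell identifier
#' @param well_id well identifier
#' @param conditions named character vector, one level per condition field
#' @param coords integer n_pixels x 2 matrix of 0-based (row, col) pixel
#'   coordinates; pixel centers sit at integer positions
#' @param intensities numeric n_pixels x n_channels matrix
#' @return an object of class `CellRecord`
#' @export
cell_record <- function(cell_id, well_id, conditions, coords, intensities) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "integer"
  intensities <- as.matrix(intensities)
  if (nrow(coords) < 1L) stop("a cell needs at least one pixel")
  if (nrow(coords) != nrow(intensities))
    stop("coords and intensities must have the same number of rows")
  if (ncol(coords) != 2L) stop("coords must have two columns (row, col)")
  if (anyDuplicated(paste(coords[, 1], coords[, 2])))
    stop("pixel coordinates must be unique within a cell")
  structure(list(cell_id = as.character(cell_id),
                 well_id = as.character(well_id),
                 conditions = conditions,
                 coords = coords,
                 intensities = intensities),
            class = "CellRecord")
}

#' Multiplexed dataset container
#'
#' @param cells list of [cell_record()] objects
#' @param panel a [channel_panel()]
#' @param schema a [condition_schema()]
#' @param split optional named character vector cell_id -> one of
#'   "train"/"val"/"test"
#' @return an object of class `MultiplexedDataset`
#' @export
multiplexed_dataset <- function(cells, panel, schema, split = NULL) {
  if (length(cells) == 0) stop("no cells")
  nc <- vapply(cells, function(x) ncol(x$intensities), 1L)
  if (any(nc != length(panel$names)))
    stop("all cells must share the panel's channel dimension")
  ids <- vapply(cells, function(x) x$cell_id, "")
  if (anyDuplicated(ids)) stop("cell ids must be unique")
  names(cells) <- ids
  for (cell in cells) {
    for (f in schema$fields) {
      lev <- cell$conditions[[f]]
      if (is.null(lev) || !(lev %in% schema$levels[[f]]))
        stop(sprintf("cell %s: condition '%s' level '%s' not in schema",
                     cell$cell_id, f, lev %||% "<missing>"))
    }
  }
  if (!is.null(split)) {
    if (!all(ids %in% names(split)))
      stop("split must cover all cells")
    split <- split[ids]
  }
  structure(list(cells = cells, panel = panel, schema = schema, split = split),
            class = "MultiplexedDataset")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.MultiplexedDataset <- function(x, ...) {
  cat(sprintf("MultiplexedDataset: %d cells, %d channels, %d pixels\n",
              length(x$cells), length(x$panel$names), n_pixels(x)))
  cat("  condition fields:", paste(x$schema$fields, collapse = ", "), "\n")
  if (!is.null(x$split))
    cat("  split:", paste(names(table(x$split)), table(x$split),
                          sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Number of channels of a dataset
#' @param ds a `MultiplexedDataset`
#' @return integer
#' @export
n_channels <- function(ds) length(ds$panel$names)

#' Cell identifiers of a dataset
#' @param ds a `MultiplexedDataset`
#' @return character vector
#' @export
cell_ids <- function(ds) names(ds$cells)

#' Total pixel count of a dataset
#' @param ds a `MultiplexedDataset`
#' @return integer
#' @export
n_pixels <- function(ds) {
  sum(vapply(ds$cells, function(x) nrow(x$coords), 1L))
}

#' Cells restricted to one or more splits
#' @param ds a `MultiplexedDataset`
#' @param split character vector of split names, or NULL for all cells
#' @return list of `CellRecord`
#' @export
cells_in_split <- function(ds, split = NULL) {
  if (is.null(split) || is.null(ds$split)) return(ds$cells)
  ds$cells[names(ds$split)[ds$split %in% split]]
}

#' Stack all pixel intensities of a dataset into one matrix
#'
#' @param ds a `MultiplexedDataset`
#' @param split optional split restriction
#' @return list with `intensities` (N x C), `cell_id` (length N) and
#'   `pixel` (within-cell pixel index)
#' @export
dataset_pixels <- function(ds, split = NULL) {
  cells <- cells_in_split(ds, split)
  mats <- lapply(cells, function(x) x$intensities)
  n <- vapply(mats, nrow, 1L)
  list(intensities = do.call(rbind, mats),
       cell_id = rep(vapply(cells, function(x) x$cell_id, ""), n),
       pixel = unlist(lapply(n, seq_len), use.names = FALSE))
}

#' Per-cell condition levels as a data frame
#' @param ds a `MultiplexedDataset`
#' @return data.frame with cell_id, well_id and one column per condition field
#' @export
cell_metadata <- function(ds) {
  df <- data.frame(cell_id = cell_ids(ds),
                   well_id = vapply(ds$cells, function(x) x$well_id, ""),
                   stringsAsFactors = FALSE, row.names = NULL)
  for (f in ds$schema$fields)
    df[[f]] <- vapply(ds$cells, function(x) as.character(x$conditions[[f]]), "")
  if (!is.null(ds$split)) df$split <- unname(ds$split[df$cell_id])
  df
}

#' One-hot encode condition levels under a schema
#'
#' One block of columns per condition field (in schema order); each block sums
#' to one per row.
#'
#' @param schema a [condition_schema()]
#' @param conditions data.frame (or named list for one row) with one column
#'   per condition field
#' @return binary matrix n x K, K the total number of levels
#' @export
condition_onehot <- function(schema, conditions) {
  if (!is.data.frame(conditions)) conditions <- as.data.frame(conditions)
  blocks <- lapply(schema$fields, function(f) {
    lev <- schema$levels[[f]]
    v <- as.character(conditions[[f]])
    bad <- !(v %in% lev)
    if (any(bad))
      stop(sprintf("unknown level(s) for condition '%s': %s", f,
                   paste(unique(v[bad]), collapse = ", ")))
    m <- matrix(0, nrow = length(v), ncol = length(lev),
                dimnames = list(NULL, paste(f, lev, sep = ":")))
    m[cbind(seq_along(v), match(v, lev))] <- 1
    m
  })
  do.call(cbind, blocks)
}

#' Total one-hot width of a schema
#' @param schema a [condition_schema()]
#' @return integer
#' @export
onehot_width <- function(schema) sum(lengths(schema$levels))
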