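# On-disk layouts.
#
# tiff_csv: channels.csv (index,name,background,scale), cells.csv
#   (cell_id,well_id,field,mask_label,<condition fields>[,split]), per-field
#   multi-page float TIFF stack_<field>.tif (one page per channel, values
#   scaled into [0,1] by the per-channel `scale` recorded in channels.csv) and
#   integer label-mask TIFF mask_<field>.tif (0 = background, k = mask_label
#   of cell k). Raw (nonnegative) intensities only.
#
# csv_dir: exact plain-text interchange - channels.csv, cells.csv, pixels.csv
#   (cell_id,row,col,<channels>) and schema.yaml. Used as the internal
#   interchange format.

write_schema_yaml <- function(schema, path) {
  yaml::write_yaml(list(fields = as.list(schema$fields),
                        levels = schema$levels), path)
}

read_schema_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  condition_schema(y$levels[unlist(y$fields)])
}

#' Write a dataset to disk
#'
#' @param ds a `MultiplexedDataset`
#' @param root directory to create
#' @param layout `"csv_dir"` (exact plain-text interchange, the default) or
#'   `"tiff_csv"` (per-field image stacks plus label masks; raw nonnegative
#'   intensities only)
#' @return `root`, invisibly
#' @export
write_dataset <- function(ds, root, layout = c("csv_dir", "tiff_csv")) {
  layout <- match.arg(layout)
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  meta <- cell_metadata(ds)
  chans <- data.frame(index = seq_along(ds$panel$names) - 1L,
                      name = ds$panel$names,
                      background = ds$panel$background)
  if (!is.null(ds$panel$quantiles)) chans$quantile <- ds$panel$quantiles
  write_schema_yaml(ds$schema, file.path(root, "schema.yaml"))
  if (layout == "csv_dir") {
    px <- dataset_pixels(ds)
    co <- do.call(rbind, lapply(ds$cells, function(x) x$coords))
    tab <- data.table::data.table(cell_id = px$cell_id,
                                  row = co[, 1], col = co[, 2])
    ints <- data.table::as.data.table(px$intensities)
    data.table::setnames(ints, ds$panel$names)
    data.table::fwrite(cbind(tab, ints), file.path(root, "pixels.csv"))
    write.csv(chans, file.path(root, "channels.csv"), row.names = FALSE)
    write.csv(meta, file.path(root, "cells.csv"), row.names = FALSE)
    return(invisible(root))
  }
  # tiff_csv: one field per cell, named after the cell id
  mins <- vapply(ds$cells, function(x) min(x$intensities), 1)
  if (any(mins < 0))
    stop("tiff_csv layout stores raw nonnegative intensities; ",
         "use csv_dir for background-subtracted data")
  scale <- pmax(vapply(seq_len(n_channels(ds)), function(ch) {
    max(vapply(ds$cells, function(x) max(x$intensities[, ch]), 1))
  }, 1), .Machine$double.eps)
  chans$scale <- scale
  meta$field <- meta$cell_id
  meta$mask_label <- seq_len(nrow(meta))
  write.csv(chans, file.path(root, "channels.csv"), row.names = FALSE)
  write.csv(meta, file.path(root, "cells.csv"), row.names = FALSE)
  for (i in seq_along(ds$cells)) {
    cell <- ds$cells[[i]]
    nr <- max(cell$coords[, 1]) + 1L
    nc <- max(cell$coords[, 2]) + 1L
    mask <- matrix(0L, nr, nc)
    mask[cell$coords + 1L] <- meta$mask_label[i]
    pages <- lapply(seq_len(n_channels(ds)), function(ch) {
      img <- matrix(0, nr, nc)
      img[cell$coords + 1L] <- cell$intensities[, ch] / scale[ch]
      img
    })
    tiff::writeTIFF(pages, file.path(root, sprintf("stack_%s.tif", cell$cell_id)),
                    bits.per.sample = 32L)
    tiff::writeTIFF(mask / 65535,
                    file.path(root, sprintf("mask_%s.tif", cell$cell_id)),
                    bits.per.sample = 16L)
  }
  invisible(root)
}

infer_schema <- function(meta, fields) {
  condition_schema(setNames(lapply(fields, function(f)
    sort(unique(meta[[f]]))), fields))
}

#' Load a dataset from disk
#'
#' @param root dataset directory written by [write_dataset()] (or following
#'   the same layout conventions)
#' @param layout `"csv_dir"` or `"tiff_csv"`
#' @return a `MultiplexedDataset`
#' @export
load_dataset <- function(root, layout = c("csv_dir", "tiff_csv")) {
  layout <- match.arg(layout)
  if (!dir.exists(root)) stop(sprintf("dataset root does not exist: %s", root))
  need <- c("channels.csv", "cells.csv")
  miss <- need[!file.exists(file.path(root, need))]
  if (length(miss))
    stop(sprintf("missing required file(s): %s", paste(miss, collapse = ", ")))
  chans <- read.csv(file.path(root, "channels.csv"), stringsAsFactors = FALSE)
  chans <- chans[order(chans$index), ]
  meta <- read.csv(file.path(root, "cells.csv"), stringsAsFactors = FALSE,
                   colClasses = c(cell_id = "character"))
  if (nrow(meta) == 0) stop("no cells in metadata")
  reserved <- c("cell_id", "well_id", "field", "mask_label", "split")
  fields <- setdiff(names(meta), reserved)
  schema <- if (file.exists(file.path(root, "schema.yaml")))
    read_schema_yaml(file.path(root, "schema.yaml")) else
      infer_schema(meta, fields)
  panel <- channel_panel(chans$name, chans$background,
                         quantiles = chans$quantile)
  split <- if ("split" %in% names(meta))
    setNames(meta$split, meta$cell_id) else NULL
  if (layout == "csv_dir") {
    if (!file.exists(file.path(root, "pixels.csv")))
      stop("missing required file(s): pixels.csv")
    px <- data.table::fread(file.path(root, "pixels.csv"),
                            colClasses = list(character = "cell_id"))
    cells <- lapply(seq_len(nrow(meta)), function(i) {
      rows <- px[px$cell_id == meta$cell_id[i], ]
      if (nrow(rows) == 0)
        stop(sprintf("cell(s) in metadata without pixels: %s", meta$cell_id[i]))
      cell_record(meta$cell_id[i], meta$well_id[i],
                  setNames(as.list(meta[i, fields, drop = FALSE]),
                           schema$fields),
                  as.matrix(rows[, c("row", "col")]),
                  as.matrix(rows[, panel$names, with = FALSE]))
    })
    return(multiplexed_dataset(cells, panel, schema, split))
  }
  # tiff_csv
  scale <- chans$scale
  if (is.null(scale)) scale <- rep(1, nrow(chans))
  cells <- vector("list", nrow(meta))
  for (fld in unique(meta$field)) {
    stack_path <- file.path(root, sprintf("stack_%s.tif", fld))
    mask_path <- file.path(root, sprintf("mask_%s.tif", fld))
    if (!file.exists(stack_path))
      stop(sprintf("missing channel stack for field %s (expected %s)",
                   fld, stack_path))
    if (!file.exists(mask_path))
      stop(sprintf("missing label mask for field %s", fld))
    pages <- tiff::readTIFF(stack_path, all = TRUE)
    if (length(pages) != nrow(chans))
      stop(sprintf("stack %s has %d pages but %d channels declared (first: %s)",
                   fld, length(pages), nrow(chans), chans$name[1]))
    mask <- tiff::readTIFF(mask_path, as.is = TRUE)
    if (!is.integer(mask)) stop("label mask is not integer-valued")
    rows_here <- which(meta$field == fld)
    absent <- meta$cell_id[rows_here][!(meta$mask_label[rows_here] %in% mask)]
    if (length(absent))
      stop(sprintf("cell(s) in metadata absent from mask: %s",
                   paste(absent, collapse = ", ")))
    for (i in rows_here) {
      idx <- which(mask == meta$mask_label[i], arr.ind = TRUE)
      ints <- vapply(seq_along(pages),
                     function(ch) pages[[ch]][idx] * scale[ch],
                     numeric(nrow(idx)))
      cells[[i]] <- cell_record(meta$cell_id[i], meta$well_id[i],
                                setNames(as.list(meta[i, fields, drop = FALSE]),
                                         schema$fields),
                                idx - 1L, ints)
    }
  }
  multiplexed_dataset(cells, panel, schema, split)
}
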