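# Cluster annotation: channel-enrichment summaries and user-provided merges.

#' Per-cluster channel profile and enrichment z-scores
#'
#' Mean intensity over all pixels of each cluster per channel, plus per-channel
#' z-scores across clusters (each column standardized to mean 0, sd 1), the
#' standard view for deciding which structure a cluster represents.
#'
#' @param intensities N x C pixel intensity matrix (normalized)
#' @param labels per-pixel cluster labels (length N)
#' @param channel_names optional channel names for the columns
#' @return list with `mean` (K x C), `z` (K x C; NA-flagged when the
#'   cross-cluster sd of a channel is 0), `n_pixels` (per cluster)
#' @export
cluster_channel_profile <- function(intensities, labels,
                                    channel_names = colnames(intensities)) {
  labs <- sort(unique(labels))
  m <- rowsum(intensities, group = labels) /
    as.vector(table(factor(labels, levels = sort(unique(labels)))))
  m <- m[as.character(labs), , drop = FALSE]
  colnames(m) <- channel_names
  sds <- apply(m, 2, sd)
  z <- scale(m)
  z[, sds == 0 | is.na(sds)] <- NA_real_
  attr(z, "scaled:center") <- NULL
  attr(z, "scaled:scale") <- NULL
  list(mean = m, z = z,
       n_pixels = as.vector(table(factor(labels, levels = labs))))
}

#' Propose an annotation map from canonical marker enrichment
#'
#' Assigns each raw cluster the structure whose canonical marker channel is
#' most enriched in that cluster, measured as the log2 ratio of the cluster's
#' mean to the pixel-weighted overall channel mean; clusters in which no
#' canonical marker reaches `min_log2_enrichment` get the `default` name.
#' This mirrors the usual manual procedure (merge clusters by presence of
#' canonical organelle markers among their top enriched channels, fall back
#' to "background" when none is present) and is the offline, reproducible
#' path; the result can be edited and re-applied via [read_annotation()] /
#' [apply_annotation()]. Enrichment ratios rather than cross-cluster
#' z-scores are used because a z-score is unstable for channels with little
#' cross-cluster variation.
#'
#' @param profile result of [cluster_channel_profile()]
#' @param marker_map named character vector channel name -> structure name
#'   (channels without an entry are treated as non-canonical)
#' @param min_log2_enrichment minimum log2 cluster-vs-overall enrichment for
#'   a marker to count as present (default 1, i.e. twofold)
#' @param default name for clusters without an enriched canonical marker
#' @return named character vector raw cluster id -> annotated name
#' @export
propose_annotation <- function(profile, marker_map, min_log2_enrichment = 1,
                               default = "background") {
  m <- profile$mean
  markers <- intersect(names(marker_map), colnames(m))
  if (length(markers) == 0) stop("no marker channel found in the profile")
  overall <- colSums(m * profile$n_pixels) / sum(profile$n_pixels)
  # negative (noise-dominated) means give NaN enrichment, treated as absent
  enr <- suppressWarnings(log2(sweep(m, 2, overall, "/")))
  out <- vapply(seq_len(nrow(m)), function(i) {
    ei <- enr[i, markers]
    if (all(!is.finite(ei))) return(default)
    top <- markers[which.max(ei)]
    if (max(ei, na.rm = TRUE) >= min_log2_enrichment)
      unname(marker_map[top]) else default
  }, "")
  setNames(out, rownames(m))
}

#' Read an annotation mapping file
#'
#' @param path CSV with columns `raw_label`, `annotated_name`
#' @return named character vector raw label -> annotated name
#' @export
read_annotation <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("raw_label", "annotated_name") %in% names(df)))
    stop("annotation file needs columns raw_label, annotated_name")
  if (any(df$annotated_name == "")) stop("annotated names must be non-empty")
  setNames(df$annotated_name, as.character(df$raw_label))
}

#' Apply an annotation map to cluster labels
#'
#' Replaces raw cluster ids by annotated landmark names; merges (many raw ids
#' to one name) are allowed. Pixel coverage is unchanged.
#'
#' @param labels per-pixel raw cluster labels
#' @param mapping named vector raw label -> annotated name (every raw id
#'   present in `labels` must be mapped)
#' @return character vector of annotated labels
#' @export
apply_annotation <- function(labels, mapping) {
  lab <- as.character(labels)
  unmapped <- setdiff(unique(lab), names(mapping))
  if (length(unmapped))
    stop(sprintf("unmapped cluster id(s): %s",
                 paste(sort(unmapped), collapse = ", ")))
  if (any(mapping == "")) stop("annotated names must be non-empty")
  unname(mapping[lab])
}
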