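# Landmark identification: subsampling, kNN-graph Leiden clustering,
# projection of labels to all pixels, and clustering agreement scores.

#' Exact k-nearest-neighbour indices
#'
#' Brute-force Euclidean search (BLAS-backed, chunked); exact by construction.
#'
#' @param query n x d matrix of query points
#' @param ref m x d matrix of reference points
#' @param k number of neighbours
#' @return n x k integer matrix of 1-based row indices into `ref`, ordered by
#'   increasing distance (ties broken by smaller index)
#' @export
knn_index <- function(query, ref, k) {
  if (k > nrow(ref)) stop("k exceeds the number of reference points")
  .knn_index_cpp(as.matrix(query), as.matrix(ref), as.integer(k))
}

#' Subsample pixel indices for graph clustering
#'
#' Uniform sampling without replacement; if `n` is at least the number of
#' available pixels, all indices are returned with a warning.
#'
#' @param n_total total number of pixels (or a matrix whose rows are counted)
#' @param n subsample size (default 150000)
#' @param seed integer seed
#' @return sorted integer index vector
#' @export
subsample_for_clustering <- function(n_total, n = 150000L, seed = 0L) {
  if (is.matrix(n_total)) n_total <- nrow(n_total)
  if (n >= n_total) {
    warning("subsample size >= available pixels; taking all")
    return(seq_len(n_total))
  }
  set.seed(seed)
  sort(sample.int(n_total, n))
}

#' Leiden clustering of a kNN graph
#'
#' Builds the undirected, unweighted union of k-nearest-neighbour edges and
#' partitions it with the Leiden algorithm under the resolution-parameterized
#' modularity objective (RBConfiguration style). Cluster ids are renumbered
#' 1..K by decreasing cluster size.
#'
#' @param vectors n x d matrix (latent means or normalized pixel profiles)
#' @param k neighbours per point (default 15)
#' @param resolution Leiden resolution parameter (default 0.5)
#' @param seed integer seed
#' @param n_iterations Leiden iterations (default 10)
#' @return integer cluster labels of length n
#' @export
leiden_cluster <- function(vectors, k = 15L, resolution = 0.5, seed = 0L,
                           n_iterations = 10L) {
  vectors <- as.matrix(vectors)
  n <- nrow(vectors)
  if (n < k + 1) stop("need at least k+1 rows")
  nn <- knn_index(vectors, vectors, k + 1L)
  # drop self-neighbours (guaranteed present among the k+1 closest only for
  # distinct rows; for duplicated rows drop one occurrence explicitly)
  edges <- matrix(0L, n * k, 2L)
  at <- 0L
  for (j in seq_len(k + 1L)) {
    keep <- nn[, j] != seq_len(n)
    # per row we keep only k non-self neighbours
    nkeep <- pmin(rowSums(nn != seq_len(n)), k)
    keep <- keep & (cumsum_rowwise(nn, j) <= nkeep)
    m <- sum(keep)
    if (m) {
      edges[at + seq_len(m), ] <- cbind(which(keep), nn[keep, j])
      at <- at + m
    }
  }
  edges <- edges[seq_len(at), , drop = FALSE]
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::simplify(igraph::add_vertices(g, max(0, n - igraph::vcount(g))))
  set.seed(seed)
  cl <- igraph::cluster_leiden(g, objective_function = "modularity",
                               resolution = resolution,
                               n_iterations = n_iterations)
  renumber_by_size(igraph::membership(cl))
}

# count of non-self entries among columns 1..j, per row
cumsum_rowwise <- function(nn, j) {
  rowSums(nn[, seq_len(j), drop = FALSE] != seq_len(nrow(nn)))
}

renumber_by_size <- function(labels) {
  tab <- sort(table(labels), decreasing = TRUE)
  match(as.character(labels), names(tab))
}

#' Project cluster labels to all pixels by k-NN majority vote
#'
#' Each point receives the most frequent label among its `k` nearest
#' neighbours in the clustered subsample; ties go to the smallest label id.
#'
#' @param subsample_vectors m x d matrix of clustered points
#' @param subsample_labels integer labels of the subsample
#' @param all_vectors n x d matrix of points to label
#' @param k neighbours (default 15)
#' @return integer labels of length n
#' @export
project_clusters <- function(subsample_vectors, subsample_labels,
                             all_vectors, k = 15L) {
  if (k > nrow(subsample_vectors)) stop("k exceeds the subsample size")
  nn <- knn_index(as.matrix(all_vectors), as.matrix(subsample_vectors),
                  as.integer(k))
  votes <- matrix(subsample_labels[nn], nrow(nn), ncol(nn))
  labs <- sort(unique(subsample_labels))
  counts <- vapply(labs, function(l) rowSums(votes == l),
                   numeric(nrow(votes)))
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1)
  labs[max.col(counts, ties.method = "first")]
}

#' Cluster latent representations into landmark labels for every pixel
#'
#' Subsample, Leiden-cluster the subsample, then project labels to all rows.
#'
#' @param vectors n x d matrix
#' @param n_subsample subsample size (default 150000)
#' @param k kNN graph / projection neighbours (default 15)
#' @param resolution Leiden resolution (default 0.5)
#' @param seed integer seed
#' @param space label for the feature space ("latent" or "pixel")
#' @return a `ClusterAssignment`: list with `labels` (all rows), `subsample`
#'   (indices), `subsample_labels`, `space`, `resolution`, `k`, `seed`
#' @export
cluster_pixels <- function(vectors, n_subsample = 150000L, k = 15L,
                           resolution = 0.5, seed = 0L, space = "latent") {
  vectors <- as.matrix(vectors)
  sub <- suppressWarnings(
    subsample_for_clustering(nrow(vectors), n_subsample,
                             seed = derive_seed(seed, 21L)))
  sub_labels <- leiden_cluster(vectors[sub, , drop = FALSE], k = k,
                               resolution = resolution,
                               seed = derive_seed(seed, 22L))
  labels <- project_clusters(vectors[sub, , drop = FALSE], sub_labels,
                             vectors, k = k)
  labels[sub] <- sub_labels
  structure(list(labels = labels, subsample = sub,
                 subsample_labels = sub_labels, space = space,
                 resolution = resolution, k = k, seed = seed),
            class = "ClusterAssignment")
}

#' Direct Leiden clustering of normalized pixel profiles
#'
#' The comparison baseline: the identical subsample/cluster/project pipeline
#' applied to normalized center-pixel profiles instead of latent means.
#'
#' @param profiles n x C matrix of normalized pixel profiles
#' @param resolution Leiden resolution (or vector of resolutions)
#' @param n_subsample subsample size
#' @param k neighbours
#' @param seed integer seed
#' @return a `ClusterAssignment`, or a named list of them when `resolution`
#'   has length > 1
#' @export
direct_pixel_cluster <- function(profiles, resolution = 0.5,
                                 n_subsample = 150000L, k = 15L, seed = 0L) {
  if (length(resolution) > 1L) {
    out <- lapply(resolution, function(r)
      cluster_pixels(profiles, n_subsample, k, r, seed, space = "pixel"))
    names(out) <- as.character(resolution)
    return(out)
  }
  cluster_pixels(profiles, n_subsample, k, resolution, seed, space = "pixel")
}

entropy_nat <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Agreement between two labelings
#'
#' Adjusted mutual information and adjusted Rand index under the standard
#' permutation model, plus a per-cluster homogeneity score: for each cluster i
#' of `U`, `U` is binarized into (i, not-i) and h = 1 - H(U_bin|V)/H(U_bin).
#'
#' @param U reference labels
#' @param V comparison labels (same length)
#' @return an `AgreementScores` list: `ami`, `ari`, `homogeneity_per_cluster`
#' @export
agreement <- function(U, V) {
  if (length(U) != length(V)) stop("labelings must have the same length")
  U <- as.character(U); V <- as.character(V)
  structure(list(ami = adjusted_mutual_information(U, V),
                 ari = adjusted_rand_index(U, V),
                 homogeneity_per_cluster = homogeneity_per_cluster(U, V)),
            class = "AgreementScores")
}

#' Adjusted Rand index
#' @param U,V labelings of the same length
#' @return real <= 1
#' @export
adjusted_rand_index <- function(U, V) {
  tab <- table(U, V)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (maxi - expected)
}

#' Adjusted mutual information (arithmetic normalization)
#' @param U,V labelings of the same length
#' @return real <= 1
#' @export
adjusted_mutual_information <- function(U, V) {
  tab <- table(U, V)
  n <- sum(tab)
  a <- rowSums(tab); b <- colSums(tab)
  pa <- a / n; pb <- b / n
  hu <- entropy_nat(pa); hv <- entropy_nat(pb)
  if (hu == 0 && hv == 0) return(1)
  p <- tab / n
  nz <- p > 0
  mi <- sum(p[nz] * log(p[nz] / (pa[row(tab)[nz]] * pb[col(tab)[nz]])))
  emi <- expected_mutual_information(a, b, n)
  denom <- (hu + hv) / 2 - emi
  if (abs(denom) < .Machine$double.eps) return(0)
  (mi - emi) / denom
}

# Expected MI under the hypergeometric permutation model.
expected_mutual_information <- function(a, b, n) {
  a <- as.numeric(a); b <- as.numeric(b); n <- as.numeric(n)
  emi <- 0
  lgn <- lgamma(n + 1)
  for (i in seq_along(a)) {
    ai <- a[i]
    for (j in seq_along(b)) {
      bj <- b[j]
      lo <- max(1, ai + bj - n)
      hi <- min(ai, bj)
      if (lo > hi) next
      nij <- lo:hi
      term <- (nij / n) * log(n * nij / (ai * bj))
      lw <- lgamma(ai + 1) + lgamma(bj + 1) + lgamma(n - ai + 1) +
        lgamma(n - bj + 1) - lgn - lgamma(nij + 1) - lgamma(ai - nij + 1) -
        lgamma(bj - nij + 1) - lgamma(n - ai - bj + nij + 1)
      emi <- emi + sum(term * exp(lw))
    }
  }
  emi
}

homogeneity_per_cluster <- function(U, V) {
  labs <- sort(unique(U))
  vapply(setNames(labs, labs), function(l) {
    ub <- U == l
    hu <- entropy_nat(c(mean(ub), 1 - mean(ub)))
    if (hu == 0) return(NA_real_)
    hcond <- 0
    for (v in unique(V)) {
      sel <- V == v
      pv <- mean(sel)
      hcond <- hcond + pv * entropy_nat(c(mean(ub[sel]), 1 - mean(ub[sel])))
    }
    1 - hcond / hu
  }, 1)
}

#' Export per-pixel labels as CSV and per-cell integer label-mask TIFFs
#'
#' @param ds the `MultiplexedDataset` the labels refer to
#' @param labels per-pixel labels in [dataset_pixels()] order (integer ids or
#'   annotated names; names are written to CSV and encoded as integers in the
#'   masks via the returned level table)
#' @param dir output directory (created if needed)
#' @param masks also write one `mask_<cell>.tif` per cell (default TRUE)
#' @return invisibly, a data.frame mapping mask integer codes to labels
#' @export
write_label_masks <- function(ds, labels, dir, masks = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  labs_by_cell <- split_labels_by_cell(ds, labels)
  levels_tab <- data.frame(code = seq_along(sort(unique(as.character(labels)))),
                           label = sort(unique(as.character(labels))),
                           stringsAsFactors = FALSE)
  rows <- lapply(cell_ids(ds), function(id) {
    data.table::data.table(cell_id = id,
                           row = ds$cells[[id]]$coords[, 1],
                           col = ds$cells[[id]]$coords[, 2],
                           label = labs_by_cell[[id]])
  })
  data.table::fwrite(data.table::rbindlist(rows),
                     file.path(dir, "labels.csv"))
  write.csv(levels_tab, file.path(dir, "label_codes.csv"), row.names = FALSE)
  if (masks) {
    for (id in cell_ids(ds)) {
      co <- ds$cells[[id]]$coords
      mask <- matrix(0L, max(co[, 1]) + 1L, max(co[, 2]) + 1L)
      mask[co + 1L] <- match(labs_by_cell[[id]], levels_tab$label)
      tiff::writeTIFF(mask / 65535, file.path(dir, sprintf("mask_%s.tif", id)),
                      bits.per.sample = 16L)
    }
  }
  invisible(levels_tab)
}

#' F1 score of a predicted pixel mask against a reference mask
#'
#' F1 = TP / (TP + 0.5 (FP + FN)), with the reference as ground truth.
#'
#' @param pred_mask logical vector (or index set) of predicted pixels
#' @param ref_mask logical vector (or index set) of reference pixels; when
#'   both are index sets they are interpreted over their union's universe
#' @param universe optional universe size when passing index sets
#' @return F1 in \[0, 1\]
#' @export
f1_vs_reference <- function(pred_mask, ref_mask, universe = NULL) {
  if (!is.logical(pred_mask)) {
    n <- universe %||% max(pred_mask, ref_mask, 0)
    pred_mask <- seq_len(n) %in% pred_mask
    ref_mask <- seq_len(n) %in% ref_mask
  }
  if (length(pred_mask) != length(ref_mask))
    stop("masks must cover the same pixel universe")
  tp <- sum(pred_mask & ref_mask)
  fp <- sum(pred_mask & !ref_mask)
  fn <- sum(!pred_mask & ref_mask)
  if (tp + fp + fn == 0) stop("both masks are empty; F1 undefined")
  tp / (tp + 0.5 * (fp + fn))
}
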