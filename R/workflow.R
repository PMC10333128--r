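# Config-driven end-to-end orchestration with seeded stages, a run directory
# and a resolved-config snapshot next to every stage's outputs.

#' Built-in default run configuration
#'
#' Stage parameters mirror the pipeline defaults: 3x3 neighborhood, 0.98
#' quantile, 16-d latent, 25 epochs, batch 128, learning rate 0.001,
#' 150000-pixel clustering subsample, k = 15, Leiden resolution 0.5, 19
#' log-spaced co-occurrence intervals between 2 and 80 px, object filters
#' (> 10 px, < 10% cumulative).
#'
#' @param run_dir run directory
#' @param seed master seed; per-stage seeds are derived by fixed offsets
#' @return a `RunConfig` (named list)
#' @export
default_run_config <- function(run_dir = "run", seed = 0L) {
  structure(list(
    run_dir = run_dir,
    seed = as.integer(seed),
    synth = list(n_cells_per_condition = 100L),
    prepare = list(quantile = 0.98, fractions = c(0.8, 0.1, 0.1)),
    train = list(latent_dim = 16L, epochs = 25L, batch_size = 128L,
                 learning_rate = 1e-3, fraction_per_cell = 0.1,
                 neighborhood = 3L, conditional = TRUE),
    cluster = list(n_subsample = 150000L, k = 15L, resolution = 0.5),
    annotate = list(annotation_file = NULL, marker_map = NULL),
    features = list(n_intervals = 19L, d_min = 2, d_max = 80,
                    min_area = 10L, cum_frac = 0.1),
    compare = list(probe_seeds = 0:4, max_per_class = 10000L,
                   condition_field = "perturbation")),
    class = "RunConfig")
}

#' Load and validate a run configuration from YAML
#'
#' Unknown keys (at the top level or inside a stage) are rejected.
#'
#' @param path YAML file, or NULL for the built-in defaults
#' @param seed optional master-seed override
#' @return a `RunConfig`
#' @export
load_run_config <- function(path = NULL, seed = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    bad <- setdiff(names(user), names(cfg))
    if (length(bad))
      stop(sprintf("unknown config key(s): %s", paste(bad, collapse = ", ")))
    for (nm in names(user)) {
      if (is.list(cfg[[nm]]) && is.list(user[[nm]])) {
        bad2 <- setdiff(names(user[[nm]]), names(cfg[[nm]]))
        if (length(bad2))
          stop(sprintf("unknown config key(s) under '%s': %s", nm,
                       paste(bad2, collapse = ", ")))
        cfg[[nm]] <- utils::modifyList(cfg[[nm]], user[[nm]])
      } else cfg[[nm]] <- user[[nm]]
    }
  }
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  cfg
}

stage_dir <- function(cfg, stage) file.path(cfg$run_dir, stage)

stage_done <- function(cfg, stage) {
  snap <- file.path(stage_dir(cfg, stage), "config_snapshot.yaml")
  file.exists(snap) &&
    identical(yaml::read_yaml(snap), rapply(unclass(cfg), identity,
                                            how = "list"))
}

finish_stage <- function(cfg, stage) {
  yaml::write_yaml(rapply(unclass(cfg), identity, how = "list"),
                   file.path(stage_dir(cfg, stage), "config_snapshot.yaml"))
  log_line(cfg, sprintf("stage %s done", stage))
}

log_line <- function(cfg, msg) {
  line <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"), msg)
  message(line)
  cat(line, "\n", file = file.path(cfg$run_dir, "run.log"), append = TRUE)
}

require_stage <- function(cfg, stage, file) {
  path <- file.path(stage_dir(cfg, stage), file)
  if (!file.exists(path))
    stop(sprintf("missing upstream artifact %s; run stage '%s' first",
                 path, stage))
  path
}

#' Run one pipeline stage (or all of them)
#'
#' Stages: `synth` (generate the synthetic study), `prepare` (background
#' subtraction, quantile normalization, cell split), `train` (conditional
#' sigma-VAE), `encode` (latent means for every pixel), `cluster` (Leiden on
#' a latent subsample + projection), `annotate` (apply a mapping file, or
#' identity), `features` (intensity/morphology/co-occurrence tables),
#' `compare` (probes, cluster-fraction CV, silhouettes, fold changes), `all`.
#' A stage whose config snapshot already matches is skipped unless `force`.
#'
#' @param stage stage name
#' @param config a `RunConfig` (see [load_run_config()])
#' @param force re-run even when the stage looks up to date
#' @return invisibly, the path of the stage directory
#' @export
run_pipeline <- function(stage = c("all", "synth", "prepare", "train",
                                   "encode", "cluster", "annotate",
                                   "features", "compare"),
                         config = default_run_config(), force = FALSE) {
  stage <- match.arg(stage)
  cfg <- config
  dir.create(cfg$run_dir, recursive = TRUE, showWarnings = FALSE)
  if (stage == "all") {
    for (s in c("synth", "prepare", "train", "encode", "cluster",
                "annotate", "features", "compare"))
      run_pipeline(s, cfg, force)
    return(invisible(cfg$run_dir))
  }
  sd <- stage_dir(cfg, stage)
  if (!force && stage_done(cfg, stage)) {
    log_line(cfg, sprintf("stage %s up to date; skipping", stage))
    return(invisible(sd))
  }
  dir.create(sd, recursive = TRUE, showWarnings = FALSE)
  switch(stage,
    synth = {
      out <- generate_synth_small(
        seed = derive_seed(cfg$seed, 1L),
        n_cells_per_condition = cfg$synth$n_cells_per_condition)
      write_dataset(out$dataset, file.path(sd, "dataset"))
      gtf <- ground_truth_table(out$ground_truth, out$dataset)
      data.table::fwrite(gtf, file.path(sd, "ground_truth.csv"))
      yaml::write_yaml(list(fixture = "synth-small",
                            seed = derive_seed(cfg$seed, 1L)),
                       file.path(sd, "generator.yaml"))
    },
    prepare = {
      require_stage(cfg, "synth", "dataset/pixels.csv")
      ds <- load_dataset(file.path(stage_dir(cfg, "synth"), "dataset"))
      ds <- background_subtract(ds)
      ds <- fit_and_apply_quantile_norm(ds, q = cfg$prepare$quantile)
      ds <- split_cells(ds, cfg$prepare$fractions,
                        seed = derive_seed(cfg$seed, 2L))
      write_dataset(ds, file.path(sd, "dataset"))
    },
    train = {
      require_stage(cfg, "prepare", "dataset/pixels.csv")
      ds <- load_dataset(file.path(stage_dir(cfg, "prepare"), "dataset"))
      mc <- cvae_config(latent_dim = cfg$train$latent_dim,
                        epochs = cfg$train$epochs,
                        batch_size = cfg$train$batch_size,
                        learning_rate = cfg$train$learning_rate,
                        neighborhood = cfg$train$neighborhood,
                        conditional = cfg$train$conditional,
                        seed = derive_seed(cfg$seed, 3L))
      model <- train_cvae(ds, mc,
                          fraction_per_cell = cfg$train$fraction_per_cell)
      save_cvae(model, file.path(sd, "checkpoint"))
    },
    encode = {
      require_stage(cfg, "train", "checkpoint/config.yaml")
      ds <- load_dataset(file.path(stage_dir(cfg, "prepare"), "dataset"))
      model <- load_cvae(file.path(stage_dir(cfg, "train"), "checkpoint"), ds)
      enc <- encode_dataset(model, ds)
      saveRDS(enc, file.path(sd, "latents.rds"))
    },
    cluster = {
      enc <- readRDS(require_stage(cfg, "encode", "latents.rds"))
      assign_lat <- cluster_pixels(enc$z, cfg$cluster$n_subsample,
                                   cfg$cluster$k, cfg$cluster$resolution,
                                   seed = derive_seed(cfg$seed, 4L))
      data.table::fwrite(data.table::data.table(cell_id = enc$cell_id,
                                                pixel = enc$pixel,
                                                label = assign_lat$labels),
                         file.path(sd, "labels.csv"))
      saveRDS(assign_lat, file.path(sd, "assignment.rds"))
    },
    annotate = {
      labs <- data.table::fread(require_stage(cfg, "cluster", "labels.csv"))
      ds <- load_dataset(file.path(stage_dir(cfg, "prepare"), "dataset"))
      prof <- cluster_channel_profile(dataset_pixels(ds)$intensities,
                                      labs$label, ds$panel$names)
      write.csv(cbind(cluster = rownames(prof$mean),
                      as.data.frame(prof$z)),
                file.path(sd, "enrichment_z.csv"), row.names = FALSE)
      mapping <- if (!is.null(cfg$annotate$annotation_file)) {
        read_annotation(cfg$annotate$annotation_file)
      } else if (!is.null(cfg$annotate$marker_map)) {
        propose_annotation(prof, unlist(cfg$annotate$marker_map))
      } else {
        ids <- sort(unique(labs$label))
        setNames(sprintf("CSL%02d", ids), ids)
      }
      write.csv(data.frame(raw_label = names(mapping),
                           annotated_name = unname(mapping)),
                file.path(sd, "annotation.csv"), row.names = FALSE)
      labs$label <- apply_annotation(labs$label, mapping)
      data.table::fwrite(labs, file.path(sd, "labels.csv"))
      write_label_masks(ds, labs$label, file.path(sd, "masks"))
    },
    features = {
      labs <- data.table::fread(require_stage(cfg, "annotate", "labels.csv"))
      ds <- load_dataset(file.path(stage_dir(cfg, "prepare"), "dataset"))
      ft <- feature_table(ds, labs$label, cfg$features$min_area,
                          cfg$features$cum_frac)
      write.csv(ft, file.path(sd, "features_intensity.csv"),
                row.names = FALSE)
      iv <- log_spaced_intervals(cfg$features$n_intervals,
                                 cfg$features$d_min, cfg$features$d_max)
      curves <- cooccurrence_curves(ds, labs$label, iv)
      saveRDS(curves, file.path(sd, "cooccurrence.rds"))
      write.csv(iv, file.path(sd, "intervals.csv"), row.names = FALSE)
    },
    compare = {
      require_stage(cfg, "features", "cooccurrence.rds")
      enc <- readRDS(require_stage(cfg, "encode", "latents.rds"))
      labs <- data.table::fread(file.path(stage_dir(cfg, "annotate"),
                                          "labels.csv"))
      ds <- load_dataset(file.path(stage_dir(cfg, "prepare"), "dataset"))
      cond <- enc$conditions[[cfg$compare$condition_field]]
      probes_lat <- probe_over_seeds(enc$z, cond, cfg$compare$probe_seeds,
                                     cfg$compare$max_per_class)
      probes_px <- probe_over_seeds(enc$centers, cond,
                                    cfg$compare$probe_seeds,
                                    cfg$compare$max_per_class)
      probes <- rbind(cbind(space = "latent", probes_lat),
                      cbind(space = "pixel", probes_px))
      write.csv(probes, file.path(sd, "probes.csv"), row.names = FALSE)
      cv <- cluster_fraction_cv(labs$label, cond)
      write.csv(cv$per_cluster, file.path(sd, "cluster_cv.csv"),
                row.names = FALSE)
      ft <- read.csv(file.path(stage_dir(cfg, "features"),
                               "features_intensity.csv"),
                     stringsAsFactors = FALSE,
                     colClasses = c(cell_id = "character"))
      meta <- cell_metadata(ds)
      fc <- fold_changes(ft, meta, ds$panel$names,
                         condition_field = cfg$compare$condition_field)
      write.csv(fc, file.path(sd, "fold_changes.csv"), row.names = FALSE)
      curves <- readRDS(file.path(stage_dir(cfg, "features"),
                                  "cooccurrence.rds"))
      sil <- silhouette_table(ft, meta, ds$panel$names,
                              cfg$compare$condition_field, curves)
      write.csv(sil, file.path(sd, "silhouette.csv"), row.names = FALSE)
    })
  finish_stage(cfg, stage)
  invisible(sd)
}

ground_truth_table <- function(gt, ds) {
  rows <- lapply(cell_ids(ds), function(id) {
    data.table::data.table(cell_id = id,
                           row = ds$cells[[id]]$coords[, 1],
                           col = ds$cells[[id]]$coords[, 2],
                           label = gt$labels[[id]])
  })
  data.table::rbindlist(rows)
}

#' Per-cell feature representations for perturbation comparisons
#'
#' Three standard views of a cell: whole-cell mean channel intensities, the
#' flattened per-landmark mean intensities, and the flattened log2 spatial
#' co-occurrence tensor (missing entries as 0).
#'
#' @param ft a [feature_table()] result
#' @param channels channel names
#' @param curves optional result of [cooccurrence_curves()]
#' @return named list of cells x features matrices (rownames = cell ids)
#' @export
cell_representations <- function(ft, channels, curves = NULL) {
  cells <- unique(ft$cell_id)
  csls <- sort(unique(ft$csl))
  whole <- vapply(channels, function(ch) nucleus_reference(ft, ch)[cells],
                  numeric(length(cells)))
  rownames(whole) <- cells
  per_csl <- matrix(0, length(cells), length(csls) * length(channels),
                    dimnames = list(cells, NULL))
  for (i in seq_along(csls)) {
    sub <- ft[ft$csl == csls[i], ]
    block <- as.matrix(sub[, channels, drop = FALSE])
    block[is.na(block)] <- 0
    per_csl[sub$cell_id, (i - 1) * length(channels) + seq_along(channels)] <-
      block
  }
  out <- list(whole_cell_intensity = whole, per_csl_intensity = per_csl)
  if (!is.null(curves)) {
    cooc <- t(vapply(cells, function(id) {
      v <- log2(as.vector(curves[[id]]))
      v[!is.finite(v)] <- 0
      v
    }, numeric(length(curves[[cells[1]]]))))
    out$cooccurrence <- cooc
  }
  out
}

silhouette_table <- function(ft, meta, channels, condition_field,
                             curves = NULL) {
  reps <- cell_representations(ft, channels, curves)
  cells <- rownames(reps[[1]])
  cond <- meta[[condition_field]][match(cells, meta$cell_id)]
  levs <- unique(cond)
  rows <- list()
  for (rn in names(reps)) {
    rep_mat <- reps[[rn]]
    for (a in seq_along(levs)) for (b in seq_along(levs)) {
      if (a >= b) next
      s <- pairwise_silhouette(rep_mat[cond == levs[a], , drop = FALSE],
                               rep_mat[cond == levs[b], , drop = FALSE])
      rows[[length(rows) + 1L]] <- data.frame(
        p = levs[a], q = levs[b], s_pq = s$s_pq, s_qp = s$s_qp,
        symmetric = s$symmetric, representation = rn,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
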