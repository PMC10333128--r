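# Shared fixtures built in code. The expensive trained-pipeline fixture is
# memoised so the acceptance-style tests share one cVAE training run.

make_cell <- function(cell_id = "c1", well_id = "w1",
                      conditions = list(perturbation = "control"),
                      coords, intensities) {
  cell_record(cell_id, well_id, conditions, coords, intensities)
}

# a dense square cell: side x side block of pixels
square_cell <- function(side = 5, n_channels = 3, cell_id = "c1",
                        well_id = "w1",
                        conditions = list(perturbation = "control"),
                        fill = NULL) {
  coords <- as.matrix(expand.grid(row = 0:(side - 1), col = 0:(side - 1)))
  ints <- if (is.null(fill))
    matrix(seq_len(side^2 * n_channels), side^2, n_channels)
  else matrix(fill, side^2, n_channels)
  make_cell(cell_id, well_id, conditions, coords, ints)
}

tiny_dataset <- function(n_cells = 6, side = 5, n_channels = 3, seed = 1) {
  set.seed(seed)
  schema <- condition_schema(list(perturbation = c("control", "treated")))
  cells <- lapply(seq_len(n_cells), function(i) {
    lev <- if (i %% 2 == 0) "treated" else "control"
    square_cell(side, n_channels, cell_id = sprintf("c%d", i),
                well_id = sprintf("w%d", (i %% 2) + 1),
                conditions = list(perturbation = lev),
                fill = rnorm(side^2 * n_channels, 10, 2))
  })
  multiplexed_dataset(cells, channel_panel(paste0("ch", seq_len(n_channels))),
                      schema)
}

# small synthetic study used for mid-weight tests (fast: ~15k pixels)
small_synth <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_synth_small(seed = 11, n_cells_per_condition = 5)
    cache
  }
})

# Trained-pipeline fixture at the default study scale, shared by the
# acceptance tests (training runs once per test session).
trained_pipeline <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    seed <- 1
    out <- generate_synth_small(seed = seed)
    ds <- fit_and_apply_quantile_norm(background_subtract(out$dataset))
    ds <- split_cells(ds, seed = derive_seed(seed, 2))
    model <- train_cvae(ds, cvae_config(seed = derive_seed(seed, 3)),
                        fraction_per_cell = 1.0)
    enc <- encode_dataset(model, ds)
    cache <<- list(seed = seed, truth = out$ground_truth, ds = ds,
                   model = model, enc = enc)
    cache
  }
})
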