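# Small screen configurations reused across tests. Sizes are kept at the low
# end of the study design (one plate, 3 experiments, a few hundred cells per
# sample) so the suite stays fast while exercising the full pipeline.

tiny_config <- function(...) {
  args <- utils::modifyList(
    list(n_variants = 6, plate_size = 6, n_scr_per_plate = 3,
         n_experiments = 3, cells_per_sample = 300, seed = 101L),
    list(...))
  do.call(screen_config, args)
}

# a cell table built by hand: one variant, one experiment, given yp vectors
manual_cells <- function(exposed, sham, variant = "KO001",
                         experiment = "1", plate = "1") {
  rbind(
    data.frame(experiment = experiment, plate = plate, variant = variant,
               condition = "exposed", cell_id = seq_along(exposed),
               hoechst = 100, yp = exposed),
    data.frame(experiment = experiment, plate = plate, variant = variant,
               condition = "sham", cell_id = seq_along(sham),
               hoechst = 100, yp = sham)
  )
}

# delta rows built directly (bypassing cell tables) for normalization tests
manual_deltas <- function(variants, values, experiment = "1", plate = "1",
                          metric = "mean") {
  data.frame(variant = variants, experiment = experiment, plate = plate,
             metric = metric, value = values, stringsAsFactors = FALSE)
}
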