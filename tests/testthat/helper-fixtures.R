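# Shared fixtures: everything is generated in code at test time.

SPACING <- 40000

make_signal <- function(values, chromosome = "chrT", spacing = SPACING,
                        sample_id = "test") {
  probe_signal(chromosome, spacing * seq_along(values), values, sample_id)
}

small_spec <- function(n_probes = 400, ...) {
  simulation_spec(n_probes = n_probes, ...)
}

# default parameters with the signal range pinned to the simulator's range,
# as segment_signal is used on simulated data throughout the suite
sim_params <- function(...) {
  fit_parameters(signal_range = 1, ...)
}

write_probe_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# a simple hand-built three-segment map: CTR(1.8) - TTR down - CTR(1.2),
# on an even 40 kb grid; junctions at probes j1 and j2
three_segment_fit <- function(n = 120, j1 = 40, j2 = 60) {
  lev1 <- 1.8; lev2 <- 1.2
  slope <- (lev2 - lev1) / ((j2 - j1) * SPACING)
  values <- c(rep(lev1, j1),
              lev1 + slope * SPACING * seq_len(j2 - j1 - 1),
              rep(lev2, n - j2 + 1))
  sim <- list(
    signal = make_signal(values),
    truth = list(
      clean_values = values,
      true_type = c(rep("CTR", j1), rep("TTR", j2 - j1), rep("CTR", n - j2)),
      true_breakpoints = c(j1, j2),
      segments = data.frame(start_idx = c(1, j1, j2), end_idx = c(j1, j2, n),
                            type = c("CTR", "TTR", "CTR"))
    )
  )
  segmentation_from_truth(sim)
}
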