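# shared small synthetic panel, built once per test run
.panel_cache <- new.env(parent = emptyenv())

small_panel <- function(seed = 42) {
  key <- paste0("p", seed)
  if (is.null(.panel_cache[[key]])) {
    sp <- panel_spec(
      n_lines = 24, males_per_line = c(8L, 10L),
      n_variants = 60
    )
    .panel_cache[[key]] <- simulate_panel(sp, seed = seed)
  }
  .panel_cache[[key]]
}

# tiny hand-written observation table: two males, deterministic scores
toy_observations <- function(T = 30L) {
  tibble::tibble(
    line_id = rep(c("L1", "L2"), each = T),
    block_id = "b1",
    trial_id = "t1",
    arena = rep(c("1", "2"), each = T),
    male_id = rep(c("m1", "m2"), each = T),
    timepoint = rep(0:(T - 1L), 2),
    ordinal_score = c(rep(1L, T), rep(8L, T))
  )
}
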