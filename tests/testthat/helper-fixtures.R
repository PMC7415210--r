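# build a windowed_fc object directly from an edge matrix (windows x edges)
as_windowed <- function(edges, p, id = "x") {
  structure(list(id = id, edges = edges, n_regions = p,
                 region_labels = sprintf("R%03d", seq_len(p)),
                 starts = seq_len(nrow(edges)) - 1L,
                 window_length = 10L, step = 1L, tr = 3,
                 flags = vector("list", nrow(edges))),
            class = "windowed_fc")
}

# random valid windowed_fc derived from an actual random time series
random_windowed <- function(n_timepoints, p, seed, id = "x") {
  set.seed(seed)
  x <- matrix(rnorm(n_timepoints * p), n_timepoints, p)
  sliding_window_fc(x, window_params(), id = id)
}

# a small cohort in a temp dir; returns list(dir, manifest, truth)
small_cohort <- function(seed = 1, n_per_group = 4, n_regions = 20, ...) {
  cfg <- generator_config(n_per_group = n_per_group, n_regions = n_regions,
                          seed = seed, ...)
  generate_cohort(cfg, withr::local_tempdir(.local_envir = parent.frame()))
}

# planted window-level labels: the state when all time points of the window
# share it, NA for switch-spanning windows
pure_window_labels <- function(state_seq, window_length = 10, step = 1) {
  n <- (length(state_seq) - window_length) %/% step + 1
  vapply(seq_len(n), function(i) {
    seg <- state_seq[((i - 1) * step + 1):((i - 1) * step + window_length)]
    if (all(seg == seg[1])) seg[1] else NA_integer_
  }, integer(1))
}
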