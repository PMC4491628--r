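# shared fixtures: everything is generated in code at test time

# tiny tabular motion file: 3 frames, 2 markers
write_tiny_tab <- function(path, nan = FALSE) {
  rows <- c("0 0 0 1 0 0",
            "0 0.1 0 1 0.1 0",
            if (nan) "0 NaN 0 1 0.2 0" else "0 0.2 0 1 0.2 0")
  writeLines(c("# markers: A B", "# rate: 120", rows), path)
  path
}

# a layer with `n` trained unit-vector patterns (deterministic construction)
toy_trained_layer <- function(n = 2, dim = 348, seed = 7, reps = 200,
                              orthogonal = FALSE, ...) {
  ly <- pattern_layer(n_input = dim, seed = seed, ...)
  pats <- if (orthogonal) {
    lapply(seq_len(n), function(i) { v <- numeric(dim); v[i] <- 1; v })
  } else {
    set.seed(seed)
    lapply(seq_len(n), function(i) { v <- stats::rnorm(dim); v / sqrt(sum(v^2)) })
  }
  for (p in pats) {
    train_winner(ly, p, free_index(ly))       # recruit
    for (r in seq_len(reps)) train_winner(ly, p, ly$P - 1L)
  }
  ly$prev_winner <- NA_integer_
  ly
}
free_index <- biomotion:::free_index

# random unit 3-vector
runit3 <- function() { v <- stats::rnorm(3); v / sqrt(sum(v^2)) }

# fast experiment config used by non-acceptance tests
test_cfg <- function(...) run_config(seed = 11, ...)
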