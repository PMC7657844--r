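# Shared small fixtures built in code at test time.

fixture_gaussian <- function(N, D, seed = 1, sd = 1) {
  set.seed(seed)
  matrix(rnorm(N * D, sd = sd), N, D)
}

# Small counts matrix with a known pass/fail pattern for the filters.
fixture_counts <- function() {
  counts <- rbind(
    c(5, 0, 2, 0, 1),   # 3 features
    c(0, 0, 0, 0, 0),   # empty cell
    c(1, 1, 1, 1, 1),   # 5 features
    c(2, 3, 0, 0, 0),   # 2 features
    c(0, 4, 4, 0, 0),   # 2 features
    c(7, 0, 0, 1, 2)    # 3 features
  )
  count_matrix(counts,
               cell_ids = paste0("c", 1:6),
               gene_ids = paste0("g", 1:5))
}
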