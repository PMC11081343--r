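# Independent brute-force oracles used by several test files.

# Nested-loop evaluation of the additive lattice decomposition: for every
# cell, walk the included terms and index each tensor directly.
materialize_oracle <- function(dp) {
  lat <- dp$lattice
  nc <- n_cells(lat)
  km <- cell_multi_index(lat, seq_len(nc))
  out <- matrix(0, nc, dp$n_coef)
  for (cell in seq_len(nc)) {
    kap <- km[cell, ]
    for (term in dp$terms) {
      row <- 1L
      stride <- 1L
      for (d in term$dims) {
        row <- row + kap[d] * stride
        stride <- stride * lat$dims[d]
      }
      out[cell, ] <- out[cell, ] + dp$values[term$offset + row, ]
    }
  }
  out
}
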