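# Small reusable fixtures built in code.

tiny_connectome <- function(n = 3, seed = 11) {
  set.seed(seed)
  w <- matrix(runif(n * n), n, n)
  w <- (w + t(w)) / 2
  diag(w) <- 0
  d <- matrix(25, n, n)
  diag(d) <- 0
  connectome(w, d)
}

flat_eeg <- function(data, dt = 1e-3, t0 = 0) {
  eeg_timeseries(t0 + (seq_len(ncol(data)) - 1) * dt, data)
}

single_node <- function() connectome(matrix(0, 1, 1), matrix(0, 1, 1))
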