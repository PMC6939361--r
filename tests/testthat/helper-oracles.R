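# Independent oracles, kept deliberately naive so they never share code with
# the implementation paths they check.

# Direct O(d^2) circular convolution: c[k] = sum_j a[j] * b[(k - j) mod d],
# one explicit sum per output entry.
conv_direct <- function(a, b) {
  d <- length(a)
  j <- 0:(d - 1)
  vapply(0:(d - 1), function(k) sum(a * b[((k - j) %% d) + 1]), numeric(1))
}

# Involution via FFT conjugation: the approximate inverse has spectrum
# conj(fft(a)), computed here without touching hrr_inverse.
inverse_fft_oracle <- function(a) {
  Re(fft(Conj(fft(a)), inverse = TRUE)) / length(a)
}

# Tiny deterministic fixtures shared across files.
toy_vocab <- function(dim = 256, n = 8, seed = 42, prefix = "s") {
  hrr_vocabulary(sprintf("%s%02d", prefix, seq_len(n)), dim, seed)
}
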