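# Independent brute-force oracles for the ordinal core.

# all permutations of 1..m in lexicographic order (recursive enumeration,
# independent of the Lehmer-code path under test)
perms_lex <- function(m) {
  if (m == 1L) return(matrix(1L, 1, 1))
  sub <- perms_lex(m - 1L)
  do.call(rbind, lapply(seq_len(m), function(first) {
    rest <- setdiff(seq_len(m), first)
    cbind(first, matrix(rest[sub], nrow(sub), m - 1L))
  }))
}

# brute-force symbolization: explicit embedded vectors, stable order(),
# rank by row-matching against the enumerated permutation table
brute_symbolize <- function(x, m, tau = 1L) {
  P <- perms_lex(m)
  key <- apply(P, 1, paste, collapse = ",")
  n <- length(x) - (m - 1L) * tau
  vapply(seq_len(n), function(j) {
    v <- x[j + (0:(m - 1L)) * tau]
    match(paste(order(v), collapse = ","), key)
  }, integer(1))
}

brute_counts <- function(ranks, m) {
  vapply(seq_len(factorial(m)), function(i) sum(ranks == i), integer(1))
}

# single-sided FFT amplitude of a (steady-state) segment at frequency f
fft_amplitude <- function(x, f, fs) {
  n <- length(x)
  k <- round(f * n / fs)
  stopifnot(abs(k - f * n / fs) < 1e-6)  # segment must hold integer cycles
  2 * Mod(stats::fft(x)[k + 1]) / n
}
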