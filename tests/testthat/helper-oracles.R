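# Independent oracles used by the unit and acceptance tests. These stay
# deliberately naive (nested loops, forward substitution) so they cannot
# share a code path with the implementation they check.

# brute-force linear convolution by explicit double loop
conv_oracle <- function(x, y) {
  out <- numeric(length(x) + length(y) - 1L)
  for (i in seq_along(x))
    for (j in seq_along(y))
      out[i + j - 1L] <- out[i + j - 1L] + x[i] * y[j]
  out
}

# solve L x = b for square lower-triangular L by forward substitution
forward_sub_oracle <- function(l, b) {
  n <- nrow(l)
  x <- numeric(n)
  for (i in seq_len(n)) {
    s <- b[i]
    if (i > 1L) s <- s - sum(l[i, 1:(i - 1L)] * x[1:(i - 1L)])
    x[i] <- s / l[i, i]
  }
  x
}

# random valid metabolite record for property tests
random_record <- function(n_peaks = sample(2:8, 1), name = "rnd") {
  base <- sample(100:400, 1)
  metabolite_record(
    name = paste0(name, "-", base),
    mz_values = base + seq_len(n_peaks) - 1 + round(runif(n_peaks, 0, 0.2), 3),
    intensities = round(runif(n_peaks, 0, 100), 6),
    n_carbons_metabolite = sample(1:6, 1),
    n_carbons_fragment = sample(1:6, 1)
  )
}

# the worked-example alanine fragment (3 carbons, m0 = 259)
alanine_record <- function() {
  metabolite_record(
    "Alanine (Ala)",
    c(259.15, 260.1, 261.1, 262.1, 263.1, 264.1, 265.1),
    c(0.07, 8.53, 2.3, 2.39, 44.59, 8.79, 3.88),
    n_carbons_metabolite = 3, n_carbons_fragment = 3
  )
}

# published reference values for the alanine worked example
TAB_NA_PCT <- c(96.7068262369, 3.2564842893, 0.0365527107, 0.0001367631)
TAB_RA <- c(1.01811623727288, 0, 0, 0.436317933953475)
TAB_RA_PCT <- c(70.0008468870352, 0, 0, 29.9991531129648)
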