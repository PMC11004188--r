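# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Naive two-pass across-trial variance, a literal double loop.
brute_force_variance <- function(positions) {
  n <- nrow(positions)
  out <- numeric(ncol(positions))
  for (t in seq_len(ncol(positions))) {
    mu <- 0
    for (j in seq_len(n)) mu <- mu + positions[j, t]
    mu <- mu / n
    s <- 0
    for (i in seq_len(n)) s <- s + (positions[i, t] - mu)^2
    out[t] <- s / (n - 1)
  }
  out
}

# Quadratic-formula roots of a*s^2 + b*s + c, sorted by real part.
quad_roots <- function(a, b, c) {
  disc <- sqrt(as.complex(b^2 - 4 * a * c))
  sort(c((-b + disc) / (2 * a), (-b - disc) / (2 * a)))
}

# Small helper to wrap a matrix of trials into an ensemble on a given grid.
make_ensemble <- function(time, positions, align = FALSE) {
  trajectory_ensemble(time, positions, units = "units", align = align)
}
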