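# O(n^2) pairwise brute-force oracle for the four deprivation indices,
# written directly from the pairwise definition: each person's index is the
# average over all group members of the pairwise shortfall.
oracle_indices <- function(income) {
  n <- length(income)
  yit <- dea <- pod <- pct <- numeric(n)
  mu <- mean(income)
  for (i in seq_len(n)) {
    s <- 0
    slog <- 0
    for (k in seq_len(n)) {
      if (income[k] > income[i]) {
        s <- s + (income[k] - income[i])
        slog <- slog + (log(income[k]) - log(income[i]))
      }
    }
    yit[i] <- s / n
    dea[i] <- s / (n * mu)
    pod[i] <- slog / n
    r <- mean(rank(income, ties.method = "average")[income == income[i]])
    pct[i] <- 100 * (rank(income, ties.method = "average")[i] - 1) / (n - 1)
  }
  list(yitzhaki = yit, deaton = dea, podder = pod, percentile = pct)
}

# compact right-hand form: share strictly above times (their mean - own income)
oracle_compact_yitzhaki <- function(income) {
  n <- length(income)
  vapply(seq_len(n), function(i) {
    above <- income[income > income[i]]
    if (length(above) == 0) return(0)
    (length(above) / n) * (mean(above) - income[i])
  }, 0)
}

small_pop <- function(seed = 1, nv = 6, size = c(8, 12), ...) {
  add_rd_indices(generate_population(
    sim_config(n_villages = nv, residents_per_village = size, seed = seed, ...)
  ))
}
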