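# Independent reference implementations used as oracles across test files.
# These are deliberately loop-written and share no code with the package.

# Consecutive-pair threshold scan, the classification rule written directly.
bf_classify <- function(z, threshold = 3, n_consec = 2) {
  best_plus <- -Inf; best_minus <- -Inf
  for (i in seq_len(length(z) - n_consec + 1)) {
    w <- z[i:(i + n_consec - 1)]
    if (all(w > threshold)) best_plus <- max(best_plus, mean(abs(w)))
    if (all(w < -threshold)) best_minus <- max(best_minus, mean(abs(w)))
  }
  if (is.finite(best_plus) && is.finite(best_minus)) {
    if (best_plus >= best_minus) "PLUS" else "MINUS"
  } else if (is.finite(best_plus)) "PLUS"
  else if (is.finite(best_minus)) "MINUS"
  else "NONE"
}

# O(n^3) Ward agglomeration via the Lance-Williams recurrence on squared
# Euclidean distances (heights on the ward.D2 scale). Returns the cophenetic
# distance matrix, which identifies the tree uniquely.
bf_ward_cophenetic <- function(x) {
  n <- nrow(x)
  d2 <- as.matrix(stats::dist(x))^2
  active <- seq_len(n)
  members <- lapply(seq_len(n), identity)
  sizes <- rep(1, n)
  coph <- matrix(0, n, n)
  for (step in seq_len(n - 1)) {
    best <- c(NA, NA); bestd <- Inf
    for (ii in seq_along(active)) for (jj in seq_along(active)) {
      if (jj <= ii) next
      a <- active[ii]; b <- active[jj]
      if (d2[a, b] < bestd) { bestd <- d2[a, b]; best <- c(a, b) }
    }
    a <- best[1]; b <- best[2]
    h <- sqrt(bestd)
    for (p in members[[a]]) for (q in members[[b]]) {
      coph[p, q] <- h; coph[q, p] <- h
    }
    na_ <- sizes[a]; nb_ <- sizes[b]
    for (k in active) {
      if (k == a || k == b) next
      nk <- sizes[k]
      d2[a, k] <- ((na_ + nk) * d2[a, k] + (nb_ + nk) * d2[b, k] -
                     nk * d2[a, b]) / (na_ + nb_ + nk)
      d2[k, a] <- d2[a, k]
    }
    members[[a]] <- c(members[[a]], members[[b]])
    sizes[a] <- na_ + nb_
    active <- setdiff(active, b)
  }
  coph
}

# Small planted session used by several recovery tests.
make_small_session <- function(fractions = c(cs_plus = 1), n = 20, seed = 1,
                               amplitude = 6, trial_gain_sd = 0.2) {
  pop <- population_spec(n, fractions, response_amplitude = amplitude,
                         trial_gain_sd = trial_gain_sd, seed = seed)
  generate_session(pop, session_spec())
}

# Align + block + Z for one tone type.
ztensor_for <- function(sim, tone_type, block_size = 2) {
  ztransform_pretone(block_average(
    align_and_bin(sim$traces, sim$schedule, tone_type),
    block_size = block_size))
}
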