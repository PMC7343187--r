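# Seeded differential-evolution search (rand/1/bin) with box constraints.
# Used as the global stage of kinetic parameter fitting; callers wrap it in
# withr::with_seed so results are reproducible bitwise for a given seed.
.de_optimize <- function(fn, lower, upper, pop_size = 10 * length(lower),
                         generations = 100, F = 0.8, CR = 0.9) {
  d <- length(lower)
  stopifnot(length(upper) == d, all(upper > lower))
  pop <- matrix(stats::runif(pop_size * d, lower, upper),
                nrow = pop_size, ncol = d, byrow = TRUE)
  cost <- apply(pop, 1, fn)
  for (g in seq_len(generations)) {
    for (i in seq_len(pop_size)) {
      idx <- sample(setdiff(seq_len(pop_size), i), 3)
      trial <- pop[idx[1], ] + F * (pop[idx[2], ] - pop[idx[3], ])
      cross <- stats::runif(d) < CR
      cross[sample.int(d, 1)] <- TRUE
      trial <- ifelse(cross, trial, pop[i, ])
      trial <- pmin(pmax(trial, lower), upper)
      trial_cost <- fn(trial)
      if (trial_cost <= cost[i]) {
        pop[i, ] <- trial
        cost[i] <- trial_cost
      }
    }
  }
  best <- which.min(cost)
  list(par = pop[best, ], value = cost[best])
}
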