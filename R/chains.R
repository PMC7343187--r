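#' Configuration for stochastic poly-glutamate chain simulation
#'
#' Describes the discrete-time Markov model of a single RpsF glutamate tail:
#' at each step one glutamate is added with probability `p_add`, the terminal
#' glutamate is removed with probability `p_cut` (active only above the
#' protease floor of `min_cut_length` residues), the chain is released
#' (terminating a processive run) with probability `release_prob`, and
#' otherwise nothing happens. The protease:ligase activity ratio
#' `rho = p_cut / p_add` is the primary control; the chain length is capped
#' at `max_length` (probability mass accumulates at the cap).
#'
#' @param p_add per-step glutamate addition probability.
#' @param p_cut per-step cleavage probability; if `NULL`, derived as
#'   `rho * p_add`.
#' @param rho protease:ligase activity ratio; used when `p_cut` is `NULL`
#'   (default 1).
#' @param release_prob per-step chain termination probability (processive,
#'   no-protease mode); default 0.
#' @param min_cut_length protease floor, default 4 glutamate units.
#' @param max_length chain cap, default 100 glutamate units.
#' @param horizon number of steps per chain (protease mode records at this
#'   fixed horizon; processive chains record at release), default 1e4.
#' @param n_sims replicate chain count, default 1e6.
#' @param initial_length starting tail length, default 0.
#' @return a list of class `chain_config`.
#' @export
chain_config <- function(p_add = 0.3, p_cut = NULL, rho = NULL,
                         release_prob = 0, min_cut_length = 4,
                         max_length = 100, horizon = 1e4, n_sims = 1e6,
                         initial_length = 0) {
  if (is.null(p_cut)) {
    rho <- rho %||% 1
    p_cut <- rho * p_add
  } else {
    rho <- if (p_add > 0) p_cut / p_add else Inf
  }
  probs <- c(p_add = p_add, p_cut = p_cut, release_prob = release_prob)
  if (any(probs < 0) || any(probs > 1) || sum(probs) > 1) {
    stop("probabilities must lie in [0,1] and sum to at most 1",
         call. = FALSE)
  }
  if (min_cut_length < 0 || max_length < min_cut_length) {
    stop("need 0 <= min_cut_length <= max_length", call. = FALSE)
  }
  if (initial_length < 0 || initial_length > max_length) {
    stop("initial_length must lie in [0, max_length]", call. = FALSE)
  }
  structure(list(p_add = p_add, p_cut = p_cut, rho = rho,
                 p_idle = 1 - sum(probs), release_prob = release_prob,
                 min_cut_length = as.integer(min_cut_length),
                 max_length = as.integer(max_length),
                 horizon = as.integer(horizon), n_sims = as.integer(n_sims),
                 initial_length = as.integer(initial_length)),
            class = "chain_config")
}

#' Simulate a single chain to its recorded length
#'
#' @param config a [chain_config()].
#' @param seed optional integer seed.
#' @return final chain length (integer in `[0, max_length]`).
#' @export
simulate_single_chain <- function(config, seed = NULL) {
  stopifnot(inherits(config, "chain_config"))
  run <- function() {
    simulate_chains_cpp(1L, config$horizon, config$p_add, config$p_cut,
                        config$release_prob, config$min_cut_length,
                        config$max_length, config$initial_length)[1]
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Empirical chain-length distribution over replicate chains
#'
#' Averages `n_sims` independent replicate chains into a probability mass
#' function over lengths `0..max_length` (the expected chain-length
#' distribution of Fig-5-style population averages).
#'
#' @param config a [chain_config()].
#' @param seed integer seed (default 1); the result is seed-deterministic.
#' @return a `chain_length_distribution`: list with `length` (0..max),
#'   `prob`, `n_sims`, `seed`, `config`.
#' @export
chain_length_distribution <- function(config, seed = 1) {
  stopifnot(inherits(config, "chain_config"), config$n_sims >= 1)
  lens <- withr::with_seed(seed, {
    simulate_chains_cpp(config$n_sims, config$horizon, config$p_add,
                        config$p_cut, config$release_prob,
                        config$min_cut_length, config$max_length,
                        config$initial_length)
  })
  counts <- tabulate(lens + 1L, nbins = config$max_length + 1L)
  structure(list(length = 0:config$max_length,
                 prob = counts / config$n_sims,
                 n_sims = config$n_sims, seed = seed, config = config),
            class = "chain_length_distribution")
}

#' @export
print.chain_length_distribution <- function(x, ...) {
  cat("<chain_length_distribution> n_sims:", x$n_sims,
      " mode:", distribution_mode(x),
      " mean:", format(sum(x$length * x$prob), digits = 4), "\n")
  invisible(x)
}

#' @export
plot.chain_length_distribution <- function(x, ...) {
  graphics::plot(x$length, x$prob, type = "h", xlab = "chain length (Glu)",
                 ylab = "probability", ...)
  invisible(x)
}

#' Closed-form capped-geometric distribution of processive extension
#'
#' In the no-protease limit a chain extends with per-step probability `q` and
#' terminates with probability `1 - q`, giving the geometric law
#' `P(L = k) = q^k (1 - q)`; the cap at `max_length` accumulates the tail
#' mass `q^max_length`. This is the independent oracle for the simulator's
#' processive mode, with uncapped mean `q / (1 - q)`.
#'
#' @param q per-step extension probability, `0 <= q < 1`.
#' @param max_length chain cap (default 100).
#' @return a `chain_length_distribution` with extra element `mean_uncapped`.
#' @export
geometric_oracle <- function(q, max_length = 100) {
  if (q < 0 || q >= 1) stop("need 0 <= q < 1", call. = FALSE)
  k <- 0:max_length
  prob <- q^k * (1 - q)
  prob[max_length + 1] <- q^max_length
  structure(list(length = k, prob = prob, n_sims = NA_integer_,
                 seed = NA_integer_, config = NULL,
                 mean_uncapped = q / (1 - q)),
            class = "chain_length_distribution")
}

#' Modal chain length of a distribution
#'
#' Argmax of the probability mass; ties are broken toward the smaller length.
#'
#' @param dist a `chain_length_distribution`.
#' @return integer modal length.
#' @export
distribution_mode <- function(dist) {
  stopifnot(inherits(dist, "chain_length_distribution"))
  dist$length[which.max(dist$prob)]
}

#' Expected chain length of a distribution
#'
#' @param dist a `chain_length_distribution`.
#' @return numeric mean length.
#' @export
expected_length <- function(dist) {
  stopifnot(inherits(dist, "chain_length_distribution"))
  sum(dist$length * dist$prob)
}

#' Configuration for cell-population chain simulation
#'
#' A typical cell carries roughly one RimABK complex per 500 RpsF copies, so
#' the population simulator shares a single complex (and optionally a finite
#' glutamate monomer pool) across all chains.
#'
#' @param n_rpsf RpsF copies (default 500).
#' @param n_complex RimABK complexes (default 1; only the single-complex
#'   semantics are modelled).
#' @param glutamate_pool shared free glutamate count (default `Inf`).
#' @param horizon total number of events (default 2e6).
#' @return a list of class `population_config`.
#' @export
population_config <- function(n_rpsf = 500, n_complex = 1,
                              glutamate_pool = Inf, horizon = 2e6) {
  if (n_complex != 1) {
    stop("only a single shared RimABK complex is modelled", call. = FALSE)
  }
  if (glutamate_pool < 0) stop("glutamate_pool must be >= 0", call. = FALSE)
  if (n_rpsf < 1) stop("n_rpsf must be >= 1", call. = FALSE)
  structure(list(n_rpsf = as.integer(n_rpsf), n_complex = 1L,
                 glutamate_pool = glutamate_pool, horizon = horizon),
            class = "population_config")
}

#' Simulate glutamation of an RpsF population sharing one RimABK complex
#'
#' Events are serial: the complex binds a chain and extends it processively
#' (unbinding with `release_prob`), while cleavage events hit a uniformly
#' chosen chain, are no-ops at or below the protease floor, and return the
#' removed glutamate to the shared pool (the ligase can reuse liberated
#' glutamate). Total incorporated glutamate plus the remaining pool equals
#' the initial pool at every event, exactly.
#'
#' @param chain_cfg a [chain_config()]; `release_prob` should be positive for
#'   the complex to visit more than one chain.
#' @param pop_cfg a [population_config()].
#' @param seed integer seed (default 1).
#' @return list with `lengths` (per-chain), `pool_remaining`, `summary`
#'   (tibble: `fraction_unmodified`, `fraction_modified`, `mean_length`),
#'   `conserved` (logical), and `snapshots` (tibble of step, incorporated,
#'   pool).
#' @export
simulate_population <- function(chain_cfg, pop_cfg = population_config(),
                                seed = 1) {
  stopifnot(inherits(chain_cfg, "chain_config"),
            inherits(pop_cfg, "population_config"))
  pool_arg <- if (is.infinite(pop_cfg$glutamate_pool)) -1
              else pop_cfg$glutamate_pool
  res <- withr::with_seed(seed, {
    simulate_population_cpp(pop_cfg$n_rpsf, pop_cfg$horizon,
                            chain_cfg$p_add, chain_cfg$p_cut,
                            chain_cfg$release_prob,
                            chain_cfg$min_cut_length, chain_cfg$max_length,
                            pool_arg, 100L)
  })
  lengths <- res$lengths
  list(
    lengths = lengths,
    pool_remaining = res$pool_remaining,
    summary = tibble::tibble(
      fraction_unmodified = mean(lengths == 0),
      fraction_modified = mean(lengths >= 1),
      mean_length = mean(lengths)
    ),
    conserved = res$conserved,
    snapshots = tibble::tibble(step = res$snap_step,
                               incorporated = res$snap_incorporated,
                               pool = res$snap_pool)
  )
}

#' Map enzymatic activities to chain step probabilities
#'
#' The per-step probabilities depend on the concentrations of the RimK
#' species and of RimB; the mapping is taken as proportional with a single
#' scale factor: `p_add = scale * ligase_activity` and
#' `p_cut = scale * protease_activity`, so the activity ratio `rho` is
#' preserved. Activities can come from [composite_rate()] on steady-state
#' occupancies (ligase) and from the RimB concentration (protease).
#'
#' @param ligase_activity,protease_activity non-negative activities in any
#'   common unit.
#' @param scale factor converting activity to per-step probability; must
#'   leave `p_add + p_cut <= 1`.
#' @param ... passed to [chain_config()] (e.g. `release_prob`, `n_sims`).
#' @return a [chain_config()].
#' @export
chain_probs_from_activities <- function(ligase_activity, protease_activity,
                                        scale, ...) {
  if (ligase_activity < 0 || protease_activity < 0 || scale <= 0) {
    stop("activities must be >= 0 and scale > 0", call. = FALSE)
  }
  chain_config(p_add = scale * ligase_activity,
               p_cut = scale * protease_activity, ...)
}
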