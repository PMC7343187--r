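# Shared fixture builders for the test suite; everything is generated in
# code so no binary data ships with the package.

# simple receptor-ligand pair network
pair_network <- function(R = 2.5, L = 25, Kd = 1) {
  reaction_network(
    c(R = R, L = L, RL = 0),
    data.frame(a = "R", b = "L", complex = "RL", Kd_uM = Kd)
  )
}

# exact bound complex concentration for R + L <-> RL
pair_complex_exact <- function(R, L, Kd) {
  b <- R + L + Kd
  (b - sqrt(b^2 - 4 * R * L)) / 2
}

# random two-step cascade R + L <-> RL, RL + M <-> RLM with random
# parameters; used for moiety-conservation property tests
random_cascade_network <- function(seed) {
  withr::with_seed(seed, {
    reaction_network(
      c(R = runif(1, 0.5, 5), L = runif(1, 0.5, 30),
        M = runif(1, 0.5, 10), RL = 0, RLM = 0),
      data.frame(a = c("R", "RL"), b = c("L", "M"),
                 complex = c("RL", "RLM"),
                 Kd_uM = 10^runif(2, -1, 1.5))
    )
  })
}

# thermodynamically consistent binding square around a central protein K
square_network <- function(kd_a = 1, kd_c = 2, kd_c_on_ka = 3,
                           kd_a_on_kc = kd_a * kd_c_on_ka / kd_c) {
  reaction_network(
    c(K = 1, A = 1, c = 1, KA = 0, Kc = 0, KAc = 0),
    data.frame(a = c("K", "K", "KA", "Kc"), b = c("A", "c", "c", "A"),
               complex = c("KA", "Kc", "KAc", "KAc"),
               Kd_uM = c(kd_a, kd_c, kd_c_on_ka, kd_a_on_kc))
  )
}

# reads as a GRanges on a single toy reference with given seqlength
make_reads <- function(start, width, strand = "+", ref_len = 10000,
                       ref = "toygenome") {
  GenomicRanges::GRanges(
    seqnames = rep(ref, length(start)),
    ranges = IRanges::IRanges(start = start, width = width),
    strand = rep(strand, length.out = length(start)),
    seqlengths = stats::setNames(ref_len, ref)
  )
}

# naive per-read coverage oracle: loop over reads, increment the trimmed
# window positions in a plain integer vector (one strand)
naive_coverage <- function(starts, widths, ref_len, trim = 11) {
  cov <- integer(ref_len)
  for (i in seq_along(starts)) {
    from <- starts[i] + trim
    to <- starts[i] + widths[i] - 1 - trim
    to <- min(to, ref_len)
    if (from <= to) cov[from:to] <- cov[from:to] + 1L
  }
  cov
}
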