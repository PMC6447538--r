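# Shared fixtures, all built in code.

# Small three-chromosome genome for Hi-C work.
hic_genome <- function(n_chrom = 3, len = 2e7, bin_size = 25000) {
  genome_spec(paste0("chr", seq_len(n_chrom)), rep(len, n_chrom),
              bin_size = bin_size)
}

# Eight-chromosome genome for cohort simulations.
cohort_genome <- function() {
  genome_spec(paste0("chr", 1:8), rep(3e7, 8), bin_size = 25000)
}

# Fraction of truth boundaries with a called boundary within +/- slop bp.
boundary_recovery <- function(called, truth, slop = 25000) {
  mean(vapply(seq_len(nrow(truth)), function(i) {
    any(called$chrom == truth$chrom[i] &
          abs(called$pos - truth$pos[i]) <= slop)
  }, logical(1)))
}

# Simulate, normalize and call boundaries with one caller.
sim_and_call <- function(genome, tads, method = c("di", "insulation"),
                         depth = 100, seed = 1, sample_id = "s") {
  method <- match.arg(method)
  sim <- simulate_hic(genome, tads, depth = depth, seed = seed)
  m <- balance(remove_short_range(sim$map), method = "ice")
  prof <- if (method == "di") directionality_index(m) else
    insulation_score(m)
  call_boundaries(prof, sample_id = sample_id)
}

# Brute-force BH step-up: the literal definition, independent of p.adjust.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  for (r in seq_len(m)) {
    i <- o[r]
    adj[i] <- min(1, min(p[o[seq(r, m)]] * m / seq(r, m)))
  }
  adj
}

# Brute-force hypergeometric upper tail P(X >= k) by explicit enumeration
# of the counting ratio, for small N.
hyper_oracle <- function(k, K, N, n) {
  ks <- max(0, n - (N - K)):min(K, n)
  ks <- ks[ks >= k]
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# Deterministic toy contact matrix with two clean blocks.
block_matrix <- function(n = 20, split = 10, inside = 9, outside = 1) {
  m <- matrix(outside, n, n)
  m[1:split, 1:split] <- inside
  m[(split + 1):n, (split + 1):n] <- inside
  contact_matrix("chrT", m, 25000)
}
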