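# Shared small fixtures, built in code.

kB <- 0.00831446261815324

# one-pair distogram with the given bin probabilities on the default grid
one_pair_distogram <- function(p) {
  distogram("GG", matrix(p, 1), pairs = cbind(0L, 1L))
}

# random normalized distogram over n residues on the default grid
random_distogram <- function(n, seed) {
  set.seed(seed)
  np <- n * (n - 1) / 2
  probs <- matrix(rexp(np * 64), np, 64)
  probs <- probs / rowSums(probs)
  distogram(paste(sample(c("G", "S", "A", "E", "K"), n, TRUE), collapse = ""),
            probs)
}

# annotations that keep everything: low PAE, low pLDDT (no segments)
permissive_annotations <- function(n, pae = 1, plddt = 40) {
  list(plddt = rep(plddt, n), pae = matrix(pae, n, n))
}

# deterministic small chain topology (no charges for simple geometry tests)
tiny_topology <- function(sequence = "GSGSGSGSGS") {
  build_topology(sequence, conditions())
}
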