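# Shared fixture builders. Everything is generated in code at test time.

# A random complete cue for an n x m register.
random_cue <- function(n, m) sample.int(m, n, replace = TRUE) - 1L

# A register filled with `k` random cues; returns the register and the cues.
random_filled_amr <- function(n, m, k, seed) {
  set.seed(seed)
  cues <- matrix(sample.int(m, k * n, replace = TRUE) - 1L, nrow = k)
  a <- amr_register(amr(n, m), cues)
  list(amr = a, cues = cues)
}

# A small well-separated synthetic domain reused across experiment tests.
tiny_domain <- function(seed = 11, n = 16, classes = 4, size = 400) {
  generate_domain(
    domain_spec(n = n, classes = classes, size = size,
                separation = 4, noise_sd = 1),
    seed = seed
  )
}

# Exhaustive enumeration of one-cell-per-column combinations of non-zero
# cells: the brute-force count of functions representable by a register.
enumerate_functions <- function(a) {
  supports <- lapply(seq_len(a$n), function(i) which(a$weights[, i] > 0L))
  if (any(lengths(supports) == 0L)) return(0L)
  nrow(do.call(expand.grid, supports))
}
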