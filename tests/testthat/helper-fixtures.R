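# Shared fixtures, built in code at test time.

fix_single <- function() pattern("a", c(1, 1, -1, -1))

# Independent oracle for the Hebbian outer-product rule: explicit loops,
# no matrix algebra shared with the implementation.
oracle_hebbian <- function(mats) {
  n <- length(mats[[1]])
  W <- matrix(0, n, n)
  for (v in mats) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i != j) W[i, j] <- W[i, j] + v[i] * v[j] / n
      }
    }
  }
  W
}

# Independent oracle for the energy: direct double sum.
oracle_energy <- function(s, W) {
  n <- length(s)
  e <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) e <- e - 0.5 * W[i, j] * s[i] * s[j]
    }
  }
  e
}

fix_trained_triplet <- function(wm_gain = 20) {
  tri <- make_semantic_triplet()
  sys <- memory_system(tri, place_codes(c("A", "B", "C"), 8),
                       meta = meta_params(wm_gain = wm_gain))
  sys <- perceive(sys, tri[[1]], "A")
  sys <- perceive(sys, tri[[2]], "B")
  sys <- perceive(sys, tri[[3]], "C")
  sys
}

pat_by_label <- function(sys, lb) {
  Filter(function(p) p$label == lb, sys$what$patterns)[[1]]
}
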