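test_that("Hebbian storage matches the outer-product oracle", {
  p <- fix_single()
  W <- store_patterns(list(p))
  expect_equal(W[1, 2], 1 / 4)
  expect_equal(W[1, 3], -1 / 4)
  expect_equal(diag(W), rep(0, 4))
  expect_true(isSymmetric(W))
  expect_equal(W, oracle_hebbian(list(p$values)))
  # several random sets against the loop oracle
  set.seed(5)
  for (rep in 1:3) {
    pats <- random_patterns(letters[1:3], 12)
    expect_equal(store_patterns(pats),
                 oracle_hebbian(lapply(pats, `[[`, "values")))
  }
})

test_that("storing a pattern and its negation doubles the weights", {
  p <- fix_single()
  q <- pattern("neg", -p$values)
  expect_equal(store_patterns(list(p, q)), 2 * store_patterns(list(p)))
})

test_that("stored letters are fixed points of sign dynamics", {
  letters3 <- make_letter_patterns()
  W <- store_patterns(letters3, "hebbian")
  for (p in letters3) {
    expect_equal(sign(as.vector(W %*% p$values)), p$values,
                 info = p$label)
  }
})

test_that("net input combines depressed recurrence with drives", {
  p <- fix_single()
  W <- store_patterns(list(p))
  st <- core_state(4)
  st$s <- p$values
  # r = 1, no drive: closed form h_i = xi_i (N-1)/N
  expect_equal(net_input(st, W), p$values * 3 / 4)
  # fully depressed recurrence passes only the drives through
  st$r <- rep(0, 4)
  ext <- c(1, 0, 0, -1); td <- c(0, 1, -1, 0)
  expect_equal(net_input(st, W, ext, td, g_bu = 2, g_td = 0.5),
               2 * ext + 0.5 * td)
  expect_error(net_input(st, W, external = c(1, 1)), "length")
})

test_that("depression depletes active units toward the fixed point", {
  params <- core_params(U = 0.1, tau_rec = 50)
  st <- core_state(2)
  st$s <- c(1, -1)  # unit 1 held active, unit 2 inactive
  for (i in 1:3000) st$r <- depression_update(st, params)
  expect_equal(st$r[1], 1 / 6, tolerance = 1e-6)  # (1/tau)/(1/tau + U)
  expect_equal(st$r[2], 1)
  # U = 0: pure recovery to 1 from any level
  st$r <- c(0.2, 0.5)
  p0 <- core_params(U = 0, tau_rec = 10)
  last <- st$r
  for (i in 1:200) {
    st$r <- depression_update(st, p0)
    expect_true(all(st$r >= last - 1e-12))
    last <- st$r
  }
  expect_equal(st$r, c(1, 1), tolerance = 1e-6)
})

test_that("resources stay in [0,1] for arbitrary activity sequences", {
  set.seed(42)
  params <- core_params(U = 0.9, tau_rec = 1)
  st <- core_state(8)
  for (i in 1:200) {
    st$s <- sample(c(-1, 1), 8, replace = TRUE)
    st$r <- depression_update(st, params)
    expect_true(all(st$r >= 0 & st$r <= 1))
  }
})

test_that("energy matches the direct double-sum oracle", {
  p <- fix_single()
  W <- store_patterns(list(p))
  expect_equal(energy(p$values, W), -1.5)  # -(N-1)/2 for one pattern
  expect_equal(energy(-p$values, W), -1.5) # sign symmetry
  expect_equal(energy(numeric(4), W), 0)
  set.seed(9)
  pats <- random_patterns(c("u", "v"), 10)
  W2 <- store_patterns(pats)
  s <- sample(c(-1, 1), 10, replace = TRUE)
  expect_equal(energy(s, W2), oracle_energy(s, W2))
})

test_that("overlap and nearest_attractor behave on exact and partial states", {
  p <- pattern("p", rep(c(1, -1), 4))
  expect_equal(overlap(p$values, p), 1)
  expect_equal(overlap(-p$values, p), -1)
  s <- p$values
  s[1:2] <- -s[1:2]  # agree on 6/8 units
  expect_equal(overlap(s, p), 0.5)
  tri <- make_semantic_triplet()
  expect_equal(nearest_attractor(tri[[2]]$values, tri), "Y")
  expect_true(is.na(nearest_attractor(numeric(64), tri)))
  # the shared X/Y cue is far from both at threshold 0.9
  expect_true(is.na(nearest_attractor(shared_cue(tri[[1]], tri[[2]]),
                                      tri, threshold = 0.9)))
})

test_that("deterministic settling converges to a stored attractor from any start", {
  p <- pattern("p", c(1, -1, 1, 1, -1, -1, 1, -1))
  W <- store_patterns(list(p))
  grid <- as.matrix(expand.grid(rep(list(c(-1, 1)), 8)))
  for (i in seq_len(nrow(grid))) {
    st <- core_state(8)
    st$s <- grid[i, ]
    res <- settle(st, W)
    expect_true(res$converged)
    m <- overlap(res$state, p)
    expect_true(isTRUE(all.equal(abs(m), 1)),
                info = paste("start", i, "overlap", m))
  }
})

test_that("a state already at a stored pattern settles in one sweep", {
  letters3 <- make_letter_patterns()
  W <- store_patterns(letters3)
  st <- core_state(25)
  st$s <- letters3[[2]]$values
  res <- settle(st, W)
  expect_true(res$converged)
  expect_equal(res$sweeps, 1)
  expect_equal(res$state$s, letters3[[2]]$values)
})

test_that("energy is non-increasing at every asynchronous update", {
  set.seed(77)
  pats <- random_patterns(c("a", "b", "c"), 64)
  W <- store_patterns(pats)
  for (trial in 1:20) {
    st <- core_state(64)
    st$s <- sample(c(-1, 1), 64, replace = TRUE)
    res <- settle(st, W, record_energy = TRUE)
    expect_true(res$converged)
    expect_true(all(diff(res$energy) <= 1e-12))
  }
})

test_that("partial cues of at least 60% complete every letter exactly", {
  letters3 <- make_letter_patterns()
  W <- store_patterns(letters3)
  for (p in letters3) {
    for (frac in c(0.6, 0.8)) {
      cue <- partial_cue(p, frac)
      st <- core_state(25)
      st$s <- cue
      res <- settle(st, W, external = cue, g_bu = 1)
      expect_equal(overlap(res$state, p), 1,
                   info = paste(p$label, frac))
    }
  }
})

test_that("stochastic unit rule is unbiased at vanishing gain", {
  set.seed(3)
  params <- core_params(beta = 1e-12, update = "synchronous")
  st <- core_state(400)
  st$s <- rep(-1, 400)
  h <- rep(5, 400)  # strong field, but gain ~ 0 => coin flips
  st <- core_step(st, h, params)
  expect_gt(mean(st$s > 0), 0.4)
  expect_lt(mean(st$s > 0), 0.6)
})

test_that("asynchronous deterministic step keeps a fixed point and ties keep state", {
  p <- fix_single()
  W <- store_patterns(list(p))
  st <- core_state(4)
  st$s <- p$values
  set.seed(1)
  for (i in 1:20) st <- core_step(st, net_input(st, W), core_params())
  expect_equal(st$s, p$values)
  # zero field: sign tie keeps the previous activation
  st2 <- core_state(3)
  st2$s <- c(1, -1, 0)
  st2 <- core_step(st2, numeric(3), core_params(update = "synchronous"))
  expect_equal(st2$s, c(1, -1, 0))
})

test_that("identical seeds give bit-identical noisy trajectories", {
  pats <- make_semantic_triplet()
  run <- function() {
    sys <- memory_system(pats, place_codes(c("A", "B", "C"), 8),
                         what_params = core_params(U = 0.1, tau_rec = 40),
                         meta = meta_params(sigma = 0.3, beta = 3))
    sys$what$state$s <- pats[[1]]$values
    set.seed(123)
    free_run(sys, 50)$trace
  }
  expect_identical(run(), run())
})
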