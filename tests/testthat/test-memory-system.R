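test_that("comparator flags sign disagreements over the mask", {
  v <- c(1, -1, 1, -1)
  expect_equal(compare(v, v)$total, 0)
  expect_equal(compare(-v, v)$total, 1)
  expect_equal(compare(-v, v)$per_feature, rep(1L, 4))
  # masked comparison: only attended features count
  r <- compare(c(1, 1, 1, 1), v, mask = c(1, 2))
  expect_equal(r$total, 0.5)
  expect_equal(r$per_feature, c(0L, 1L, 0L, 0L))
  # neutral components (empty state) are not mismatches
  expect_equal(compare(v, numeric(4))$total, 0)
  expect_error(compare(v, v, mask = logical(4)), "nonempty")
  expect_error(compare(c(1, -1), v), "length")
  # symmetry in the two vector arguments
  set.seed(8)
  a <- sample(c(-1, 1), 16, TRUE); b <- sample(c(-1, 1), 16, TRUE)
  expect_equal(compare(a, b)$total, compare(b, a)$total)
})

test_that("winner-take-all leaves at most one active place", {
  expect_equal(wta(c(0.2, 0.9, 0.1)), c(-1, 1, -1))
  expect_equal(wta(c(0.5, 0.5)), c(1, -1))      # tie -> lowest index
  expect_equal(wta(c(-0.3, -0.3, -0.3)), c(-1, -1, -1))  # none-code
  expect_true(is_none_code(wta(c(-1, 0))))
  expect_error(wta(numeric(0)), "place")
  set.seed(2)
  for (i in 1:20) {
    code <- wta(rnorm(6))
    expect_lte(sum(code > 0), 1)
  }
})

test_that("binding learning touches only the active place and accumulates", {
  tri <- make_semantic_triplet()
  sys <- memory_system(tri, place_codes(c("A", "B", "C"), 8))
  x <- tri[[1]]$values
  sys1 <- learn_binding(sys, x, sys$where$codes["A", ])
  expect_equal(sys1$bind$B_wp[1, ], 0.1 * x)
  expect_equal(sys1$bind$B_wp[2, ], rep(0, 64))
  expect_equal(sys1$bind$B_pw[, 1], 0.1 * x)
  # driving WHERE with the settled object activates the bound place
  expect_equal(which.max(sys1$bind$B_wp %*% x), 1)
  # none-code: no update
  sys2 <- learn_binding(sys, x, rep(-1, 8))
  expect_equal(sys2$bind$B_wp, sys$bind$B_wp)
  # 3 vs 1 presentations: row A carries 3x the X-projection of row B
  sys3 <- sys
  for (i in 1:3) sys3 <- learn_binding(sys3, x, sys$where$codes["A", ])
  sys3 <- learn_binding(sys3, x, sys$where$codes["B", ])
  proj <- as.vector(sys3$bind$B_wp %*% x)
  expect_equal(proj[1], 3 * proj[2])
})

test_that("working-memory recruitment decays others and never duplicates", {
  tri <- make_semantic_triplet()
  sys <- memory_system(tri, place_codes(c("A", "B", "C"), 8))
  sys <- perceive(sys, tri[[1]], "A")
  expect_length(sys$wm$nodes, 1)
  expect_equal(sys$wm$nodes[[1]]$a, 1)
  sys <- perceive(sys, tri[[2]], "B")
  acts <- vapply(sys$wm$nodes, `[[`, numeric(1), "a")
  expect_equal(acts, c(0.9, 1))
  # re-perceiving X@A re-activates the existing node, no duplicate
  sys <- perceive(sys, tri[[1]], "A")
  expect_length(sys$wm$nodes, 2)
  acts <- vapply(sys$wm$nodes, `[[`, numeric(1), "a")
  expect_equal(acts[1], 1)
  expect_equal(acts[2], 0.9)
})

test_that("recency gradient is strict after a no-repeat perception sequence", {
  set.seed(31)
  pats <- random_patterns(paste0("p", 1:6), 64)
  sys <- memory_system(pats, place_codes(paste0("L", 1:6), 6))
  for (i in 1:6) sys <- perceive(sys, pats[[i]], paste0("L", i))
  acts <- vapply(sys$wm$nodes, `[[`, numeric(1), "a")
  expect_length(acts, 6)
  expect_true(all(diff(acts) > 0))  # strictly increasing with recency
  expect_equal(acts, 0.9^(5:0))
})

test_that("capacity overflow evicts the least active node", {
  set.seed(17)
  pats <- random_patterns(paste0("p", 1:5), 64)
  sys <- memory_system(pats, place_codes(paste0("L", 1:5), 5),
                       wm_capacity = 3)
  for (i in 1:5) sys <- perceive(sys, pats[[i]], paste0("L", i))
  expect_length(sys$wm$nodes, 3)
  labs <- vapply(sys$wm$nodes, function(nd)
    nearest_attractor(nd$what, pats), character(1))
  expect_equal(labs, c("p3", "p4", "p5"))
})

test_that("wm selection multiplies similarity and activity, ties to recency", {
  tri <- make_semantic_triplet()
  sys <- memory_system(tri, place_codes(c("A", "B", "C"), 8))
  expect_null(wm_select(sys, cue_what = tri[[1]]$values))  # empty store
  sys <- perceive(sys, tri[[1]], "A")
  sys <- perceive(sys, tri[[2]], "B")
  # full X cue: the older X@A node wins on similarity despite lower activity
  nd <- wm_select(sys, cue_what = tri[[1]]$values)
  expect_equal(nearest_attractor(nd$what, tri), "X")
  # ambiguous shared-feature cue: equal similarity, recency wins -> Y@B
  nd2 <- wm_select(sys, cue_what = shared_cue(tri[[1]], tri[[2]]))
  expect_equal(nearest_attractor(nd2$what, tri), "Y")
  # A-not-B store: X@A, X@A, then X@B; X cue picks the recent X@B
  sys2 <- memory_system(tri, place_codes(c("A", "B", "C"), 8))
  sys2 <- perceive(sys2, tri[[1]], "A")
  sys2 <- perceive(sys2, tri[[1]], "A")
  sys2 <- perceive(sys2, tri[[1]], "B")
  nd3 <- wm_select(sys2, cue_what = tri[[1]]$values)
  expect_equal(which(nd3$where > 0), 2)  # place B
})

test_that("wm drive excites snapshot-active and inhibits inactive units", {
  node <- structure(list(a = 0.5, what = c(1, -1, 1), where = c(1, -1),
                         recruited_at = 1), class = "wm_node")
  drv <- wm_drive(node, G = 4)
  expect_equal(drv$what, c(2, -2, 2))
  expect_equal(drv$where, c(2, -2))
  expect_equal(wm_drive(node, G = 0)$what, c(0, 0, 0))
  node$a <- 0
  expect_equal(wm_drive(node, G = 4)$what, c(0, 0, 0))
  drv0 <- wm_drive(NULL, G = 4, n_what = 3, n_place = 2)
  expect_equal(drv0$what, numeric(3))
})

test_that("predictive map learns adjacent transitions only, with delay readout", {
  pm <- predictive_map(delay = 4)
  v <- function(i) { x <- rep(-1, 8); x[i] <- 1; x }
  pm <- learn_transition(pm, "X", "Y", v(1), v(2))
  pm <- learn_transition(pm, "Y", "Z", v(2), v(3))
  expect_equal(pm$S["X", "Y"], 1)
  expect_equal(pm$S["Y", "Z"], 1)
  expect_equal(pm$S["X", "Z"], 0)  # adjacency only, no skip association
  # gaps learn nothing
  pm2 <- learn_transition(pm, NA_character_, "X")
  expect_identical(pm2$S, pm$S)
  # re-experience strengthens monotonically
  pm3 <- learn_transition(pm, "X", "Y", v(1), v(2))
  expect_equal(pm3$S["X", "Y"], 2)
  # delayed readout: zero before the residence delay, successor after
  expect_equal(predictive_drive(pm, "X", 3, 8), numeric(8))
  expect_equal(predictive_drive(pm, "X", 4, 8), v(2))
  expect_equal(predictive_drive(pm, "Z", 10, 8), numeric(8))  # chain end
  expect_equal(predictive_drive(pm, NA_character_, 10, 8), numeric(8))
})

test_that("perception learns two disjoint chains across an episode break", {
  pats <- make_pairwise_patterns(c("X", "Y", "Z", "P", "Q", "R"), 4)
  sys <- memory_system(pats, place_codes(c("A", "B"), 4))
  sys <- train_episode(sys, c("X", "Y", "Z"))
  sys <- train_episode(sys, c("P", "Q", "R"))
  S <- sys$pmap$S
  expect_equal(S["X", "Y"], 1)
  expect_equal(S["Y", "Z"], 1)
  expect_equal(S["P", "Q"], 1)
  expect_equal(S["Q", "R"], 1)
  expect_equal(S["Z", "P"], 0)  # no association across the episode break
  expect_equal(sum(S), 4)
})

test_that("mismatch reset clears activations, keeps resources and memory, idempotent", {
  sys <- fix_trained_triplet()
  sys$what$state$r <- rep(0.5, 64)
  n_nodes <- length(sys$wm$nodes)
  rep_hi <- compare(-sys$what$state$s, sys$what$state$s)
  sys1 <- reset_if_surprised(sys, rep_hi)
  expect_equal(sys1$what$state$s, numeric(64))
  expect_equal(sys1$what$state$r, rep(0.5, 64))     # resources kept
  expect_length(sys1$wm$nodes, n_nodes)             # working memory kept
  expect_true(is_none_code(sys1$where$state))
  sys2 <- reset_if_surprised(sys1, compare(rep(1, 64), sys1$what$state$s))
  expect_identical(sys2$what$state, sys1$what$state) # second reset is a no-op
  # below threshold: unchanged
  sys3 <- reset_if_surprised(sys, structure(list(total = 0,
                                                 per_feature = integer(64)),
                                            class = "surprise_report"))
  expect_identical(sys3$what$state$s, sys$what$state$s)
})

test_that("perceiving the expected stimulus yields zero surprise, a novel one resets", {
  tri <- make_semantic_triplet()
  sys <- memory_system(tri, place_codes(c("A", "B", "C"), 8))
  sys <- perceive(sys, tri[[1]], "A")
  expect_equal(sys$percepts$surprise[1], 0)  # first stimulus vs empty state
  sys <- perceive(sys, tri[[1]], "A")
  expect_equal(sys$percepts$surprise[2], 0)  # expectation met
  sys <- perceive(sys, -tri[[1]]$values, NULL)
  expect_equal(sys$percepts$surprise[3], 1)  # full mismatch, reset fired
})

test_that("post-reset settling on a novel stimulus is at least as fast", {
  tri <- make_semantic_triplet()
  W <- store_patterns(tri)
  z <- tri[[3]]$values
  from_old <- core_state(64)
  from_old$s <- tri[[1]]$values
  res_old <- settle(from_old, W, external = z, g_bu = 2)
  res_new <- settle(core_state(64), W, external = z, g_bu = 2)
  expect_equal(overlap(res_new$state, tri[[3]]), 1)
  expect_lte(res_new$sweeps, res_old$sweeps)
})

test_that("trained system recalls places from objects and objects from places", {
  sys <- fix_trained_triplet()
  tri <- sys$what$patterns
  for (i in 1:3) {
    rp <- recall_place(sys, tri[[i]])
    expect_equal(rp$place, c("A", "B", "C")[i])
    ro <- recall_object(sys, c("A", "B", "C")[i])
    expect_equal(ro$object, c("X", "Y", "Z")[i])
    expect_equal(ro$overlap, 1)
  }
  # untrained system returns the none-code
  fresh <- memory_system(tri, place_codes(c("A", "B", "C"), 8),
                         meta = meta_params(wm_gain = 0))
  rp0 <- recall_place(fresh, tri[[1]])
  expect_true(is.na(rp0$place))
  expect_true(is_none_code(rp0$code))
  ro0 <- recall_object(fresh, rep(-1, 8))
  expect_true(is.na(ro0$object))
})

test_that("the ambiguous shared cue recalls the more recent object's place", {
  sys <- fix_trained_triplet()
  tri <- sys$what$patterns
  amb <- shared_cue(tri[[1]], tri[[2]])
  expect_equal(recall_place(sys, amb)$place, "B")
  # and the identification network restores the full recent pattern
  rp <- recall_place(sys, amb)
  expect_equal(overlap(rp$what_state, tri[[2]]), 1)
})

test_that("the same store answers A at zero gain and B at high gain", {
  tri <- make_semantic_triplet()
  for (seed in 1:20) {
    set.seed(seed)
    sys <- memory_system(tri, place_codes(c("A", "B", "C"), 8))
    for (i in 1:4) sys <- perceive(sys, tri[[1]], "A")
    sys <- perceive(sys, tri[[1]], "B")
    expect_equal(recall_place(sys, tri[[1]], wm_gain = 0)$place, "A")
    expect_equal(recall_place(sys, tri[[1]], wm_gain = 20)$place, "B")
  }
})

test_that("a strong working memory overrides a 3:1 long-term binding bias", {
  tri <- make_semantic_triplet()
  sys <- memory_system(tri, place_codes(c("A", "B", "C"), 8))
  for (i in 1:3) sys <- perceive(sys, tri[[1]], "A")
  sys <- perceive(sys, tri[[1]], "B")
  # binding margin toward A is (3-1)*eta*N = 12.8; G beyond it flips to B
  expect_equal(recall_place(sys, tri[[1]], wm_gain = 0)$place, "A")
  expect_equal(recall_place(sys, tri[[1]], wm_gain = 20)$place, "B")
})

test_that("free run without destabilizing forces stays in the cued attractor", {
  tri <- make_semantic_triplet()
  sys <- memory_system(tri, place_codes(c("A", "B", "C"), 8),
                       what_params = core_params(U = 0),
                       meta = meta_params(sigma = 0, g_td = 0))
  sys$what$state$s <- tri[[2]]$values
  set.seed(4)
  fr <- free_run(sys, 40)
  expect_true(all(fr$trace$label == "Y"))
  expect_true(all(fr$trace$overlap == 1))
})

test_that("object-place co-activation recalls pairs past WHAT-alone capacity", {
  set.seed(11)
  k <- 20
  pats <- random_patterns(paste0("p", 1:k), 64)
  places <- place_codes(paste0("L", 1:k), k)
  sys <- memory_system(pats, places, eta = 0.3,
                       meta = meta_params(wm_gain = 0))
  for (i in 1:k) sys <- perceive(sys, pats[[i]], paste0("L", i))
  what_ok <- 0; joint_ok <- 0
  for (i in 1:k) {
    cue <- partial_cue(pats[[i]], 0.6)
    st <- core_state(64); st$s <- cue
    res <- settle(st, sys$what$W, external = cue, g_bu = 1)
    if (isTRUE(all.equal(overlap(res$state, pats[[i]]), 1))) {
      what_ok <- what_ok + 1
    }
    ro <- recall_object(sys, paste0("L", i), wm_gain = 0)
    if (identical(ro$object, pats[[i]]$label)) joint_ok <- joint_ok + 1
  }
  expect_lt(what_ok, k)        # WHAT alone degrades at this load
  expect_gt(joint_ok, what_ok) # the joint system holds more pairs
})
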