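#' Default configuration for a simulation task
#'
#' Every task runner takes a validated configuration with a mandatory
#' seed. The defaults below are the package's standard study conditions;
#' the noise and depression settings of the wandering and replay tasks
#' were calibrated once (see the methods vignette) and are part of the
#' task definition, not free knobs of the runners.
#'
#' @param task Task name, one of `"pattern_completion"`,
#'   `"place_recall"`, `"object_recall"`, `"a_not_b"`, `"dmts"`,
#'   `"semantic_wandering"`, `"episodic_recall"`, `"vte"`.
#' @return Named list of defaults (without a seed).
#' @export
default_task_config <- function(task) {
  recall_shared <- list(
    n_features = 64, n_active = 20, n_shared = 8, n_place = 8,
    train = list(c("X", "A"), c("Y", "B"), c("Z", "C")),
    eta = 0.1, wm_gain = 20
  )
  switch(task,
    pattern_completion = list(cue_label = "L", cue_fraction = 0.5),
    place_recall = recall_shared,
    object_recall = recall_shared,
    a_not_b = list(n_features = 64, n_active = 20, n_shared = 8,
                   n_place = 8, k_A = 4, wm_gains = c(0, 20), eta = 0.1),
    dmts = list(n_features = 64, n_active = 20, n_shared = 8, n_place = 8,
                sample = "X", delay_steps = 10,
                comparisons = c("X", "Y")),
    semantic_wandering = list(
      n_features = 64, n_active = 20, n_shared = 8, tau_rec = 40,
      beta = 3, min_events = 200,
      conditions = list(
        low = list(sigma = 0.2, U = 0.10, n_steps = 4500),
        high = list(sigma = 0.48, U = 0, n_steps = 7000),
        no_noise = list(sigma = 0, U = 0.05, n_steps = 2000)
      )
    ),
    episodic_recall = list(
      chains = list(c("X", "Y", "Z"), c("P", "Q", "R")),
      pair_block = 4, g_td = 2.5, delay = 5,
      noise = c(0, 0.45), n_runs = 500, n_steps = 250
    ),
    vte = list(
      chains = list(c("A", "B", "C"), c("X", "Y", "Z", "G")),
      pair_block = 3, g_td = 2.5, delay = 5, goal = "G", n_steps = 150
    ),
    stop(sprintf("unknown task '%s'", task))
  )
}

#' All task names
#' @return Character vector of the task names known to [run_task()].
#' @export
task_names <- function() {
  c("pattern_completion", "place_recall", "object_recall", "a_not_b",
    "dmts", "semantic_wandering", "episodic_recall", "vte")
}

#' Build a validated task configuration
#'
#' Fills defaults from [default_task_config()], overrides them with
#' `...`, and validates; unknown fields are rejected.
#'
#' @param task Task name.
#' @param seed Integer seed (mandatory; every runner is deterministic
#'   given the configuration and seed).
#' @param ... Field overrides.
#' @return List of class `"task_config"`.
#' @export
task_config <- function(task, seed, ...) {
  if (missing(seed) || is.null(seed)) stop("'seed' is mandatory")
  seed <- as.integer(seed)
  if (is.na(seed)) stop("'seed' must be an integer")
  cfg <- default_task_config(task)
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) {
    stop(sprintf("unknown config field(s) for task '%s': %s",
                 task, paste(bad, collapse = ", ")))
  }
  cfg[names(dots)] <- dots
  validate_task_config(task, cfg)
  structure(c(list(task = task, seed = seed), cfg),
            class = "task_config")
}

validate_task_config <- function(task, cfg) {
  chk_pos <- function(field, strict = FALSE) {
    v <- cfg[[field]]
    if (is.null(v)) return(invisible())
    if (!is.numeric(v) || any(v < 0) || (strict && any(v <= 0))) {
      stop(sprintf("config field '%s' must be %s", field,
                   if (strict) "positive" else "nonnegative"))
    }
  }
  for (f in intersect(names(cfg),
                      c("n_features", "n_active", "n_place", "k_A",
                        "delay_steps", "n_runs", "n_steps", "tau_rec",
                        "pair_block", "delay"))) {
    chk_pos(f, strict = TRUE)
  }
  for (f in intersect(names(cfg), c("noise", "eta", "wm_gain",
                                    "wm_gains", "g_td", "n_shared"))) {
    chk_pos(f)
  }
  if (!is.null(cfg$conditions)) {
    for (nm in names(cfg$conditions)) {
      cond <- cfg$conditions[[nm]]
      if (!is.null(cond$sigma) && cond$sigma < 0) {
        stop(sprintf("config field 'noise' (conditions$%s$sigma) must be nonnegative", nm))
      }
      if (!is.null(cond$U) && (cond$U < 0 || cond$U > 1)) {
        stop(sprintf("config field 'conditions$%s$U' must be in [0, 1]", nm))
      }
    }
  }
  invisible(cfg)
}

new_task_result <- function(task, config, verdicts, traces = list(),
                            summary = list()) {
  structure(list(task = task, config = config,
                 verdicts = unlist(verdicts), traces = traces,
                 summary = summary),
            class = "task_result")
}

#' @export
print.task_result <- function(x, ...) {
  cat(sprintf("<task_result '%s': %d/%d checks passed>\n", x$task,
              sum(x$verdicts), length(x$verdicts)))
  for (nm in names(x$verdicts)) {
    cat(sprintf("  [%s] %s\n", if (x$verdicts[[nm]]) "ok" else "FAIL", nm))
  }
  invisible(x)
}

#' Did every check of a task result pass?
#' @param result A `task_result`.
#' @return Logical scalar.
#' @export
task_passed <- function(result) all(result$verdicts)

# Shared builder: triplet-based system for the recall-style tasks.
triplet_system <- function(cfg, wm_gain = cfg$wm_gain %||% 20) {
  tri <- make_semantic_triplet(cfg$n_features, cfg$n_active, cfg$n_shared)
  places <- place_codes(c("A", "B", "C"), cfg$n_place)
  memory_system(tri, places, rule = "hebbian",
                what_params = core_params(),
                eta = cfg$eta %||% 0.1,
                meta = meta_params(wm_gain = wm_gain))
}

#' Train a system on one episode of stimuli
#'
#' Perceives the stimuli in order (each at its place, if given) through
#' the full perception pipeline, then closes the episode so that no
#' predictive association is learned across episode boundaries.
#'
#' @param system A [memory_system()].
#' @param labels Character vector of stored-pattern labels, in episode
#'   order.
#' @param places Optional character vector of place labels (recycled if
#'   length 1), or NULL for no attended place.
#' @return Updated system.
#' @export
train_episode <- function(system, labels, places = NULL) {
  P <- pattern_matrix(system$what$patterns)
  if (!is.null(places) && length(places) == 1L) {
    places <- rep(places, length(labels))
  }
  for (i in seq_along(labels)) {
    system <- perceive(system, as.numeric(P[labels[i], ]),
                       if (is.null(places)) NULL else places[i])
  }
  system$last_label <- NA_character_
  system
}

# ---- runners --------------------------------------------------------------

#' Pattern completion from a partial letter cue
#'
#' Stores the three letter bitmaps, clamps part of one letter as a cue
#' (unknown cells neutral) and settles. Checks that the full pattern is
#' recovered exactly and that the energy decreases monotonically while
#' it is.
#'
#' @param cfg A `task_config` for `"pattern_completion"`.
#' @return A `task_result`.
#' @export
run_pattern_completion <- function(cfg) {
  set.seed(cfg$seed)
  letters3 <- make_letter_patterns()
  W <- store_patterns(letters3, "hebbian")
  target <- Filter(function(p) p$label == cfg$cue_label, letters3)[[1]]
  cue <- partial_cue(target, cfg$cue_fraction)
  st <- core_state(target$N)
  st$s <- cue
  res <- settle(st, W, external = cue, g_bu = 1, record_energy = TRUE)
  final_overlap <- overlap(res$state, target)
  en <- res$energy
  verdicts <- list(
    completed = isTRUE(all.equal(final_overlap, 1)),
    energy_monotone = all(diff(en) <= 1e-12),
    energy_decreased = en[length(en)] < en[1],
    converged = res$converged
  )
  trace <- data.frame(step = seq_along(en) - 1L, energy = en)
  new_task_result("pattern_completion", cfg, verdicts,
                  traces = list(settle = trace),
                  summary = list(final_overlap = final_overlap,
                                 sweeps = res$sweeps,
                                 energy_drop = en[1] - en[length(en)]))
}

#' Place recall after object-place training
#'
#' Trains the system on the object-place pairs of `cfg$train` (one
#' perception each, in order), then cues the WHAT network with each
#' object and with the ambiguous shared-feature cue of the first two
#' objects. The ambiguous cue must recall the place of the more
#' recently seen object.
#'
#' @param cfg A `task_config` for `"place_recall"`.
#' @return A `task_result`.
#' @export
run_place_recall <- function(cfg) {
  set.seed(cfg$seed)
  sys <- triplet_system(cfg)
  objs <- vapply(cfg$train, `[[`, character(1), 1)
  plcs <- vapply(cfg$train, `[[`, character(1), 2)
  sys <- train_episode(sys, objs, plcs)
  pats <- sys$what$patterns
  pat_of <- function(lb) Filter(function(p) p$label == lb, pats)[[1]]
  verdicts <- list()
  answers <- character(0)
  for (i in seq_along(objs)) {
    rp <- recall_place(sys, pat_of(objs[i]))
    answers[objs[i]] <- rp$place %||% NA_character_
    verdicts[[paste0("cue_", objs[i])]] <-
      identical(rp$place, plcs[i])
  }
  # ambiguous cue: the features shared by the triplet's X and Y (the two
  # objects with overlapping feature sets); recency should pick the
  # place of whichever of the pair was trained later
  pair <- intersect(c("X", "Y"), objs)
  amb <- shared_cue(pat_of(pair[1]), pat_of(pair[2]))
  recent <- pair[which.max(match(pair, objs))]
  rp <- recall_place(sys, amb)
  answers["ambiguous"] <- rp$place %||% NA_character_
  verdicts$ambiguous_recent <-
    identical(rp$place, plcs[match(recent, objs)])
  new_task_result("place_recall", cfg, verdicts,
                  summary = list(answers = answers))
}

#' Object recall from place cues
#'
#' Same training as [run_place_recall()]; cues each place and checks the
#' bound object is recalled with full overlap.
#'
#' @param cfg A `task_config` for `"object_recall"`.
#' @return A `task_result`.
#' @export
run_object_recall <- function(cfg) {
  set.seed(cfg$seed)
  sys <- triplet_system(cfg)
  objs <- vapply(cfg$train, `[[`, character(1), 1)
  plcs <- vapply(cfg$train, `[[`, character(1), 2)
  sys <- train_episode(sys, objs, plcs)
  verdicts <- list()
  answers <- character(0)
  overlaps <- numeric(0)
  for (i in seq_along(plcs)) {
    ro <- recall_object(sys, plcs[i])
    answers[plcs[i]] <- ro$object %||% NA_character_
    overlaps[plcs[i]] <- ro$overlap
    verdicts[[paste0("cue_", plcs[i])]] <-
      identical(ro$object, objs[i]) && isTRUE(all.equal(ro$overlap, 1))
  }
  new_task_result("object_recall", cfg, verdicts,
                  summary = list(answers = answers, overlaps = overlaps))
}

#' The A-not-B task across working-memory gains
#'
#' Shows object X at place A `k_A` times, then once at place B, and asks
#' "where is X?" at each working-memory output gain in `cfg$wm_gains`.
#' With the gain at zero the stronger long-term binding wins (the
#' perseverative A answer); with a developed working memory the most
#' recent location B wins.
#'
#' @param cfg A `task_config` for `"a_not_b"`.
#' @return A `task_result`; `summary$answers` maps each gain to its
#'   answer.
#' @export
run_a_not_b <- function(cfg) {
  set.seed(cfg$seed)
  sys <- triplet_system(cfg)
  x <- sys$what$patterns[[1]]
  for (i in seq_len(cfg$k_A)) sys <- perceive(sys, x, "A")
  sys <- perceive(sys, x, "B")
  answers <- character(0)
  for (g in cfg$wm_gains) {
    rp <- recall_place(sys, x, wm_gain = g)
    answers[as.character(g)] <- rp$place %||% NA_character_
  }
  lo <- as.character(min(cfg$wm_gains))
  hi <- as.character(max(cfg$wm_gains))
  verdicts <- list(
    low_gain_perseverates = identical(answers[[lo]], "A"),
    high_gain_updates = identical(answers[[hi]], "B")
  )
  new_task_result("a_not_b", cfg, verdicts,
                  summary = list(answers = answers, k_A = cfg$k_A))
}

#' Delayed matching to sample
#'
#' Perceives the sample stimulus, waits `delay_steps` of free running
#' with no input, then reads the remembered stimulus out of working
#' memory and compares each comparison stimulus against it. The match
#' must produce zero surprise; a non-match produces surprise confined to
#' the features the two stimuli do not share. The decision itself
#' (pick the least-surprising option) is reported as data, not acted on.
#'
#' @param cfg A `task_config` for `"dmts"`.
#' @return A `task_result`; `summary$surprise` maps comparison labels to
#'   comparator totals.
#' @export
run_dmts <- function(cfg) {
  set.seed(cfg$seed)
  sys <- triplet_system(cfg)
  pats <- sys$what$patterns
  pat_of <- function(lb) Filter(function(p) p$label == lb, pats)[[1]]
  sample_p <- pat_of(cfg$sample)
  sys <- perceive(sys, sample_p, NULL)
  if (cfg$delay_steps > 0) {
    fr <- free_run(sys, cfg$delay_steps)
    sys <- fr$system
  }
  # working-memory readout of the remembered sample
  acts <- vapply(sys$wm$nodes, `[[`, numeric(1), "a")
  recalled <- sys$wm$nodes[[which.max(acts)]]$what
  totals <- numeric(0)
  reports <- list()
  for (lb in cfg$comparisons) {
    rep_i <- compare(pat_of(lb)$values, recalled)
    totals[lb] <- rep_i$total
    reports[[lb]] <- rep_i
  }
  match_lb <- cfg$sample
  non_match <- setdiff(cfg$comparisons, match_lb)
  flags_ok <- TRUE
  for (lb in non_match) {
    shared <- pat_of(lb)$values > 0 & sample_p$values > 0
    agree_off <- pat_of(lb)$values < 0 & sample_p$values < 0
    if (any(reports[[lb]]$per_feature[shared | agree_off] != 0)) {
      flags_ok <- FALSE
    }
  }
  verdicts <- list(
    match_no_surprise = isTRUE(totals[[match_lb]] == 0),
    nonmatch_surprises = all(totals[non_match] > 0),
    flags_on_nonshared_only = flags_ok
  )
  new_task_result("dmts", cfg, verdicts,
                  summary = list(surprise = totals,
                                 least_surprise = names(which.min(totals))))
}

#' Semantic mind-wandering over the feature-overlap triplet
#'
#' Free-runs the triplet-trained WHAT network (no predictive map) under
#' each named condition, logs attractor events, and summarizes the
#' transition structure. At low noise the state moves only between
#' feature-sharing attractors (X-Y, Y-Z, returns) and never hops
#' directly between the unrelated X and Z; at high noise it can; with
#' depression and no input noise it leaves and falls back to the same
#' attractor.
#'
#' @param cfg A `task_config` for `"semantic_wandering"`.
#' @return A `task_result` with per-condition event logs and transition
#'   matrices.
#' @export
run_semantic_wandering <- function(cfg) {
  tri <- make_semantic_triplet(cfg$n_features, cfg$n_active, cfg$n_shared)
  places <- place_codes(c("A", "B", "C"), 8)
  out_events <- list()
  out_trans <- list()
  verdicts <- list()
  for (nm in names(cfg$conditions)) {
    cond <- cfg$conditions[[nm]]
    sys <- memory_system(tri, places, rule = "hebbian",
                         what_params = core_params(U = cond$U,
                                                   tau_rec = cfg$tau_rec),
                         meta = meta_params(g_td = 0, sigma = cond$sigma,
                                            beta = cfg$beta))
    sys$what$state$s <- tri[[1]]$values
    set.seed(cfg$seed + match(nm, names(cfg$conditions)))
    fr <- free_run(sys, cond$n_steps)
    ev <- event_log(fr$trace)
    out_events[[nm]] <- ev
    out_trans[[nm]] <- transition_counts(ev, labels = c("X", "Y", "Z"))
  }
  xz <- function(M) M["X", "Z"] + M["Z", "X"]
  verdicts$low_noise_enough_events <-
    nrow(out_events$low) >= cfg$min_events
  verdicts$low_noise_no_unrelated <- xz(out_trans$low) == 0
  verdicts$high_noise_unrelated <- xz(out_trans$high) >= 1
  verdicts$no_noise_returns <-
    isTRUE(return_fraction(out_events$no_noise) > 0.8)
  new_task_result("semantic_wandering", cfg, verdicts,
                  traces = list(events = out_events),
                  summary = list(transitions = out_trans,
                                 n_events = vapply(out_events, nrow,
                                                   integer(1)),
                                 return_fraction =
                                   return_fraction(out_events$no_noise)))
}

# Build the chain-trained system for replay tasks.
chain_system <- function(labels, chains, pair_block, g_td, delay,
                         sigma = 0, U = 0, tau_rec = 40) {
  pats <- make_pairwise_patterns(labels, pair_block)
  places <- place_codes(c("A", "B"), 4)
  sys <- memory_system(pats, places, rule = "hebbian",
                       what_params = core_params(U = U, tau_rec = tau_rec),
                       pmap_delay = delay,
                       meta = meta_params(g_td = g_td, sigma = sigma))
  for (ch in chains) sys <- train_episode(sys, ch)
  sys
}

# Cue the trained system and free-run; returns the visited sequence.
replay_once <- function(sys, cue_label, n_steps, sigma) {
  P <- pattern_matrix(sys$what$patterns)
  sys$what$state$s <- as.numeric(P[cue_label, ])
  sys$what$state$r <- rep(1, ncol(P))
  meta <- sys$meta
  meta$sigma <- sigma
  fr <- free_run(sys, n_steps, meta = meta)
  list(seq = event_sequence(event_log(fr$trace)), trace = fr$trace)
}

#' Episodic recall and reverie blending
#'
#' Trains the two episode chains through perception, then cues each
#' chain head and free-runs. With no noise the delayed predictive
#' associations replay each chain exactly. At the calibrated elevated
#' noise the run is repeated `n_runs` times: occasionally the state,
#' having reached the end of the first chain, is captured by the middle
#' of the other chain and the replay continues there -- a novel sequence
#' blending the two episodes (X,Y,Z,Q,R).
#'
#' @param cfg A `task_config` for `"episodic_recall"`.
#' @return A `task_result`; `summary$crossovers` counts blended runs.
#' @export
run_episodic_recall <- function(cfg) {
  labels <- unique(unlist(cfg$chains))
  sys <- chain_system(labels, cfg$chains, cfg$pair_block, cfg$g_td,
                      cfg$delay)
  sigma0 <- min(cfg$noise)
  sigma_hi <- max(cfg$noise)
  verdicts <- list()
  traces <- list()
  for (ch in cfg$chains) {
    set.seed(cfg$seed)
    rp <- replay_once(sys, ch[1], cfg$n_steps, sigma0)
    traces[[paste0("replay_", ch[1])]] <- rp$trace
    verdicts[[paste0("exact_replay_", ch[1])]] <-
      identical(rp$seq, ch)
  }
  crossover_target <- c(cfg$chains[[1]],
                        cfg$chains[[2]][-1])  # X Y Z Q R
  hits <- 0L
  example <- NULL
  for (i in seq_len(cfg$n_runs)) {
    set.seed(cfg$seed + i)
    rp <- replay_once(sys, cfg$chains[[1]][1], cfg$n_steps, sigma_hi)
    if (length(rp$seq) >= length(crossover_target) &&
        grepl(paste(crossover_target, collapse = ""),
              paste(rp$seq, collapse = ""), fixed = TRUE)) {
      hits <- hits + 1L
      if (is.null(example)) example <- rp$seq
    }
  }
  verdicts$crossover_observed <- hits >= 1L
  new_task_result("episodic_recall", cfg, verdicts, traces = traces,
                  summary = list(crossovers = hits, n_runs = cfg$n_runs,
                                 crossover_rate = hits / cfg$n_runs,
                                 example_crossover = example))
}

#' Vicarious trial and error at a choice point
#'
#' Trains a dead-end route (A,B,C) and a goal route (X,Y,Z,G) as
#' episodes, then cues each route's first place and lets the memory
#' replay the expected outcome with no noise. Looking toward the dead
#' end replays A,B,C without ever reaching the goal; looking toward the
#' goal route replays a sequence ending in G.
#'
#' @param cfg A `task_config` for `"vte"`.
#' @return A `task_result`; `summary$replays` holds both sequences.
#' @export
run_vte <- function(cfg) {
  labels <- unique(unlist(cfg$chains))
  sys <- chain_system(labels, cfg$chains, cfg$pair_block, cfg$g_td,
                      cfg$delay)
  replays <- list()
  for (ch in cfg$chains) {
    set.seed(cfg$seed)
    rp <- replay_once(sys, ch[1], cfg$n_steps, 0)
    replays[[ch[1]]] <- rp$seq
  }
  dead <- cfg$chains[[1]]
  goal_chain <- cfg$chains[[2]]
  verdicts <- list(
    dead_end_replayed = identical(replays[[dead[1]]], dead),
    dead_end_avoids_goal = !(cfg$goal %in% replays[[dead[1]]]),
    goal_route_reaches_goal =
      length(replays[[goal_chain[1]]]) > 0 &&
      replays[[goal_chain[1]]][length(replays[[goal_chain[1]]])] == cfg$goal
  )
  new_task_result("vte", cfg, verdicts,
                  summary = list(replays = replays))
}

#' Run a task by name
#'
#' @param cfg A `task_config`.
#' @return The task's `task_result`.
#' @export
run_task <- function(cfg) {
  stopifnot(inherits(cfg, "task_config"))
  runner <- switch(cfg$task,
    pattern_completion = run_pattern_completion,
    place_recall = run_place_recall,
    object_recall = run_object_recall,
    a_not_b = run_a_not_b,
    dmts = run_dmts,
    semantic_wandering = run_semantic_wandering,
    episodic_recall = run_episodic_recall,
    vte = run_vte,
    stop(sprintf("unknown task '%s'", cfg$task))
  )
  runner(cfg)
}
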