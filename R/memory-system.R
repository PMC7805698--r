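#' System-level metaparameters
#'
#' The small set of knobs that switch the memory system between modes of
#' operation. `g_bu` and `g_td` weight bottom-up (stimulus) versus
#' top-down (internal expectation) drive; `beta`/`sigma` are forwarded to
#' the cores and control the randomness of state transitions (the
#' arousal/gain metaparameter); `wm_gain` is the output gain of the
#' working memory onto the cortical networks; `theta_reset` is the
#' surprise fraction above which the memory state is cleared so a novel
#' stimulus can be coded quickly.
#'
#' @param g_bu,g_td Nonnegative drive weights.
#' @param beta Unit gain (may be `Inf`).
#' @param sigma Input noise SD.
#' @param wm_gain Working-memory output gain, >= 0.
#' @param theta_reset Reset threshold in (0, 1].
#' @return List of class `"meta_params"`.
#' @export
meta_params <- function(g_bu = 2, g_td = 1, beta = Inf, sigma = 0,
                        wm_gain = 20, theta_reset = 0.5) {
  stopifnot(g_bu >= 0, g_td >= 0, beta > 0, sigma >= 0, wm_gain >= 0,
            theta_reset > 0, theta_reset <= 1)
  structure(list(g_bu = g_bu, g_td = g_td, beta = beta, sigma = sigma,
                 wm_gain = wm_gain, theta_reset = theta_reset),
            class = "meta_params")
}

#' Assemble the three-network memory system
#'
#' Composes the identification (WHAT) attractor network, the
#' winner-take-all localization (WHERE) network over orthogonal place
#' codes, the bidirectional object-place bindings, the recruitment-based
#' working memory, and the delayed predictive map into one system object.
#'
#' @param what_patterns List of [pattern()] objects stored in WHAT.
#' @param places Place-code matrix from [place_codes()].
#' @param rule Storage rule for WHAT (see [store_patterns()]).
#' @param what_params [core_params()] for the WHAT core.
#' @param eta Binding learning rate (default 0.1).
#' @param wm_lambda Working-memory decay per recruitment event, in (0,1].
#' @param wm_capacity Maximum number of working-memory nodes.
#' @param wm_threshold Joint-state similarity above which a perception
#'   re-activates an existing node instead of recruiting a new one.
#' @param pmap_delay Predictive-association delay d in steps.
#' @param pmap_eta Predictive learning rate.
#' @param meta [meta_params()].
#' @return Object of class `"memory_system"`.
#' @export
memory_system <- function(what_patterns, places,
                          rule = c("hebbian", "covariance"),
                          what_params = core_params(),
                          eta = 0.1,
                          wm_lambda = 0.9, wm_capacity = 16,
                          wm_threshold = 0.95,
                          pmap_delay = 5, pmap_eta = 1,
                          meta = meta_params()) {
  rule <- match.arg(rule)
  P <- pattern_matrix(what_patterns)
  n <- ncol(P)
  n_place <- ncol(places)
  sys <- list(
    what = list(W = store_patterns(what_patterns, rule),
                patterns = what_patterns,
                state = core_state(n),
                params = what_params),
    where = list(codes = places,
                 n = n_place,
                 state = rep(-1, n_place)),
    bind = list(B_wp = matrix(0, n_place, n),
                B_pw = matrix(0, n, n_place),
                eta = eta),
    wm = list(nodes = list(), lambda = wm_lambda, capacity = wm_capacity,
              threshold = wm_threshold),
    pmap = predictive_map(delay = pmap_delay, eta = pmap_eta),
    meta = meta,
    last_label = NA_character_,
    clock = 0L
  )
  class(sys) <- "memory_system"
  sys
}

#' @export
print.memory_system <- function(x, ...) {
  cat(sprintf(paste0("<memory_system: WHAT N = %d (%d patterns), ",
                     "WHERE n = %d (%d places), WM nodes = %d>\n"),
              length(x$what$state$s), length(x$what$patterns),
              x$where$n, nrow(x$where$codes), length(x$wm$nodes)))
  invisible(x)
}

# ---- comparator -----------------------------------------------------------

#' Comparator: surprise between input and memory state
#'
#' Flags every attended feature on which the sensory input and the
#' current attractor state disagree in sign (strict disagreement:
#' `input_i * state_i < 0`; a neutral/empty component on either side does
#' not count as a mismatch, so the first stimulus against an empty state
#' yields zero surprise). The total is the mismatch fraction over the
#' mask.
#'
#' @param input Sensory input vector.
#' @param state Attractor-state vector (or [core_state()]).
#' @param mask Logical vector (or index vector) of attended features;
#'   default: all.
#' @return List of class `"surprise_report"` with `total` (mismatch
#'   fraction) and `per_feature` (0/1 flags, length N).
#' @export
compare <- function(input, state, mask = NULL) {
  s <- if (inherits(state, "core_state")) state$s else as.numeric(state)
  input <- as.numeric(input)
  n <- length(s)
  if (length(input) != n) stop("length mismatch between input and state")
  if (is.null(mask)) mask <- rep(TRUE, n)
  if (!is.logical(mask)) {
    idx <- mask
    mask <- rep(FALSE, n)
    mask[idx] <- TRUE
  }
  if (!any(mask)) stop("comparator mask must be nonempty")
  flags <- integer(n)
  flags[mask & (input * s < 0)] <- 1L
  structure(list(total = sum(flags) / sum(mask), per_feature = flags),
            class = "surprise_report")
}

# ---- localization ---------------------------------------------------------

#' Winner-take-all place selection
#'
#' Leaves exactly one place unit active: `+1` at the argmax, `-1`
#' elsewhere. Ties break to the lowest index. If no activation is
#' positive there is no attended place and the none-code (all `-1`) is
#' returned.
#'
#' @param activations Numeric place-activation vector.
#' @return One-hot code (or none-code) of the same length.
#' @export
wta <- function(activations) {
  n <- length(activations)
  if (n < 1L) stop("need at least one place unit")
  code <- rep(-1, n)
  if (max(activations) > 0) code[which.max(activations)] <- 1
  code
}

#' Is a place code the none-code?
#' @param code Place-code vector.
#' @return TRUE if no unit is active.
#' @export
is_none_code <- function(code) !any(code > 0)

# Map a one-hot code back to its place label (NA for the none-code).
place_label <- function(code, codes) {
  k <- which(code > 0)
  if (length(k) != 1L) return(NA_character_)
  hit <- which(apply(codes, 1, function(rw) which.max(rw) == k &
                       rw[k] > 0))
  if (length(hit) >= 1L) rownames(codes)[hit[1L]] else NA_character_
}

# Resolve a place given as label or code into a code vector.
resolve_place <- function(system, place) {
  if (is.character(place)) {
    if (!place %in% rownames(system$where$codes)) {
      stop(sprintf("unknown place label '%s'", place))
    }
    system$where$codes[place, ]
  } else {
    as.numeric(place)
  }
}

#' Learn an object-place binding
#'
#' Strengthens the association between the currently active place unit
#' and the settled WHAT state, in both directions. Only the active
#' place's row/column is touched; the none-code performs no update.
#' Bindings are only updated at perception events, never during recall.
#'
#' @param system A [memory_system()].
#' @param what_state Settled WHAT activation vector.
#' @param where_code One-hot place code.
#' @return Updated system.
#' @export
learn_binding <- function(system, what_state, where_code) {
  k <- which(where_code > 0)
  if (length(k) != 1L) return(system)
  eta <- system$bind$eta
  system$bind$B_wp[k, ] <- system$bind$B_wp[k, ] + eta * what_state
  system$bind$B_pw[, k] <- system$bind$B_pw[, k] + eta * what_state
  system
}

# ---- working memory -------------------------------------------------------

joint_similarity <- function(a, b) sum(a * b) / length(a)

#' Recruit (or re-activate) a working-memory node
#'
#' After a perception event, if no existing node's snapshot matches the
#' joint WHAT x WHERE state above the similarity threshold, a new node is
#' recruited with activity 1 holding an immutable snapshot of the joint
#' state; otherwise the matching node is re-activated to 1. Either way
#' the remaining nodes decay by the factor `lambda`, which implements the
#' recency gradient. On capacity overflow the least active node is
#' evicted.
#'
#' @param system A [memory_system()].
#' @param what_state Settled WHAT activation vector.
#' @param where_code Place code at the event.
#' @param novelty Optional [compare()] report for the event (stored on
#'   the node for inspection; recruitment itself is driven by snapshot
#'   similarity).
#' @return Updated system.
#' @export
recruit <- function(system, what_state, where_code, novelty = NULL) {
  wm <- system$wm
  joint <- c(what_state, where_code)
  match_idx <- 0L
  if (length(wm$nodes) > 0) {
    sims <- vapply(wm$nodes,
                   function(nd) joint_similarity(joint, c(nd$what, nd$where)),
                   numeric(1))
    best <- which.max(sims)
    if (sims[best] >= wm$threshold) match_idx <- best
  }
  wm$nodes <- lapply(wm$nodes, function(nd) {
    nd$a <- wm$lambda * nd$a
    nd
  })
  if (match_idx > 0L) {
    wm$nodes[[match_idx]]$a <- 1
    wm$nodes[[match_idx]]$recruited_at <- system$clock
  } else {
    node <- structure(list(a = 1, what = what_state, where = where_code,
                           recruited_at = system$clock,
                           novelty = if (is.null(novelty)) NA_real_
                                     else novelty$total),
                      class = "wm_node")
    wm$nodes <- c(wm$nodes, list(node))
    if (length(wm$nodes) > wm$capacity) {
      drop <- which.min(vapply(wm$nodes, function(nd) nd$a, numeric(1)))
      wm$nodes <- wm$nodes[-drop]
    }
  }
  system$wm <- wm
  system
}

#' Select the working-memory node matching a partial cue
#'
#' Scores every node by activity x similarity, where similarity is
#' computed only over the cue's non-neutral components (a partial cue
#' says nothing about the features it leaves at 0). Returns the
#' highest-scoring node if its score is positive, else `NULL`; ties go to
#' the most recently recruited node. Because the score is a product,
#' both criteria matter: a recently active node loses to an older one
#' whose snapshot actually matches the cue.
#'
#' @param system A [memory_system()].
#' @param cue_what Cue over WHAT units (0 = unknown), or NULL.
#' @param cue_where Cue over place units, or NULL.
#' @return The selected `wm_node` (with attribute `"index"`) or `NULL`.
#' @export
wm_select <- function(system, cue_what = NULL, cue_where = NULL) {
  nodes <- system$wm$nodes
  if (length(nodes) == 0) return(NULL)
  n_what <- length(system$what$state$s)
  n_place <- system$where$n
  if (is.null(cue_what)) cue_what <- numeric(n_what)
  if (is.null(cue_where)) cue_where <- numeric(n_place)
  cue <- c(cue_what, cue_where)
  nz <- cue != 0
  if (!any(nz)) return(NULL)
  scores <- vapply(nodes, function(nd) {
    snap <- c(nd$what, nd$where)
    nd$a * sum(cue[nz] * snap[nz]) / sum(nz)
  }, numeric(1))
  recency <- vapply(nodes, function(nd) nd$recruited_at, numeric(1))
  best <- which(scores == max(scores))
  best <- best[which.max(recency[best])]
  if (scores[best] <= 0) return(NULL)
  node <- nodes[[best]]
  attr(node, "index") <- best
  node
}

#' Top-down drive from a working-memory node
#'
#' `G * a * snapshot`: positive on the snapshot's active units
#' (excitation) and negative on its inactive units (inhibition), for both
#' the WHAT and WHERE parts. With `G = 0` (undeveloped prefrontal mode)
#' or a silent node the drive vanishes.
#'
#' @param node A `wm_node` (or NULL).
#' @param G Working-memory output gain.
#' @param n_what,n_place Dimensions used when `node` is NULL.
#' @return List with `what` and `where` drive vectors.
#' @export
wm_drive <- function(node, G, n_what = NULL, n_place = NULL) {
  if (is.null(node)) {
    return(list(what = numeric(n_what %||% 0),
                where = numeric(n_place %||% 0)))
  }
  list(what = G * node$a * node$what, where = G * node$a * node$where)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- predictive map -------------------------------------------------------

#' Delayed predictive associations between attractors
#'
#' Hetero-associative map at the attractor-event level: experiencing
#' attractor u followed by attractor v strengthens u -> v. Readout is
#' delayed: only after the system has resided in u for at least `delay`
#' steps does the map drive the state toward u's learned successor(s).
#'
#' @param delay Residence delay d in steps before the prediction is read
#'   out (default 5).
#' @param eta Increment per experienced transition.
#' @return Object of class `"predictive_map"`.
#' @export
predictive_map <- function(delay = 5, eta = 1) {
  stopifnot(delay >= 1, eta > 0)
  structure(list(labels = character(0), patterns = list(),
                 S = matrix(0, 0, 0), delay = delay, eta = eta),
            class = "predictive_map")
}

pmap_register <- function(pmap, label, values) {
  if (label %in% pmap$labels) return(pmap)
  k <- length(pmap$labels)
  S <- matrix(0, k + 1, k + 1)
  if (k > 0) S[seq_len(k), seq_len(k)] <- pmap$S
  pmap$labels <- c(pmap$labels, label)
  pmap$patterns[[label]] <- values
  dimnames(S) <- list(pmap$labels, pmap$labels)
  pmap$S <- S
  pmap
}

#' Learn one episodic transition
#'
#' Associates two consecutively experienced attractor events. A `NA`
#' event on either side is a no-op (no association across gaps).
#' Re-experiencing a transition strengthens it monotonically.
#'
#' @param pmap A [predictive_map()].
#' @param prev_label,label Labels of the two events (NA allowed).
#' @param prev_values,values The corresponding attractor patterns.
#' @return Updated map.
#' @export
learn_transition <- function(pmap, prev_label, label,
                             prev_values = NULL, values = NULL) {
  if (is.na(prev_label) || is.na(label)) return(pmap)
  pmap <- pmap_register(pmap, prev_label, prev_values)
  pmap <- pmap_register(pmap, label, values)
  pmap$S[prev_label, label] <- pmap$S[prev_label, label] + pmap$eta
  pmap
}

#' Delayed predictive drive
#'
#' Zero until the system has resided in the current attractor for at
#' least `pmap$delay` steps; thereafter a drive vector proportional to
#' the learned successor pattern(s) of the current attractor (successor
#' strengths weight the stored patterns).
#'
#' @param pmap A [predictive_map()].
#' @param label Current attractor label (NA when between attractors).
#' @param residence Consecutive steps spent in `label`.
#' @param n Unit count (for the zero vector).
#' @return Drive vector of length `n`.
#' @export
predictive_drive <- function(pmap, label, residence, n) {
  zero <- numeric(n)
  if (is.na(label) || residence < pmap$delay) return(zero)
  if (!label %in% pmap$labels) return(zero)
  w <- pmap$S[label, ]
  if (all(w == 0)) return(zero)
  drive <- zero
  for (k in seq_along(w)) {
    if (w[k] != 0) drive <- drive + w[k] * pmap$patterns[[pmap$labels[k]]]
  }
  drive
}

# ---- perception and recall ------------------------------------------------

#' Mismatch-triggered reset
#'
#' If the comparator total exceeds `theta_reset`, the WHAT and WHERE
#' activations are cleared to the empty state so the novel stimulus can
#' be coded quickly. Synaptic resources and working memory are kept:
#' surprise resets the state, not the history. Applying a reset twice is
#' the same as applying it once.
#'
#' @param system A [memory_system()].
#' @param report A [compare()] report.
#' @param theta_reset Threshold; defaults to the system's metaparameter.
#' @return Updated system.
#' @export
reset_if_surprised <- function(system, report,
                               theta_reset = system$meta$theta_reset) {
  if (report$total > theta_reset) {
    system$what$state$s[] <- 0
    system$where$state <- rep(-1, system$where$n)
  }
  system
}

#' Perceive a stimulus at a place
#'
#' One bottom-up perception event: the incoming stimulus is compared to
#' the current memory state (possibly triggering a mismatch reset), WHAT
#' settles on the stimulus, WHERE applies winner-take-all to the place
#' input, the object-place binding is learned, a working-memory node is
#' recruited, and an episodic transition from the previous attractor
#' event is recorded.
#'
#' @param system A [memory_system()].
#' @param stimulus WHAT input vector (a [pattern()] is accepted).
#' @param place Place label, place code, or NULL (no attended place).
#' @return Updated system. The perception is appended to
#'   `system$percepts` (step, label, place, surprise).
#' @export
perceive <- function(system, stimulus, place = NULL) {
  if (inherits(stimulus, "pattern")) stimulus <- stimulus$values
  report <- compare(stimulus, system$what$state$s)
  system <- reset_if_surprised(system, report)
  res <- settle(system$what$state, system$what$W, external = stimulus,
                params = system$what$params, g_bu = system$meta$g_bu)
  system$what$state <- res$state
  code <- if (is.null(place)) rep(-1, system$where$n)
          else wta(resolve_place(system, place))
  system$where$state <- code
  system <- learn_binding(system, res$state$s, code)
  label <- nearest_attractor(res$state$s, system$what$patterns)
  if (!is.na(label)) {
    vals <- function(lb) {
      P <- pattern_matrix(system$what$patterns)
      if (is.na(lb)) NULL else as.numeric(P[lb, ])
    }
    system$pmap <- learn_transition(system$pmap, system$last_label, label,
                                    vals(system$last_label), vals(label))
  }
  system$clock <- system$clock + 1L
  system <- recruit(system, res$state$s, code, novelty = report)
  system$last_label <- label
  rec <- data.frame(step = system$clock, label = label %||% NA_character_,
                    place = place_label(code, system$where$codes),
                    surprise = report$total, stringsAsFactors = FALSE)
  system$percepts <- rbind(system$percepts, rec)
  system
}

#' Recall the place of an object
#'
#' Query (non-learning): working memory is probed with the WHAT cue; the
#' WHAT network settles on the cue plus any working-memory top-down
#' drive; the localization network is then driven by the binding
#' projection of the settled WHAT state plus the working-memory place
#' drive, and winner-take-all picks the place. With zero working-memory
#' gain the long-term binding strengths alone decide.
#'
#' @param system A [memory_system()].
#' @param cue WHAT cue vector (or [pattern()]); 0 = unknown feature.
#' @param wm_gain Working-memory output gain; defaults to the system's
#'   metaparameter.
#' @return List with `place` (label or NA), `code`, the settled
#'   `what_state`, `activations` of the place units, and `trace`
#'   (an episode-trace data frame of the settling).
#' @export
recall_place <- function(system, cue, wm_gain = system$meta$wm_gain) {
  if (inherits(cue, "pattern")) cue <- cue$values
  node <- wm_select(system, cue_what = cue)
  drv <- wm_drive(node, wm_gain, n_what = length(system$what$state$s),
                  n_place = system$where$n)
  # queries settle from the empty memory state (activations cleared,
  # resources kept), so the answer reflects cue + memory, not whatever
  # state the system happened to linger in
  system$what$state$s[] <- 0
  res <- settle(system$what$state, system$what$W, external = cue,
                params = system$what$params, g_bu = system$meta$g_bu,
                topdown = drv$what, g_td = system$meta$g_td,
                record_energy = TRUE)
  act <- as.vector(system$bind$B_wp %*% res$state$s) + drv$where
  code <- wta(act)
  list(place = place_label(code, system$where$codes), code = code,
       what_state = res$state, activations = act,
       trace = settle_trace(res, system))
}

#' Recall the object at a place
#'
#' Query (non-learning): the place cue selects a working-memory node via
#' its WHERE part; WHAT is driven top-down by the binding column of the
#' active place plus the working-memory drive and settles; the label of
#' the nearest stored attractor is reported.
#'
#' @param system A [memory_system()].
#' @param place Place label or code.
#' @param wm_gain Working-memory output gain.
#' @return List with `object` (label or NA), settled `what_state`, final
#'   `overlap` with the reported pattern, and `trace`.
#' @export
recall_object <- function(system, place, wm_gain = system$meta$wm_gain) {
  code <- wta(resolve_place(system, place))
  n <- length(system$what$state$s)
  node <- wm_select(system, cue_where = code)
  drv <- wm_drive(node, wm_gain, n_what = n, n_place = system$where$n)
  k <- which(code > 0)
  bind_drive <- if (length(k) == 1L) system$bind$B_pw[, k] else numeric(n)
  td <- bind_drive + drv$what
  system$what$state$s[] <- 0  # query starts from the empty memory state
  if (all(td == 0)) {
    # no binding and no working-memory match: nothing recalls
    res <- settle(system$what$state, system$what$W,
                  params = system$what$params, record_energy = TRUE)
  } else {
    res <- settle(system$what$state, system$what$W, topdown = td,
                  g_td = system$meta$g_td, params = system$what$params,
                  record_energy = TRUE)
  }
  lab <- nearest_attractor(res$state$s, system$what$patterns)
  ov <- if (is.na(lab)) NA_real_ else {
    P <- pattern_matrix(system$what$patterns)
    overlap(res$state$s, as.numeric(P[lab, ]))
  }
  list(object = lab, what_state = res$state, overlap = ov,
       trace = settle_trace(res, system))
}

settle_trace <- function(res, system) {
  en <- res$energy
  if (is.null(en)) en <- energy(res$state, system$what$W)
  data.frame(step = seq_along(en) - 1L, energy = en)
}

# ---- free running ---------------------------------------------------------

#' Free-run the memory system (decoupled from input)
#'
#' Top-down mode: with `g_bu = 0` the WHAT network evolves under its own
#' recurrent dynamics, synaptic depression, additive noise and the
#' delayed predictive drive. Each step is one asynchronous sweep in a
#' freshly randomized unit order, followed by a depression update. The
#' visited attractor (if any) is logged at every step.
#'
#' @param system A [memory_system()].
#' @param n_steps Number of sweeps.
#' @param meta [meta_params()] controlling `sigma`, `beta` and `g_td`;
#'   defaults to the system's own.
#' @param threshold Attractor-detection overlap threshold for the logged
#'   labels.
#' @param residence_threshold Looser overlap threshold used only for the
#'   internal residence clock that gates the delayed predictive drive;
#'   keeps the episodic readout robust to noise jitter around an
#'   attractor.
#' @return List with the updated `system` and `trace`, an
#'   `episode_trace` data frame (step, label, overlap, energy).
#' @export
free_run <- function(system, n_steps, meta = system$meta,
                     threshold = 0.9, residence_threshold = 0.75) {
  W <- system$what$W
  params <- system$what$params
  P <- pattern_matrix(system$what$patterns)
  labels <- rownames(P)
  n <- ncol(P)
  s <- system$what$state$s
  r <- system$what$state$r
  sigma <- meta$sigma
  beta <- meta$beta
  cur_label <- nearest_label(P, s, residence_threshold)
  residence <- if (is.na(cur_label)) 0L else 1L
  out_label <- character(n_steps)
  out_overlap <- numeric(n_steps)
  out_energy <- numeric(n_steps)
  # Once the delayed association fires it keeps driving until the state
  # lands in another attractor (or times out), so a transition survives
  # noise jitter part-way between the two patterns.
  drive_vec <- NULL
  drive_src <- NA_character_
  drive_age <- 0L
  for (step in seq_len(n_steps)) {
    if (is.null(drive_vec) && !is.na(cur_label)) {
      dv <- predictive_drive(system$pmap, cur_label, residence, n)
      if (any(dv != 0)) {
        drive_vec <- dv
        drive_src <- cur_label
        drive_age <- 0L
      }
    }
    td <- if (is.null(drive_vec)) numeric(n) else meta$g_td * drive_vec
    h <- as.vector(W %*% (r * s)) + td
    ord <- sample.int(n)
    for (i in ord) {
      hi <- h[i] + if (sigma > 0) stats::rnorm(1, 0, sigma) else 0
      si <- if (is.infinite(beta)) {
        if (hi > 0) 1 else if (hi < 0) -1 else s[i]
      } else {
        if (stats::runif(1) < stats::plogis(2 * beta * hi)) 1 else -1
      }
      if (si != s[i]) {
        h <- h + W[, i] * r[i] * (si - s[i])
        s[i] <- si
      }
    }
    st <- list(s = s, r = r)
    r <- depression_update(st, params)
    m <- as.vector(P %*% s) / n
    best <- which.max(m)
    lab <- if (m[best] >= threshold) labels[best] else NA_character_
    loose <- if (m[best] >= residence_threshold) labels[best] else NA_character_
    if (!is.na(loose) && identical(loose, cur_label)) {
      residence <- residence + 1L
    } else {
      cur_label <- loose
      residence <- if (is.na(loose)) 0L else 1L
    }
    if (!is.null(drive_vec)) {
      drive_age <- drive_age + 1L
      landed <- !is.na(cur_label) && !identical(cur_label, drive_src)
      if (landed || drive_age > 4L * system$pmap$delay) {
        drive_vec <- NULL
        drive_src <- NA_character_
      }
    }
    out_label[step] <- lab
    out_overlap[step] <- m[best]
    out_energy[step] <- energy_value(s, W)
  }
  system$what$state$s <- s
  system$what$state$r <- r
  system$what$state$t <- system$what$state$t + n_steps
  trace <- data.frame(step = seq_len(n_steps), label = out_label,
                      overlap = out_overlap, energy = out_energy,
                      stringsAsFactors = FALSE)
  class(trace) <- c("episode_trace", "data.frame")
  list(system = system, trace = trace)
}

nearest_label <- function(P, s, threshold) {
  m <- as.vector(P %*% s) / ncol(P)
  best <- which.max(m)
  if (m[best] >= threshold) rownames(P)[best] else NA_character_
}
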