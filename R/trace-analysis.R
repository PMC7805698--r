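#' Project states onto the stored patterns' principal components
#'
#' Computes the first two principal axes of the stored pattern set
#' (centered on the pattern mean, never on the trajectory) and projects
#' every trajectory state onto them. This is the 2-D "memory space" view
#' of a run: stored patterns map to well-separated points and a settling
#' trajectory traces a path from the cue to the recalled pattern.
#'
#' @param states Matrix of states (rows) or list of state vectors.
#' @param patterns List of at least two stored [pattern()] objects.
#' @return Data frame with columns `PC1`, `PC2`, one row per state.
#' @export
pc_projection <- function(states, patterns) {
  if (length(patterns) < 2) stop("need at least two stored patterns")
  P <- pattern_matrix(patterns)
  if (is.list(states) && !is.data.frame(states)) {
    states <- do.call(rbind, states)
  }
  states <- as.matrix(states)
  if (ncol(states) != ncol(P)) stop("state length does not match patterns")
  ctr <- colMeans(P)
  pc <- stats::prcomp(P, center = ctr, scale. = FALSE)
  proj <- sweep(states, 2, ctr) %*% pc$rotation[, 1:2, drop = FALSE]
  data.frame(PC1 = proj[, 1], PC2 = proj[, 2])
}

#' Attractor events in an episode trace
#'
#' Turns the per-step nearest-attractor labels of a trace into discrete
#' events: every contiguous run of the same label lasting at least
#' `min_dwell` steps becomes one event; below-threshold stretches are
#' gaps. Oscillations shorter than `min_dwell` produce no event.
#'
#' @param trace An `episode_trace` data frame (needs `step` and `label`
#'   columns), or a bare character vector of per-step labels.
#' @param min_dwell Minimum dwell in steps (default 3).
#' @return Data frame with columns `label`, `entry`, `exit` (step
#'   numbers), zero rows if no event qualifies.
#' @export
event_log <- function(trace, min_dwell = 3) {
  labels <- if (is.data.frame(trace)) as.character(trace$label) else as.character(trace)
  steps <- if (is.data.frame(trace) && !is.null(trace$step)) trace$step else seq_along(labels)
  if (length(labels) == 0) {
    return(data.frame(label = character(0), entry = numeric(0),
                      exit = numeric(0), stringsAsFactors = FALSE))
  }
  rl <- rle(ifelse(is.na(labels), ".none.", labels))
  ends <- cumsum(rl$lengths)
  starts <- ends - rl$lengths + 1L
  keep <- rl$values != ".none." & rl$lengths >= min_dwell
  data.frame(label = rl$values[keep],
             entry = steps[starts[keep]],
             exit = steps[ends[keep]],
             stringsAsFactors = FALSE)
}

#' Collapse an event log to its distinct-attractor sequence
#'
#' Consecutive events with the same label (leave-and-return excursions)
#' are merged, leaving the order in which distinct attractors were
#' visited -- the "episode" a replay run produces.
#'
#' @param events Event data frame from [event_log()] or a character
#'   vector of event labels.
#' @return Character vector of visited labels.
#' @export
event_sequence <- function(events) {
  labs <- if (is.data.frame(events)) events$label else as.character(events)
  if (length(labs) == 0) return(character(0))
  labs[c(TRUE, labs[-1] != labs[-length(labs)])]
}

#' Transition counts between attractor events
#'
#' Counts consecutive event pairs across one or more event logs.
#' Self-transitions (leave-and-return to the same attractor) are not
#' counted; the diagonal stays zero. Use the event logs directly to
#' study return behavior.
#'
#' @param events One event log (data frame or label vector) or a list of
#'   them.
#' @param labels Label universe for the matrix dimensions; defaults to
#'   the labels seen.
#' @return `K x K` integer matrix of counts, from-label in rows.
#' @export
transition_counts <- function(events, labels = NULL) {
  if (is.data.frame(events) || !is.list(events)) events <- list(events)
  seqs <- lapply(events, function(ev) {
    if (is.data.frame(ev)) ev$label else as.character(ev)
  })
  if (is.null(labels)) labels <- unique(unlist(seqs))
  K <- length(labels)
  M <- matrix(0L, K, K, dimnames = list(labels, labels))
  for (ev in seqs) {
    if (length(ev) < 2) next
    for (i in seq_len(length(ev) - 1)) {
      a <- ev[i]; b <- ev[i + 1]
      if (a != b) M[a, b] <- M[a, b] + 1L
    }
  }
  M
}

#' Fraction of leave-and-return excursions
#'
#' Among consecutive event pairs, the fraction that revisit the same
#' attractor. Near 1 means the state wanders out of an attractor and
#' falls back (the no-noise depression regime); low values mean the
#' state latches onward to other attractors.
#'
#' @param events Event log (data frame or label vector).
#' @return Scalar in `[0, 1]`, `NaN` if fewer than two events.
#' @export
return_fraction <- function(events) {
  labs <- if (is.data.frame(events)) events$label else as.character(events)
  if (length(labs) < 2) return(NaN)
  mean(labs[-length(labs)] == labs[-1])
}

#' Energy / surprise series of a trace
#'
#' Aligned `(step, value)` series extracted from an episode trace, for
#' plotting or export.
#'
#' @param trace An `episode_trace` data frame.
#' @return Data frame with `step` and `value`.
#' @export
energy_trace <- function(trace) {
  data.frame(step = trace$step, value = trace$energy)
}

#' @rdname energy_trace
#' @export
surprise_trace <- function(trace) {
  if (is.null(trace$surprise)) stop("trace has no surprise column")
  data.frame(step = trace$step, value = trace$surprise)
}

#' Write an episode trace as TSV
#'
#' @param trace Data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  utils::write.table(trace, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
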