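#' Bipolar feature pattern
#'
#' Creates a labelled bipolar pattern, the currency of the identification
#' (WHAT) network. Each element codes one feature: `+1` = feature present,
#' `-1` = feature absent.
#'
#' @param label Short character label (e.g. `"X"`).
#' @param values Numeric vector with elements in `{-1, +1}`.
#' @return An object of class `"pattern"` with fields `label`, `values`
#'   and `N` (the unit count).
#' @examples
#' p <- pattern("X", c(1, 1, -1, -1))
#' p$N
#' @export
pattern <- function(label, values) {
  if (!is.character(label) || length(label) != 1L || !nzchar(label)) {
    stop("'label' must be a single non-empty string")
  }
  values <- as.numeric(values)
  if (length(values) < 1L || !all(values %in% c(-1, 1))) {
    stop("pattern values must all be -1 or +1")
  }
  structure(list(label = label, values = values, N = length(values)),
            class = "pattern")
}

#' @export
print.pattern <- function(x, ...) {
  cat(sprintf("<pattern '%s': N = %d, %d active>\n",
              x$label, x$N, sum(x$values > 0)))
  invisible(x)
}

#' Stack a pattern set into a matrix
#'
#' @param patterns List of [pattern()] objects with equal length and unique
#'   labels.
#' @return A `K x N` numeric matrix, one pattern per row, row names set to
#'   the labels.
#' @export
pattern_matrix <- function(patterns) {
  if (length(patterns) < 1L) stop("need at least one pattern")
  ns <- vapply(patterns, function(p) p$N, integer(1))
  if (length(unique(ns)) != 1L) stop("all patterns must have the same length")
  labels <- vapply(patterns, function(p) p$label, character(1))
  if (anyDuplicated(labels)) stop("pattern labels must be unique")
  m <- do.call(rbind, lapply(patterns, function(p) p$values))
  rownames(m) <- labels
  m
}

#' Random dense bipolar patterns
#'
#' Draws `k` independent patterns of length `n` with i.i.d. equiprobable
#' `+1/-1` units, suitable for Hebbian storage (pairwise overlaps
#' concentrate near 0 for large `n`). Uses the current RNG state.
#'
#' @param labels Character vector of labels, one per pattern.
#' @param n Units per pattern.
#' @return List of [pattern()] objects.
#' @export
random_patterns <- function(labels, n) {
  lapply(labels, function(lb) {
    pattern(lb, sample(c(-1, 1), n, replace = TRUE))
  })
}

#' Letter bitmaps on a 5x5 grid
#'
#' The three letter-like shapes used throughout the pattern-completion
#' examples: `L` (left column plus bottom row), `X` (both diagonals) and
#' `+` (centre row plus centre column). Each bitmap has 9 active cells out
#' of 25; active cells map to `+1`, empty cells to `-1`. The shapes share a
#' few cells (e.g. `L` and `+` meet on the left column and bottom row), so
#' they form a mildly correlated set.
#'
#' @return List of three [pattern()] objects labelled `"L"`, `"X"`, `"+"`,
#'   each with `N = 25` (row-major flattening of the grid).
#' @export
make_letter_patterns <- function() {
  bitmaps <- list(
    L = c("#....",
          "#....",
          "#....",
          "#....",
          "#####"),
    X = c("#...#",
          ".#.#.",
          "..#..",
          ".#.#.",
          "#...#"),
    `+` = c("..#..",
            "..#..",
            "#####",
            "..#..",
            "..#..")
  )
  lapply(names(bitmaps), function(lb) {
    cells <- unlist(strsplit(bitmaps[[lb]], ""))
    pattern(lb, ifelse(cells == "#", 1, -1))
  })
}

#' Semantic triplet with controlled feature overlap
#'
#' Builds three equally active patterns X, Y, Z in which X and Y share
#' `n_shared` active features, Y and Z share `n_shared` other active
#' features, and X and Z share none. This is the stimulus set used for
#' semantic mind-wandering: transitions between feature-overlapping
#' attractors are "semantically related", X-to-Z hops are not.
#'
#' @param n_features Total unit count (default 64).
#' @param n_active Active (`+1`) features per pattern (default 20).
#' @param n_shared Active features shared by X,Y and by Y,Z (default 8).
#'   Must satisfy `2 * n_shared <= n_active` and
#'   `3 * n_active - 2 * n_shared <= n_features`.
#' @return List of three [pattern()] objects labelled `"X"`, `"Y"`, `"Z"`.
#' @export
make_semantic_triplet <- function(n_features = 64, n_active = 20,
                                  n_shared = 8) {
  if (2 * n_shared > n_active) stop("need n_active >= 2 * n_shared")
  if (3 * n_active - 2 * n_shared > n_features) {
    stop("n_features too small for the requested overlap structure")
  }
  blk <- function(from, len) if (len > 0) seq(from, length.out = len) else integer(0)
  shared_xy <- blk(1, n_shared)
  x_only   <- blk(n_shared + 1, n_active - n_shared)
  shared_yz <- blk(n_active + 1, n_shared)
  y_only   <- blk(n_active + n_shared + 1, n_active - 2 * n_shared)
  z_only   <- blk(2 * n_active - n_shared + 1, n_active - n_shared)
  as_pat <- function(lb, idx) {
    v <- rep(-1, n_features)
    v[idx] <- 1
    pattern(lb, v)
  }
  list(as_pat("X", c(shared_xy, x_only)),
       as_pat("Y", c(shared_xy, shared_yz, y_only)),
       as_pat("Z", c(shared_yz, z_only)))
}

#' Pairwise-balanced sparse pattern set
#'
#' Builds `K` equally active patterns over `choose(K, 2) * s` units by
#' dedicating a block of `s` units to every unordered pair of patterns:
#' each unit is active (`+1`) in exactly the two patterns of its pair.
#' Every pattern is active on `(K - 1) * s` units, every pair of patterns
#' shares exactly `s` active units, and the bipolar overlaps are small
#' and identical for all pairs, so the set stores stably under Hebbian
#' learning with uniform attractor depths. Used for episode chains,
#' where uniform basins keep replay unbiased.
#'
#' @param labels Character vector of `K >= 2` pattern labels.
#' @param s Units dedicated to each pattern pair (default 4).
#' @return List of `K` [pattern()] objects of length `choose(K, 2) * s`.
#' @export
make_pairwise_patterns <- function(labels, s = 4) {
  K <- length(labels)
  if (K < 2) stop("need at least two labels")
  if (s < 1) stop("'s' must be >= 1")
  pairs <- utils::combn(K, 2)
  n <- ncol(pairs) * s
  vs <- matrix(-1, K, n)
  for (j in seq_len(ncol(pairs))) {
    idx <- ((j - 1) * s + 1):(j * s)
    vs[pairs[1, j], idx] <- 1
    vs[pairs[2, j], idx] <- 1
  }
  lapply(seq_len(K), function(i) pattern(labels[i], vs[i, ]))
}

#' Orthogonal one-hot place codes
#'
#' One code per location: `+1` at the location's own unit, `-1` elsewhere.
#' Codes are pairwise maximally distinct, which is what lets the
#' localization network sidestep crosstalk between bindings.
#'
#' @param labels Character vector of place labels (e.g. `c("A","B","C")`).
#' @param n_place Number of place units; defaults to `length(labels)`.
#'   Must be at least `length(labels)`.
#' @return A `length(labels) x n_place` matrix of codes, row names set to
#'   the labels.
#' @export
place_codes <- function(labels, n_place = length(labels)) {
  if (anyDuplicated(labels)) stop("place labels must be unique")
  if (n_place < length(labels)) stop("n_place must be >= number of labels")
  codes <- matrix(-1, nrow = length(labels), ncol = n_place,
                  dimnames = list(labels, NULL))
  for (i in seq_along(labels)) codes[i, i] <- 1
  codes
}

#' Partial cue from a pattern
#'
#' Keeps a leading fraction of a pattern's units and sets the rest to the
#' neutral value 0 (unknown, not absent). Used to probe pattern completion.
#'
#' @param p A [pattern()].
#' @param frac Fraction of units to keep, in (0, 1].
#' @param keep Optional explicit indices to keep (overrides `frac`).
#' @return Numeric cue vector of length `p$N` with 0 on the unknown units.
#' @export
partial_cue <- function(p, frac = 0.5, keep = NULL) {
  if (is.null(keep)) {
    if (frac <= 0 || frac > 1) stop("'frac' must be in (0, 1]")
    keep <- seq_len(max(1L, floor(frac * p$N)))
  }
  v <- numeric(p$N)
  v[keep] <- p$values[keep]
  v
}

#' Shared-feature cue between two patterns
#'
#' Returns a cue that is `+1` exactly on the active features common to
#' both patterns and neutral (0) everywhere else -- the "ambiguous"
#' stimulus equally similar to both.
#'
#' @param p,q Two [pattern()] objects of equal length.
#' @return Numeric cue vector.
#' @export
shared_cue <- function(p, q) {
  if (p$N != q$N) stop("patterns must have the same length")
  v <- numeric(p$N)
  v[p$values > 0 & q$values > 0] <- 1
  v
}
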