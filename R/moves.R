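#' Interleaving test for an adjacent line pair
#'
#' Two adjacent parallel lines (columns `i`, `i+1` or rows `i`, `i+1`) are
#' *interleaved* when their segment intervals partially overlap: neither
#' nested nor disjoint, with all four endpoints distinct.  Commuting an
#' interleaved pair changes one crossing between the two strands and models a
#' type II topoisomerase strand passage; commuting a non-interleaved pair
#' preserves the knot type.
#'
#' @param g A [grid_diagram()].
#' @param axis `"column"` or `"row"`.
#' @param i 0-based index of the lower/left line of the pair
#'   (`0 <= i <= n-2`).
#' @return Logical.
#' @export
interleaved <- function(g, axis = c("column", "row"), i) {
  cls <- classify_juxtaposition(g, axis, i)
  cls$interleaved
}

#' Classify one adjacent-pair juxtaposition
#'
#' An interleaved adjacent pair has two *inner* endpoints, one on each line,
#' lying inside the other line's interval.  The perpendicular segment attached
#' at each inner endpoint either extends across the neighbouring line
#' ("inward") or away from it.  The pair is classified:
#'
#' * `"hooked"` — both extend inward; the two arcs cross twice and bound a
#'   rectangle of width 1 and height `|y1 - y2|`, whose area is reported;
#' * `"free"` — both extend away (no crossings between the pair);
#' * `"mixed"` — one of each;
#' * `"not-interleaved"` — the pair is nested or disjoint.
#'
#' A hooked juxtaposition with area 1 (the rectangle is one elementary lattice
#' square) is *strongly hooked*.
#'
#' @inheritParams interleaved
#' @return A one-row tibble like [classify_juxtapositions()].
#' @export
classify_juxtaposition <- function(g, axis = c("column", "row"), i) {
  stopifnot(is_grid_diagram(g))
  axis <- match.arg(axis)
  check_pair_index(g, i)
  tab <- classify_juxtapositions(g)
  tab[tab$axis == axis & tab$index == i, ]
}

#' Classify every adjacent-pair juxtaposition of a diagram
#'
#' @param g A [grid_diagram()].
#' @return A tibble with one row per adjacent pair on both axes and columns
#'   `axis` (`"column"`/`"row"`), `index` (0-based lower line of the pair),
#'   `interleaved` (logical), `class` (`"hooked"`, `"mixed"`, `"free"`, or
#'   `"not-interleaved"`), `area` (integer, defined only for hooked pairs,
#'   `NA` otherwise), and `strongly_hooked` (`class == "hooked" & area == 1`).
#' @seealso [classify_juxtaposition()], [passage_sites()]
#' @export
classify_juxtapositions <- function(g) {
  stopifnot(is_grid_diagram(g))
  tab <- as_tibble(gk_classify_pairs(g$x, g$o))
  tab$strongly_hooked <- !is.na(tab$area) & tab$area == 1L
  tab
}

check_pair_index <- function(g, i) {
  if (length(i) != 1 || is.na(i) || i != trunc(i) || i < 0 || i > g$n - 2) {
    abort(sprintf("Pair index must be a single integer in 0..%d.", g$n - 2),
      class = "gridknot_bad_input"
    )
  }
}

#' Commute an adjacent pair of rows or columns
#'
#' Exchanges lines `i` and `i+1` on the given axis.  When the pair is
#' interleaved this is a strand passage (the crossing count between the two
#' strands changes); otherwise it is a topology-preserving move.  The
#' operation is an involution: commuting the same pair twice restores the
#' diagram.
#'
#' @inheritParams interleaved
#' @return The commuted `grid_diagram`.
#' @export
commute_pair <- function(g, axis = c("column", "row"), i) {
  stopifnot(is_grid_diagram(g))
  axis <- match.arg(axis)
  check_pair_index(g, i)
  res <- gk_commute(g$x, g$o, if (axis == "column") 0L else 1L, as.integer(i))
  new_grid_diagram(res$x, res$o)
}

#' Passage sites of a diagram under a policy
#'
#' Lists the adjacent-pair sites at which a strand passage is fired:
#'
#' * `"unbiased"` — every interleaved adjacent pair on both axes (a
#'   hypothetical topoisomerase with no geometric site selection);
#' * `"hooked"` — only pairs classified hooked with rectangle area at most
#'   `max_area` (`max_area = 1` keeps exactly the strongly hooked sites,
#'   modeling passage only at hooked juxtapositions).
#'
#' Hooked sites are always a subset of unbiased sites.
#'
#' @param g A [grid_diagram()].
#' @param policy `"unbiased"` or `"hooked"`.
#' @param max_area Maximum rectangle area for the hooked policy.
#' @return A tibble with columns `axis`, `index`, `class`, and `area`
#'   (zero rows, same columns, when no site qualifies).
#' @export
passage_sites <- function(g, policy = c("unbiased", "hooked"), max_area = 1L) {
  policy <- match.arg(policy)
  tab <- classify_juxtapositions(g)
  keep <- if (policy == "unbiased") {
    tab$interleaved
  } else {
    tab$class == "hooked" & tab$area <= max_area
  }
  tab[keep, c("axis", "index", "class", "area")]
}

#' One destabilization, if available
#'
#' Searches for a 2-by-2 block of the board containing three markings; such a
#' block lets the grid number be reduced by one without changing the knot
#' type (the lone pair column and its row are deleted and the remaining
#' marking reconnects the strands).  The scan order is deterministic.
#'
#' @param g A [grid_diagram()].
#' @return The destabilized `grid_diagram` (grid number `n - 1`), or `NULL`
#'   when no 2-by-2 block with three markings exists.
#' @export
destabilize_once <- function(g) {
  stopifnot(is_grid_diagram(g))
  res <- gk_destabilize_once(g$x, g$o)
  if (!res$found) {
    return(NULL)
  }
  new_grid_diagram(res$x, res$o)
}

#' Simplify a grid diagram by topology-preserving moves
#'
#' Greedily destabilizes whenever possible; when stuck, walks over random
#' non-interleaved (topology-preserving) commutations looking for a new
#' destabilization, up to `max_steps` total moves.  The walk uses a
#' deterministic generator seeded from the diagram itself (or from `seed`),
#' so the result is reproducible.  The knot type is preserved by
#' construction; the grid number never increases.
#'
#' @param g A [grid_diagram()].
#' @param max_steps Total move budget.
#' @param seed Optional integer seed; by default derived from the diagram.
#' @return The simplified `grid_diagram`.
#' @export
simplify_grid <- function(g, max_steps = 2000L, seed = NULL) {
  stopifnot(is_grid_diagram(g))
  if (is.null(seed)) {
    v <- c(g$x, g$o)
    seed <- sum((v + 1) * (seq_along(v) * 2654435761)) %% 2^31
  }
  res <- gk_simplify(g$x, g$o, as.integer(max_steps), as.numeric(seed))
  new_grid_diagram(res$x, res$o)
}
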