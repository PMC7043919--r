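#' Exhaustive strand-passage event scan
#'
#' For every canonical single-component diagram with grid number in
#' `gn_min:gn_max`, fires a commutation at every interleaved adjacent pair on
#' both axes (non-cyclic adjacency), labels source and result by census
#' lookup, and aggregates events by grid number, knot-type transition, and
#' juxtaposition geometry.  Each (diagram, site) pair counts one event.
#'
#' @param gn_min,gn_max Grid-number range, `3 <= gn_min <= gn_max <= 7`.
#' @param dedup When `TRUE`, events are directed edges of the diagram
#'   network instead: for each source diagram, distinct resulting canonical
#'   diagrams count once, classified by the most-hooked site that produces
#'   them (minimal hooked area, hooked before mixed/free).  Default `FALSE`
#'   (one event per site, the paper-style count).
#' @return A tibble with columns `gn`, `from`, `to` (knot labels), `category`
#'   (`"free"`, `"mixed"`, `"hooked"`), `area` (hooked rectangle area, `NA`
#'   otherwise), and `count`.
#' @seealso [flux_table()] which aggregates these events under a policy.
#' @export
passage_events <- function(gn_min, gn_max = gn_min, dedup = FALSE) {
  if (gn_min < 3 || gn_max > 7 || gn_min > gn_max) {
    abort("passage_events supports 3 <= gn_min <= gn_max <= 7.",
      class = "gridknot_bad_input"
    )
  }
  tab <- as_tibble(gk_passage_events(
    as.integer(gn_min), as.integer(gn_max), isTRUE(dedup)
  ))
  attr(tab, "gn_range") <- c(gn_min, gn_max)
  attr(tab, "dedup") <- isTRUE(dedup)
  tab
}

#' Knot-interconversion flux table under a passage policy
#'
#' Aggregates strand-passage events into a directed flux table
#' `count[from][to]`:
#'
#' * policy `"unbiased"` — passages at every interleaved juxtaposition; on an
#'   exhaustive census the table is exactly symmetric (detailed balance).
#' * policy `"hooked"` — passages only at juxtapositions classified hooked
#'   with rectangle area at most `max_area` (`max_area = 1`: strongly hooked
#'   only); symmetry breaks toward simpler knots.
#'
#' @param events A [passage_events()] tibble, or a tibble with the same
#'   columns produced by [sampled_flux_study()].
#' @param policy `"unbiased"` or `"hooked"`.
#' @param max_area Maximum hooked rectangle area for the hooked policy.
#' @return A tibble of class `flux_table` with columns `from`, `to`, `count`,
#'   and attributes `policy`, `max_area`, `gn_range`, and `per_gn` (the
#'   per-grid-number breakdown, columns `gn`, `from`, `to`, `count`).
#' @export
flux_table <- function(events, policy = c("unbiased", "hooked"), max_area = 1L) {
  policy <- match.arg(policy)
  needed <- c("gn", "from", "to", "category", "area", "count")
  if (!all(needed %in% names(events))) {
    abort("`events` must have columns gn, from, to, category, area, count.",
      class = "gridknot_bad_input"
    )
  }
  keep <- if (policy == "unbiased") {
    rep(TRUE, nrow(events))
  } else {
    events$category == "hooked" & !is.na(events$area) & events$area <= max_area
  }
  ev <- events[keep, ]
  per_gn <- ev %>%
    group_by(.data$gn, .data$from, .data$to) %>%
    summarise(count = sum(.data$count), .groups = "drop")
  tab <- per_gn %>%
    group_by(.data$from, .data$to) %>%
    summarise(count = sum(.data$count), .groups = "drop")
  structure(tab,
    policy = policy,
    max_area = if (policy == "hooked") max_area else Inf,
    gn_range = attr(events, "gn_range"),
    per_gn = per_gn,
    class = c("flux_table", class(tab))
  )
}

flux_count <- function(f, from, to) {
  v <- f$count[f$from == from & f$to == to]
  if (length(v) == 0) 0 else sum(v)
}

#' Row-normalized transition probabilities
#'
#' The probability that a configuration of a given knot type converts into
#' each knot type, given one strand passage under the table's policy.  Rows
#' with zero events are flagged undefined rather than treated as errors.
#'
#' @param f A [flux_table()].
#' @return A tibble with columns `from`, `to`, `count`, `row_total`,
#'   `probability`, and `defined`; probabilities sum to 1 within each defined
#'   `from` row.
#' @export
transition_probabilities <- function(f) {
  stopifnot(inherits(f, "flux_table"))
  f %>%
    group_by(.data$from) %>%
    mutate(
      row_total = sum(.data$count),
      defined = .data$row_total > 0,
      probability = ifelse(.data$defined, .data$count / .data$row_total, NA_real_)
    ) %>%
    ungroup()
}

#' Knot closeness of two knot types
#'
#' The ratio between the strand passages interconverting the two given knot
#' types (in either direction) and all type-changing strand passages in the
#' table.  Closeness is symmetric in its two labels, and the values over all
#' unordered label pairs sum to 1.
#'
#' @param f A [flux_table()].
#' @param a,b Knot labels.
#' @return A single fraction.
#' @export
knot_closeness <- function(f, a, b) {
  stopifnot(inherits(f, "flux_table"))
  changing <- sum(f$count[f$from != f$to])
  if (changing == 0) {
    abort("No type-changing events in this flux table.",
      class = "gridknot_bad_input"
    )
  }
  (flux_count(f, a, b) + flux_count(f, b, a)) / changing
}

#' Knotting reduction factor between two knot types
#'
#' Compares the directed fluxes between knot types `a` and `b` under a
#' geometrically restricted (hooked) policy with the unbiased fluxes.  The
#' reduction factor `flux(a -> b) / flux(b -> a)` of the restricted table
#' says how much the equilibrium proportion of `a` relative to `b` would be
#' diminished by many rounds of restricted passages; for an exhaustive
#' unbiased census the same ratio is exactly 1 (detailed balance).
#'
#' @param unbiased,hooked [flux_table()]s over the same diagram set.
#' @param a,b Knot labels (default trefoil versus unknot).
#' @return A list of class `reduction_report` with the two directed counts
#'   under each policy, `factor` (the hooked ratio; `Inf` when the
#'   denominator is 0 and the numerator positive, flagged 1 when both are 0),
#'   `unbiased_ratio`, and flags `infinite` and `both_zero`.
#' @export
reduction_factor <- function(unbiased, hooked, a = "3_1", b = "0_1") {
  stopifnot(inherits(unbiased, "flux_table"), inherits(hooked, "flux_table"))
  hab <- flux_count(hooked, a, b)
  hba <- flux_count(hooked, b, a)
  uab <- flux_count(unbiased, a, b)
  uba <- flux_count(unbiased, b, a)
  both_zero <- hab == 0 && hba == 0
  fac <- if (both_zero) 1 else if (hba == 0) Inf else hab / hba
  structure(
    list(
      a = a, b = b,
      hooked_ab = hab, hooked_ba = hba, factor = fac,
      unbiased_ab = uab, unbiased_ba = uba,
      unbiased_ratio = if (uba > 0) uab / uba else NA_real_,
      infinite = is.infinite(fac), both_zero = both_zero,
      max_area = attr(hooked, "max_area"),
      gn_range = attr(hooked, "gn_range")
    ),
    class = "reduction_report"
  )
}

#' @export
print.reduction_report <- function(x, ...) {
  cat(sprintf(
    "<reduction_report> %s <-> %s\n  hooked (max area %s): %s -> %s: %g, %s -> %s: %g\n  reduction factor: %s%s\n  unbiased ratio: %s\n",
    x$a, x$b, format(x$max_area), x$a, x$b, x$hooked_ab, x$b, x$a, x$hooked_ba,
    format(x$factor), if (x$both_zero) " (both directions zero)" else "",
    format(x$unbiased_ratio)
  ))
  invisible(x)
}

#' Reduction-factor sweep over the hooked-area threshold
#'
#' Recomputes the knotting reduction factor while tightening the maximal
#' hooked rectangle area, quantifying how geometric selectivity of passage
#' sites strengthens topological simplification.
#'
#' @param events A [passage_events()] tibble.
#' @param max_areas Integer vector of area thresholds.
#' @param a,b Knot labels.
#' @return A tibble with columns `max_area`, `flux_ab`, `flux_ba`, `factor`.
#' @export
area_sweep <- function(events, max_areas = 1:3, a = "3_1", b = "0_1") {
  unb <- flux_table(events, "unbiased")
  rows <- lapply(max_areas, function(ma) {
    rep <- reduction_factor(unb, flux_table(events, "hooked", max_area = ma), a, b)
    tibble(
      max_area = ma, flux_ab = rep$hooked_ab, flux_ba = rep$hooked_ba,
      factor = rep$factor
    )
  })
  bind_rows(rows)
}
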