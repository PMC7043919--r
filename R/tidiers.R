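#' Tidy a knot census
#'
#' @param x A [knot_census()].
#' @param ... Unused.
#' @return A tibble with columns `gn`, `knot`, `count`, `total`, and
#'   `probability` (the occurrence probability within each grid number).
#' @method tidy knot_census
#' @export
tidy.knot_census <- function(x, ...) {
  occurrence_probabilities(x)
}

#' One-row summary of a knot census
#'
#' @param x A [knot_census()].
#' @param ... Unused.
#' @return A one-row tibble with `gn_min`, `gn_max`, `n_labels`,
#'   `n_diagrams`, and `unknot_fraction`.
#' @method glance knot_census
#' @export
glance.knot_census <- function(x, ...) {
  tibble(
    gn_min = min(x$gn), gn_max = max(x$gn),
    n_labels = length(unique(x$knot)),
    n_diagrams = sum(x$count),
    unknot_fraction = sum(x$count[x$knot == "0_1"]) / sum(x$count)
  )
}

#' Plot occurrence probabilities of a census
#'
#' Occurrence probability of each knot type as a function of the grid number,
#' on a logarithmic scale.
#'
#' @param object A [knot_census()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot knot_census
#' @export
autoplot.knot_census <- function(object, ...) {
  dat <- occurrence_probabilities(object)
  ggplot2::ggplot(
    dat,
    ggplot2::aes(x = .data$gn, y = .data$probability, colour = .data$knot)
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "grid number", y = "occurrence probability", colour = "knot",
      title = "Knot occurrence probabilities by grid number"
    )
}

#' Tidy a flux table
#'
#' @param x A [flux_table()].
#' @param ... Unused.
#' @return A tibble with `from`, `to`, `count`, plus the table's policy and
#'   area threshold as columns.
#' @method tidy flux_table
#' @export
tidy.flux_table <- function(x, ...) {
  tibble(
    from = x$from, to = x$to, count = x$count,
    policy = attr(x, "policy"), max_area = attr(x, "max_area")
  )
}

#' One-row summary of a flux table
#'
#' @param x A [flux_table()].
#' @param ... Unused.
#' @return A one-row tibble with the policy, total event count, number of
#'   type-changing events, and the maximal relative asymmetry over label
#'   pairs (0 for an exhaustive unbiased census).
#' @method glance flux_table
#' @export
glance.flux_table <- function(x, ...) {
  pairs <- unique(x[x$from != x$to, c("from", "to")])
  asym <- 0
  if (nrow(pairs) > 0) {
    rel <- vapply(seq_len(nrow(pairs)), function(i) {
      ab <- flux_count(x, pairs$from[i], pairs$to[i])
      ba <- flux_count(x, pairs$to[i], pairs$from[i])
      if (ab + ba == 0) 0 else abs(ab - ba) / (ab + ba)
    }, numeric(1))
    asym <- max(rel)
  }
  tibble(
    policy = attr(x, "policy"), max_area = attr(x, "max_area"),
    events = sum(x$count), type_changing = sum(x$count[x$from != x$to]),
    max_rel_asymmetry = asym
  )
}

#' Plot a flux table as a directed heat map
#'
#' @param object A [flux_table()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot flux_table
#' @export
autoplot.flux_table <- function(object, ...) {
  ggplot2::ggplot(
    tidy(object),
    ggplot2::aes(x = .data$to, y = .data$from, fill = log10(.data$count + 1))
  ) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), size = 3) +
    ggplot2::labs(
      x = "to knot", y = "from knot", fill = "log10(events + 1)",
      title = sprintf("Strand-passage fluxes (%s policy)", attr(object, "policy"))
    )
}

#' Tidy a reduction report
#'
#' @param x A [reduction_factor()] report.
#' @param ... Unused.
#' @return A one-row tibble.
#' @method tidy reduction_report
#' @export
tidy.reduction_report <- function(x, ...) {
  tibble(
    a = x$a, b = x$b, hooked_ab = x$hooked_ab, hooked_ba = x$hooked_ba,
    factor = x$factor, unbiased_ab = x$unbiased_ab, unbiased_ba = x$unbiased_ba,
    unbiased_ratio = x$unbiased_ratio, max_area = x$max_area
  )
}
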