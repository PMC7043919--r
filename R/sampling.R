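#' Uniformly sample a canonical single-component grid diagram
#'
#' Draws `x` uniformly from all permutations of `{0..n-1}` and an independent
#' uniform n-cycle `c`, and sets `o = c^-1(x)`, which guarantees a single
#' component and distinct markings in every column by construction (no
#' rejection step).  The canonical form is returned; uniformity on the swap
#' quotient holds because each unordered pair is produced by exactly two
#' ordered constructions.  Randomness comes from R's global generator, so
#' `set.seed()` gives reproducible draws.
#'
#' @param n Grid number, `n >= 3`.
#' @return A canonical single-component [grid_diagram()].
#' @examples
#' set.seed(1)
#' sample_grid(7)
#' @export
sample_grid <- function(n) {
  if (n < 3) {
    abort("sample_grid requires n >= 3.", class = "gridknot_bad_input")
  }
  n <- as.integer(n)
  x <- sample.int(n) - 1L
  cyc <- c(0L, sample.int(n - 1L)) # the n-cycle (0 c1 c2 ... c_{n-1})
  sinv <- integer(n) # sinv[c(j)] = previous element of the cycle
  for (j in seq_len(n)) sinv[cyc[j %% n + 1L] + 1L] <- cyc[j]
  o <- sinv[x + 1L]
  canonical_form(new_grid_diagram(x, o))
}

#' @rdname sample_grid
#' @param m Number of diagrams to draw.
#' @return `sample_grids()`: a `grid_set` of `m` canonical diagrams.
#' @export
sample_grids <- function(n, m) {
  n <- as.integer(n)
  X <- matrix(0L, nrow = m, ncol = n)
  O <- matrix(0L, nrow = m, ncol = n)
  for (k in seq_len(m)) {
    g <- sample_grid(n)
    X[k, ] <- g$x
    O[k, ] <- g$o
  }
  structure(list(x = X, o = O, n = n), class = "grid_set")
}

#' Sampled knot census at a fixed grid number
#'
#' Draws `n_samples` uniform canonical single-component diagrams of grid
#' number `gn`, identifies each with [identify_knot()], and tabulates label
#' fractions with binomial standard errors.
#'
#' @param gn Grid number.
#' @param n_samples Number of draws.
#' @param seed Root seed (mandatory for reproducibility).
#' @return A tibble with columns `gn`, `knot`, `count`, `fraction`, and `se`,
#'   plus attributes `n_samples` and `seed`.
#' @export
sampled_census <- function(gn, n_samples = 10000L, seed = 1L) {
  set.seed(seed)
  labels <- character(n_samples)
  for (k in seq_len(n_samples)) {
    labels[k] <- identify_knot(sample_grid(gn))
  }
  tab <- tibble(knot = labels) %>%
    count(.data$knot, name = "count") %>%
    mutate(
      gn = as.integer(gn),
      fraction = .data$count / n_samples,
      se = sqrt(.data$fraction * (1 - .data$fraction) / n_samples)
    ) %>%
    select("gn", "knot", "count", "fraction", "se")
  attr(tab, "n_samples") <- n_samples
  attr(tab, "seed") <- seed
  tab
}

#' Sampled strand-passage flux study
#'
#' Draws uniform diagrams at a fixed grid number, fires every passage site
#' permitted by the policy on each draw, identifies source and result knot
#' types, and accumulates an event table compatible with [flux_table()].
#' For the unbiased policy a near-symmetry diagnostic is attached: exhaustive
#' censuses are exactly symmetric, sampled tables only in expectation.
#'
#' @param gn Grid number.
#' @param n_samples Number of draws.
#' @param seed Root seed.
#' @param policy `"unbiased"` or `"hooked"`.
#' @param max_area Maximum hooked rectangle area for the hooked policy.
#' @return A tibble with the [passage_events()] columns (`gn`, `from`, `to`,
#'   `category`, `area`, `count`), attributes `n_samples`, `seed`, `policy`,
#'   and, for the unbiased policy, `asymmetry` (a tibble of relative
#'   asymmetries of off-diagonal label pairs).
#' @export
sampled_flux_study <- function(gn, n_samples = 10000L, seed = 1L,
                               policy = c("unbiased", "hooked"), max_area = 1L) {
  policy <- match.arg(policy)
  set.seed(seed)
  acc <- new.env(parent = emptyenv())
  bump <- function(from, to, category, area) {
    key <- paste(from, to, category, area, sep = "\r")
    acc[[key]] <- (if (is.null(acc[[key]])) 0 else acc[[key]]) + 1
  }
  for (k in seq_len(n_samples)) {
    g <- sample_grid(gn)
    from <- identify_knot(g)
    jux <- classify_juxtapositions(g)
    keep <- if (policy == "unbiased") {
      jux$interleaved
    } else {
      jux$class == "hooked" & !is.na(jux$area) & jux$area <= max_area
    }
    jux <- jux[keep, ]
    for (r in seq_len(nrow(jux))) {
      g2 <- commute_pair(g, jux$axis[r], jux$index[r])
      to <- identify_knot(g2)
      bump(from, to, jux$class[r], if (is.na(jux$area[r])) "NA" else jux$area[r])
    }
  }
  keys <- ls(acc)
  parts <- strsplit(keys, "\r", fixed = TRUE)
  tab <- tibble(
    gn = as.integer(gn),
    from = vapply(parts, `[`, character(1), 1),
    to = vapply(parts, `[`, character(1), 2),
    category = vapply(parts, `[`, character(1), 3),
    area = suppressWarnings(as.integer(vapply(parts, `[`, character(1), 4))),
    count = vapply(keys, function(k) acc[[k]], numeric(1))
  ) %>% arrange(.data$from, .data$to, .data$category, .data$area)
  attr(tab, "gn_range") <- c(gn, gn)
  attr(tab, "n_samples") <- n_samples
  attr(tab, "seed") <- seed
  attr(tab, "policy") <- policy
  if (policy == "unbiased") {
    f <- tab %>%
      group_by(.data$from, .data$to) %>%
      summarise(count = sum(.data$count), .groups = "drop")
    pairs <- f %>% filter(.data$from < .data$to)
    asym <- lapply(seq_len(nrow(pairs)), function(i) {
      a <- pairs$from[i]
      b <- pairs$to[i]
      ab <- sum(f$count[f$from == a & f$to == b])
      ba <- sum(f$count[f$from == b & f$to == a])
      tibble(
        from = a, to = b, ab = ab, ba = ba,
        rel_asymmetry = if (ab + ba > 0) abs(ab - ba) / (ab + ba) else 0
      )
    })
    attr(tab, "asymmetry") <- bind_rows(asym)
  }
  tab
}
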