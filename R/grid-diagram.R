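#' Construct and validate a grid diagram
#'
#' A grid diagram of grid number `n` places one X and one O marking in every
#' row and every column of an n-by-n board.  It is encoded by two permutations
#' of `{0, ..., n-1}`: `x[c]` and `o[c]` are the rows of the X and O markings
#' in column `c` (0-based, row 0 at the bottom).  Column `c` carries a vertical
#' segment between its two markings, row `r` a horizontal segment between its
#' two markings, and vertical segments always pass over horizontal ones.
#'
#' The diagram represents a knot (rather than a multi-component link) exactly
#' when the permutation sending `o[c]` to `x[c]` is a single n-cycle; the
#' number of its cycles is the number of closed components.
#'
#' @param x,o Integer vectors of equal length `n >= 2`; each must be a
#'   permutation of `0:(n-1)`, and `x[c] != o[c]` for every column.
#' @return An object of class `grid_diagram`: a list with elements `x`, `o`,
#'   `n`, and `components` (the number of closed curve components).
#' @examples
#' g <- grid_diagram(c(1, 2, 0), c(0, 1, 2))
#' g
#' component_count(g)
#' @seealso [canonical_form()], [grid_crossings()], [render_ascii()]
#' @export
grid_diagram <- function(x, o) {
  x <- check_perm(x, "x")
  o <- check_perm(o, "o")
  if (length(x) != length(o)) {
    abort("`x` and `o` must have the same length.", class = "gridknot_bad_input")
  }
  n <- length(x)
  if (n < 2) {
    abort("A grid diagram needs grid number n >= 2.", class = "gridknot_bad_input")
  }
  bad <- which(x == o)
  if (length(bad) > 0) {
    abort(
      sprintf(
        "X and O markings coincide in column %s (0-based column %d).",
        bad[1] - 1L, bad[1] - 1L
      ),
      class = c("gridknot_coincident_markings", "gridknot_bad_input")
    )
  }
  new_grid_diagram(x, o)
}

new_grid_diagram <- function(x, o) {
  structure(
    list(
      x = as.integer(x), o = as.integer(o), n = length(x),
      components = gk_component_count(as.integer(x), as.integer(o))
    ),
    class = "grid_diagram"
  )
}

check_perm <- function(v, name) {
  if (!is.numeric(v) || anyNA(v) || any(v != trunc(v))) {
    abort(sprintf("`%s` must be a vector of integers.", name),
      class = "gridknot_bad_input"
    )
  }
  v <- as.integer(v)
  n <- length(v)
  if (!identical(sort(v), 0:(n - 1))) {
    abort(
      sprintf("`%s` must be a permutation of 0:(n-1); a row is missing or used twice.", name),
      class = c("gridknot_not_a_permutation", "gridknot_bad_input")
    )
  }
  v
}

#' @export
print.grid_diagram <- function(x, ...) {
  cat(sprintf(
    "<grid_diagram> n = %d, %d component%s%s\n",
    x$n, x$components, if (x$components == 1) "" else "s",
    if (x$components == 1) " (knot)" else " (link)"
  ))
  cat(render_ascii(x), sep = "\n")
  invisible(x)
}

#' Test whether an object is a grid diagram
#' @param x Any object.
#' @return `TRUE` for `grid_diagram` objects.
#' @export
is_grid_diagram <- function(x) inherits(x, "grid_diagram")

#' Grid number (board size) of a diagram
#' @param g A [grid_diagram()].
#' @return Integer grid number `n`.
#' @export
grid_size <- function(g) {
  stopifnot(is_grid_diagram(g))
  g$n
}

#' Number of closed components of a grid diagram
#'
#' Counts the cycles of the permutation sending `o[c]` to `x[c]`.  A value of
#' 1 means the diagram is a knot; larger values mean a multi-component link.
#'
#' @param g A [grid_diagram()].
#' @return Integer component count.
#' @export
component_count <- function(g) {
  stopifnot(is_grid_diagram(g))
  g$components
}

#' @rdname component_count
#' @export
is_knot_diagram <- function(g) component_count(g) == 1L

#' Canonical form under the marking-swap quotient
#'
#' Swapping the X and O marking sets of a grid diagram produces the same curve
#' with reversed orientation, so diagrams are counted modulo this swap.  The
#' canonical representative is the lexicographically smaller of `(x, o)` and
#' `(o, x)`.  Under this quotient there are exactly `n! (n-1)! / 2` canonical
#' single-component diagrams of grid number `n`.
#'
#' @param g A [grid_diagram()].
#' @return A canonical `grid_diagram` (idempotent; swap-invariant).
#' @export
canonical_form <- function(g) {
  stopifnot(is_grid_diagram(g))
  key_x <- g$x
  key_o <- g$o
  if (lex_leq(key_o, key_x) && !identical(key_o, key_x)) {
    new_grid_diagram(key_o, key_x)
  } else {
    g
  }
}

#' @rdname canonical_form
#' @export
is_canonical <- function(g) {
  stopifnot(is_grid_diagram(g))
  lex_leq(g$x, g$o)
}

lex_leq <- function(a, b) {
  d <- a - b
  i <- which(d != 0)
  if (length(i) == 0) {
    return(TRUE)
  }
  d[i[1]] < 0
}

#' Crossings of a grid diagram
#'
#' A crossing occurs wherever a vertical segment's open row interval contains
#' the row of a horizontal segment whose open column interval contains the
#' vertical segment's column.  The vertical segment is always the overpass.
#'
#' @param g A [grid_diagram()].
#' @return A tibble with integer columns `col` (column of the vertical,
#'   overpassing segment) and `row` (row of the horizontal segment), one row
#'   per crossing.
#' @export
grid_crossings <- function(g) {
  stopifnot(is_grid_diagram(g))
  m <- gk_crossings(g$x, g$o)
  tibble(col = as.integer(m[, 1]), row = as.integer(m[, 2]))
}

#' Mirror image of a grid diagram
#'
#' Reflecting the board left to right (reversing the column order) reverses
#' the orientation of the plane while keeping vertical segments vertical, so
#' the overpass convention is untouched and every crossing changes sign: the
#' result is a diagram of the mirror-image knot.  (Transposing the board is
#' *not* a mirror: it also exchanges which strand is on top, and the two
#' reversals cancel.)
#'
#' @param g A [grid_diagram()].
#' @return A `grid_diagram` of the mirror knot.
#' @export
mirror_grid <- function(g) {
  stopifnot(is_grid_diagram(g))
  new_grid_diagram(rev(g$x), rev(g$o))
}

#' Cyclic translation of rows or columns
#'
#' Moving the outermost line of the board to the opposite side (a toroidal
#' translation) is a knot-preserving grid move.
#'
#' @param g A [grid_diagram()].
#' @param k Integer shift (any sign).
#' @param axis `"column"` or `"row"`.
#' @return A translated `grid_diagram` of the same knot type.
#' @export
cyclic_translate <- function(g, k = 1L, axis = c("column", "row")) {
  stopifnot(is_grid_diagram(g))
  axis <- match.arg(axis)
  n <- g$n
  k <- ((as.integer(k) %% n) + n) %% n
  if (axis == "column") {
    idx <- ((0:(n - 1L) + k) %% n) + 1L
    new_grid_diagram(g$x[idx], g$o[idx])
  } else {
    new_grid_diagram((g$x + k) %% n, (g$o + k) %% n)
  }
}

#' Connected sum of two grid diagrams
#'
#' Builds a grid diagram of the connected sum of two knots by the corner-merge
#' construction: the first diagram is cyclically translated so that an X
#' marking sits in its top-right corner, the second so that an O marking sits
#' in its bottom-left corner; the boards are overlaid on that shared corner
#' cell, the two corner markings are deleted, and the merged row and column
#' each keep exactly one marking from each summand.  The result has grid
#' number `n1 + n2 - 1`.
#'
#' @param g1,g2 Single-component [grid_diagram()]s.
#' @return A `grid_diagram` of the connected sum.
#' @export
grid_connected_sum <- function(g1, g2) {
  stopifnot(is_grid_diagram(g1), is_grid_diagram(g2))
  if (!is_knot_diagram(g1) || !is_knot_diagram(g2)) {
    abort("Connected sum requires single-component diagrams.",
      class = "gridknot_multi_component"
    )
  }
  n1 <- g1$n
  n2 <- g2$n
  # put g1's X marking at the top-right corner
  c1 <- which(g1$x == n1 - 1L) - 1L
  g1 <- cyclic_translate(g1, c1 + 1L, "column")
  # put g2's O marking at the bottom-left corner
  c2 <- which(g2$o == 0L) - 1L
  g2 <- cyclic_translate(g2, c2, "column")
  n <- n1 + n2 - 1L
  x <- integer(n)
  o <- integer(n)
  # columns 0 .. n1-2: from g1 unchanged
  x[1:(n1 - 1L)] <- g1$x[1:(n1 - 1L)]
  o[1:(n1 - 1L)] <- g1$o[1:(n1 - 1L)]
  # merged column n1-1: g1's O plus g2's X (corner X of g1 and O of g2 deleted)
  x[n1] <- g2$x[1] + n1 - 1L
  o[n1] <- g1$o[n1]
  # columns n1 .. n-1: from g2 shifted up/right by n1-1
  if (n2 > 1) {
    x[(n1 + 1L):n] <- g2$x[2:n2] + n1 - 1L
    o[(n1 + 1L):n] <- g2$o[2:n2] + n1 - 1L
  }
  grid_diagram(x, o)
}

#' Render a grid diagram as fixed-width ASCII art
#'
#' Rows are printed top (row `n-1`) to bottom (row 0).  `X` and `O` mark the
#' markings, `|` and `-` the vertical and horizontal segments (`|` shown at
#' crossings, since vertical segments overpass), and `.` empty cells.
#' [parse_ascii()] inverts the rendering.
#'
#' @param g A [grid_diagram()].
#' @return A character vector of `n` lines.
#' @export
render_ascii <- function(g) {
  stopifnot(is_grid_diagram(g))
  n <- g$n
  cells <- matrix(".", nrow = n, ncol = n) # [row + 1, col + 1]
  for (c in 0:(n - 1L)) {
    lo <- min(g$x[c + 1L], g$o[c + 1L])
    hi <- max(g$x[c + 1L], g$o[c + 1L])
    if (hi - lo > 1L) cells[(lo + 2L):hi, c + 1L] <- "|"
  }
  xcol <- integer(n)
  ocol <- integer(n)
  xcol[g$x + 1L] <- 0:(n - 1L)
  ocol[g$o + 1L] <- 0:(n - 1L)
  for (r in 0:(n - 1L)) {
    lo <- min(xcol[r + 1L], ocol[r + 1L])
    hi <- max(xcol[r + 1L], ocol[r + 1L])
    if (hi - lo > 1L) {
      seg <- (lo + 2L):hi
      horiz <- cells[r + 1L, seg] == "."
      cells[r + 1L, seg[horiz]] <- "-"
    }
  }
  for (c in 0:(n - 1L)) {
    cells[g$x[c + 1L] + 1L, c + 1L] <- "X"
    cells[g$o[c + 1L] + 1L, c + 1L] <- "O"
  }
  vapply(n:1, function(r) paste(cells[r, ], collapse = " "), character(1))
}

#' Parse the ASCII rendering of a grid diagram
#'
#' @param lines Character vector as produced by [render_ascii()].
#' @return A [grid_diagram()] with `parse_ascii(render_ascii(g))` equal to `g`.
#' @export
parse_ascii <- function(lines) {
  n <- length(lines)
  x <- rep(NA_integer_, n)
  o <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    r <- n - i # line 1 is the top row n-1
    ch <- strsplit(gsub(" ", "", lines[i]), "")[[1]]
    if (length(ch) != n) {
      abort("ASCII grid is not square.", class = "gridknot_bad_input")
    }
    for (c in seq_len(n)) {
      if (ch[c] == "X") x[c] <- r
      if (ch[c] == "O") o[c] <- r
    }
  }
  if (anyNA(x) || anyNA(o)) {
    abort("ASCII grid is missing X or O markings.", class = "gridknot_bad_input")
  }
  grid_diagram(x, o)
}

#' String form of a grid diagram
#'
#' The compact CLI string form is `"x=1,2,0;o=0,1,2"`.
#'
#' @param g A [grid_diagram()].
#' @return A single string.
#' @export
grid_to_string <- function(g) {
  stopifnot(is_grid_diagram(g))
  sprintf(
    "x=%s;o=%s",
    paste(g$x, collapse = ","), paste(g$o, collapse = ",")
  )
}

#' @rdname grid_to_string
#' @param s A string of the form `"x=...;o=..."`.
#' @export
grid_from_string <- function(s) {
  m <- regmatches(s, regexec("^x=([0-9,]+);o=([0-9,]+)$", s))[[1]]
  if (length(m) != 3) {
    abort("Grid string must look like \"x=1,2,0;o=0,1,2\".",
      class = "gridknot_bad_input"
    )
  }
  grid_diagram(
    as.integer(strsplit(m[2], ",")[[1]]),
    as.integer(strsplit(m[3], ",")[[1]])
  )
}
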