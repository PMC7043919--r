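#' Convert a grid diagram to a planar diagram (PD)
#'
#' Traverses the knot (vertical segments from X to O, horizontal segments from
#' O to X) and records, for every crossing, the four incident edge identifiers
#' in counterclockwise rotational order starting from the incoming under-edge,
#' together with the crossing sign.  Edges are the arcs between consecutive
#' crossing passages along the knot; each edge identifier appears exactly
#' twice.  Vertical segments are always the over-strand.
#'
#' @param g A single-component [grid_diagram()].
#' @return An object of class `planar_diagram`: a tibble with one row per
#'   crossing and columns `crossing`, `a`, `b`, `c`, `d` (edge ids, CCW from
#'   the incoming under-edge; `a`/`c` under, `b`/`d` over) and `sign`
#'   (+1 or -1), with attributes `n_edges` and `writhe`.
#' @export
to_planar_diagram <- function(g) {
  stopifnot(is_grid_diagram(g))
  if (!is_knot_diagram(g)) {
    abort("Planar-diagram conversion requires a single-component grid.",
      class = "gridknot_multi_component"
    )
  }
  n <- g$n
  cr <- as_tibble(gk_crossings(g$x, g$o))
  nc <- nrow(cr)
  empty <- tibble(
    crossing = integer(0), a = integer(0), b = integer(0),
    c = integer(0), d = integer(0), sign = integer(0)
  )
  if (nc == 0) {
    return(structure(empty, n_edges = 0L, writhe = 0L,
      class = c("planar_diagram", class(empty))
    ))
  }
  xcol <- integer(n)
  ocol <- integer(n)
  xcol[g$x + 1L] <- 0:(n - 1L)
  ocol[g$o + 1L] <- 0:(n - 1L)
  # passages in traversal order: one row per crossing passage
  pass_cross <- integer(0) # crossing id
  pass_over <- logical(0) # TRUE if this passage is the over (vertical) strand
  pass_dir <- integer(0) # +1 up/right, -1 down/left
  col <- 0L
  repeat {
    # vertical segment of column `col`, X -> O
    dy <- if (g$o[col + 1L] > g$x[col + 1L]) 1L else -1L
    vc <- which(cr$col == col)
    if (length(vc) > 0) {
      vc <- vc[order(cr$row[vc], decreasing = dy < 0)]
      pass_cross <- c(pass_cross, vc)
      pass_over <- c(pass_over, rep(TRUE, length(vc)))
      pass_dir <- c(pass_dir, rep(dy, length(vc)))
    }
    # horizontal segment of row o[col], O -> X
    r <- g$o[col + 1L]
    nxt <- xcol[r + 1L]
    dx <- if (nxt > col) 1L else -1L
    hr <- which(cr$row == r)
    if (length(hr) > 0) {
      hr <- hr[order(cr$col[hr], decreasing = dx < 0)]
      pass_cross <- c(pass_cross, hr)
      pass_over <- c(pass_over, rep(FALSE, length(hr)))
      pass_dir <- c(pass_dir, rep(dx, length(hr)))
    }
    col <- nxt
    if (col == 0L) break
  }
  np <- length(pass_cross) # = 2 * nc
  # edge j (1-based) runs from passage j to passage (j mod np) + 1
  in_edge <- c(np, seq_len(np - 1L)) # edge arriving at passage j
  out_edge <- seq_len(np) # edge leaving passage j
  rows <- vector("list", nc)
  for (k in seq_len(nc)) {
    ju <- which(pass_cross == k & !pass_over)
    jo <- which(pass_cross == k & pass_over)
    dx <- pass_dir[ju]
    dyo <- pass_dir[jo]
    # stub angles around the crossing: under-in opposite under-out, etc.
    stubs <- c(
      under_in = atan2(0, -dx), under_out = atan2(0, dx),
      over_in = atan2(-dyo, 0), over_out = atan2(dyo, 0)
    )
    edges <- c(
      under_in = in_edge[ju], under_out = out_edge[ju],
      over_in = in_edge[jo], over_out = out_edge[jo]
    )
    rel <- (stubs - stubs[["under_in"]]) %% (2 * pi)
    ccw <- edges[order(rel)]
    rows[[k]] <- tibble(
      crossing = k, a = ccw[[1]], b = ccw[[2]], c = ccw[[3]], d = ccw[[4]],
      sign = if (dx == dyo) 1L else -1L
    )
  }
  pd <- bind_rows(rows)
  structure(pd, n_edges = np, writhe = sum(pd$sign),
    class = c("planar_diagram", class(pd))
  )
}

#' Laurent polynomial helper
#'
#' Internal light-weight representation: list(tmin = lowest exponent,
#' coeffs = integer coefficients from tmin upward, trailing/leading zeros
#' stripped).
#' @noRd
laurent <- function(tmin, coeffs) {
  nz <- which(coeffs != 0)
  if (length(nz) == 0) {
    return(list(tmin = 0L, coeffs = 0))
  }
  list(
    tmin = as.integer(tmin + nz[1] - 1L),
    coeffs = as.numeric(coeffs[nz[1]:nz[length(nz)]])
  )
}

laurent_mirror <- function(p) {
  laurent(-(p$tmin + length(p$coeffs) - 1L), rev(p$coeffs))
}

laurent_string <- function(p) {
  paste0("t^", p$tmin, ":", paste(p$coeffs, collapse = ","))
}

#' Mirror-normalize a Laurent polynomial
#'
#' Returns the canonical representative of `{V(t), V(1/t)}` (the
#' lexicographically smaller encoding), so that a knot and its mirror image
#' produce identical output.
#' @noRd
laurent_mirror_normalize <- function(p) {
  q <- laurent_mirror(p)
  if (laurent_string(q) < laurent_string(p)) q else p
}

#' Jones polynomial of a planar diagram (mirror-normalized)
#'
#' Computes the Kauffman bracket by the 2^c state sum over the planar
#' diagram's edges, applies the writhe correction, substitutes `t = A^-4`,
#' and mirror-normalizes the result (canonical representative of
#' `{V(t), V(1/t)}`), so left- and right-handed versions of a knot give the
#' same polynomial.  This pure-R evaluation is independent of the compiled
#' grid-based implementation used by [jones_poly()] and serves as its
#' cross-check oracle.
#'
#' @param pd A [to_planar_diagram()] result.
#' @param max_crossings Refuse diagrams with more crossings than this
#'   (the state sum is exponential).
#' @return A list with `tmin` (lowest exponent), `coeffs` (integer
#'   coefficients from `tmin` upward), and `ok` (`FALSE` when the crossing
#'   bound was exceeded; other fields are then absent).
#' @export
jones_normalized <- function(pd, max_crossings = 14L) {
  stopifnot(inherits(pd, "planar_diagram"))
  nc <- nrow(pd)
  if (nc == 0) {
    return(list(tmin = 0L, coeffs = 1, ok = TRUE))
  }
  if (nc > max_crossings) {
    return(list(ok = FALSE))
  }
  np <- attr(pd, "n_edges")
  w <- attr(pd, "writhe")
  # bracket coefficients over powers of A, offset so index 1 is A^(-3*nc - 2*nc)
  off <- 3L * nc + 2L * nc
  bracket <- numeric(2L * off + 1L)
  for (st in 0:(2^nc - 1L)) {
    parent <- seq_len(np)
    find <- function(v) {
      while (parent[v] != v) v <- parent[v]
      v
    }
    na <- 0L
    for (k in seq_len(nc)) {
      if (bitwAnd(st, bitwShiftL(1L, k - 1L)) != 0L) {
        na <- na + 1L
        p1 <- c(pd$a[k], pd$d[k])
        p2 <- c(pd$b[k], pd$c[k])
      } else {
        p1 <- c(pd$a[k], pd$b[k])
        p2 <- c(pd$c[k], pd$d[k])
      }
      r1 <- find(p1[1])
      r2 <- find(p1[2])
      if (r1 != r2) parent[r1] <- r2
      r1 <- find(p2[1])
      r2 <- find(p2[2])
      if (r1 != r2) parent[r1] <- r2
    }
    loops <- sum(vapply(seq_len(np), function(v) find(v) == v, logical(1)))
    e <- 2L * na - nc # (#A) - (#B)
    L <- loops - 1L # bracket gets delta^L, delta = -A^2 - A^-2
    for (j in 0:L) {
      expo <- e + 2L * L - 4L * j
      coefd <- choose(L, j) * (-1)^L
      bracket[expo + off + 1L] <- bracket[expo + off + 1L] + coefd
    }
  }
  # V(A) = (-A)^(-3w) * bracket, then t = A^(-4)
  sgn <- if (w %% 2 == 0) 1 else -1
  idx <- which(bracket != 0)
  aexp <- idx - 1L - off - 3L * w
  if (any(aexp %% 4L != 0L)) {
    abort("internal error: bracket exponent not divisible by 4")
  }
  texp <- -aexp %/% 4L
  ord <- order(texp)
  texp <- texp[ord]
  vals <- sgn * bracket[idx][ord]
  coeffs <- numeric(texp[length(texp)] - texp[1] + 1L)
  coeffs[texp - texp[1] + 1L] <- vals
  p <- laurent_mirror_normalize(laurent(texp[1], coeffs))
  list(tmin = p$tmin, coeffs = p$coeffs, ok = TRUE)
}

#' Alexander polynomial from a planar diagram (independent oracle)
#'
#' Builds the Alexander matrix from the diagram's Wirtinger presentation (one
#' row per crossing over the under-arc generators), deletes one row and one
#' column, and takes the determinant by fraction-free (Bareiss) elimination
#' over integer polynomials.  The result is normalized like
#' [alexander_poly()]: symmetric in `t <-> 1/t` with `Delta(1) = 1`.  This
#' construction shares no code with the winding-matrix method and is used to
#' cross-validate it.
#'
#' @param pd A [to_planar_diagram()] result.
#' @return A list with `coeffs` (centered coefficient vector, constant term in
#'   the middle) and `ok`.
#' @export
alexander_from_pd <- function(pd) {
  stopifnot(inherits(pd, "planar_diagram"))
  nc <- nrow(pd)
  if (nc == 0) {
    return(list(coeffs = 1, ok = TRUE))
  }
  np <- attr(pd, "n_edges")
  # under-arcs: maximal edge runs between under-passages.  Edge e belongs to
  # the arc that ends at the under-passage it feeds.  Arc id of an edge =
  # id of the next under-passage reached by following edges forward.
  # Edge j runs from passage j to passage (j mod np)+1; an edge "stops" when
  # its head passage is an under-passage.
  # head passage of edge j is (j mod np) + 1; for crossing k the head of its
  # under-in edge `a` is the under-passage of crossing k.
  arc_of <- integer(np)
  head_is_under <- logical(np)
  head_is_under[pd$a] <- TRUE
  # walk forward assigning arcs
  arc <- 0L
  # order edges along the traversal: edge j+1 follows edge j
  start <- pd$a[1] # an edge ending at an under-passage
  j <- (start %% np) + 1L
  repeat {
    arc <- arc + 1L
    repeat {
      arc_of[j] <- arc
      stop_here <- head_is_under[j]
      j <- (j %% np) + 1L
      if (stop_here) break
    }
    if (j == (start %% np) + 1L) break
  }
  n_arcs <- arc
  if (n_arcs != nc) {
    abort("internal error: arc count != crossing count")
  }
  # Wirtinger/Fox row per crossing: under-in arc i, under-out arc j, over
  # arc k.  Positive crossing: t*x_i - x_j + (1 - t)*x_k = 0;
  # negative: x_i - t*x_j + (t - 1)*x_k ... conventions differ by units only;
  # we use rows invariant-correct up to +-t^m, which normalization removes.
  # Entries are degree<=1 integer polynomials c0 + c1 t, stored as 2-vectors.
  m <- nc
  M0 <- matrix(0, m, m) # constant parts
  M1 <- matrix(0, m, m) # t parts
  for (k in seq_len(m)) {
    ai <- arc_of[pd$a[k]]
    aj <- arc_of[pd$c[k]]
    ak <- arc_of[pd$b[k]] # over edges b/d share an arc
    if (pd$sign[k] > 0) {
      M1[k, ai] <- M1[k, ai] + 1
      M0[k, aj] <- M0[k, aj] - 1
      M0[k, ak] <- M0[k, ak] + 1
      M1[k, ak] <- M1[k, ak] - 1
    } else {
      M0[k, ai] <- M0[k, ai] + 1
      M1[k, aj] <- M1[k, aj] - 1
      M0[k, ak] <- M0[k, ak] - 1
      M1[k, ak] <- M1[k, ak] + 1
    }
  }
  if (m == 1) {
    return(list(coeffs = 1, ok = TRUE))
  }
  # delete last row and column; Bareiss over polynomial entries
  A <- vector("list", (m - 1L)^2)
  dim(A) <- c(m - 1L, m - 1L)
  for (i in seq_len(m - 1L)) {
    for (jx in seq_len(m - 1L)) A[[i, jx]] <- c(M0[i, jx], M1[i, jx])
  }
  det_poly <- bareiss_poly_det(A)
  normalize_alexander(det_poly)
}

# multiply two integer polynomials (coefficient vectors, constant first)
poly_mul <- function(p, q) {
  if (length(p) == 0 || length(q) == 0) {
    return(0)
  }
  out <- numeric(length(p) + length(q) - 1L)
  for (i in seq_along(p)) {
    if (p[i] != 0) {
      idx <- i:(i + length(q) - 1L)
      out[idx] <- out[idx] + p[i] * q
    }
  }
  out
}

poly_sub <- function(p, q) {
  n <- max(length(p), length(q))
  pp <- c(p, numeric(n - length(p)))
  qq <- c(q, numeric(n - length(q)))
  pp - qq
}

poly_trim <- function(p) {
  nz <- which(p != 0)
  if (length(nz) == 0) {
    return(numeric(0))
  }
  p[1:nz[length(nz)]]
}

# exact division of integer polynomials (remainder must vanish)
poly_div_exact <- function(p, d) {
  p <- poly_trim(p)
  d <- poly_trim(d)
  if (length(p) == 0) {
    return(numeric(0))
  }
  if (length(d) == 0) abort("polynomial division by zero")
  q <- numeric(length(p) - length(d) + 1L)
  r <- p
  for (k in length(q):1) {
    lead <- if (length(r) >= k + length(d) - 1L) r[k + length(d) - 1L] else 0
    cq <- lead / d[length(d)]
    if (cq != trunc(cq)) abort("non-exact polynomial division in Bareiss step")
    q[k] <- cq
    if (cq != 0) {
      idx <- k:(k + length(d) - 1L)
      r[idx] <- r[idx] - cq * d
    }
  }
  if (any(abs(poly_trim(r)) > 1e-9)) abort("non-zero remainder in Bareiss step")
  q
}

# fraction-free determinant of a matrix of integer polynomials
bareiss_poly_det <- function(A) {
  m <- nrow(A)
  sign <- 1
  prev <- 1
  for (k in seq_len(m - 1L)) {
    if (length(poly_trim(A[[k, k]])) == 0) {
      piv <- NULL
      for (r in (k + 1L):m) {
        if (length(poly_trim(A[[r, k]])) > 0) {
          piv <- r
          break
        }
      }
      if (is.null(piv)) {
        return(numeric(0))
      }
      tmp <- A[k, ]
      A[k, ] <- A[piv, ]
      A[piv, ] <- tmp
      sign <- -sign
    }
    for (i in (k + 1L):m) {
      for (j in (k + 1L):m) {
        num <- poly_sub(
          poly_mul(A[[k, k]], A[[i, j]]),
          poly_mul(A[[i, k]], A[[k, j]])
        )
        A[[i, j]] <- poly_div_exact(num, prev)
      }
      A[[i, k]] <- 0
    }
    prev <- A[[k, k]]
  }
  out <- poly_trim(A[[m, m]])
  if (sign < 0) out <- -out
  out
}

# normalize a raw Alexander determinant (+- t^m Delta(t)) to the centered
# symmetric form with Delta(1) = 1
normalize_alexander <- function(p) {
  p <- poly_trim(p)
  if (length(p) == 0) {
    return(list(coeffs = numeric(0), ok = FALSE))
  }
  nzlo <- which(p != 0)[1]
  c <- p[nzlo:length(p)]
  ok <- length(c) %% 2 == 1
  if (any(c != rev(c))) ok <- FALSE
  s <- sum(c)
  if (s == -1) {
    c <- -c
    s <- 1
  }
  if (s != 1) ok <- FALSE
  list(coeffs = c, ok = ok)
}
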