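# Shared lazily-computed fixtures, memoized for the duration of the test run
# so the heavy exhaustive scans are performed at most once each.

.shared <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.shared[[key]])) .shared[[key]] <- force(expr)
  .shared[[key]]
}

census_37 <- function() memo("census_37", knot_census(3, 7))
events_57 <- function() memo("events_57", passage_events(5, 7))
grids_5 <- function() memo("grids_5", enumerate_grids(5))

# one fixed minimal trefoil diagram (verified in tests by its invariants)
trefoil_5 <- function() {
  memo("trefoil_5", {
    gs <- grids_5()
    for (i in seq_len(grid_set_size(gs))) {
      g <- grid_at(gs, i)
      if (knot_determinant(g) == 3) {
        return(g)
      }
    }
    stop("no trefoil found at GN 5")
  })
}

unknot_3 <- function() grid_diagram(c(1, 2, 0), c(0, 1, 2))

random_valid_grid <- function(n) {
  # a not-necessarily-single-component random grid (for constructor tests)
  repeat {
    x <- sample.int(n) - 1L
    o <- sample.int(n) - 1L
    if (all(x != o)) {
      return(grid_diagram(x, o))
    }
  }
}
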