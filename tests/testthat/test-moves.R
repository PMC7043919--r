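test_that("interleaving detection matches the interval-overlap definition", {
  set.seed(5)
  for (k in 1:30) {
    g <- random_valid_grid(6)
    for (axis in c("column", "row")) {
      for (i in 0:(g$n - 2L)) {
        # reference implementation straight from the definition
        if (axis == "column") {
          a <- sort(c(g$x[i + 1L], g$o[i + 1L]))
          b <- sort(c(g$x[i + 2L], g$o[i + 2L]))
        } else {
          xc <- order(g$x) - 1L
          oc <- order(g$o) - 1L
          a <- sort(c(xc[i + 1L], oc[i + 1L]))
          b <- sort(c(xc[i + 2L], oc[i + 2L]))
        }
        distinct <- length(unique(c(a, b))) == 4
        nested <- (a[1] < b[1] && b[2] < a[2]) || (b[1] < a[1] && a[2] < b[2])
        disjoint <- a[2] < b[1] || b[2] < a[1]
        expect_identical(
          interleaved(g, axis, i),
          distinct && !nested && !disjoint
        )
      }
    }
  }
})

test_that("commutation is an involution with class-determined crossing change", {
  set.seed(17)
  for (k in 1:40) {
    g <- canonical_form(sample_grid(6))
    jux <- classify_juxtapositions(g)
    jux <- jux[jux$interleaved, ]
    for (r in seq_len(nrow(jux))) {
      g2 <- commute_pair(g, jux$axis[r], jux$index[r])
      expect_identical(grid_size(g2), grid_size(g))
      # involution
      g3 <- commute_pair(g2, jux$axis[r], jux$index[r])
      expect_identical(g3$x, g$x)
      expect_identical(g3$o, g$o)
      # the two arcs cross twice (hooked), once on each side (mixed), or not
      # at all (free): the passage changes the crossing count by -2, 0, +2
      delta <- nrow(grid_crossings(g2)) - nrow(grid_crossings(g))
      expected <- switch(jux$class[r], hooked = -2L, mixed = 0L, free = 2L)
      expect_identical(delta, expected)
    }
  }
})

test_that("commuting a non-interleaved pair preserves the knot type", {
  set.seed(19)
  checked <- 0
  for (k in 1:50) {
    g <- canonical_form(sample_grid(6))
    a <- alexander_poly(g)$coeffs
    jux <- classify_juxtapositions(g)
    ni <- jux[!jux$interleaved, ]
    for (r in seq_len(nrow(ni))) {
      g2 <- commute_pair(g, ni$axis[r], ni$index[r])
      expect_identical(alexander_poly(g2)$coeffs, a)
      checked <- checked + 1
    }
    if (checked >= 40) break
  }
  expect_gte(checked, 40)
  expect_error(commute_pair(unknot_3(), "column", 99L),
    class = "gridknot_bad_input"
  )
})

test_that("juxtaposition classes are exclusive, exhaustive, and area-consistent", {
  set.seed(23)
  for (k in 1:30) {
    g <- canonical_form(sample_grid(7))
    jux <- classify_juxtapositions(g)
    expect_identical(nrow(jux), 2L * (7L - 1L))
    expect_true(all(jux$class[jux$interleaved] %in% c("free", "mixed", "hooked")))
    expect_true(all(jux$class[!jux$interleaved] == "not-interleaved"))
    expect_true(all(is.na(jux$area) | jux$class == "hooked"))
    expect_true(all(jux$area[jux$class == "hooked"] >= 1))
    expect_identical(
      jux$strongly_hooked,
      !is.na(jux$area) & jux$area == 1L & jux$class == "hooked"
    )
  }
})

test_that("a strongly hooked site is no longer hooked after its passage", {
  set.seed(29)
  checked <- 0
  for (k in 1:800) {
    g <- canonical_form(sample_grid(6))
    jux <- classify_juxtapositions(g)
    hs <- jux[jux$strongly_hooked %in% TRUE, ]
    for (r in seq_len(nrow(hs))) {
      g2 <- commute_pair(g, hs$axis[r], hs$index[r])
      cls <- classify_juxtaposition(g2, hs$axis[r], hs$index[r])
      expect_false(identical(cls$class, "hooked"))
      checked <- checked + 1
    }
    if (checked >= 50) break
  }
  expect_gte(checked, 50)
})

test_that("passage_sites honours the policy", {
  set.seed(37)
  g <- canonical_form(sample_grid(7))
  s_unb <- passage_sites(g, "unbiased")
  s_hook <- passage_sites(g, "hooked", max_area = 1)
  jux <- classify_juxtapositions(g)
  expect_identical(nrow(s_unb), sum(jux$interleaved))
  expect_identical(
    nrow(s_hook),
    sum(jux$strongly_hooked %in% TRUE)
  )
  expect_true(all(s_hook$class == "hooked"))
})

test_that("destabilization shrinks the grid and preserves the knot type", {
  tre <- trefoil_5()
  big <- grid_connected_sum(tre, unknot_3()) # GN 7 trefoil with slack
  expect_identical(grid_size(big), 7L)
  expect_identical(alexander_poly(big)$coeffs, alexander_poly(tre)$coeffs)
  d <- destabilize_once(big)
  expect_false(is.null(d))
  expect_identical(grid_size(d), 6L)
  expect_identical(alexander_poly(d)$coeffs, alexander_poly(tre)$coeffs)
})

test_that("simplify_grid reaches minimal forms and never changes the knot", {
  # the staircase unknot is already minimal at GN 2 or 3
  s <- simplify_grid(unknot_3())
  expect_lte(grid_size(s), 3L)
  # trefoil cannot simplify below its arc index 5
  tre <- trefoil_5()
  s2 <- simplify_grid(grid_connected_sum(tre, unknot_3()))
  expect_identical(grid_size(s2), 5L)
  expect_identical(alexander_poly(s2)$coeffs, alexander_poly(tre)$coeffs)
  # randomized: invariants preserved, size non-increasing, deterministic
  set.seed(41)
  for (k in 1:25) {
    g <- canonical_form(sample_grid(8))
    a <- alexander_poly(g)$coeffs
    s <- simplify_grid(g)
    expect_lte(grid_size(s), grid_size(g))
    expect_identical(alexander_poly(s)$coeffs, a)
    s_again <- simplify_grid(g)
    expect_identical(s_again$x, s$x)
    expect_identical(s_again$o, s$o)
  }
})
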