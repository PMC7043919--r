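test_that("constructor validates permutations and marking separation", {
  g <- grid_diagram(c(1, 2, 0), c(0, 1, 2))
  expect_s3_class(g, "grid_diagram")
  expect_identical(grid_size(g), 3L)
  expect_true(is_knot_diagram(g))

  expect_error(grid_diagram(c(1, 1, 0), c(0, 1, 2)),
    class = "gridknot_not_a_permutation"
  )
  expect_error(grid_diagram(c(0, 1, 2), c(0, 2, 1)),
    class = "gridknot_coincident_markings"
  )
  expect_error(grid_diagram(c(1, 0), c(0, 1, 2)), class = "gridknot_bad_input")
  expect_error(grid_diagram(c(0), c(0)), class = "gridknot_bad_input")
  # both specific classes are also usage errors
  expect_error(grid_diagram(c(1, 1, 0), c(0, 1, 2)), class = "gridknot_bad_input")
})

test_that("component count distinguishes knots from links", {
  expect_identical(component_count(unknot_3()), 1L)
  # x == o + 1 shifted: two-component example at n = 4
  g <- grid_diagram(c(1, 0, 3, 2), c(0, 1, 2, 3))
  expect_identical(component_count(g), 2L)
  expect_false(is_knot_diagram(g))
})

test_that("canonical form is the lex-min of the swap pair and idempotent", {
  set.seed(101)
  for (k in 1:50) {
    g <- random_valid_grid(6)
    cg <- canonical_form(g)
    expect_true(is_canonical(cg))
    expect_identical(canonical_form(cg), cg)
    # swapping x and o gives the same canonical form
    swapped <- grid_diagram(g$o, g$x)
    expect_identical(canonical_form(swapped), cg)
    # canonical form is one of the two representatives
    expect_true(
      (identical(cg$x, g$x) && identical(cg$o, g$o)) ||
        (identical(cg$x, g$o) && identical(cg$o, g$x))
    )
  }
})

test_that("crossings: vertical strand must span the horizontal's row strictly inside", {
  # trefoil standard GN-5 diagram has known crossing count >= 3
  tre <- trefoil_5()
  cr <- grid_crossings(tre)
  expect_true(nrow(cr) >= 3)
  expect_true(all(cr$col >= 0 & cr$col < 5 & cr$row >= 0 & cr$row < 5))
  # unknot at GN 3 in staircase form has no crossings
  expect_identical(nrow(grid_crossings(unknot_3())), 0L)
})

test_that("mirror reverses chirality but preserves mirror-lumped invariants", {
  tre <- trefoil_5()
  m <- mirror_grid(tre)
  expect_identical(alexander_poly(m)$coeffs, alexander_poly(tre)$coeffs)
  expect_identical(knot_determinant(m), knot_determinant(tre))
  # raw (non-normalized) Jones of the two chiralities must differ,
  # normalized must agree
  jr <- gridknot:::gk_jones(tre$x, tre$o, 16L)
  jm <- gridknot:::gk_jones(m$x, m$o, 16L)
  expect_false(identical(
    list(jr$tmin, as.numeric(jr$coeffs)),
    list(jm$tmin, as.numeric(jm$coeffs))
  ))
  expect_identical(jones_poly(m)$coeffs, jones_poly(tre)$coeffs)
  # involution
  expect_identical(mirror_grid(m)$x, tre$x)
  expect_identical(mirror_grid(m)$o, tre$o)
})

test_that("cyclic translation preserves knot type and grid size", {
  tre <- trefoil_5()
  for (axis in c("column", "row")) {
    for (k in 1:4) {
      g2 <- cyclic_translate(tre, k, axis)
      expect_identical(grid_size(g2), 5L)
      expect_identical(alexander_poly(g2)$coeffs, alexander_poly(tre)$coeffs)
    }
  }
})

test_that("connected sum adds grid numbers minus one and multiplies Alexander", {
  tre <- trefoil_5()
  s <- grid_connected_sum(tre, tre)
  expect_identical(grid_size(s), 9L)
  expect_true(is_knot_diagram(s))
  # Delta(3_1 # 3_1) = Delta(3_1)^2 = (t - 1 + 1/t)^2 = t^2 - 2t + 3 - 2/t + 1/t^2
  expect_identical(alexander_poly(s)$coeffs, c(1, -2, 3, -2, 1))
  expect_identical(knot_determinant(s), 9)
})

test_that("ASCII rendering round-trips", {
  set.seed(7)
  for (k in 1:20) {
    g <- random_valid_grid(7)
    txt <- render_ascii(g)
    g2 <- parse_ascii(txt)
    expect_identical(g2$x, g$x)
    expect_identical(g2$o, g$o)
  }
})

test_that("string form round-trips and rejects malformed input", {
  g <- trefoil_5()
  s <- grid_to_string(g)
  g2 <- grid_from_string(s)
  expect_identical(g2$x, g$x)
  expect_identical(g2$o, g$o)
  expect_error(grid_from_string("x=1,2,0"), class = "gridknot_bad_input")
  expect_error(grid_from_string("nonsense"), class = "gridknot_bad_input")
})

test_that("print method runs without error", {
  expect_output(print(unknot_3()), "grid_diagram")
})
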