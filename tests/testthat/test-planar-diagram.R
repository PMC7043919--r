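test_that("planar diagram structure is well formed", {
  tre <- trefoil_5()
  pd <- to_planar_diagram(tre)
  expect_s3_class(pd, "planar_diagram")
  nc <- nrow(pd)
  expect_identical(nrow(grid_crossings(tre)), nc)
  np <- attr(pd, "n_edges")
  expect_identical(np, 2L * nc)
  # every edge id appears exactly twice across the a, b, c, d slots
  ids <- c(pd$a, pd$b, pd$c, pd$d)
  expect_identical(sort(unique(ids)), seq_len(np))
  expect_true(all(table(ids) == 2))
  expect_identical(attr(pd, "writhe"), sum(pd$sign))
})

test_that("crossing-free diagram converts to the empty planar diagram", {
  pd <- to_planar_diagram(unknot_3())
  expect_identical(nrow(pd), 0L)
  expect_identical(attr(pd, "n_edges"), 0L)
  j <- jones_normalized(pd)
  expect_true(j$ok)
  expect_identical(j$coeffs, 1)
})

test_that("writhe flips sign under mirroring", {
  set.seed(31)
  for (k in 1:25) {
    g <- canonical_form(sample_grid(6))
    w <- attr(to_planar_diagram(g), "writhe")
    wm <- attr(to_planar_diagram(mirror_grid(g)), "writhe")
    expect_identical(wm, -w)
  }
})

test_that("pure-R Jones matches compiled Jones exhaustively at GN 5", {
  gs <- grids_5()
  for (i in seq_len(grid_set_size(gs))) {
    g <- grid_at(gs, i)
    jc <- jones_poly(g)
    jr <- jones_normalized(to_planar_diagram(g))
    expect_identical(jc$tmin, jr$tmin)
    expect_identical(as.numeric(jc$coeffs), as.numeric(jr$coeffs))
  }
})

test_that("pure-R Jones matches compiled Jones on random GN-6/7 diagrams", {
  set.seed(1234)
  for (k in 1:60) {
    g <- sample_grid(if (k %% 2 == 0) 6 else 7)
    jc <- jones_poly(g)
    jr <- jones_normalized(to_planar_diagram(g))
    expect_identical(jc$tmin, jr$tmin)
    expect_identical(as.numeric(jc$coeffs), as.numeric(jr$coeffs))
  }
})

test_that("Wirtinger Alexander oracle matches winding-matrix Alexander, GN <= 5", {
  for (n in 3:4) {
    gs <- enumerate_grids(n)
    for (i in seq_len(grid_set_size(gs))) {
      g <- grid_at(gs, i)
      expect_identical(
        alexander_from_pd(to_planar_diagram(g))$coeffs,
        alexander_poly(g)$coeffs
      )
    }
  }
  gs <- grids_5()
  for (i in seq_len(grid_set_size(gs))) {
    g <- grid_at(gs, i)
    expect_identical(
      alexander_from_pd(to_planar_diagram(g))$coeffs,
      alexander_poly(g)$coeffs
    )
  }
})

test_that("Wirtinger Alexander oracle matches on random GN-6/7 diagrams", {
  set.seed(99)
  for (k in 1:60) {
    g <- sample_grid(if (k %% 2 == 0) 6 else 7)
    expect_identical(
      alexander_from_pd(to_planar_diagram(g))$coeffs,
      alexander_poly(g)$coeffs
    )
  }
})

test_that("multi-component grids are refused", {
  g <- grid_diagram(c(1, 0, 3, 2), c(0, 1, 2, 3))
  expect_error(to_planar_diagram(g), class = "gridknot_multi_component")
})

test_that("Jones crossing bound returns ok = FALSE instead of hanging", {
  tre <- trefoil_5()
  pd <- to_planar_diagram(tre)
  expect_false(jones_normalized(pd, max_crossings = 1L)$ok)
  expect_false(jones_poly(tre, max_crossings = 1L)$ok)
})
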