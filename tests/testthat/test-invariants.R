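test_that("Alexander polynomial of reference knots", {
  # unknot
  expect_identical(alexander_poly(unknot_3())$coeffs, 1)
  # trefoil: t - 1 + 1/t
  tre <- trefoil_5()
  ap <- alexander_poly(tre)
  expect_true(ap$ok)
  expect_identical(ap$coeffs, c(1, -1, 1))
  expect_identical(ap$tmin, -1L)
})

test_that("Alexander normalization invariants hold on random diagrams", {
  set.seed(11)
  for (k in 1:60) {
    g <- sample_grid(sample(5:9, 1))
    ap <- alexander_poly(g)
    expect_true(ap$ok)
    cf <- ap$coeffs
    expect_identical(length(cf) %% 2L, 1L) # odd length (centered)
    expect_identical(cf, rev(cf)) # palindromic
    expect_identical(sum(cf), 1) # Delta(1) = 1
    expect_identical(knot_determinant(g) %% 2, 1) # determinant odd
  }
})

test_that("exact rational Alexander evaluation", {
  tre <- trefoil_5()
  # Delta(3_1) = t - 1 + 1/t: at t = -1 -> |-3| = 3; at t = 2 -> 3/2
  e <- alexander_eval(tre, -1L)
  expect_identical(e$numerator, 3)
  expect_identical(e$denominator, 1)
  e2 <- alexander_eval(tre, 2L)
  expect_identical(e2$numerator, 3)
  expect_identical(e2$denominator, 2)
  e3 <- alexander_eval(tre, 2L, 3L) # 2/3 - 1 + 3/2 = 7/6
  expect_identical(e3$numerator, 7)
  expect_identical(e3$denominator, 6)
  expect_error(alexander_eval(tre, 0L), class = "gridknot_bad_input")
})

test_that("Jones polynomial of reference knots", {
  expect_identical(jones_poly(unknot_3())$coeffs, 1)
  j <- jones_poly(trefoil_5())
  # mirror-normalized trefoil: -t^-4 + t^-3 + t^-1
  expect_identical(j$tmin, -4L)
  expect_identical(as.numeric(j$coeffs), c(-1, 1, 0, 1))
})

test_that("invariants are unchanged by topology-preserving moves", {
  set.seed(13)
  for (k in 1:20) {
    g <- canonical_form(sample_grid(6))
    fp <- invariant_fingerprint(g, jones = TRUE)
    variants <- list(
      cyclic_translate(g, 2, "column"),
      cyclic_translate(g, 3, "row"),
      mirror_grid(g), # mirror-lumped invariants only
      simplify_grid(g)
    )
    jux <- classify_juxtapositions(g)
    ni <- jux[!jux$interleaved, ]
    if (nrow(ni) > 0) {
      variants <- c(variants, list(commute_pair(g, ni$axis[1], ni$index[1])))
    }
    for (v in variants) {
      fv <- invariant_fingerprint(v, jones = TRUE)
      expect_identical(fv$determinant, fp$determinant)
      expect_identical(fv$alexander, fp$alexander)
      expect_identical(fv$jones$coeffs, fp$jones$coeffs)
    }
  }
})

test_that("the packaged knot table is consistent", {
  tab <- knot_table()
  expect_true(all(c("0_1", "3_1", "4_1", "5_1", "5_2", "8_19", "8_20", "8_21", "3_1#3_1")
  %in% tab$name))
  for (i in seq_len(nrow(tab))) {
    a <- tab$alexander[[i]]
    expect_identical(length(a) %% 2L, 1L) # centered, odd length
    expect_identical(a, rev(a)) # palindromic
    expect_identical(sum(a), 1) # Delta(1) = 1
    d <- (length(a) - 1) / 2
    det <- abs(sum(a * (-1)^(seq_along(a) - 1 - d)))
    expect_identical(det, tab$determinant[i]) # determinant consistent
  }
  # the single Alexander collision carries Jones disambiguation data
  keys <- vapply(tab$alexander, function(a) paste(a, collapse = ","), character(1))
  dup <- keys[duplicated(keys)]
  expect_identical(length(dup), 1L)
  collided <- tab$name[keys == dup]
  expect_setequal(collided, c("8_20", "3_1#3_1"))
  expect_true(all(!vapply(tab$jones[keys == dup], is.null, logical(1))))
})

test_that("identify_knot labels reference diagrams correctly", {
  expect_identical(identify_knot(unknot_3()), "0_1")
  tre <- trefoil_5()
  expect_identical(identify_knot(tre), "3_1")
  expect_identical(identify_knot(mirror_grid(tre)), "3_1") # mirror-lumped
  # Jones-disambiguated connected sums (both chirality classes)
  expect_identical(identify_knot(grid_connected_sum(tre, tre)), "3_1#3_1")
  expect_identical(
    identify_knot(grid_connected_sum(tre, mirror_grid(tre))),
    "3_1#3_1"
  )
})

test_that("identify_knot is invariant under moves (exhaustive GN <= 5)", {
  for (n in 3:4) {
    gs <- enumerate_grids(n)
    for (i in seq_len(grid_set_size(gs))) {
      g <- grid_at(gs, i)
      lab <- identify_knot(g)
      expect_identical(identify_knot(cyclic_translate(g, 1, "column")), lab)
    }
  }
  gs <- grids_5()
  for (i in seq_len(grid_set_size(gs))) {
    g <- grid_at(gs, i)
    lab <- identify_knot(g)
    expect_identical(identify_knot(cyclic_translate(g, 2, "row")), lab)
  }
})

test_that("identify_knot is invariant under randomized moves up to GN 10", {
  set.seed(47)
  for (k in 1:30) {
    g <- canonical_form(sample_grid(sample(6:10, 1)))
    lab <- identify_knot(g)
    g2 <- cyclic_translate(g, sample(1:3, 1), sample(c("column", "row"), 1))
    jux <- classify_juxtapositions(g2)
    ni <- jux[!jux$interleaved, ]
    if (nrow(ni) > 0) {
      r <- sample(nrow(ni), 1)
      g2 <- commute_pair(g2, ni$axis[r], ni$index[r])
    }
    expect_identical(identify_knot(g2), lab)
  }
})
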