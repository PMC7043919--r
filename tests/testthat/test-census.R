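test_that("grid_count_formula matches n! (n-1)! / 2 and is vectorized", {
  expect_identical(grid_count_formula(3), 6)
  expect_identical(grid_count_formula(5), 1440)
  expect_identical(grid_count_formula(3:7), c(6, 72, 1440, 43200, 1814400))
  expect_error(grid_count_formula(2), class = "gridknot_bad_input")
})

test_that("enumeration yields each canonical diagram exactly once", {
  for (n in 3:5) {
    gs <- if (n == 5) grids_5() else enumerate_grids(n)
    m <- grid_set_size(gs)
    expect_identical(m, as.integer(grid_count_formula(n)))
    keys <- character(m)
    for (i in seq_len(m)) {
      g <- grid_at(gs, i)
      expect_identical(component_count(g), 1L)
      expect_true(is_canonical(g))
      keys[i] <- grid_to_string(g)
    }
    expect_identical(anyDuplicated(keys), 0L)
  }
})

test_that("enumeration range guard", {
  expect_error(enumerate_grids(2), class = "gridknot_bad_input")
  expect_error(enumerate_grids(8), class = "gridknot_bad_input")
})

test_that("knot census at GN 3-6 matches exact reference counts", {
  cen <- knot_census(3, 6)
  expect_s3_class(cen, "knot_census")
  get <- function(gn, knot) {
    v <- cen$count[cen$gn == gn & cen$knot == knot]
    if (length(v) == 0) 0 else v
  }
  # GN 3, 4: unknot only
  expect_identical(get(3, "0_1"), 6)
  expect_identical(get(4, "0_1"), 72)
  # GN 5: 10 trefoils (arc index 5), everything else unknotted
  expect_identical(get(5, "3_1"), 10)
  expect_identical(get(5, "0_1"), 1430)
  # GN 6: figure-eight enters (arc index 6)
  expect_identical(get(6, "4_1"), 36)
  expect_identical(get(6, "3_1"), 936)
  expect_identical(get(6, "0_1"), 43200 - 936 - 36)
  # totals match the closed formula per gn
  tot <- tapply(cen$count, cen$gn, sum)
  expect_identical(as.numeric(tot), grid_count_formula(3:6))
  # realizable label sets are constrained by arc index
  expect_identical(sort(unique(cen$knot[cen$gn == 5])), c("0_1", "3_1"))
  expect_identical(sort(unique(cen$knot[cen$gn == 6])), c("0_1", "3_1", "4_1"))
})

test_that("census identification agrees with the full R pipeline at GN 5", {
  cen <- knot_census(5, 5)
  gs <- grids_5()
  labs <- character(grid_set_size(gs))
  for (i in seq_along(labs)) labs[i] <- identify_knot(grid_at(gs, i))
  r_counts <- sort(table(labs))
  for (nm in names(r_counts)) {
    expect_identical(
      as.numeric(r_counts[[nm]]),
      cen$count[cen$knot == nm & cen$gn == 5]
    )
  }
})

test_that("occurrence probabilities sum to one per gn", {
  cen <- knot_census(3, 6)
  p <- occurrence_probabilities(cen)
  sums <- tapply(p$probability, p$gn, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  expect_identical(
    p$probability[p$gn == 5 & p$knot == "3_1"],
    10 / 1440
  )
})

test_that("tidiers and plot methods work on a census", {
  cen <- knot_census(3, 5)
  td <- tidy(cen)
  expect_true(all(c("gn", "knot", "count", "total", "probability") %in% names(td)))
  gl <- glance(cen)
  expect_identical(nrow(gl), 1L)
  expect_identical(gl$n_diagrams, sum(cen$count))
  expect_s3_class(autoplot(cen), "ggplot")
})
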