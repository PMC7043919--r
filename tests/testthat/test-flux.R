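test_that("passage_events at GN 5 reproduces exact reference counts", {
  ev <- passage_events(5)
  expect_true(all(c("gn", "from", "to", "category", "area", "count") %in% names(ev)))
  unb <- flux_table(ev, "unbiased")
  # all 10 GN-5 trefoils have strongly hooked sites unknotting them
  hk <- flux_table(ev, "hooked", max_area = 1)
  expect_identical(gridknot:::flux_count(hk, "3_1", "0_1"), 24)
  expect_identical(gridknot:::flux_count(hk, "0_1", "3_1"), 0)
  # detailed balance of the unbiased exhaustive table
  expect_identical(
    gridknot:::flux_count(unb, "3_1", "0_1"),
    gridknot:::flux_count(unb, "0_1", "3_1")
  )
})

test_that("unbiased exhaustive flux tables are exactly symmetric (GN 5 and 6)", {
  for (gn in 5:6) {
    f <- flux_table(passage_events(gn), "unbiased")
    labs <- unique(c(f$from, f$to))
    for (a in labs) {
      for (b in labs) {
        if (a < b) {
          expect_identical(
            gridknot:::flux_count(f, a, b),
            gridknot:::flux_count(f, b, a)
          )
        }
      }
    }
    expect_identical(glance(f)$max_rel_asymmetry, 0)
  }
})

test_that("hooked fluxes break symmetry toward simpler knots at GN 6", {
  ev <- passage_events(6)
  hk <- flux_table(ev, "hooked", max_area = 1)
  ab <- gridknot:::flux_count(hk, "3_1", "0_1")
  ba <- gridknot:::flux_count(hk, "0_1", "3_1")
  expect_identical(ab, 1380)
  expect_identical(ba, 80)
  rep <- reduction_factor(flux_table(ev, "unbiased"), hk)
  expect_identical(rep$factor, ab / ba)
  expect_gt(rep$factor, 15)
  expect_identical(rep$unbiased_ratio, 1)
})

test_that("GN-5 hooked reduction factor is infinite", {
  ev <- passage_events(5)
  rep <- reduction_factor(
    flux_table(ev, "unbiased"),
    flux_table(ev, "hooked", max_area = 1)
  )
  expect_true(rep$infinite)
  expect_identical(rep$factor, Inf)
  expect_output(print(rep), "reduction factor")
})

test_that("hooked events are a monotone subset of unbiased events by area", {
  ev <- passage_events(6)
  n_unb <- sum(flux_table(ev, "unbiased")$count)
  prev <- 0
  for (ma in 1:4) {
    n_h <- sum(flux_table(ev, "hooked", max_area = ma)$count)
    expect_gte(n_h, prev)
    expect_lte(n_h, n_unb)
    prev <- n_h
  }
  sweep <- area_sweep(ev, max_areas = 1:3)
  expect_identical(nrow(sweep), 3L)
  expect_true(all(diff(sweep$flux_ab) >= 0))
})

test_that("transition probabilities are row-normalized", {
  tp <- transition_probabilities(flux_table(passage_events(6), "unbiased"))
  sums <- tapply(tp$probability, tp$from, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
})

test_that("knot closeness is symmetric and sums to 1 over unordered pairs", {
  f <- flux_table(passage_events(6), "unbiased")
  expect_identical(
    knot_closeness(f, "3_1", "0_1"),
    knot_closeness(f, "0_1", "3_1")
  )
  labs <- unique(c(f$from, f$to))
  tot <- 0
  for (i in seq_along(labs)) {
    for (j in seq_along(labs)) {
      if (i < j) tot <- tot + knot_closeness(f, labs[i], labs[j])
    }
  }
  expect_equal(tot, 1)
})

test_that("flux_table input validation and tidiers", {
  expect_error(flux_table(tibble::tibble(bad = 1)), class = "gridknot_bad_input")
  expect_error(passage_events(2), class = "gridknot_bad_input")
  expect_error(passage_events(5, 8), class = "gridknot_bad_input")
  f <- flux_table(passage_events(5), "hooked")
  td <- tidy(f)
  expect_true(all(c("from", "to", "count", "policy", "max_area") %in% names(td)))
  expect_s3_class(autoplot(f), "ggplot")
  rep <- reduction_factor(flux_table(passage_events(5), "unbiased"), f)
  expect_identical(nrow(tidy(rep)), 1L)
})

test_that("dedup mode counts distinct resulting diagrams and is bounded above", {
  ev <- passage_events(5, dedup = FALSE)
  ed <- passage_events(5, dedup = TRUE)
  expect_lte(sum(ed$count), sum(ev$count))
  # per-transition dedup counts never exceed raw counts
  key <- function(d) paste(d$gn, d$from, d$to, d$category, d$area)
  m <- match(key(ed), key(ev))
  expect_true(all(!is.na(m)))
  expect_true(all(ed$count <= ev$count[m]))
})
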