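# gridknot

Exact, desk-scale modeling of how type II topoisomerases change the knotting
of circular DNA, using grid diagrams (arc presentations of knots).

## The science

A type II topoisomerase cuts double-stranded DNA, passes another duplex
segment through the gap, and reseals the cut — a **strand passage**, which
changes exactly one crossing of the knot formed by the DNA axis.  In vitro,
these enzymes keep the steady-state fraction of knotted DNA circles far
*below* topological equilibrium, which is puzzling for an enzyme that acts
locally and cannot see the global topology.  A leading explanation is
geometric selection: if the enzyme preferentially acts at **hooked
juxtapositions** — two sharply bent segments curving toward each other —
local geometry becomes a reliable statistical proxy for global topology.

`gridknot` makes this argument exactly computable.  A **grid diagram** of
size *n* (the *grid number*, GN) is an *n* × *n* board with one X and one O
marking in every row and column; column markings are joined vertically, row
markings horizontally, and vertical segments always pass over horizontal
ones.  Two permutations encode the whole diagram, so the configuration space
is finite: exactly *n*!(*n*−1)!/2 canonical single-component diagrams per
grid number, and a strand passage is an **interleaving commutation** of two
adjacent rows or columns.  Every headline number below is an exact
combinatorial count over these finite sets, not a simulation estimate.

## Worked example

```r
library(gridknot)

g <- grid_diagram(c(0, 1, 2, 3, 4), c(3, 4, 0, 1, 2))
g
#> <grid_diagram> n = 5, 1 component (knot)
#> . O - - X
#> O | - X |
#> | | X | O
#> | X | O .
#> X - O . .

identify_knot(g)
#> [1] "3_1"
alexander_poly(g)$coeffs   # t - 1 + 1/t: the trefoil
#> [1]  1 -1  1
jones_poly(g)[c("tmin", "coeffs")]  # -t^-4 + t^-3 + t^-1 (mirror-normalized)
#> $tmin
#> [1] -4
#> $coeffs
#> [1] -1  1  0  1
```

Every adjacent row/column pair is classified by its juxtaposition geometry
(`hooked` with its rectangle area, `mixed`, `free`, or not interleaved):

```r
classify_juxtapositions(g)
#> # A tibble: 8 × 6
#>   axis   index interleaved class   area strongly_hooked
#>   <chr>  <int> <lgl>       <chr>  <int> <lgl>
#> 1 column     0 TRUE        mixed     NA FALSE
#> 2 column     1 TRUE        mixed     NA FALSE
#> 3 column     2 TRUE        hooked     1 TRUE
#> 4 column     3 TRUE        mixed     NA FALSE
#> 5 row        0 TRUE        mixed     NA FALSE
#> 6 row        1 TRUE        hooked     1 TRUE
#> 7 row        2 TRUE        mixed     NA FALSE
#> 8 row        3 TRUE        mixed     NA FALSE

# firing the strongly hooked passage unknots the trefoil
identify_knot(commute_pair(g, "column", 2))
#> [1] "0_1"
```

Exhaustive knot censuses (the GN 3–7 census has 1,859,118 diagrams and runs
in under a minute):

```r
knot_census(3, 6)
#> # A tibble: 7 × 3
#>      gn knot  count
#>   <int> <chr> <dbl>
#> 1     3 0_1       6
#> 2     4 0_1      72
#> 3     5 0_1    1430
#> 4     5 3_1      10
#> 5     6 0_1   42228
#> 6     6 3_1     936
#> 7     6 4_1      36
```

Firing a passage at every interleaved site of every GN-6 diagram gives the
knot-interconversion flux table.  Unbiased passages satisfy exact detailed
balance; restricting to strongly hooked sites breaks the symmetry sharply
toward unknotting:

```r
ev <- passage_events(6)
flux_table(ev, "unbiased")
#> # A tibble: 5 × 3
#>   from  to    count
#> * <chr> <chr> <dbl>
#> 1 0_1   0_1   73200
#> 2 0_1   3_1    6240
#> 3 0_1   4_1     360
#> 4 3_1   0_1    6240
#> 5 4_1   0_1     360

reduction_factor(flux_table(ev, "unbiased"),
                 flux_table(ev, "hooked", max_area = 1))
#> <reduction_report> 3_1 <-> 0_1
#>   hooked (max area 1): 3_1 -> 0_1: 1380, 0_1 -> 3_1: 80
#>   reduction factor: 17.25
#>   unbiased ratio: 1
```

At GN 5 the bias is total: all 10 trefoil diagrams carry strongly hooked
sites that unknot them (24 such events) while no strongly hooked passage on
any of the 1,430 unknot diagrams creates a knot — an infinite reduction
factor.  Relaxing the hook-tightness threshold weakens the effect
monotonically:

```r
area_sweep(ev, max_areas = 1:3)
#> # A tibble: 3 × 4
#>   max_area flux_ab flux_ba factor
#>      <int>   <dbl>   <dbl>  <dbl>
#> 1        1    1380      80   17.2
#> 2        2    1692     160   10.6
#> 3        3    1728     192    9
```

Beyond exhaustive reach, `sample_grid()` draws exactly uniform canonical
diagrams constructively (no rejection); at GN 17, about 55% of 2,000 sampled
conformations are already knotted by the exact Alexander test.

## Installation and use

```r
# from a source checkout
R CMD INSTALL .
```

The command-line interface mirrors the R API and writes a JSON run manifest
next to every output:

```sh
Rscript inst/cli/gridknot.R census --gn-min 3 --gn-max 7 --out census.csv
Rscript inst/cli/gridknot.R fluxes --gn-min 6 --gn-max 6 --policy hooked --out flux.csv
Rscript inst/cli/gridknot.R identify --grid "x=0,1,2,3,4;o=3,4,0,1,2"
```

## Package tour

| Area | Functions |
| --- | --- |
| Core structures | `grid_diagram()`, `canonical_form()`, `grid_crossings()`, `to_planar_diagram()`, `render_ascii()`, `mirror_grid()`, `grid_connected_sum()` |
| Moves | `commute_pair()`, `classify_juxtapositions()`, `passage_sites()`, `destabilize_once()`, `simplify_grid()` |
| Invariants | `alexander_poly()`, `alexander_eval()`, `jones_poly()`, `identify_knot()` |
| Census | `grid_count_formula()`, `enumerate_grids()`, `knot_census()`, `occurrence_probabilities()` |
| Fluxes | `passage_events()`, `flux_table()`, `transition_probabilities()`, `knot_closeness()`, `reduction_factor()`, `area_sweep()` |
| Sampling | `sample_grid()`, `sampled_census()`, `sampled_flux_study()` |
| Tidy/plot | `tidy()`, `glance()`, `autoplot()` on censuses and flux tables |
| I/O + CLI | `write_grids_jsonl()`, `write_table_csv()`, `run_cli()` |

See the vignette (`vignettes/grid-diagram-topoisomerase.Rmd`) for the full
methods narrative.
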