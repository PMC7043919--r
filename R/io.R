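#' Write and read grid diagrams as JSON lines
#'
#' One diagram per line: `{"n": 5, "x": [...], "o": [...]}`.  The round trip
#' is bit-exact.
#'
#' @param grids A list of [grid_diagram()]s or a `grid_set`.
#' @param path Output file path.
#' @return `write_grids_jsonl()` returns `path` invisibly;
#'   `read_grids_jsonl()` returns a list of `grid_diagram`s.
#' @export
write_grids_jsonl <- function(grids, path) {
  if (inherits(grids, "grid_set")) {
    grids <- lapply(seq_len(grid_set_size(grids)), function(i) grid_at(grids, i))
  }
  lines <- vapply(grids, function(g) {
    jsonlite::toJSON(
      list(n = jsonlite::unbox(g$n), x = g$x, o = g$o),
      auto_unbox = FALSE
    )
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_grids_jsonl
#' @export
read_grids_jsonl <- function(path) {
  lines <- readLines(path)
  lapply(lines, function(ln) {
    rec <- jsonlite::fromJSON(ln)
    g <- grid_diagram(rec$x, rec$o)
    if (g$n != rec$n) {
      abort("Grid record length does not match its declared n.",
        class = "gridknot_bad_input"
      )
    }
    g
  })
}

#' Write a table as CSV with a commented metadata header
#'
#' Metadata lines are prefixed `# key: value`; [read_table_csv()] skips them.
#' Column order is preserved, encoding UTF-8, line endings LF.
#'
#' @param tab A data frame.
#' @param path Output path.
#' @param metadata Named character/numeric vector written as header comments.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(tab, path, metadata = NULL) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(metadata) > 0) {
    hdr <- sprintf("# %s: %s", names(metadata), as.character(metadata))
    writeLines(hdr, con, sep = "\n", useBytes = TRUE)
  }
  body <- readr::format_csv(tab)
  writeLines(sub("\n$", "", body), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' @rdname write_table_csv
#' @return `read_table_csv()`: a tibble.
#' @export
read_table_csv <- function(path) {
  readr::read_csv(path, comment = "#", show_col_types = FALSE, progress = FALSE)
}
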