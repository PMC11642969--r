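# Small in-code fixtures shared across test files.

# A hand-written measurement table: three clades, specimens in the
# pre-extinction and modern bins (plus one intermediate-bin row that must
# never enter a fauna table).
make_fixture_records <- function() {
  tibble::tibble(
    species = c(
      rep("Alpha one", 3), rep("Alpha two", 2), "Alpha big",
      rep("Alpha one", 2), rep("Alpha new", 3),
      rep("Beta one", 4), rep("Beta two", 2),
      rep("Beta one", 3),
      rep("Gamma one", 2), "Gamma one",
      rep("Gamma two", 2),
      "Alpha mid"
    ),
    clade = c(
      rep("Alphidae", 6), rep("Alphidae", 5),
      rep("Betidae", 6), rep("Betidae", 3),
      rep("Gammidae", 3), rep("Gammidae", 2),
      "Alphidae"
    ),
    time_bin = c(
      rep("pre_extinction", 6),
      rep("modern", 5),
      rep("pre_extinction", 6),
      rep("modern", 3),
      rep("pre_extinction", 2), "modern",
      rep("modern", 2),
      "post_pre_modern"
    ),
    length_mm = c(
      10, 12, 14, 8, 9, 60,
      11, 13, 20, 22, 24,
      30, 32, 34, 36, 25, 27,
      18, 20, 22,
      40, 44, 41,
      15, 17,
      50
    ),
    source = "fixture",
    from_figure = c(rep(FALSE, 25), TRUE)
  )
}

write_fixture_csv <- function(records = make_fixture_records(),
                              path = withr::local_tempfile(fileext = ".csv",
                                                           .local_envir = parent.frame())) {
  readr::write_csv(records, path)
  path
}

# Independent linear-interpolation quantile oracle (sorting + type-7
# interpolation written out by hand).
oracle_quantile <- function(x, p) {
  xs <- sort(x)
  n <- length(xs)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  xs[lo] + (h - lo) * (xs[hi] - xs[lo])
}
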