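test_that("reading a measurement CSV validates and partitions rows", {
  path <- write_fixture_csv()
  records <- read_measurements(path)
  fixture <- make_fixture_records()
  expect_equal(nrow(records), nrow(fixture))
  expect_equal(records$length_mm, fixture$length_mm)
  expect_setequal(unique(records$clade), c("Alphidae", "Betidae", "Gammidae"))
  report <- attr(records, "parse_report")
  expect_equal(report$rows_read, nrow(fixture))
  expect_equal(report$rows_rejected, 0)

  # header-only file -> empty collection, nothing rejected
  empty_path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(make_fixture_records()[0, ], empty_path)
  empty <- read_measurements(empty_path)
  expect_equal(nrow(empty), 0)
  expect_equal(attr(empty, "parse_report")$rows_rejected, 0)
})

test_that("invalid rows and columns are reported by name and index", {
  bad <- make_fixture_records()
  bad$length_mm[3] <- -3
  path <- write_fixture_csv(bad)
  expect_error(read_measurements(path), "row 3")

  bad2 <- make_fixture_records()
  bad2$time_bin[5] <- "holocene"
  path2 <- write_fixture_csv(bad2)
  expect_error(read_measurements(path2), "unknown time-bin label")
  expect_error(read_measurements(path2), "pre_extinction")

  dropped <- read_measurements(
    path, measurement_dialect(on_invalid = "drop"))
  expect_equal(attr(dropped, "parse_report")$rows_rejected, 1)
  expect_equal(attr(dropped, "parse_report")$rejected_rows, 3)
  expect_equal(nrow(dropped), nrow(bad) - 1)

  noclade <- make_fixture_records()[, c("species", "time_bin", "length_mm")]
  path3 <- write_fixture_csv(noclade)
  expect_error(read_measurements(path3), "'clade'")
})

test_that("column mapping and bin-label translation are configurable", {
  renamed <- make_fixture_records()
  names(renamed) <- c("taxon", "family", "bin", "len", "src", "fig")
  renamed$bin <- c(pre_extinction = "PP", post_pre_modern = "CALA",
                   modern = "REC")[renamed$bin]
  path <- write_fixture_csv(renamed)
  dialect <- measurement_dialect(
    species = "taxon", clade = "family", time_bin = "bin", length = "len",
    source = "src", from_figure = "fig",
    bin_labels = c(PP = "pre_extinction", CALA = "post_pre_modern",
                   REC = "modern"))
  records <- read_measurements(path, dialect)
  expect_equal(records$time_bin, make_fixture_records()$time_bin)
  expect_equal(records$length_mm, make_fixture_records()$length_mm)
})

test_that("species summaries compute mean, max and typical sizes per bin", {
  one <- tibble::tibble(species = "Solo", clade = "Conidae",
                        time_bin = "modern", length_mm = 12,
                        source = NA_character_, from_figure = FALSE)
  s1 <- summarize_species(one)
  expect_equal(s1$mean_mm, 12)
  expect_equal(s1$max_mm, 12)
  expect_equal(s1$typical_mm, 12)

  three <- tibble::tibble(species = "Trio", clade = "Xidae",
                          time_bin = "pre_extinction",
                          length_mm = c(10, 20, 30),
                          source = NA_character_, from_figure = FALSE)
  s3 <- summarize_species(three)
  expect_equal(s3$mean_mm, 20)
  expect_equal(s3$max_mm, 30)
  expect_true(is.na(s3$typical_mm)) # not a typical-metric clade

  s <- summarize_species(make_fixture_records())
  expect_equal(nrow(s), 12) # distinct (species, bin) groups
  a1pre <- s[s$species == "Alpha one" & s$time_bin == "pre_extinction", ]
  expect_equal(a1pre$n_specimens, 3L)
  expect_equal(a1pre$mean_mm, 12)
  expect_equal(a1pre$max_mm, 14)
  expect_true(all(s$max_mm >= s$mean_mm))
})

test_that("summaries are permutation-invariant and reject mixed clades", {
  records <- make_fixture_records()
  shuffled <- records[withr::with_seed(42, sample(nrow(records))), ]
  expect_equal(summarize_species(records), summarize_species(shuffled))

  mixed <- records
  mixed$clade[mixed$species == "Beta one"][1] <- "Alphidae"
  expect_error(summarize_species(mixed), "more than one clade")
})

test_that("the typical rule is pluggable and bounded by the group range", {
  records <- make_fixture_records()
  s_med <- summarize_species(records, typical_rule = stats::median,
                             typical_clades = unique(records$clade))
  expect_false(anyNA(s_med$typical_mm))
  # default (mean) rule: min <= typical <= max for every group
  s_def <- summarize_species(records, typical_clades = unique(records$clade))
  grp_min <- tapply(records$length_mm,
                    paste(records$species, records$time_bin),
                    min)
  key <- paste(s_def$species, s_def$time_bin)
  expect_true(all(s_def$typical_mm >= grp_min[key]))
  expect_true(all(s_def$typical_mm <= s_def$max_mm))
})

test_that("figure-derived measurements can be dropped for sensitivity runs", {
  records <- make_fixture_records()
  s_all <- summarize_species(records)
  s_drop <- summarize_species(records, include_figure_derived = FALSE)
  expect_true("Alpha mid" %in% s_all$species)
  expect_false("Alpha mid" %in% s_drop$species)
})

test_that("fauna tables take pre and modern bins only, honouring exclusions", {
  s <- summarize_species(make_fixture_records())
  f <- build_fauna(s, "Alphidae", metric = "mean")
  expect_setequal(f$pre_species, c("Alpha one", "Alpha two", "Alpha big"))
  expect_setequal(f$modern_species, c("Alpha one", "Alpha new"))
  expect_false("Alpha mid" %in% c(f$pre_species, f$modern_species))

  f_ex <- build_fauna(s, "Alphidae", metric = "mean", exclusions = "Alpha big")
  expect_setequal(f_ex$pre_species, c("Alpha one", "Alpha two"))
  expect_equal(mean(f_ex$pre_sizes), mean(c(12, 8.5)))

  f_surv <- build_fauna(s, "Alphidae", metric = "mean",
                        modern_scope = "survivors")
  expect_equal(f_surv$modern_species, "Alpha one")

  # single pre-extinction species
  g <- build_fauna(s, "Gammidae", metric = "max")
  expect_equal(length(g$pre_sizes), 1)
  expect_equal(g$pre_sizes, 44)

  expect_error(build_fauna(s, "Nosuchidae"), "clade not present")
  expect_error(build_fauna(s, "Betidae", metric = "typical"),
               "typical size not available")
})

test_that("read -> summarize -> build reproduces generator species means", {
  sc <- sim_scenario(seed = 11)
  gen <- generate_fauna(sc)
  path <- withr::local_tempfile(fileext = ".csv")
  write_measurements(gen$records, path)
  records <- read_measurements(path)
  summaries <- summarize_species(records, typical_clades = character())
  fauna <- build_fauna(summaries, sc$clade, metric = "mean")
  expect_equal(length(fauna$pre_sizes), gen$truth$n_f)
  expect_equal(length(fauna$modern_sizes), gen$truth$n_m)
  direct_means <- tapply(
    gen$records$length_mm,
    paste(gen$records$species, gen$records$time_bin),
    mean)
  pre_key <- paste(fauna$pre_species, "pre_extinction")
  mod_key <- paste(fauna$modern_species, "modern")
  expect_equal(fauna$pre_sizes, as.numeric(direct_means[pre_key]),
               tolerance = 1e-9)
  expect_equal(fauna$modern_sizes, as.numeric(direct_means[mod_key]),
               tolerance = 1e-9)
})
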