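# Reading, validating and summarizing specimen-level size measurements.
#
# The measurement unit throughout is shell length in mm, recorded parallel to
# the coiling axis. Specimens are assigned to one of three time bins:
# "pre_extinction" (Plio-Pleistocene, pooling Pliocene and earliest
# Pleistocene units), "post_pre_modern" (post-extinction but pre-modern
# fossil record), and "modern" (extant populations). Bin membership is an
# input column, never computed from stratigraphy.

#' Canonical time-bin labels
#'
#' @return Character vector of the three accepted time-bin labels, in
#'   stratigraphic order: `"pre_extinction"`, `"post_pre_modern"`, `"modern"`.
#' @export
time_bins <- function() {
  c("pre_extinction", "post_pre_modern", "modern")
}

#' CSV dialect for measurement tables
#'
#' Describes how to map the columns of a measurement CSV onto the fields of a
#' specimen record, how to translate the file's time-bin labels onto the
#' canonical labels of [time_bins()], and what to do with invalid rows.
#'
#' @param species,clade,time_bin,length Column names in the file holding the
#'   species name, clade (family) name, time-bin label, and shell length (mm).
#' @param source,from_figure Optional column names for measurement provenance
#'   and for the flag marking measurements taken from published figures
#'   rather than physical specimens. Absent columns default to `NA` and
#'   `FALSE` respectively.
#' @param bin_labels Named character vector mapping labels as they appear in
#'   the file (names) to canonical labels (values). Defaults to the identity
#'   mapping on [time_bins()].
#' @param on_invalid Either `"error"` (default): any row with a non-positive
#'   or non-numeric length, or an unknown time-bin label, aborts the read
#'   with a row-level message; or `"drop"`: such rows are rejected and
#'   counted in the parse report.
#' @return An object of class `measurement_dialect`.
#' @export
measurement_dialect <- function(species = "species", clade = "clade",
                                time_bin = "time_bin", length = "length_mm",
                                source = "source", from_figure = "from_figure",
                                bin_labels = NULL,
                                on_invalid = c("error", "drop")) {
  on_invalid <- match.arg(on_invalid)
  if (is.null(bin_labels)) {
    bin_labels <- setNames(time_bins(), time_bins())
  }
  if (is.null(names(bin_labels)) || any(!nzchar(names(bin_labels)))) {
    stop_ps("`bin_labels` must be a fully named character vector")
  }
  if (!all(bin_labels %in% time_bins())) {
    stop_ps("`bin_labels` values must be canonical labels: ",
            paste(time_bins(), collapse = ", "))
  }
  structure(
    list(species = species, clade = clade, time_bin = time_bin,
         length = length, source = source, from_figure = from_figure,
         bin_labels = bin_labels, on_invalid = on_invalid),
    class = "measurement_dialect"
  )
}

#' Read a specimen measurement table
#'
#' Reads a CSV of specimen-level shell measurements (one row per measured
#' specimen) and returns a validated tibble of specimen records with columns
#' `species`, `clade`, `time_bin`, `length_mm`, `source`, `from_figure`.
#' Row order is preserved. A parse report (rows read, rows rejected,
#' rejected row indices) is attached as attribute `"parse_report"`.
#'
#' @param path Path to a CSV file (UTF-8, comma-separated, header row).
#' @param dialect A [measurement_dialect()] describing the column mapping.
#' @param verbose Emit a one-line parse report message.
#' @return Tibble of specimen records.
#' @export
read_measurements <- function(path, dialect = measurement_dialect(),
                              verbose = FALSE) {
  if (!inherits(dialect, "measurement_dialect")) {
    stop_ps("`dialect` must be created by measurement_dialect()")
  }
  if (!file.exists(path)) stop_ps("measurement file not found: ", path)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  mandatory <- c(dialect$species, dialect$clade, dialect$time_bin, dialect$length)
  missing <- setdiff(mandatory, names(raw))
  if (length(missing) > 0) {
    stop_ps("missing mandatory column(s) in ", path, ": ",
            paste0("'", missing, "'", collapse = ", "))
  }

  n_read <- nrow(raw)
  length_num <- suppressWarnings(as.numeric(raw[[dialect$length]]))
  bad_length <- which(is.na(length_num) | length_num <= 0)
  bin_canon <- unname(dialect$bin_labels[raw[[dialect$time_bin]]])
  bad_bin <- which(is.na(bin_canon))

  if (dialect$on_invalid == "error") {
    if (length(bad_length) > 0) {
      stop_ps("row ", bad_length[1], ": non-positive or non-numeric length '",
              raw[[dialect$length]][bad_length[1]], "'")
    }
    if (length(bad_bin) > 0) {
      stop_ps("row ", bad_bin[1], ": unknown time-bin label '",
              raw[[dialect$time_bin]][bad_bin[1]], "'; accepted labels: ",
              paste(names(dialect$bin_labels), collapse = ", "))
    }
  }
  rejected <- sort(union(bad_length, bad_bin))
  keep <- setdiff(seq_len(n_read), rejected)

  src <- if (dialect$source %in% names(raw)) raw[[dialect$source]] else rep(NA_character_, n_read)
  fig <- if (dialect$from_figure %in% names(raw)) {
    f <- toupper(trimws(raw[[dialect$from_figure]]))
    f %in% c("TRUE", "T", "1", "YES")
  } else {
    rep(FALSE, n_read)
  }

  records <- tibble(
    species = raw[[dialect$species]][keep],
    clade = raw[[dialect$clade]][keep],
    time_bin = bin_canon[keep],
    length_mm = length_num[keep],
    source = src[keep],
    from_figure = fig[keep]
  )
  report <- list(rows_read = n_read, rows_rejected = length(rejected),
                 rejected_rows = rejected)
  attr(records, "parse_report") <- report
  if (verbose) {
    message("read ", n_read, " rows from ", path, "; rejected ",
            length(rejected))
  }
  records
}

#' Write a specimen measurement table
#'
#' Writes records in the same CSV format [read_measurements()] reads
#' (round-trip guarantee, used by the synthetic fauna generator).
#'
#' @param records Tibble of specimen records.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(records, path) {
  validate_records(records)
  readr::write_csv(records, path)
  invisible(path)
}

validate_records <- function(records) {
  needed <- c("species", "clade", "time_bin", "length_mm")
  missing <- setdiff(needed, names(records))
  if (length(missing) > 0) {
    stop_ps("records are missing column(s): ", paste(missing, collapse = ", "))
  }
  if (nrow(records) > 0) {
    if (any(!is.finite(records$length_mm)) || any(records$length_mm <= 0)) {
      stop_ps("all specimen lengths must be positive and finite")
    }
    if (!all(records$time_bin %in% time_bins())) {
      stop_ps("time_bin values must be among: ", paste(time_bins(), collapse = ", "))
    }
  }
  invisible(records)
}

#' Summarize specimens into species-level size descriptors
#'
#' Aggregates specimen records into one row per (species, time bin) with the
#' specimen count, arithmetic mean length, maximum length, and a "typical"
#' size. The typical-size rule is pluggable: cone-snail workers use a
#' clade-specific typical-size metric in place of the raw mean, and the exact
#' computation varies between datasets, so `typical_rule` accepts any
#' function of a length vector. The default rule is the arithmetic mean, and
#' `typical_mm` is only filled for clades named in `typical_clades` (`NA`
#' elsewhere).
#'
#' @param records Tibble of specimen records (see [read_measurements()]).
#' @param typical_rule Function mapping a numeric vector of lengths (mm) to a
#'   single typical size (mm). Default: arithmetic mean.
#' @param typical_clades Character vector of clades for which `typical_mm` is
#'   computed. Default `"Conidae"`.
#' @param include_figure_derived Keep measurements flagged as taken from
#'   published figures (default `TRUE`); set `FALSE` for sensitivity runs.
#' @return Tibble with columns `species`, `clade`, `time_bin`,
#'   `n_specimens`, `mean_mm`, `max_mm`, `typical_mm`.
#' @export
summarize_species <- function(records, typical_rule = NULL,
                              typical_clades = "Conidae",
                              include_figure_derived = TRUE) {
  validate_records(records)
  if (is.null(typical_rule)) typical_rule <- function(x) mean(x)
  if (!is.function(typical_rule)) stop_ps("`typical_rule` must be a function")
  if (!include_figure_derived && "from_figure" %in% names(records)) {
    records <- records[!records$from_figure, , drop = FALSE]
  }
  if (nrow(records) == 0) {
    return(tibble(species = character(), clade = character(),
                  time_bin = character(), n_specimens = integer(),
                  mean_mm = double(), max_mm = double(), typical_mm = double()))
  }
  clades_per_species <- records |>
    dplyr::distinct(.data$species, .data$clade) |>
    dplyr::count(.data$species)
  mixed <- clades_per_species$species[clades_per_species$n > 1]
  if (length(mixed) > 0) {
    stop_ps("species assigned to more than one clade: ",
            paste(mixed, collapse = ", "))
  }
  out <- records |>
    group_by(.data$species, .data$clade, .data$time_bin) |>
    summarise(
      n_specimens = dplyr::n(),
      mean_mm = mean(.data$length_mm),
      max_mm = max(.data$length_mm),
      typical_mm = if (first(.data$clade) %in% typical_clades) {
        as.numeric(typical_rule(.data$length_mm))
      } else {
        NA_real_
      },
      .groups = "drop"
    )
  out$time_bin <- factor(out$time_bin, levels = time_bins())
  out <- arrange(out, .data$clade, .data$time_bin, .data$species)
  out$time_bin <- as.character(out$time_bin)
  out
}

#' @export
#' @rdname summarize_species
#' @param summaries Species-summary tibble.
#' @param path Output CSV path.
write_species_summary <- function(summaries, path) {
  readr::write_csv(summaries, path)
  invisible(path)
}

#' Construct a fauna table directly from size vectors
#'
#' A fauna table holds the per-species sizes of one clade in the
#' pre-extinction and modern time bins; it is the unit on which the
#' turnover classification operates. Most users build one from species
#' summaries with [build_fauna()]; this constructor is for species-level
#' size vectors obtained elsewhere.
#'
#' @param pre_sizes,modern_sizes Positive numeric vectors of per-species
#'   sizes (mm), one entry per species in the respective bin.
#' @param clade Clade label.
#' @param metric Which species-level descriptor the sizes represent:
#'   `"mean"`, `"max"`, or `"typical"`.
#' @param pre_species,modern_species Optional parallel species-name vectors.
#' @return Object of class `fauna_table`.
#' @export
fauna_table <- function(pre_sizes, modern_sizes, clade = "fauna",
                        metric = c("mean", "max", "typical"),
                        pre_species = NULL, modern_species = NULL) {
  metric <- match.arg(metric)
  pre_sizes <- as.numeric(pre_sizes)
  modern_sizes <- as.numeric(modern_sizes)
  for (v in list(pre_sizes, modern_sizes)) {
    if (length(v) > 0 && (any(!is.finite(v)) || any(v <= 0))) {
      stop_ps("all fauna sizes must be positive and finite")
    }
  }
  if (is.null(pre_species)) {
    pre_species <- sprintf("pre_%d", seq_along(pre_sizes))
  }
  if (is.null(modern_species)) {
    modern_species <- sprintf("mod_%d", seq_along(modern_sizes))
  }
  stopifnot(length(pre_species) == length(pre_sizes),
            length(modern_species) == length(modern_sizes))
  structure(
    list(clade = clade, metric = metric,
         pre_sizes = pre_sizes, modern_sizes = modern_sizes,
         pre_species = pre_species, modern_species = modern_species),
    class = "fauna_table"
  )
}

#' @export
print.fauna_table <- function(x, ...) {
  cat("Fauna table:", x$clade, "(metric:", x$metric, "size)\n")
  cat("  pre-extinction species (N_f):", length(x$pre_sizes), "\n")
  cat("  modern species (N_m):       ", length(x$modern_sizes), "\n")
  invisible(x)
}

#' Build a clade fauna table from species summaries
#'
#' Extracts the per-species sizes of one clade into a [fauna_table()]:
#' `pre_sizes` from the pre-extinction bin and `modern_sizes` from the
#' modern bin (the intermediate post-extinction fossil bin never enters the
#' turnover comparison). Species appearing in both bins contribute one entry
#' to each vector.
#'
#' @param summaries Output of [summarize_species()].
#' @param clade Clade to extract.
#' @param metric Species-level size descriptor: `"mean"`, `"max"`, or
#'   `"typical"`.
#' @param exclusions Species names to drop from both bins (e.g. a
#'   disputed clade member for a sensitivity run).
#' @param modern_scope `"extant"` (default): the modern vector holds every
#'   modern species of the clade; `"survivors"`: only modern species that
#'   also occur in the pre-extinction bin.
#' @return A [fauna_table()].
#' @export
build_fauna <- function(summaries, clade,
                        metric = c("mean", "max", "typical"),
                        exclusions = character(),
                        modern_scope = c("extant", "survivors")) {
  metric <- match.arg(metric)
  modern_scope <- match.arg(modern_scope)
  if (!clade %in% summaries$clade) {
    stop_ps("clade not present in summaries: '", clade, "'")
  }
  s <- summaries[summaries$clade == clade & !(summaries$species %in% exclusions), ,
                 drop = FALSE]
  pre <- s[s$time_bin == "pre_extinction", , drop = FALSE]
  mod <- s[s$time_bin == "modern", , drop = FALSE]
  if (modern_scope == "survivors") {
    mod <- mod[mod$species %in% pre$species, , drop = FALSE]
  }
  col <- switch(metric, mean = "mean_mm", max = "max_mm", typical = "typical_mm")
  if (metric == "typical") {
    bad <- c(pre$species[is.na(pre[[col]])], mod$species[is.na(mod[[col]])])
    if (length(bad) > 0) {
      stop_ps("typical size not available for species: ",
              paste(unique(bad), collapse = ", "),
              " (configure `typical_clades`/`typical_rule` in summarize_species)")
    }
  }
  fauna_table(pre_sizes = pre[[col]], modern_sizes = mod[[col]],
              clade = clade, metric = metric,
              pre_species = pre$species, modern_species = mod$species)
}

#' Write a fauna table as a long-format CSV
#'
#' One row per species per bin: `clade`, `metric`, `bin`, `species`,
#' `size_mm`.
#'
#' @param fauna A [fauna_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_fauna <- function(fauna, path) {
  stopifnot(inherits(fauna, "fauna_table"))
  readr::write_csv(fauna_long(fauna), path)
  invisible(path)
}

fauna_long <- function(fauna) {
  tibble(
    clade = fauna$clade,
    metric = fauna$metric,
    bin = c(rep("pre_extinction", length(fauna$pre_sizes)),
            rep("modern", length(fauna$modern_sizes))),
    species = c(fauna$pre_species, fauna$modern_species),
    size_mm = c(fauna$pre_sizes, fauna$modern_sizes)
  )
}
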