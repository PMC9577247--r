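#' Experimental design specification
#'
#' Describes the factorial layout of a biomass-to-nanopaper experiment:
#' biomass varieties, plant sections nested within variety, ordered
#' homogenisation energy levels, and the replication structure (nanopaper
#' duplicates per sample, tensile strips per duplicate).
#'
#' @param varieties character vector of variety labels (unique, non-empty).
#' @param sections_by_variety named list mapping each variety to its section
#'   labels. A plain character vector is recycled to every variety.
#' @param energy_levels character vector of energy labels, in increasing
#'   treatment order.
#' @param n_duplicates number of nanopaper duplicates per
#'   variety x section x energy sample.
#' @param n_strips number of tensile strips per nanopaper duplicate.
#'
#' @return An object of class `design_spec`.
#' @seealso [default_design()] for the sorghum study layout.
#' @export
design_spec <- function(varieties, sections_by_variety, energy_levels,
                        n_duplicates, n_strips) {
  varieties <- as.character(varieties)
  energy_levels <- as.character(energy_levels)
  if (!is.list(sections_by_variety)) {
    sections_by_variety <- stats::setNames(
      rep(list(as.character(sections_by_variety)), length(varieties)),
      varieties
    )
  }
  check_labels <- function(x, what) {
    if (length(x) == 0L) stop(what, " must be non-empty", call. = FALSE)
    if (anyDuplicated(x)) stop(what, " labels must be unique", call. = FALSE)
    invisible(x)
  }
  check_labels(varieties, "varieties")
  check_labels(energy_levels, "energy_levels")
  if (!setequal(names(sections_by_variety), varieties)) {
    stop("sections_by_variety must be named by the varieties", call. = FALSE)
  }
  for (v in varieties) {
    check_labels(sections_by_variety[[v]], paste0("sections for variety ", v))
  }
  n_duplicates <- as.integer(n_duplicates)
  n_strips <- as.integer(n_strips)
  if (n_duplicates < 1L || n_strips < 1L) {
    stop("n_duplicates and n_strips must be positive integers", call. = FALSE)
  }
  structure(
    list(
      varieties = varieties,
      sections_by_variety = sections_by_variety[varieties],
      energy_levels = energy_levels,
      n_duplicates = n_duplicates,
      n_strips = n_strips
    ),
    class = "design_spec"
  )
}

#' Default sorghum biomass-to-nanopaper design
#'
#' Four sorghum varieties, three plant sections nested in each variety,
#' three homogenisation energy levels, two nanopaper duplicates per sample
#' and eight tensile strips per duplicate (576 strip observations in total).
#'
#' @return A [design_spec()] object.
#' @export
default_design <- function() {
  design_spec(
    varieties = c("Sugargraze", "Yemen", "GreenleafBMR", "Graingrass"),
    sections_by_variety = c("Leaf", "Sheath", "Stem"),
    energy_levels = c("Low", "Medium", "High"),
    n_duplicates = 2L,
    n_strips = 8L
  )
}

#' @export
print.design_spec <- function(x, ...) {
  n_sections <- sum(lengths(x$sections_by_variety))
  cat("Experimental design:\n")
  cat("  varieties:     ", paste(x$varieties, collapse = ", "), "\n")
  cat("  sections:      ", n_sections, "(nested within variety)\n")
  cat("  energy levels: ", paste(x$energy_levels, collapse = " < "), "\n")
  cat("  replication:   ", x$n_duplicates, "duplicates x",
      x$n_strips, "strips\n")
  cat("  design cells:  ", length(design_cells(x)$variety), "samples,",
      length(design_cells(x)$variety) * x$n_duplicates * x$n_strips,
      "strip observations\n")
  invisible(x)
}

# All (variety, section, energy) sample cells of a design, sorted.
design_cells <- function(design) {
  cells <- do.call(rbind, lapply(design$varieties, function(v) {
    expand.grid(
      variety = v,
      section = design$sections_by_variety[[v]],
      energy = design$energy_levels,
      stringsAsFactors = FALSE
    )
  }))
  cells[order(cells$variety, cells$section, cells$energy), , drop = FALSE]
}

#' Sample identifiers of a design
#'
#' Samples are the variety x section x energy cells; identifiers join the
#' three labels with a pipe (`"variety|section|energy"`), which sorts
#' unambiguously.
#'
#' @param design a [design_spec()].
#' @return Character vector of sample ids, sorted.
#' @export
sample_ids <- function(design) {
  cells <- design_cells(design)
  sort(paste(cells$variety, cells$section, cells$energy, sep = "|"))
}

obs_factor_cols <- c("variety", "section", "energy", "nanopaper", "strip")
obs_key_cols <- c(obs_factor_cols, "metric")

#' Long-format observation table
#'
#' One row per measured strip and metric, keyed by the five design factors.
#' Values may be `NA` (blank cells on read) but never infinite; keys must be
#' unique. If a design is supplied, every (variety, section) pair must exist
#' in it.
#'
#' @param data data.frame with columns `variety`, `section`, `energy`,
#'   `nanopaper`, `strip`, `metric`, `value`.
#' @param design optional [design_spec()] to validate factor labels against.
#' @return The validated data.frame with class `observation_table`.
#' @export
observation_table <- function(data, design = NULL) {
  missing_cols <- setdiff(c(obs_key_cols, "value"), names(data))
  if (length(missing_cols) > 0L) {
    stop("observation table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  data <- as.data.frame(data)[, c(obs_key_cols, "value")]
  for (col in obs_key_cols) data[[col]] <- as.character(data[[col]])
  data$value <- as.numeric(data$value)
  bad <- !is.na(data$value) & !is.finite(data$value)
  if (any(bad)) {
    stop("non-finite value(s) in rows: ",
         paste(utils::head(which(bad), 5L), collapse = ", "), call. = FALSE)
  }
  key <- do.call(paste, c(data[obs_key_cols], sep = "\r"))
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1L]
    stop("duplicate observation key: ",
         gsub("\r", " / ", dup, fixed = TRUE), call. = FALSE)
  }
  if (!is.null(design)) {
    pairs <- unique(data[, c("variety", "section")])
    for (i in seq_len(nrow(pairs))) {
      v <- pairs$variety[i]
      if (!v %in% design$varieties ||
          !pairs$section[i] %in% design$sections_by_variety[[v]]) {
        stop("(variety, section) pair not in design: ",
             v, " / ", pairs$section[i], call. = FALSE)
      }
    }
  }
  rownames(data) <- NULL
  class(data) <- c("observation_table", "data.frame")
  data
}

#' Metric names present in an observation table
#' @param table an [observation_table()].
#' @return Character vector of metric names, sorted.
#' @export
metrics_of <- function(table) sort(unique(table$metric))

#' Read an observation table from CSV
#'
#' Expects a wide CSV: one row per strip, the five factor columns, and one
#' numeric column per metric. `schema` renames non-standard factor columns.
#'
#' @param path CSV file (comma separated, header row, UTF-8).
#' @param schema optional named character vector mapping standard factor names
#'   to the file's column names, e.g. `c(variety = "Variety")`.
#' @param design optional [design_spec()] to validate against.
#' @param quiet suppress the row/metric count message.
#' @return An [observation_table()] in long format.
#' @export
read_observations <- function(path, schema = NULL, design = NULL,
                              quiet = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                         colClasses = "character")
  colmap <- stats::setNames(obs_factor_cols, obs_factor_cols)
  if (!is.null(schema)) colmap[names(schema)] <- schema
  missing_cols <- colmap[!colmap %in% names(raw)]
  if (length(missing_cols) > 0L) {
    stop("missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  metric_cols <- setdiff(names(raw), colmap)
  if (length(metric_cols) == 0L) {
    stop("no metric columns found in ", path, call. = FALSE)
  }
  long <- do.call(rbind, lapply(metric_cols, function(m) {
    vals <- trimws(raw[[m]])
    vals[vals == ""] <- NA_character_
    num <- suppressWarnings(as.numeric(vals))
    bad <- which(!is.na(vals) & is.na(num))
    if (length(bad) > 0L) {
      stop("non-numeric value for metric '", m, "' at data row ", bad[1L],
           ": '", vals[bad[1L]], "'", call. = FALSE)
    }
    data.frame(
      variety = raw[[colmap[["variety"]]]],
      section = raw[[colmap[["section"]]]],
      energy = raw[[colmap[["energy"]]]],
      nanopaper = raw[[colmap[["nanopaper"]]]],
      strip = raw[[colmap[["strip"]]]],
      metric = m,
      value = num,
      stringsAsFactors = FALSE
    )
  }))
  tab <- observation_table(long, design = design)
  if (!quiet) {
    message(nrow(raw), " rows, ", length(metric_cols), " metric(s): ",
            paste(metric_cols, collapse = ", "))
  }
  tab
}

#' Write an observation table to CSV (wide format)
#'
#' Inverse of [read_observations()]: factor columns plus one column per
#' metric; `NA` values are written as blank cells.
#'
#' @param table an [observation_table()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_observations <- function(table, path) {
  wide <- stats::reshape(
    as.data.frame(table),
    idvar = obs_factor_cols, timevar = "metric", direction = "wide"
  )
  names(wide) <- sub("^value\\.", "", names(wide))
  metric_cols <- sort(setdiff(names(wide), obs_factor_cols))
  wide <- wide[do.call(order, wide[obs_factor_cols]),
               c(obs_factor_cols, metric_cols)]
  utils::write.csv(wide, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Samples-by-metrics matrix
#'
#' Container for a numeric samples x metrics matrix with unique row and
#' column labels, optionally carrying a per-metric direction (+1 higher is
#' better, -1 lower is better).
#'
#' @param values numeric matrix with row names (sample ids) and column names
#'   (metric names).
#' @param directions optional named vector of +1/-1 per metric.
#' @return `values` with class `metric_matrix` and a `directions` attribute.
#' @export
metric_matrix <- function(values, directions = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("metric matrix needs row (sample) and column (metric) names",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(values)) || anyDuplicated(colnames(values))) {
    stop("duplicate sample or metric labels", call. = FALSE)
  }
  if (!all(is.finite(values))) {
    stop("metric matrix entries must be finite", call. = FALSE)
  }
  if (!is.null(directions)) {
    if (is.null(names(directions)) ||
        !all(names(directions) %in% colnames(values)) ||
        !all(directions %in% c(-1, 1))) {
      stop("directions must be a named vector of +1/-1 over the metrics",
           call. = FALSE)
    }
  }
  structure(values, directions = directions,
            class = c("metric_matrix", "matrix", "array"))
}

#' @export
print.metric_matrix <- function(x, ...) {
  cat("metric_matrix: ", nrow(x), " samples x ", ncol(x), " metrics\n",
      sep = "")
  print(utils::head(unclass(x), 6L), ...)
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}

#' Aggregate strip observations up to a sampling level
#'
#' Averages metric values over all units below the chosen level (complete
#' case: `NA` values are dropped per metric before averaging). Sample ids
#' join the identifying factor labels with pipes; rows and columns are
#' sorted, so the result is deterministic.
#'
#' @param table an [observation_table()].
#' @param level `"sample"` (variety x section x energy; the CNF sample),
#'   `"nanopaper"` (one row per duplicate sheet) or `"strip"` (no averaging).
#' @return A [metric_matrix()].
#' @export
aggregate_to_samples <- function(table,
                                 level = c("sample", "nanopaper", "strip")) {
  level <- match.arg(level)
  if (nrow(table) == 0L) stop("empty observation table", call. = FALSE)
  id_cols <- switch(level,
    sample = c("variety", "section", "energy"),
    nanopaper = c("variety", "section", "energy", "nanopaper"),
    strip = obs_factor_cols
  )
  id <- do.call(paste, c(as.data.frame(table)[id_cols], sep = "|"))
  keep <- !is.na(table$value)
  means <- tapply(table$value[keep],
                  list(id[keep], table$metric[keep]), mean)
  ids <- sort(rownames(means))
  mets <- sort(colnames(means))
  values <- means[ids, mets, drop = FALSE]
  if (anyNA(values)) {
    stop("no observed values for some sample x metric cells; ",
         "cannot build a complete metric matrix", call. = FALSE)
  }
  metric_matrix(values)
}

#' Write / read a metric matrix as wide CSV
#'
#' @param m a [metric_matrix()].
#' @param path CSV path; first column `sample_id`, one column per metric.
#' @return `path` (write) or a [metric_matrix()] (read).
#' @export
write_metric_matrix <- function(m, path) {
  df <- data.frame(sample_id = rownames(m), unclass(m),
                   check.names = FALSE, row.names = NULL)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_metric_matrix
#' @export
read_metric_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df)) {
    stop("metric matrix CSV needs a sample_id column", call. = FALSE)
  }
  values <- as.matrix(df[, setdiff(names(df), "sample_id"), drop = FALSE])
  rownames(values) <- df$sample_id
  metric_matrix(values)
}

#' Check replication balance against a design
#'
#' Counts observed strips per design cell (variety x section x energy) and
#' metric, and compares with the expected `n_duplicates * n_strips`. `NA`
#' values count as missing.
#'
#' @param table an [observation_table()].
#' @param design a [design_spec()].
#' @return A list of class `balance_report`: `is_balanced` flag, the expected
#'   per-cell count, and a `cells` data.frame with observed counts (only
#'   unbalanced cells are flagged in printing).
#' @export
validate_balance <- function(table, design) {
  cells <- design_cells(design)
  expected <- design$n_duplicates * design$n_strips
  mets <- if (nrow(table) > 0L) metrics_of(table) else character()
  grid <- expand.grid(idx = seq_len(nrow(cells)),
                      metric = if (length(mets)) mets else NA_character_,
                      stringsAsFactors = FALSE)
  out <- data.frame(
    variety = cells$variety[grid$idx],
    section = cells$section[grid$idx],
    energy = cells$energy[grid$idx],
    metric = grid$metric,
    expected = expected,
    observed = 0L,
    stringsAsFactors = FALSE
  )
  if (nrow(table) > 0L) {
    tab <- table[!is.na(table$value), , drop = FALSE]
    key_obs <- paste(tab$variety, tab$section, tab$energy, tab$metric,
                     sep = "\r")
    key_out <- paste(out$variety, out$section, out$energy, out$metric,
                     sep = "\r")
    counts <- table(key_obs)
    hit <- key_out %in% names(counts)
    out$observed[hit] <- as.integer(counts[key_out[hit]])
  }
  structure(
    list(
      is_balanced = nrow(out) > 0L && length(mets) > 0L &&
        all(out$observed == out$expected),
      expected_per_cell = expected,
      cells = out
    ),
    class = "balance_report"
  )
}

#' @export
print.balance_report <- function(x, ...) {
  cat("Balance report: ",
      if (x$is_balanced) "balanced" else "NOT balanced",
      " (expected ", x$expected_per_cell, " strips per cell)\n", sep = "")
  off <- x$cells[x$cells$observed != x$cells$expected, , drop = FALSE]
  if (nrow(off) > 0L) {
    cat(nrow(off), "cell(s) off balance; first few:\n")
    print(utils::head(off, 5L))
  }
  invisible(x)
}
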