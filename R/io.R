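# CSV and configuration I/O. Panels and injury logs travel as long-format
# UTF-8 CSV with a short metadata header of '#' comment lines (seed and
# content hash), so that deterministic outputs can be reproduced and
# verified bit-for-bit.

metadata_header <- function(kind, data, seed = NULL) {
  c(
    sprintf("# injurydesign %s", kind),
    if (!is.null(seed)) sprintf("# seed: %d", as.integer(seed)),
    sprintf("# hash: %s", rlang::hash(data))
  )
}

count_leading_comments <- function(path) {
  lines <- readr::read_lines(path, n_max = 50)
  n <- 0L
  for (l in lines) {
    if (startsWith(l, "#")) n <- n + 1L else break
  }
  n
}

#' Write / read a daily-state panel as CSV
#'
#' Long-format CSV with columns `participant_id`, `day_index`, `variable`,
#' `value` (and `latent` if present), preceded by `#` metadata lines
#' (seed if supplied, content hash). Reading validates the panel: the
#' required columns must be present, `(participant, day, variable)`
#' triples must be unique (duplicates are reported with their file line
#' numbers), and non-missing values must be positive integer categories.
#' Unknown extra columns are kept with a warning. An empty file with a
#' valid header yields an empty panel.
#'
#' @param panel Panel tibble (see [simulate_state_panel()]).
#' @param path File path.
#' @param seed Optional integer seed recorded in the metadata header.
#' @return `write_panel_csv()` returns `path` invisibly;
#'   `read_panel_csv()` returns the panel tibble.
#' @examples
#' cfg <- generator_config(n_participants = 3, n_days = 4, seed = 2)
#' p <- simulate_state_panel(cfg)
#' f <- tempfile(fileext = ".csv")
#' write_panel_csv(p, f, seed = cfg$seed)
#' identical(read_panel_csv(f)$value, p$value)
#' @export
write_panel_csv <- function(panel, path, seed = NULL) {
  stopifnot(is.data.frame(panel))
  readr::write_lines(metadata_header("panel", panel, seed), path)
  readr::write_csv(panel, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_panel_csv
#' @export
read_panel_csv <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  panel <- readr::read_csv(
    path, comment = "#", show_col_types = FALSE,
    col_types = readr::cols(
      participant_id = readr::col_character(),
      day_index = readr::col_integer(),
      variable = readr::col_character(),
      value = readr::col_integer(),
      .default = readr::col_guess()
    )
  )
  required <- c("participant_id", "day_index", "variable", "value")
  missing_cols <- setdiff(required, names(panel))
  if (length(missing_cols) > 0) {
    abort(paste0(path, ": missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  extra <- setdiff(names(panel), c(required, "latent"))
  if (length(extra) > 0) {
    warn(paste0(path, ": unknown column(s) kept as-is: ",
                paste(extra, collapse = ", ")))
  }
  key <- paste(panel$participant_id, panel$day_index, panel$variable)
  dup <- which(duplicated(key))
  if (length(dup) > 0) {
    offset <- count_leading_comments(path) + 1L
    abort(sprintf(
      "%s: duplicate (participant, day, variable) at line(s) %s", path,
      paste(utils::head(dup + offset, 10), collapse = ", ")))
  }
  bad <- which(!is.na(panel$value) & (panel$value < 1))
  if (length(bad) > 0) {
    offset <- count_leading_comments(path) + 1L
    abort(sprintf("%s: state values below 1 at line(s) %s", path,
                  paste(utils::head(bad + offset, 10), collapse = ", ")))
  }
  panel
}

#' Write / read an injury log as CSV
#'
#' Columns `participant_id`, `day_index`, `classification`,
#' `missed_performances`, with the same metadata-header convention as
#' [write_panel_csv()]. Reading validates that time-loss (`"tl1"`) records
#' miss at least one performance.
#'
#' @param log Injury-log tibble (see [simulate_injuries()]).
#' @param path File path.
#' @param seed Optional integer seed recorded in the metadata header.
#' @return `write_injury_csv()` returns `path` invisibly;
#'   `read_injury_csv()` the log tibble.
#' @export
write_injury_csv <- function(log, path, seed = NULL) {
  stopifnot(is.data.frame(log))
  readr::write_lines(metadata_header("injury-log", log, seed), path)
  readr::write_csv(log, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_injury_csv
#' @export
read_injury_csv <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  log <- readr::read_csv(
    path, comment = "#", show_col_types = FALSE,
    col_types = readr::cols(
      participant_id = readr::col_character(),
      day_index = readr::col_integer(),
      .default = readr::col_guess()
    )
  )
  if (all(c("classification", "missed_performances") %in% names(log))) {
    bad <- which(log$classification == "tl1" & log$missed_performances < 1)
    if (length(bad) > 0) {
      offset <- count_leading_comments(path) + 1L
      abort(sprintf(
        "%s: tl1 record(s) with no missed performances at line(s) %s",
        path, paste(utils::head(bad + offset, 10), collapse = ", ")))
    }
  }
  log
}

#' Read a run configuration from YAML or JSON
#'
#' Scenario and generator configurations are plain YAML (or JSON) maps
#' whose keys mirror the arguments of [generator_config()],
#' [trial_design()], [matched_design()] and [plan_scenarios()].
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    if (!requireNamespace("jsonlite", quietly = TRUE)) {
      abort("reading JSON configs requires the jsonlite package")
    }
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    abort(sprintf("unsupported config format '.%s' (use YAML or JSON)", ext))
  }
}
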