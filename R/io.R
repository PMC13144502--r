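# Flat-CSV input/output: one dialect (comma, header row, UTF-8, decimal
# point). Unit normalisation happens once at this boundary: heights in m,
# energies in kcal/day (a `kj` intake column is converted on read).

COHORT_FILES <- c(participants = "participants.csv",
                  isotope = "isotope_samples.csv",
                  doses = "doses.csv",
                  intake = "intake.csv")

#' Write a synthetic cohort to a directory of CSV files
#'
#' Writes `participants.csv`, `isotope_samples.csv`, `doses.csv` and
#' `intake.csv` (plus `truth.csv` when the simulation carries ground truth)
#' in the schema that [read_cohort()] consumes.
#'
#' @param sim A `cohort_sim` from [simulate_cohort()], or a compatible list.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort_csv <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(sim$participants, file.path(dir, COHORT_FILES[["participants"]]))
  readr::write_csv(sim$isotope$samples, file.path(dir, COHORT_FILES[["isotope"]]))
  readr::write_csv(sim$isotope$doses, file.path(dir, COHORT_FILES[["doses"]]))
  readr::write_csv(sim$intake, file.path(dir, COHORT_FILES[["intake"]]))
  if (!is.null(sim$truth)) {
    readr::write_csv(sim$truth, file.path(dir, "truth.csv"))
  }
  invisible(dir)
}

read_checked <- function(path, required, label) {
  if (!file.exists(path)) abort(paste0(label, " file not found: ", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    abort(paste0(label, " (", basename(path), ") is missing required column(s): ",
                 paste(miss, collapse = ", ")))
  }
  extra <- setdiff(names(df), required)
  if (length(extra)) {
    warn(paste0(label, ": ignoring unknown column(s): ",
                paste(extra, collapse = ", ")))
  }
  df
}

validate_rows <- function(df, col, check, msg, label) {
  bad <- which(!check(df[[col]]))
  if (length(bad)) {
    ids <- if ("participant_id" %in% names(df)) df$participant_id[bad]
           else if ("id" %in% names(df)) df$id[bad] else "?"
    abort(paste0(label, ": ", msg, " at row(s) ",
                 paste(head(bad, 5), collapse = ", "),
                 " (participant ", paste(head(ids, 5), collapse = ", "), ")"))
  }
  invisible(df)
}

#' Read a validation cohort from CSV files
#'
#' Reads the four sheets written by [write_cohort_csv()] (or hand-prepared in
#' the same schema), validates them row by row (positive weights and heights,
#' non-negative intakes, known tracers) and normalises units: an intake sheet
#' may carry `kj` instead of `kcal`, converted on read by / 4.184.
#'
#' @param dir Directory holding the four CSVs, or a named list/vector of
#'   paths (`participants`, `isotope`, `doses`, `intake`).
#' @return A list shaped like [simulate_cohort()] output (minus `params` and
#'   `truth`): `participants`, `isotope` (`samples`, `doses`), `intake`.
#' @export
read_cohort <- function(dir) {
  paths <- if (is.character(dir) && length(dir) == 1 && dir.exists(dir)) {
    as.list(file.path(dir, COHORT_FILES))
  } else as.list(dir)
  names(paths) <- names(paths) %||% names(COHORT_FILES)

  participants <- read_checked(
    paths$participants,
    c("id", "sex", "age_years", "height_m", "weight_day1_kg",
      "weight_day8_kg", "fm_kg", "ffm_kg", "ree_kcal_day", "pal_lifestyle"),
    "participants")
  validate_rows(participants, "weight_day1_kg", function(x) is.finite(x) & x > 0,
                "non-positive body weight", "participants")
  validate_rows(participants, "height_m",
                function(x) is.finite(x) & x > 1.2 & x < 2.2,
                "height outside (1.2, 2.2) m", "participants")

  samples <- read_checked(paths$isotope,
                          c("participant_id", "time_h", "tracer", "excess_ppm"),
                          "isotope samples")
  validate_rows(samples, "tracer", function(x) x %in% c("18O", "2H"),
                "unknown tracer", "isotope samples")
  validate_rows(samples, "time_h", function(x) is.finite(x) & x >= 0,
                "negative sample time", "isotope samples")

  doses <- read_checked(paths$doses,
                        c("participant_id", "tracer", "dose_g", "atom_fraction"),
                        "doses")
  validate_rows(doses, "dose_g", function(x) is.finite(x) & x > 0,
                "non-positive dose mass", "doses")

  intake_req <- c("participant_id", "tool", "day", "kcal", "carb_g", "sugar_g",
                  "fat_g", "satfat_g", "protein_g", "fibre_g", "occasions")
  intake_raw <- readr::read_csv(paths$intake, show_col_types = FALSE,
                                progress = FALSE)
  if (!"kcal" %in% names(intake_raw) && "kj" %in% names(intake_raw)) {
    intake_raw$kcal <- kcal_kj(intake_raw$kj, "kcal")
    intake_raw$kj <- NULL
    inform("intake sheet: converted `kj` column to kcal (/ 4.184)")
  }
  miss <- setdiff(intake_req, names(intake_raw))
  if (length(miss)) abort(paste0("intake sheet is missing required column(s): ",
                                 paste(miss, collapse = ", ")))
  intake <- intake_raw[intake_req]
  validate_rows(intake, "kcal", function(x) is.finite(x) & x >= 0,
                "negative energy intake", "intake")

  list(participants = participants,
       isotope = list(samples = samples, doses = doses),
       intake = intake)
}

#' Write and read a validity scorecard as long-format CSV
#'
#' @param report A `validity_report` from [build_scorecard()], or the long
#'   tibble from [as_tibble()] on one.
#' @param path CSV path.
#' @return `write_scorecard_csv()` returns `path` invisibly;
#'   `read_scorecard_csv()` returns the long tibble (`facet`, `metric`,
#'   `value`).
#' @export
write_scorecard_csv <- function(report, path) {
  long <- if (inherits(report, "validity_report")) as_tibble(report) else report
  readr::write_csv(long, path)
  invisible(path)
}

#' @rdname write_scorecard_csv
#' @export
read_scorecard_csv <- function(path) {
  read_checked(path, c("facet", "metric", "value"), "scorecard")
}
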