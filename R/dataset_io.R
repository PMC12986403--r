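# Reading, validating and filtering the 12-column datasets.
#
# Column order (positional; header text is ignored):
#   1-4  preoperative sphere (D), cylinder (D), axis (deg), vertex (mm)
#   5-8  intended target sphere, cylinder, axis, vertex
#   9-12 postoperative sphere, cylinder, axis, vertex
# Negative-cylinder notation at the spectacle plane, or corneal astigmatism
# entered with all sphere and vertex columns 0.

DATASET_COLUMNS <- c(
  "pre_sphere", "pre_cyl", "pre_axis", "pre_vertex",
  "target_sphere", "target_cyl", "target_axis", "target_vertex",
  "post_sphere", "post_cyl", "post_axis", "post_vertex"
)

#' Read a 12-column cohort dataset
#'
#' Reads an XLSX (first worksheet) or CSV file with one header row followed
#' by one data row per eye. Columns are mapped positionally; the header text
#' is ignored and extra columns beyond the twelfth are dropped with a
#' warning. Blank cells, empty strings and NA are treated as missing; zero is
#' a value (corneal-data mode relies on literal zeros). Axis values of 180
#' are normalized to 0. No exclusion is applied at this stage: every row is
#' returned with status \code{"pending"}; run [apply_exclusions()] next.
#'
#' @param path Path to a \code{.xlsx} or \code{.csv} file.
#' @param group_name Label for the cohort (used in tables and logs).
#' @return A \code{cohort} object: list with \code{group_name}, \code{data}
#'   (data frame with \code{row_index}, the 12 numeric columns,
#'   \code{status}, \code{reason}), \code{source_path} and
#'   \code{exclusion_log}.
#' @export
read_cohort <- function(path, group_name = basename(path)) {
  if (!file.exists(path)) stop("input file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    xlsx = ,
    xls = as.data.frame(readxl::read_excel(path, sheet = 1,
                                           col_types = "text",
                                           .name_repair = "minimal")),
    csv = utils::read.csv(path, header = TRUE, colClasses = "character",
                          check.names = FALSE, strip.white = TRUE),
    stop("unsupported file type '.", ext, "' (expected .xlsx or .csv): ",
         path)
  )
  if (ncol(raw) < 12) {
    stop("schema error in ", path, ": expected 12 columns, found ", ncol(raw))
  }
  if (ncol(raw) > 12) {
    warning("ignoring ", ncol(raw) - 12, " extra column(s) beyond the 12 ",
            "mandatory ones in ", path)
    raw <- raw[, 1:12]
  }
  names(raw) <- DATASET_COLUMNS
  parsed <- as.data.frame(lapply(seq_along(raw), function(j) {
    parse_numeric_column(raw[[j]], j, path)
  }))
  names(parsed) <- DATASET_COLUMNS
  validate_ranges(parsed, path)
  for (col in grep("_axis$", DATASET_COLUMNS, value = TRUE)) {
    present <- !is.na(parsed[[col]])
    parsed[[col]][present] <- normalize_axis(parsed[[col]][present])
  }
  data <- cbind(row_index = seq_len(nrow(parsed)), parsed)
  data$status <- rep("pending", nrow(data))
  data$reason <- rep("", nrow(data))
  structure(
    list(group_name = group_name, data = data, source_path = path,
         exclusion_log = data.frame(row_index = integer(), reason = character())),
    class = "cohort"
  )
}

# Parse one character column to numeric; blank/NA -> NA, anything else must
# parse (decimal notation, tolerating a unicode minus).
parse_numeric_column <- function(x, col_index, path) {
  x <- trimws(as.character(x))
  x[x == "" | toupper(x) == "NA"] <- NA_character_
  num <- suppressWarnings(as.numeric(gsub("−", "-", x)))
  bad <- which(!is.na(x) & is.na(num))
  if (length(bad) > 0) {
    stop("parse error in ", path, ": non-numeric value '", x[bad[1]],
         "' at data row ", bad[1], ", column ", col_index)
  }
  num
}

validate_ranges <- function(parsed, path) {
  for (col in grep("_axis$", names(parsed), value = TRUE)) {
    v <- parsed[[col]]
    bad <- which(!is.na(v) & (v < 0 | v > 180))
    if (length(bad) > 0) {
      stop("invalid axis in ", path, ": ", v[bad[1]], " at data row ",
           bad[1], ", column ", col, " (must lie in [0, 180])")
    }
  }
  for (col in grep("_vertex$", names(parsed), value = TRUE)) {
    v <- parsed[[col]]
    bad <- which(!is.na(v) & v < 0)
    if (length(bad) > 0) {
      stop("invalid vertex distance in ", path, ": ", v[bad[1]],
           " at data row ", bad[1], ", column ", col, " (must be >= 0 mm)")
    }
  }
}

#' Apply the standard exclusion rules to a cohort
#'
#' Rows with any blank among the 12 mandatory cells are excluded as missing
#' data. Complete rows whose corneal-plane TIA magnitude is below the
#' threshold are excluded as low-TIA (eyes with essentially no intended
#' astigmatic change, for which the ratio indices are unstable). A TIA of
#' exactly the threshold is included. All other rows become included.
#'
#' @param cohort A \code{cohort} from [read_cohort()].
#' @param tia_threshold Corneal-plane TIA magnitude below which an eye is
#'   excluded, dioptres. Default 0.25.
#' @return The cohort with \code{status}, \code{reason} and
#'   \code{exclusion_log} populated.
#' @export
apply_exclusions <- function(cohort, tia_threshold = 0.25) {
  stopifnot(inherits(cohort, "cohort"))
  data <- cohort$data
  cells <- data[, DATASET_COLUMNS]
  missing <- !stats::complete.cases(cells)
  status <- ifelse(missing, "excluded_missing", "included")
  reason <- ifelse(missing, "missing data in one or more of the 12 columns", "")
  complete <- which(!missing)
  if (length(complete) > 0) {
    tia <- corneal_tia_magnitude(cells[complete, , drop = FALSE])
    low <- tia < tia_threshold
    status[complete[low]] <- "excluded_low_tia"
    reason[complete[low]] <- sprintf(
      "corneal-plane TIA %.4f D below threshold %.2f D", tia[low],
      tia_threshold)
  }
  data$status <- status
  data$reason <- reason
  cohort$data <- data
  cohort$exclusion_log <- exclusion_log_of(data)
  cohort
}

exclusion_log_of <- function(data) {
  excl <- data$status != "included" & data$status != "pending"
  data.frame(row_index = data$row_index[excl], reason = data$reason[excl])
}

#' Align two cohorts for a paired design
#'
#' Pairing is by data-row position. For every row index where either side is
#' not included (missing data, low TIA, or an earlier pairing drop), the
#' partner row is marked \code{excluded_pair_partner}, so the surviving lists
#' have equal length and identical row-index sequences.
#'
#' @param group_a,group_b Cohorts after [apply_exclusions()].
#' @return A list with elements \code{a} and \code{b}, the aligned cohorts.
#' @export
align_pairs <- function(group_a, group_b) {
  stopifnot(inherits(group_a, "cohort"), inherits(group_b, "cohort"))
  na <- nrow(group_a$data)
  nb <- nrow(group_b$data)
  if (na != nb) {
    stop("paired design requires equal row counts, got ", na, " vs ", nb,
         " (pairing by row position is undefined beyond the shorter file)")
  }
  mark_partner <- function(self, other) {
    drop <- self$data$status == "included" & other$data$status != "included"
    self$data$status[drop] <- "excluded_pair_partner"
    self$data$reason[drop] <- paste0(
      "partner row excluded in paired group (",
      other$data$status[drop], ")")
    self$exclusion_log <- exclusion_log_of(self$data)
    self
  }
  list(a = mark_partner(group_a, group_b), b = mark_partner(group_b, group_a))
}

#' Included rows of a cohort
#'
#' @param cohort A \code{cohort}.
#' @return Data frame of the rows with status \code{"included"}
#'   (\code{row_index} + the 12 columns).
#' @export
included_data <- function(cohort) {
  cohort$data[cohort$data$status == "included",
              c("row_index", DATASET_COLUMNS)]
}

#' Write a cohort's exclusion log as a plain-text sidecar
#'
#' @param cohort A \code{cohort} after [apply_exclusions()].
#' @param path Output path for the log file.
#' @return \code{path}, invisibly.
#' @export
write_exclusion_log <- function(cohort, path) {
  log <- cohort$exclusion_log
  counts <- table(factor(cohort$data$status,
                         levels = c("included", "excluded_missing",
                                    "excluded_low_tia",
                                    "excluded_pair_partner")))
  lines <- c(
    paste0("Exclusion log for group '", cohort$group_name, "' (",
           cohort$source_path, ")"),
    sprintf("rows: %d total, %d included, %d missing-data, %d low-TIA, %d pair-partner",
            nrow(cohort$data), counts[["included"]],
            counts[["excluded_missing"]], counts[["excluded_low_tia"]],
            counts[["excluded_pair_partner"]]),
    if (nrow(log) > 0) sprintf("row %d: %s", log$row_index, log$reason)
    else "no rows excluded"
  )
  writeLines(lines, path)
  invisible(path)
}

#' Write a 12-column dataset as CSV
#'
#' Writes the 12 mandatory columns (plus header) so that the file round-trips
#' through [read_cohort()] with identical numeric values.
#'
#' @param data Data frame containing the 12 dataset columns.
#' @param path Output path (\code{.csv}).
#' @return \code{path}, invisibly.
#' @export
write_cohort_csv <- function(data, path) {
  out <- data[, DATASET_COLUMNS]
  header <- c(
    "PreopSphere", "PreopCylinder", "PreopAxis", "PreopVertex",
    "TargetSphere", "TargetCylinder", "TargetAxis", "TargetVertex",
    "PostopSphere", "PostopCylinder", "PostopAxis", "PostopVertex"
  )
  lines <- c(paste(header, collapse = ","),
             apply(out, 1, function(row) {
               paste(ifelse(is.na(row), "",
                            formatC(as.numeric(row), digits = 15,
                                    format = "g")), collapse = ",")
             }))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.cohort <- function(x, ...) {
  counts <- table(x$data$status)
  cat("<cohort> group '", x$group_name, "' from ", x$source_path, "\n",
      sep = "")
  cat("  rows:", nrow(x$data), "-",
      paste(names(counts), as.integer(counts), collapse = ", "), "\n")
  invisible(x)
}
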