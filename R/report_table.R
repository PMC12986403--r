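# Standardized vector-analysis table: fixed row order, fixed formatting,
# rendered as a 300-DPI TIFF with byte-identical CSV and JSON exports.

#' Format a value for the standardized table
#'
#' \describe{
#'   \item{metric}{mean ± SD, both to 2 decimal places ("1.23 ± 0.45"); an
#'     unavailable SD (single eye) renders as "—".}
#'   \item{p}{4 decimal places, with a display floor: values below 0.00005
#'     render as "<0.0001".}
#'   \item{d}{Cohen's d to 2 decimal places.}
#'   \item{pct}{1 decimal place with a "%" suffix.}
#' }
#' Unavailable values render as an em dash.
#'
#' @param kind One of \code{"metric"}, \code{"p"}, \code{"d"}, \code{"pct"}.
#' @param value The value (for \code{"metric"}, the mean).
#' @param sd The SD (only for \code{kind = "metric"}).
#' @return A character scalar.
#' @export
format_value <- function(kind = c("metric", "p", "d", "pct"), value,
                         sd = NA_real_) {
  kind <- match.arg(kind)
  dash <- "—"
  if (is.null(value) || is.na(value)) return(dash)
  switch(kind,
    metric = sprintf("%.2f ± %s", value,
                     if (is.na(sd)) dash else sprintf("%.2f", sd)),
    p = if (value < 0.00005) "<0.0001" else sprintf("%.4f", value),
    d = sprintf("%.2f", value),
    pct = sprintf("%.1f%%", value)
  )
}

# Fixed row descriptors: label, summary accessor, comparison key (or NA).
table_row_specs <- function() {
  list(
    list(label = "TIA (D)", metric = "TIA"),
    list(label = "SIA (D)", metric = "SIA"),
    list(label = "DV (D)", metric = "DV"),
    list(label = "CI", metric = "CI", geo = "CI"),
    list(label = "ME (D)", metric = "ME"),
    list(label = "AE (°)", metric = "AE"),
    list(label = "IOS", metric = "IOS", geo = "IOS"),
    list(label = "% ME within ±0.50 D", pct = "pct_me_within_050",
         binary = "ME within ±0.50 D"),
    list(label = "% ME within ±1.00 D", pct = "pct_me_within_100",
         binary = "ME within ±1.00 D"),
    list(label = "% AE within ±15°", pct = "pct_ae_within_15",
         binary = "AE within ±15°"),
    list(label = "% AE > 15°", pct = "pct_ae_gt_15"),
    list(label = "% AE < −15°", pct = "pct_ae_lt_m15")
  )
}

#' Assemble the standardized vector-analysis table
#'
#' Builds the fixed-order table: an n row, the seven continuous metrics as
#' mean ± SD (CI and IOS additionally carry their geometric mean in
#' parentheses), and the five threshold-proportion rows. Two-group tables add
#' a p-value and a Cohen's d column; the proportion rows that have a binary
#' test (ME ±0.50 D, ME ±1.00 D, AE ±15°) carry its p-value, the two AE tail
#' rows do not.
#'
#' @param summaries List of 1 or 2 [summarize_group()] results.
#' @param comparisons [compare_groups()] result (empty or NULL for a single
#'   group).
#' @param group_names Character vector matching \code{summaries}.
#' @param label Table caption text.
#' @param footnote Optional extra footnote line (e.g. exclusion counts).
#' @return A \code{vector_table} object: list with \code{label},
#'   \code{group_names}, \code{rows} (data frame of formatted strings) and
#'   \code{footnote}.
#' @export
build_table <- function(summaries, comparisons = NULL, group_names,
                        label = "Astigmatism vector analysis",
                        footnote = NULL) {
  if (length(summaries) < 1 || length(summaries) > 2) {
    stop("build_table expects 1 or 2 group summaries")
  }
  if (length(group_names) != length(summaries)) {
    stop("group_names must match the number of summaries")
  }
  two <- length(summaries) == 2
  if (two && (is.null(comparisons) || nrow(comparisons) == 0)) {
    stop("two-group table requires comparison results")
  }
  specs <- table_row_specs()
  value_col <- function(s) {
    vapply(specs, function(sp) {
      if (!is.null(sp$metric)) {
        st <- s$stats[[sp$metric]]
        txt <- format_value("metric", st$mean, st$sd)
        if (!is.null(sp$geo)) {
          g <- s$geometric[[sp$geo]]$geometric_mean
          txt <- paste0(txt, " (", if (is.na(g)) "—"
                        else sprintf("%.2f", g), ")")
        }
        txt
      } else {
        format_value("pct", s$proportions[[sp$pct]])
      }
    }, character(1))
  }
  rows <- data.frame(
    Metric = c("n", vapply(specs, `[[`, character(1), "label")),
    stringsAsFactors = FALSE
  )
  for (i in seq_along(summaries)) {
    rows[[group_names[i]]] <- c(as.character(summaries[[i]]$n_included),
                                value_col(summaries[[i]]))
  }
  if (two) {
    lookup <- function(key, col) {
      if (is.na(key)) return(NA_real_)
      hit <- comparisons[comparisons$metric == key, col]
      if (length(hit) == 0) NA_real_ else hit[1]
    }
    keys <- vapply(specs, function(sp) {
      if (!is.null(sp$metric)) sp$metric
      else if (!is.null(sp$binary)) sp$binary
      else NA_character_
    }, character(1))
    rows[["p-value"]] <- c("", vapply(keys, function(k) {
      format_value("p", lookup(k, "p_value"))
    }, character(1)))
    rows[["Cohen's d"]] <- c("", vapply(keys, function(k) {
      format_value("d", lookup(k, "cohens_d"))
    }, character(1)))
  }
  structure(list(label = label, group_names = group_names, rows = rows,
                 footnote = footnote),
            class = "vector_table")
}

#' @export
print.vector_table <- function(x, ...) {
  cat(x$label, "\n")
  print(x$rows, row.names = FALSE, right = FALSE)
  if (!is.null(x$footnote)) cat(x$footnote, "\n")
  invisible(x)
}

#' Render a vector table to TIFF, CSV and JSON
#'
#' Writes three sibling files sharing a path stem: a 300-DPI TIFF image of
#' the table (publication artwork), a UTF-8 CSV, and a JSON export (one
#' object per table row). The CSV and JSON carry exactly the formatted
#' strings shown in the image and are byte-identical across repeated runs.
#'
#' @param table A \code{vector_table} from [build_table()].
#' @param out_stem Output path without extension; \code{.tiff},
#'   \code{.csv} and \code{.json} are appended.
#' @return Named character vector of the three paths, invisibly.
#' @export
render_table_image <- function(table, out_stem) {
  stopifnot(inherits(table, "vector_table"))
  dir <- dirname(out_stem)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(tiff = paste0(out_stem, ".tiff"),
             csv = paste0(out_stem, ".csv"),
             json = paste0(out_stem, ".json"))
  write_table_csv(table, paths[["csv"]])
  write_table_json(table, paths[["json"]])
  draw_table_tiff(table, paths[["tiff"]])
  invisible(paths)
}

write_table_csv <- function(table, path) {
  rows <- table$rows
  quote_csv <- function(x) {
    needs <- grepl('[",\n]', x)
    x[needs] <- paste0('"', gsub('"', '""', x[needs]), '"')
    x
  }
  lines <- c(
    paste0("# ", table$label),
    paste(quote_csv(names(rows)), collapse = ","),
    apply(rows, 1, function(r) paste(quote_csv(unname(r)), collapse = ","))
  )
  if (!is.null(table$footnote)) lines <- c(lines, paste0("# ", table$footnote))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(enc2utf8(lines), con, useBytes = TRUE)
  invisible(path)
}

write_table_json <- function(table, path) {
  obj <- list(label = table$label, group_names = table$group_names,
              rows = table$rows)
  if (!is.null(table$footnote)) obj$footnote <- table$footnote
  json <- jsonlite::toJSON(obj, dataframe = "rows", auto_unbox = TRUE,
                           pretty = TRUE)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(enc2utf8(as.character(json)), con, useBytes = TRUE)
  invisible(path)
}

draw_table_tiff <- function(table, path, dpi = 300) {
  rows <- table$rows
  ncol <- ncol(rows)
  nrow <- nrow(rows)
  width_in <- max(6.5, 2.6 + 1.5 * ncol)
  height_in <- 0.28 * (nrow + 4)
  grDevices::tiff(path, width = width_in, height = height_in, units = "in",
                  res = dpi, compression = "lzw")
  on.exit(grDevices::dev.off())
  op <- graphics::par(mar = c(0.2, 0.2, 0.2, 0.2))
  on.exit(graphics::par(op), add = TRUE, after = FALSE)
  graphics::plot.new()
  graphics::plot.window(xlim = c(0, 1), ylim = c(0, 1))
  col_x <- c(0.02, seq(0.40, 0.98, length.out = max(ncol - 1, 1)))
  header_y <- 1 - 1.6 / (nrow + 4)
  row_y <- header_y - (seq_len(nrow) + 0.4) / (nrow + 4)
  graphics::text(0.5, 1 - 0.5 / (nrow + 4), table$label, font = 2,
                 cex = 0.95)
  for (j in seq_len(ncol)) {
    adj <- if (j == 1) 0 else 0.5
    graphics::text(col_x[j], header_y, names(rows)[j], font = 2, cex = 0.8,
                   adj = adj)
    graphics::text(col_x[j], row_y, rows[[j]], cex = 0.75, adj = adj)
  }
  graphics::segments(0, header_y - 0.25 / (nrow + 4), 1,
                     header_y - 0.25 / (nrow + 4))
  graphics::segments(0, header_y + 0.7 / (nrow + 4), 1,
                     header_y + 0.7 / (nrow + 4))
  bottom <- min(row_y) - 0.5 / (nrow + 4)
  graphics::segments(0, bottom, 1, bottom)
  if (!is.null(table$footnote)) {
    graphics::text(0.02, bottom - 0.7 / (nrow + 4), table$footnote,
                   cex = 0.6, adj = 0)
  }
  invisible(path)
}
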