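# End-to-end workflow: read -> exclude -> (pair) -> per-eye metrics ->
# summaries -> comparisons -> standardized table -> TIFF/CSV/JSON + logs.

#' Study configuration
#'
#' @param mode \code{"single"}, \code{"paired"} or \code{"unpaired"}.
#' @param group_a Path to the (first) 12-column data file.
#' @param group_b Path to the second data file (two-group modes only).
#' @param name_a,name_b Group display names.
#' @param label Caption for the standardized table.
#' @param out_dir Output directory.
#' @param tia_threshold Low-TIA exclusion threshold, dioptres (default
#'   0.25).
#' @param alpha Significance level of the normality gate (default 0.05).
#' @return A validated \code{study_config} list.
#' @export
study_config <- function(mode = c("single", "paired", "unpaired"),
                         group_a, group_b = NULL,
                         name_a = "Group A", name_b = "Group B",
                         label = "Astigmatism vector analysis",
                         out_dir = ".", tia_threshold = 0.25, alpha = 0.05) {
  mode <- match.arg(mode)
  if (mode == "single" && !is.null(group_b)) {
    stop("single-group mode takes exactly one input file")
  }
  if (mode != "single" && is.null(group_b)) {
    stop(mode, " mode requires two input files")
  }
  structure(list(mode = mode, group_a = group_a, group_b = group_b,
                 name_a = name_a, name_b = name_b, label = label,
                 out_dir = out_dir, tia_threshold = tia_threshold,
                 alpha = alpha),
            class = "study_config")
}

#' Run the full vector-analysis workflow
#'
#' Reads the input file(s), applies the missing-data and low-TIA exclusions,
#' aligns rows for a paired design, computes the per-eye Alpins metrics,
#' summarizes each group, runs the normality-gated comparisons (two-group
#' modes), and renders the standardized table as TIFF + CSV + JSON.
#' Exclusion logs (one per input) and a plain-text run log recording the
#' chosen tests and normality p-values are written alongside.
#'
#' @param config A [study_config()].
#' @return Invisibly, a list with the \code{table} (vector_table), per-group
#'   \code{summaries}, \code{comparisons}, per-eye \code{metrics}, the
#'   \code{cohorts}, and the output \code{paths}.
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "study_config"))
  if (!dir.exists(config$out_dir)) dir.create(config$out_dir, recursive = TRUE)

  a <- apply_exclusions(read_cohort(config$group_a, config$name_a),
                        config$tia_threshold)
  b <- NULL
  if (config$mode != "single") {
    b <- apply_exclusions(read_cohort(config$group_b, config$name_b),
                          config$tia_threshold)
  }
  if (config$mode == "paired") {
    aligned <- align_pairs(a, b)
    a <- aligned$a
    b <- aligned$b
  }

  data_a <- included_data(a)
  if (nrow(data_a) == 0) stop("no eyes left in '", a$group_name,
                              "' after exclusions")
  metrics_a <- compute_eye_metrics(data_a)
  summary_a <- summarize_group(metrics_a)
  metrics_b <- NULL
  summary_b <- NULL
  if (!is.null(b)) {
    data_b <- included_data(b)
    if (nrow(data_b) == 0) stop("no eyes left in '", b$group_name,
                                "' after exclusions")
    metrics_b <- compute_eye_metrics(data_b)
    summary_b <- summarize_group(metrics_b)
  }

  design <- if (config$mode == "paired") "paired" else "unpaired"
  comparisons <- compare_groups(metrics_a, metrics_b, design,
                                alpha = config$alpha)

  summaries <- Filter(Negate(is.null), list(summary_a, summary_b))
  names <- if (is.null(b)) config$name_a else c(config$name_a, config$name_b)
  footnote <- exclusion_footnote(Filter(Negate(is.null), list(a, b)))
  table <- build_table(summaries,
                       comparisons = if (is.null(b)) NULL else comparisons,
                       group_names = names, label = config$label,
                       footnote = footnote)

  stem <- file.path(config$out_dir, "vector_analysis_table")
  paths <- render_table_image(table, stem)
  for (cohort in Filter(Negate(is.null), list(a, b))) {
    log_path <- file.path(
      config$out_dir,
      paste0(basename(cohort$source_path), ".exclusions.log"))
    write_exclusion_log(cohort, log_path)
    paths <- c(paths, exclusions = log_path)
  }
  run_log <- file.path(config$out_dir, "run.log")
  write_run_log(config, list(a, b), comparisons, run_log)
  paths <- c(paths, run_log = run_log)

  invisible(list(table = table, summaries = summaries,
                 comparisons = comparisons,
                 metrics = list(a = metrics_a, b = metrics_b),
                 cohorts = list(a = a, b = b), paths = paths))
}

exclusion_footnote <- function(cohorts) {
  parts <- vapply(cohorts, function(co) {
    excl <- sum(co$data$status != "included")
    sprintf("%s: n = %d included, %d excluded", co$group_name,
            sum(co$data$status == "included"), excl)
  }, character(1))
  paste(parts, collapse = "; ")
}

write_run_log <- function(config, cohorts, comparisons, path) {
  cohorts <- Filter(Negate(is.null), cohorts)
  lines <- c(
    sprintf("mode: %s; TIA threshold: %.2f D; alpha: %.2f", config$mode,
            config$tia_threshold, config$alpha),
    vapply(cohorts, function(co) {
      counts <- table(factor(co$data$status,
                             levels = c("included", "excluded_missing",
                                        "excluded_low_tia",
                                        "excluded_pair_partner")))
      sprintf("group '%s' (%s): %d included, %d missing, %d low-TIA, %d pair-partner",
              co$group_name, co$source_path, counts[["included"]],
              counts[["excluded_missing"]], counts[["excluded_low_tia"]],
              counts[["excluded_pair_partner"]])
    }, character(1))
  )
  if (!is.null(comparisons) && nrow(comparisons) > 0) {
    lines <- c(lines, "test selection:",
               sprintf("  %-20s %-22s p=%s normality(A)=%s normality(B)=%s",
                       comparisons$metric, comparisons$test_used,
                       vapply(comparisons$p_value, format_value,
                              character(1), kind = "p"),
                       vapply(comparisons$normality_p_a, format_value,
                              character(1), kind = "p"),
                       vapply(comparisons$normality_p_b, format_value,
                              character(1), kind = "p")))
  }
  writeLines(lines, path)
  invisible(path)
}
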