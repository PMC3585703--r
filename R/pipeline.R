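# Write a report CSV with a provenance comment header (schema, seed,
# config hash) so a bundle is self-describing and reproducible.
write_report_csv <- function(df, path, seed, config_hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(
    "# gestage report; seed=%s; config_hash=%s", seed, config_hash
  ), con)
  utils::write.csv(as.data.frame(df), con, row.names = FALSE, na = "")
  invisible(path)
}

# Plain-text aligned rendering of a report table; not-defined markers
# (NA in metric columns) render as an em dash.
render_text_table <- function(df, title) {
  df <- as.data.frame(df)
  for (j in seq_along(df)) {
    col <- df[[j]]
    if (is.numeric(col)) {
      col <- ifelse(is.na(col), "—", format(round(col, 3)))
    } else {
      col <- ifelse(is.na(col), "—", as.character(col))
    }
    df[[j]] <- col
  }
  body <- utils::capture.output(print(df, row.names = FALSE))
  c(title, strrep("-", nchar(title)), body)
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)))
  })
}

#' Run the full GA analysis pipeline on a cohort file
#'
#' Orchestrates the complete analysis: read the cohort, compute every
#' available GA estimate, assign best estimates hierarchically, and write
#' the three classical comparison reports — the method-vs-reference
#' agreement table, the stratified GA-difference tables for menstrual
#' dating (maternal strata) and the Capurro exam (infant strata), and the
#' per-week GA distribution comparing the reference with the algorithm —
#' plus a machine-readable run manifest (package version, seed, config
#' hash, row counts, output files).  Identical inputs and configuration
#' produce a byte-identical bundle.  Any stage failure aborts with a
#' stage-named error and leaves an `INCOMPLETE` marker in the output
#' directory.
#'
#' @param cohort_path cohort CSV (schema of [write_cohort()]).
#' @param out_dir output directory, created if needed.
#' @param growth_path optional growth-reference CSV; default is the bundled
#'   synthetic reference.
#' @param priority assignment priority, see [assign_ga()].
#' @param strict strict outlier boundary, see [is_outlier()].
#' @param seed integer recorded in the manifest and report headers (the
#'   analysis itself is deterministic; the seed ties a bundle to the
#'   simulation that produced its input).
#' @return invisibly, a list with the in-memory results (`cohort`,
#'   `issues`, `estimates`, `assignments`, `tally`, `table1`, `table2`,
#'   `table3`, `manifest`).
#' @export
run_ga_pipeline <- function(cohort_path, out_dir, growth_path = NULL,
                            priority = c("US_7_20", "US_21_28", "US_29P", "LMP"),
                            strict = FALSE, seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  marker <- file.path(out_dir, "INCOMPLETE")
  writeLines("pipeline in progress", marker)

  growth <- run_stage("growth_reference", {
    if (is.null(growth_path)) {
      default_growth_reference()
    } else {
      read_growth_reference(growth_path)
    }
  })
  config_hash <- rlang::hash(list(
    schema = COHORT_SCHEMA, priority = priority, strict = strict,
    growth = as.data.frame(growth)
  ))

  read <- run_stage("read_cohort", read_cohort(cohort_path))
  cohort <- read$cohort
  if (nrow(read$issues) > 0) {
    readr::write_csv(
      read$issues, file.path(out_dir, "row_issues.csv"), progress = FALSE
    )
  }
  message(sprintf(
    "read_cohort: %d records read, %d rows skipped",
    nrow(cohort), nrow(read$issues)
  ))

  estimates <- run_stage("estimates", suppressWarnings(ga_estimates(cohort)))
  write_report_csv(
    estimates, file.path(out_dir, "estimates.csv"), seed, config_hash
  )

  assignments <- run_stage(
    "assign",
    assign_ga(cohort, ref = growth, priority = priority, strict = strict)
  )
  tally <- entrance_tally(assignments, priority)
  assign_out <- dplyr::mutate(
    assignments,
    excluded_methods = purrr::map_chr(
      .data$exclusion_trail,
      function(tr) paste(sprintf("%s:%s", tr$method, tr$reason), collapse = ";")
    ),
    exclusion_trail = NULL
  )
  write_report_csv(
    assign_out, file.path(out_dir, "assignments.csv"), seed, config_hash
  )
  write_report_csv(
    tally, file.path(out_dir, "entrance_tally.csv"), seed, config_hash
  )
  message(sprintf(
    "assign: %d classified, %d unclassified",
    sum(assignments$status == "classified"),
    sum(assignments$status == "unclassified")
  ))

  table1 <- run_stage(
    "method_comparison",
    method_comparison(cohort, growth = growth, strict = strict)
  )
  write_report_csv(
    table1, file.path(out_dir, "table1_method_comparison.csv"),
    seed, config_hash
  )

  table2 <- run_stage("difference_tables", {
    maternal <- c(
      "city", "age_group", "ethnicity", "schooling", "marital", "parity",
      "lmp_certain"
    )
    lmp_rows <- purrr::map(maternal, function(s) {
      dplyr::mutate(
        stratified_difference_table(cohort, "LMP", s),
        comparator = "LMP", stratifier = s, .before = 1
      )
    })
    cap_rows <- purrr::map(c("birth_weight", "ga_at_birth"), function(s) {
      dplyr::mutate(
        stratified_difference_table(cohort, "CAPURRO", s),
        comparator = "CAPURRO", stratifier = s, .before = 1
      )
    })
    dplyr::bind_rows(c(lmp_rows, cap_rows))
  })
  write_report_csv(
    table2, file.path(out_dir, "table2_ga_difference.csv"), seed, config_hash
  )

  table3 <- run_stage("ga_distribution", {
    em <- estimate_matrix(cohort, ref = growth, strict = strict)
    ref_keep <- !is.na(em$US_7_20) & !em$outlier_US_7_20
    ref_tab <- dplyr::mutate(
      ga_distribution(em$US_7_20[ref_keep]), source = "reference_us",
      .before = 1
    )
    alg_tab <- dplyr::mutate(
      ga_distribution(assignments$ga_days[assignments$status == "classified"]),
      source = "algorithm", .before = 1
    )
    dplyr::bind_rows(ref_tab, alg_tab)
  })
  write_report_csv(
    table3, file.path(out_dir, "table3_ga_distribution.csv"),
    seed, config_hash
  )

  txt <- c(
    render_text_table(table1, "Table 1. Method-vs-reference comparison"),
    "",
    render_text_table(table2, "Table 2. GA difference by strata"),
    "",
    render_text_table(table3, "Table 3. GA distribution (reference vs algorithm)")
  )
  writeLines(txt, file.path(out_dir, "tables.txt"))

  manifest <- list(
    package = "gestage",
    version = as.character(utils::packageVersion("gestage")),
    schema = COHORT_SCHEMA,
    seed = seed,
    config_hash = config_hash,
    priority = priority,
    strict = strict,
    cohort_path = basename(cohort_path),
    n_records = nrow(cohort),
    n_rows_skipped = nrow(read$issues),
    n_classified = sum(assignments$status == "classified"),
    n_unclassified = sum(assignments$status == "unclassified"),
    outputs = c(
      "estimates.csv", "assignments.csv", "entrance_tally.csv",
      "table1_method_comparison.csv", "table2_ga_difference.csv",
      "table3_ga_distribution.csv", "tables.txt"
    )
  )
  jsonlite::write_json(
    manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE
  )
  file.remove(marker)
  invisible(list(
    cohort = cohort, issues = read$issues, estimates = estimates,
    assignments = assignments, tally = tally, table1 = table1,
    table2 = table2, table3 = table3, manifest = manifest
  ))
}
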