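#' Pipeline configuration
#'
#' Assembles and validates the configuration driving [run_pipeline()]:
#' source-file paths, output directory, cleaning-cycle order, the
#' frequency-screen year span, presentation rounding, the situations analysed
#' by the rank tests, the Bonferroni switch, and the generator settings used
#' in `generate` mode. Unknown fields are rejected.
#'
#' @param reporting,indicators,facilities,emr Paths to the four source files.
#' @param out_dir Output directory for all artifacts.
#' @param order Cleaning-cycle order (see [run_cleaning_cycles()]).
#' @param year_span Frequency-screen threshold; defaults to the number of
#'   distinct years in the data.
#' @param rounding Decimal places for presentation tables. Default 2.
#' @param stats_situations Situation labels analysed across years. Default
#'   `c("B", "D")`.
#' @param bonferroni Apply Bonferroni adjustment in the post hoc table.
#'   Default `FALSE`.
#' @param generator A [generator_config()] (required for `generate`/`all`).
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(reporting = NULL, indicators = NULL,
                            facilities = NULL, emr = NULL,
                            out_dir = ".",
                            order = c("nonreporting", "erroneous", "duplicates"),
                            year_span = NULL,
                            rounding = 2L,
                            stats_situations = c("B", "D"),
                            bonferroni = FALSE,
                            generator = NULL) {
  if (!is.numeric(rounding) || rounding < 0) {
    config_error("rounding", "must be a non-negative integer")
  }
  bad <- setdiff(stats_situations, situation_table()$label)
  if (length(bad) > 0) {
    config_error("stats_situations", sprintf("contains unknown label(s): %s",
                                             paste(bad, collapse = ", ")))
  }
  if (!is.null(year_span) && (!is.numeric(year_span) || year_span < 1)) {
    config_error("year_span", "must be a positive integer or NULL")
  }
  if (!is.logical(bonferroni) || length(bonferroni) != 1L) {
    config_error("bonferroni", "must be TRUE or FALSE")
  }
  if (!is.null(generator) && !inherits(generator, "generator_config")) {
    config_error("generator", "must be created by generator_config()")
  }
  structure(
    list(
      reporting = reporting, indicators = indicators,
      facilities = facilities, emr = emr,
      out_dir = out_dir, order = order, year_span = year_span,
      rounding = as.integer(rounding), stats_situations = stats_situations,
      bonferroni = bonferroni, generator = generator
    ),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration file
#'
#' Loads a YAML configuration; keys mirror the arguments of
#' [pipeline_config()], with generator settings under a `generator` mapping
#' (keys mirroring [generator_config()], situation mixtures optional).
#' Unknown keys are rejected with a field-level message.
#'
#' @param path Path to a YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) io_error("Config file `%s` does not exist.", path)
  raw <- yaml::read_yaml(path)
  known <- c("reporting", "indicators", "facilities", "emr", "out_dir",
             "order", "year_span", "rounding", "stats_situations",
             "bonferroni", "generator")
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    config_error(unknown[1L], "is not a recognized configuration key")
  }
  gen <- NULL
  if (!is.null(raw$generator)) {
    g <- raw$generator
    gknown <- c("n_facilities", "years", "counties", "situation_mix",
                "facility_a_rate", "dup_scenario1_rate", "dup_scenario2_rate",
                "blank_zero_rate", "expected_reports_per_year", "seed")
    gunknown <- setdiff(names(g), gknown)
    if (length(gunknown) > 0) {
      config_error(paste0("generator.", gunknown[1L]),
                   "is not a recognized configuration key")
    }
    if (!is.null(g$situation_mix)) {
      g$situation_mix <- lapply(g$situation_mix, unlist)
    }
    gen <- do.call(generator_config, g)
  }
  args <- raw[setdiff(names(raw), "generator")]
  args$generator <- gen
  do.call(pipeline_config, args)
}

#' Run the pipeline
#'
#' Top-level dispatch: `generate` writes synthetic source files (plus the
#' ground-truth labels) into the output directory; `clean` ingests the four
#' sources, merges them and runs the cleaning cycles, writing six
#' `clean_<AREA>.csv` files, `cycles.json`, `audit.jsonl`, `merge_log.jsonl`
#' and `dataset4_areas.csv`; `stats` computes the distribution table, the
#' per-year count matrices and the Friedman / post hoc Wilcoxon results into
#' `report.json` and a human-readable `report.md`; `all` chains the three.
#' Progress is logged to standard error; artifacts only ever go under
#' `config$out_dir`.
#'
#' @param command One of `"generate"`, `"clean"`, `"stats"`, `"all"`.
#' @param config A [pipeline_config()].
#' @return Invisibly, a list of the artifacts produced by the final stage.
#' @export
run_pipeline <- function(command = c("all", "generate", "clean", "stats"),
                         config) {
  command <- match.arg(command)
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$out_dir
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)) {
    io_error("Cannot create output directory `%s`.", out_dir)
  }
  result <- NULL
  if (command %in% c("generate", "all")) {
    result <- pipeline_generate(config)
    if (command == "all") {
      config$reporting <- result$paths[["reporting"]]
      config$indicators <- result$paths[["indicators"]]
      config$facilities <- result$paths[["facilities"]]
      config$emr <- result$paths[["emr"]]
    }
  }
  if (command %in% c("clean", "all")) {
    result <- pipeline_clean(config)
  }
  if (command %in% c("stats", "all")) {
    result <- pipeline_stats(config)
  }
  invisible(result)
}

pipeline_generate <- function(config) {
  if (is.null(config$generator)) {
    config_error("generator", "is required for the generate command")
  }
  t0 <- Sys.time()
  registry <- generate_facility_registry(config$generator)
  extracts <- generate_extracts(registry, config$generator)
  extracts <- inject_duplicates(extracts, config$generator)
  paths <- write_sources(registry, extracts, config$out_dir)
  truth_path <- file.path(config$out_dir, "truth_labels.csv")
  readr::write_csv(extracts$truth, truth_path, na = "")
  log_stage("generate",
            n = nrow(extracts$reporting),
            seconds = as.numeric(Sys.time() - t0, units = "secs"))
  list(paths = c(paths, truth = truth_path), extracts = extracts,
       registry = registry)
}

pipeline_clean <- function(config) {
  for (f in c("reporting", "indicators", "facilities", "emr")) {
    if (is.null(config[[f]]) || !file.exists(config[[f]])) {
      config_error(f, "must point to an existing source file")
    }
  }
  t0 <- Sys.time()
  reporting <- read_reporting_extract(config$reporting)
  indicators <- read_indicator_extract(config$indicators)
  registry <- read_facility_list(config$facilities, config$emr)
  merged <- merge_sources(reporting, indicators, registry)
  res <- run_cleaning_cycles(merged$records, order = config$order)

  span <- config$year_span %||% length(unique(merged$records$year))
  # screen where duplicates are still present: the disaggregation of dataset 4
  freq_flags <- frequency_screen(
    dplyr::bind_rows(disaggregate_by_area(res$dataset4)), span
  )

  out_dir <- config$out_dir
  clean_paths <- character(0)
  for (a in names(res$area_datasets)) {
    p <- file.path(out_dir, sprintf("clean_%s.csv", a))
    readr::write_csv(res$area_datasets[[a]], p, na = "")
    clean_paths[a] <- p
  }
  cycles_path <- file.path(out_dir, "cycles.json")
  jsonlite::write_json(res$cycles, cycles_path, auto_unbox = TRUE, digits = NA)
  audit_path <- file.path(out_dir, "audit.jsonl")
  writeLines(
    vapply(seq_len(nrow(res$audit)), function(i) {
      jsonlite::toJSON(as.list(res$audit[i, ]), auto_unbox = TRUE, na = "null")
    }, character(1)),
    audit_path
  )
  mlog_path <- file.path(out_dir, "merge_log.jsonl")
  writeLines(
    vapply(seq_len(nrow(merged$log)), function(i) {
      jsonlite::toJSON(as.list(merged$log[i, ]), auto_unbox = TRUE, na = "null")
    }, character(1)),
    mlog_path
  )
  pre_path <- file.path(out_dir, "dataset4_areas.csv")
  readr::write_csv(dplyr::bind_rows(res$pre_treatment_areas), pre_path, na = "")
  counts_path <- file.path(out_dir, "situation_counts.csv")
  readr::write_csv(
    tibble::as_tibble(res$situation_counts, rownames = "area_code"),
    counts_path
  )
  meta_path <- file.path(out_dir, "clean_meta.json")
  jsonlite::write_json(
    list(dataset4_n = res$dataset4_n, dup_removed = res$dup_removed,
         year_span = span, n_freq_flagged = nrow(freq_flags)),
    meta_path, auto_unbox = TRUE, digits = NA
  )
  log_stage("clean",
            n = nrow(merged$records),
            seconds = as.numeric(Sys.time() - t0, units = "secs"))
  list(
    paths = c(clean_paths, cycles = cycles_path, audit = audit_path,
              merge_log = mlog_path, dataset4 = pre_path,
              counts = counts_path, meta = meta_path),
    result = res, merged = merged, freq_flags = freq_flags
  )
}

pipeline_stats <- function(config) {
  out_dir <- config$out_dir
  pre_path <- file.path(out_dir, "dataset4_areas.csv")
  counts_path <- file.path(out_dir, "situation_counts.csv")
  cycles_path <- file.path(out_dir, "cycles.json")
  meta_path <- file.path(out_dir, "clean_meta.json")
  for (p in c(pre_path, counts_path, cycles_path, meta_path)) {
    if (!file.exists(p)) {
      io_error("Expected artifact `%s` from the clean stage is missing.", p)
    }
  }
  t0 <- Sys.time()
  pre <- readr::read_csv(pre_path, show_col_types = FALSE, progress = FALSE)
  counts <- readr::read_csv(counts_path, show_col_types = FALSE, progress = FALSE)
  cycles <- tibble::as_tibble(jsonlite::read_json(cycles_path, simplifyVector = TRUE))
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)

  count_mat <- as.matrix(counts[setdiff(names(counts), "area_code")])
  rownames(count_mat) <- counts$area_code
  distribution <- situation_distribution(count_mat, meta$dup_removed, meta$dataset4_n)

  area_sets <- split(pre, factor(pre$area_code, levels = area_codes()))
  stats_out <- list()
  for (s in config$stats_situations) {
    m <- per_year_counts(area_sets, s)
    fr <- friedman_test(m)
    ph <- posthoc_pairwise(m, correct = config$bonferroni)
    stats_out[[s]] <- list(
      situation = s,
      count_matrix = m,
      friedman = fr[c("statistic", "statistic_uncorrected", "df",
                      "p_value", "mean_ranks", "n_blocks", "k")],
      pairwise = ph
    )
  }
  report <- list(
    distribution = distribution,
    dataset4_n = meta$dataset4_n,
    dup_removed = meta$dup_removed,
    tests = stats_out
  )
  report_path <- file.path(out_dir, "report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA)
  md <- render_report(cycles, distribution, stats_out, rounding = config$rounding)
  md_path <- file.path(out_dir, "report.md")
  writeLines(md, md_path)
  log_stage("stats", n = meta$dataset4_n,
            seconds = as.numeric(Sys.time() - t0, units = "secs"))
  list(paths = c(report = report_path, markdown = md_path),
       report = report, cycles = cycles)
}

#' Render the cleaning report
#'
#' Produces the human-readable markdown account of a cleaning run: cycle
#' accounting (records in, removed, out per rule), the per-area situation
#' distribution table, and the Friedman / pairwise Wilcoxon results. Every
#' number is taken from the supplied stage outputs; the renderer does no
#' arithmetic of its own beyond rounding.
#'
#' @param cycles Cycle-accounting tibble from [run_cleaning_cycles()].
#' @param distribution Distribution table from [situation_distribution()].
#' @param stats_out Named list of per-situation test results (see
#'   [run_pipeline()] `stats` stage).
#' @param rounding Decimal places for percentages.
#' @return Character vector of markdown lines.
#' @export
render_report <- function(cycles, distribution, stats_out = list(),
                          rounding = 2L) {
  lines <- c("# Data-cleaning report", "")
  lines <- c(lines, "## Cleaning cycles", "",
             md_table(cycles[c("cycle_id", "rule", "n_in", "n_removed", "n_out")]),
             "")
  dist <- distribution
  num_cols <- setdiff(names(dist), "situation")
  dist[num_cols] <- lapply(dist[num_cols], function(x) round(x, rounding))
  lines <- c(lines, "## Situation distribution (% of dataset-4 records per area)",
             "", md_table(dist), "")
  for (s in names(stats_out)) {
    st <- stats_out[[s]]
    lines <- c(lines, sprintf("## Rank tests for situation %s", s), "")
    fr <- st$friedman
    lines <- c(lines, sprintf(
      "Friedman chi-squared = %.4f (df = %d), p = %.4g; mean ranks: %s.",
      fr$statistic, fr$df, fr$p_value,
      paste(sprintf("%s %.2f", names(fr$mean_ranks), fr$mean_ranks),
            collapse = ", ")
    ), "")
    ph <- st$pairwise
    ph$z_value <- round(ph$z_value, 3)
    ph$p_value <- round(ph$p_value, 3)
    lines <- c(lines, md_table(ph[c("pair", "z_value", "p_value", "direction")]), "")
  }
  lines
}

md_table <- function(df) {
  df <- as.data.frame(df)
  cells <- vapply(df, function(col) {
    out <- as.character(col)
    out[is.na(out)] <- ""
    out
  }, character(nrow(df)))
  if (nrow(df) == 1L) cells <- matrix(cells, nrow = 1L)
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  body <- apply(cells, 1L, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(header, sep, body)
}

log_stage <- function(stage, n, seconds) {
  message(sprintf("[dhisclean] stage=%s records=%d elapsed=%.2fs",
                  stage, n, seconds))
}
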