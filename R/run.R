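# Batch runners behind the command-line interface: simulate recording sets,
# analyze them into a per-cell results CSV, and compare/summarize into
# publication-style tables. Identical config + seed give identical outputs.

run_log <- function(cfg, verbose, ...) {
  if (verbose) message(sprintf(...))
}

config_protocols <- function(cfg) {
  pr <- default_protocols(iv_step_duration = cfg$protocols$iv_step_duration,
                          dt = cfg$protocols$dt)
  pr[cfg$protocols$use]
}

config_cohort_spec <- function(cfg, i) {
  co <- cfg$cohorts[[i]]
  args <- co[setdiff(names(co), c("construct", "n_cells", "seed"))]
  # per-cohort seeds derived from the run seed unless given explicitly
  seed <- co$seed %||% derive_seeds(cfg$seed, length(cfg$cohorts))[i]
  do.call(reference_cohort_spec,
          c(list(construct = co$construct, n_cells = co$n_cells,
                 seed = seed), args))
}

write_run_info <- function(cfg, dir, stage) {
  info <- c(
    sprintf("stage = %s", stage),
    sprintf("seed = %d", cfg$seed),
    sprintf("config_hash = %s", cfg$config_hash),
    sprintf("cavgating_version = %s",
            as.character(utils::packageVersion("cavgating"))),
    sprintf("r_version = %s", R.version.string),
    sprintf("timestamp = %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  )
  writeLines(info, file.path(dir, paste0(stage, "-run-info.txt")))
}

#' Simulate the configured recording sets
#'
#' @param cfg A `run_config` ([read_run_config()]).
#' @param verbose Print progress.
#' @return Invisibly, the list of recordings; each is also written to
#'   `<output_dir>/recordings/` in the text dialect.
#' @export
run_simulate <- function(cfg, verbose = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  rec_dir <- file.path(cfg$output_dir, "recordings")
  dir.create(rec_dir, recursive = TRUE, showWarnings = FALSE)
  protocols <- config_protocols(cfg)
  all_recs <- list()
  for (i in seq_along(cfg$cohorts)) {
    spec <- config_cohort_spec(cfg, i)
    run_log(cfg, verbose, "simulating %s (%d cells, seed %d)",
            spec$construct_label, spec$n_cells, spec$seed)
    recs <- simulate_cohort(spec, protocols, leak = cfg$preprocess$leak)
    for (rec in recs) {
      fn <- sprintf("%s_%s.txt", rec$cell_id, tolower(rec$protocol$kind))
      write_recording(rec, file.path(rec_dir, fn))
    }
    all_recs <- c(all_recs, recs)
  }
  write_run_info(cfg, cfg$output_dir, "simulate")
  invisible(all_recs)
}

#' Analyze recordings into a per-cell results CSV
#'
#' @param cfg A `run_config`.
#' @param recordings Optional in-memory recordings; otherwise read back
#'   from `<output_dir>/recordings/`.
#' @param verbose Print progress.
#' @return The per-cell results data.frame (also written to
#'   `<output_dir>/results.csv`). QC-excluded cells stay in the table,
#'   flagged.
#' @export
run_analyze <- function(cfg, recordings = NULL, verbose = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  if (is.null(recordings)) {
    rec_dir <- file.path(cfg$output_dir, "recordings")
    files <- list.files(rec_dir, pattern = "\\.txt$", full.names = TRUE)
    if (length(files) == 0L) stop("no recordings found under ", rec_dir)
    run_log(cfg, verbose, "reading %d recordings", length(files))
    recordings <- lapply(files, read_recording)
  }
  results <- analyze_cohort(recordings, ljp = cfg$preprocess$ljp)
  utils::write.csv(results, file.path(cfg$output_dir, "results.csv"),
                   row.names = FALSE)
  write_run_info(cfg, cfg$output_dir, "analyze")
  invisible(results)
}

#' Summarize and compare constructs
#'
#' Writes the mean +/- SEM group summary, a tidy comparison table (one row
#' per statistical test) and rendered gating/kinetics tables.
#'
#' @param cfg A `run_config`.
#' @param results Optional in-memory results table; otherwise read from
#'   `<output_dir>/results.csv`.
#' @param verbose Print progress.
#' @return List with `summary`, `comparisons`, `gating_table`,
#'   `kinetics_table` (the latter `NULL` when no r-values are present).
#' @export
run_compare <- function(cfg, results = NULL, verbose = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  if (is.null(results)) {
    f <- file.path(cfg$output_dir, "results.csv")
    if (!file.exists(f)) stop("results table not found: ", f)
    results <- utils::read.csv(f, stringsAsFactors = FALSE)
  }
  summary <- summarize_groups(results)
  params <- unique(summary$parameter)
  comparisons <- if (length(unique(results$construct)) >= 2L) {
    do.call(rbind, lapply(params, function(p) {
      tryCatch(compare_constructs(results, p, reference = cfg$reference,
                                  comparisons = cfg$comparisons),
               error = function(e) NULL)
    }))
  } else {
    NULL
  }
  gating <- render_group_table(summary, comparisons, layout = "gating")
  kin_par <- intersect(paste0("r", c(50, 100, 250, 500, 1000, 5000)), params)
  kinetics <- if (length(kin_par)) {
    render_group_table(summary, comparisons, layout = "kinetics")
  } else {
    NULL
  }
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(summary, file.path(cfg$output_dir, "group-summary.csv"),
                   row.names = FALSE)
  if (!is.null(comparisons)) {
    utils::write.csv(comparisons,
                     file.path(cfg$output_dir, "comparisons.csv"),
                     row.names = FALSE)
  }
  utils::write.csv(gating, file.path(cfg$output_dir, "gating-table.csv"),
                   row.names = FALSE)
  con <- file.path(cfg$output_dir, "gating-table.txt")
  utils::capture.output(print(gating, row.names = FALSE), file = con)
  if (!is.null(kinetics)) {
    utils::write.csv(kinetics,
                     file.path(cfg$output_dir, "kinetics-table.csv"),
                     row.names = FALSE)
  }
  write_run_info(cfg, cfg$output_dir, "compare")
  invisible(list(summary = summary, comparisons = comparisons,
                 gating_table = gating, kinetics_table = kinetics))
}

#' Run the whole pipeline
#'
#' Chains [run_simulate()], [run_analyze()] and [run_compare()].
#'
#' @param cfg A `run_config`.
#' @param verbose Print progress.
#' @return The [run_compare()] result, invisibly.
#' @export
run_all <- function(cfg, verbose = FALSE) {
  recs <- run_simulate(cfg, verbose = verbose)
  results <- run_analyze(cfg, recordings = recs, verbose = verbose)
  run_compare(cfg, results = results, verbose = verbose)
}
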