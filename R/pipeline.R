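#' Configuration for a full pipeline run
#'
#' @param experiment 1 or 2.
#' @param stimulus_seed,simulation_seed Separate seeds for the stimulus
#'   build and the synthetic raters, so either can be varied alone.
#' @param params Simulation parameters; defaults to the experiment's
#'   preset.
#' @param nodes Quadrature nodes for the model fit.
#' @param min_ratings Inclusion threshold for raters.
#' @param fit_model Set `FALSE` to stop after simulation (enumeration
#'   and stimuli only).
#' @param term_tests Run the per-term likelihood-ratio tests (the most
#'   expensive stage)?
#' @return List of class `"run_config"`.
#' @export
run_config <- function(experiment = 1, stimulus_seed = 1L,
                       simulation_seed = 2L, params = NULL, nodes = 9,
                       min_ratings = 60, fit_model = TRUE,
                       term_tests = FALSE) {
  if (is.null(params))
    params <- simulation_params(if (experiment == 1) "exp1" else "exp2")
  structure(list(experiment = as.integer(experiment),
                 stimulus_seed = as.integer(stimulus_seed),
                 simulation_seed = as.integer(simulation_seed),
                 params = params, nodes = nodes,
                 min_ratings = min_ratings,
                 fit_model = fit_model, term_tests = term_tests),
            class = "run_config")
}

#' Run the full synthetic pipeline
#'
#' Enumerate the pattern spaces, build the stimulus set, simulate
#' raters, apply the inclusion filter, fit the cumulative-link mixed
#' model and (optionally) run the per-term likelihood-ratio tests.
#' Identical configuration and seeds give a bit-identical report.
#'
#' @param config A [run_config()].
#' @param out_dir Optional directory; when given, all stage artifacts
#'   and a plain-text report are written there.
#' @return List of class `"run_report"` with `config`, `conditions`,
#'   `stimuli`, `ratings`, `rating_distribution`, `fit`, `term_tests`,
#'   `estimates`, `log`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  log <- character(0)
  say <- function(fmt, ...) log <<- c(log, sprintf(fmt, ...))
  enum <- enumerate_experiment(config$experiment)
  say("enumerated %d temporal patterns, %d intensity patterns",
      nrow(enum$space$patterns), nrow(enum$intensity))
  say("%d of %d conditions used", sum(enum$conditions$used),
      nrow(enum$conditions))
  cfg <- experiment_config(config$experiment)
  stimuli <- build_experiment_stimuli(enum, cfg, seed = config$stimulus_seed)
  say("built %d trials (%d per accent type)", nrow(stimuli),
      nrow(stimuli) / 2L)
  ratings <- simulate_ratings(config$params, stimuli,
                              seed = config$simulation_seed)
  say("simulated %d ratings from %d participants", nrow(ratings),
      length(unique(ratings$participant_id)))
  kept <- apply_inclusion_filter(ratings, config$min_ratings)
  say("inclusion filter (>= %d ratings): kept %d of %d ratings",
      config$min_ratings, nrow(kept), nrow(ratings))
  dist <- table(factor(kept$rating, levels = 1:10))
  fit <- tests <- est <- NULL
  if (config$fit_model) {
    fit <- fit_clmm(kept, nodes = config$nodes)
    say("clmm fit: logLik %.3f, sigma_b %.3f, convergence %d",
        fit$logLik, fit$sigma_b, fit$convergence)
    if (config$term_tests) {
      tests <- lr_term_tests(kept, fit)
      say("term tests: %d terms", nrow(tests))
    }
    est <- condition_estimates(fit)
  }
  report <- structure(list(config = config, conditions = enum$conditions,
                           stimuli = stimuli, ratings = kept,
                           rating_distribution = dist, fit = fit,
                           term_tests = tests, estimates = est, log = log),
                      class = "run_report")
  if (!is.null(out_dir)) write_run_report(report, out_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("pipeline run\n")
  cat(paste0("  ", x$log, collapse = "\n"), "\n")
  invisible(x)
}

#' Write a run report to a directory
#'
#' Writes the enumeration table, stimulus manifest, ratings table,
#' rating distribution, term tests, condition estimates and a combined
#' human-readable `report.txt`.  Output is deterministic for a given
#' report.
#'
#' @param report A [run_pipeline()] result.
#' @param out_dir Directory (created if needed).
#' @export
write_run_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) utils::write.table(
    df, file.path(out_dir, name), sep = "\t", quote = FALSE,
    row.names = FALSE)
  w(report$conditions, "conditions.tsv")
  w(report$stimuli, "stimuli.tsv")
  write_ratings(report$ratings, file.path(out_dir, "ratings.csv"))
  if (!is.null(report$term_tests)) {
    tt <- report$term_tests
    tt$chi2 <- sprintf("%.2f", tt$chi2)
    tt$eta2 <- sprintf("%.3f", tt$eta2)
    tt$p <- sprintf("%.4f", tt$p)
    w(tt, "term_tests.tsv")
  }
  if (!is.null(report$estimates)) {
    es <- report$estimates
    es$estimate <- sprintf("%.4f", es$estimate)
    es$se <- sprintf("%.4f", es$se)
    w(es, "condition_estimates.tsv")
  }
  con <- file(file.path(out_dir, "report.txt"), "w")
  on.exit(close(con))
  cat("beatgrid pipeline report\n", file = con)
  cat(sprintf("package version %s\n",
              as.character(utils::packageVersion("beatgrid"))), file = con)
  cat(sprintf("experiment %d, stimulus seed %d, simulation seed %d\n",
              report$config$experiment, report$config$stimulus_seed,
              report$config$simulation_seed), file = con)
  cat("\n== stage log ==\n", file = con)
  writeLines(report$log, con)
  cat("\n== condition table ==\n", file = con)
  utils::write.table(report$conditions, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cat("\n== rating distribution (1-10) ==\n", file = con)
  cat(paste(as.integer(report$rating_distribution), collapse = " "),
      "\n", file = con)
  if (!is.null(report$fit)) {
    cat("\n== model ==\n", file = con)
    cat(sprintf("logLik %.6f  sigma_b %.6f  N %d  convergence %d\n",
                report$fit$logLik, report$fit$sigma_b, report$fit$N,
                report$fit$convergence), file = con)
    cat("coefficients:\n", file = con)
    utils::write.table(
      data.frame(column = names(report$fit$coefficients),
                 estimate = sprintf("%.6f", report$fit$coefficients)),
      con, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(out_dir)
}

#' Import a ratings table with validation
#'
#' Reads a delimited ratings table in the schema written by
#' [write_ratings()], checks every row (rating in 1..10, known accent
#' type, non-negative training years, no duplicate participant-trial
#' pairs) and reports rejected rows rather than silently dropping them.
#'
#' @param path CSV file path.
#' @return List with `records` (valid rows) and `rejected` (data frame
#'   of failing rows with a `reason` column).
#' @export
import_ratings <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "trial_id", "accent_type", "missing_beats",
            "off_beat_category", "training_years", "ioi_ms", "rating")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  reason <- rep("", nrow(raw))
  bad <- function(cond, why) reason[cond & reason == ""] <<- why
  bad(!is.finite(raw$rating) | raw$rating < 1 | raw$rating > 10 |
        raw$rating != round(raw$rating), "rating outside 1..10")
  bad(!raw$accent_type %in% c("temporal", "intensity"),
      "unknown accent type")
  bad(!raw$missing_beats %in% 0:3, "missing_beats outside 0..3")
  bad(!raw$off_beat_category %in% c("few", "some", "many"),
      "unknown off-beat category")
  bad(!is.finite(raw$training_years) | raw$training_years < 0,
      "invalid training years")
  bad(duplicated(raw[, c("participant_id", "trial_id")]),
      "duplicate participant-trial pair")
  ok <- reason == ""
  rejected <- raw[!ok, , drop = FALSE]
  if (nrow(rejected)) rejected$reason <- reason[!ok]
  records <- raw[ok, , drop = FALSE]
  records$rating <- as.integer(records$rating)
  rownames(records) <- rownames(rejected) <- NULL
  list(records = records, rejected = rejected)
}
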