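#' Pipeline configuration
#'
#' Describes one end-to-end run: either a synthetic-generator block or a
#' pair of input CSV paths (never both), the key fields, the candidate
#' filter (window, hospitals, age floor) and an optional output directory.
#'
#' @param generator A [cohort_config()] (or list of its arguments) for
#'   simulate mode, or `NULL`.
#' @param survey_path,admissions_path CSV paths for file mode, or `NULL`.
#' @param key_fields Linkage key columns.
#' @param window Closed month interval of candidate discharges.
#' @param hospitals Study hospital set.
#' @param min_age Survey/candidate age floor.
#' @param seed Seed for simulate mode (overrides the generator block's).
#' @param out_dir If non-`NULL`, stage outputs (CSV), the manifest (JSON)
#'   and a JSON-lines log are written there.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(generator = NULL, survey_path = NULL,
                            admissions_path = NULL,
                            key_fields = identifier_keys(),
                            window = c("2013-10", "2013-12"),
                            hospitals = vocab_hospital[1:7],
                            min_age = 45, seed = NULL, out_dir = NULL) {
  file_mode <- !is.null(survey_path) || !is.null(admissions_path)
  if (!is.null(generator) && file_mode) {
    stop("configuration error: supply either a generator block or input ",
         "paths, not both", call. = FALSE)
  }
  if (file_mode && (is.null(survey_path) || is.null(admissions_path))) {
    stop("configuration error: file mode needs both survey_path and ",
         "admissions_path", call. = FALSE)
  }
  if (is.null(generator) && !file_mode) {
    stop("configuration error: supply a generator block or input paths",
         call. = FALSE)
  }
  if (!is.null(generator)) {
    if (!inherits(generator, "cohort_config")) {
      generator <- do.call(cohort_config, generator)
    }
    if (!is.null(seed)) {
      generator <- do.call(cohort_config,
                           utils::modifyList(unclass(generator),
                                             list(seed = as.integer(seed))))
    }
  }
  assert_month(window)
  structure(list(generator = generator, survey_path = survey_path,
                 admissions_path = admissions_path, key_fields = key_fields,
                 window = window, hospitals = hospitals, min_age = min_age,
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file with the [pipeline_config()] fields; a `generator`
#'   mapping is passed to [cohort_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- raw[intersect(names(raw),
                        c("generator", "survey_path", "admissions_path",
                          "key_fields", "window", "hospitals", "min_age",
                          "seed", "out_dir"))]
  do.call(pipeline_config, args)
}

#' Run the full linkage-analysis pipeline
#'
#' Executes simulate (optional) -> preprocess -> link -> outcomes ->
#' analyze, carrying a manifest of row counts at every stage. The manifest's
#' ledger always reconciles: eligible survey rows = unique + one-to-many +
#' unmatched, and every dropped row is counted with its stage.
#'
#' @param config A `pipeline_config` ([pipeline_config()] /
#'   [read_pipeline_config()]).
#' @return List with `survey`, `admissions`, `candidates`, `linkage`
#'   (a `linkage_result`), `analysis` (the linked analysis table), `stats`
#'   (crosstabs, crude ORs, chi-square, bias diagnostics, six adjusted
#'   models and their rendered tables) and `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  log_lines <- list()
  note <- function(stage, ...) {
    entry <- c(list(stage = stage), list(...))
    log_lines[[length(log_lines) + 1L]] <<- entry
  }
  wrap <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop("[stage ", stage, "] ", conditionMessage(e), call. = FALSE)
    })
  }

  # --- simulate or read -----------------------------------------------
  if (!is.null(config$generator)) {
    pop <- wrap("simulate", generate_population(config$generator))
    survey_raw <- emit_survey(pop)
    admissions_raw <- emit_admissions(pop)
    note("simulate", n_patients = nrow(pop$patients),
         n_episodes = nrow(pop$episodes), seed = config$generator$seed)
  } else {
    pop <- NULL
    survey_raw <- wrap("read", tibble::as_tibble(
      utils::read.csv(config$survey_path, stringsAsFactors = FALSE)))
    admissions_raw <- wrap("read", tibble::as_tibble(
      utils::read.csv(config$admissions_path, stringsAsFactors = FALSE)))
    note("read", n_survey = nrow(survey_raw),
         n_admissions = nrow(admissions_raw))
  }

  # --- preprocess ------------------------------------------------------
  survey <- wrap("preprocess", standardize(survey_raw))
  admissions <- wrap("preprocess", standardize(admissions_raw))
  note("standardize", survey_dropped = filter_report(survey)$n_dropped,
       admissions_dropped = filter_report(admissions)$n_dropped,
       reason = "invalid_key_field")

  eligible <- filter_survey_eligible(survey, min_age = config$min_age)
  note("filter_survey_eligible", n_input = nrow(survey),
       n_kept = nrow(eligible), reason = "age_below_floor")
  candidates <- wrap("preprocess", filter_admission_candidates(
    admissions, window = config$window, hospitals = config$hospitals,
    min_age = config$min_age))
  note("filter_admission_candidates", n_input = nrow(admissions),
       n_kept = nrow(candidates),
       reason = "outside_window_or_hospital_or_age_or_destination")

  # --- link ------------------------------------------------------------
  linkage <- wrap("link",
                  link_deterministic(eligible, candidates,
                                     key_fields = config$key_fields))
  rep <- matching_report(linkage)
  note("link", n_unique = rep$n_unique, n_one_to_many = rep$n_one_to_many,
       n_unmatched = rep$n_unmatched,
       matching_rate_pct = rep$matching_rate_pct,
       reason = "one_to_many_and_unmatched_excluded_from_analysis")

  # --- outcomes --------------------------------------------------------
  analysis <- wrap("outcomes", {
    linked <- linked_patients(linkage, eligible, candidates)
    linked <- flag_readmissions(linked, admissions)
    derive_covariates(linked)
  })
  note("outcomes", n_analysis = nrow(analysis),
       n_readmit_any = sum(analysis$readmit_any),
       n_readmit_ae = sum(analysis$readmit_ae),
       n_readmit_opd = sum(analysis$readmit_opd))

  # --- analyze ---------------------------------------------------------
  stats_out <- wrap("analyze", analyze_linked(analysis, eligible, linkage))
  note("analyze", n_models = length(stats_out$models))

  manifest <- list(
    config_hash = rlang::hash(unclass(config)),
    seed = if (!is.null(config$generator)) config$generator$seed else NA,
    counts = list(
      survey_input = nrow(survey_raw),
      survey_standardized = nrow(survey),
      survey_eligible = nrow(eligible),
      admissions_input = nrow(admissions_raw),
      admissions_standardized = nrow(admissions),
      admission_candidates = nrow(candidates),
      linked_unique = rep$n_unique,
      one_to_many = rep$n_one_to_many,
      unmatched = rep$n_unmatched,
      analysis_rows = nrow(analysis),
      readmitted_any = sum(analysis$readmit_any)),
    matching_rate_pct = rep$matching_rate_pct,
    reconciles = rep$n_unique + rep$n_one_to_many + rep$n_unmatched ==
      nrow(eligible),
    log = log_lines)

  out <- list(population = pop, survey = eligible, admissions = admissions,
              candidates = candidates, linkage = linkage,
              analysis = analysis, stats = stats_out, manifest = manifest)
  if (!is.null(config$out_dir)) write_pipeline_outputs(out, config$out_dir)
  out
}

# The statistical layer over one linked analysis table.
analyze_linked <- function(analysis, eligible_survey, linkage) {
  vars <- c("sex", "age_group", "los_group", "specialty_group")
  crosstabs <- lapply(stats::setNames(vars, vars), function(v) {
    crosstab(analysis, v, "readmit_any")
  })

  or2x2 <- function(flag) {
    a <- sum(analysis[[flag]] & analysis$readmit_any)
    b <- sum(analysis[[flag]] & !analysis$readmit_any)
    c <- sum(!analysis[[flag]] & analysis$readmit_any)
    d <- sum(!analysis[[flag]] & !analysis$readmit_any)
    odds_ratio_woolf(a, b, c, d)
  }
  crude <- list(quality = or2x2("quality_high"),
                experience = or2x2("experience_high"))

  los_tab <- table(analysis$readmit_any,
                   factor(analysis$los_group,
                          levels = c("1-3 days", "4-7 days", "8+ days")))
  chi2_los <- pearson_chi2(los_tab)

  # linkage-bias diagnostics: linked vs not-uniquely-linked respondents
  linked_ids <- linkage$unique_pairs$survey_id
  is_linked <- eligible_survey$survey_id %in% linked_ids
  # degenerate when one status group is empty: diagnostic undefined, not fatal
  try_bias <- function(...) tryCatch(linkage_bias_test(...),
                                     error = function(e) NULL)
  bias <- list(
    quality = try_bias(
      eligible_survey$quality_rating[is_linked],
      eligible_survey$quality_rating[!is_linked]),
    experience = try_bias(
      eligible_survey$experience_score[is_linked],
      eligible_survey$experience_score[!is_linked],
      binning = c(-0.5, 4.5, 5.5, 6.5, 7.5, 8.5, 9.5, 10.5)))

  models <- list()
  tables <- list()
  for (exper in c("quality", "experience")) {
    fits <- lapply(stats::setNames(c("any", "ae", "opd"),
                                   c("any", "ae", "opd")), function(oc) {
      readmission_model(analysis, outcome = oc, experience = exper)
    })
    models[[exper]] <- fits
    tables[[exper]] <- model_tables(fits)
  }

  list(crosstabs = crosstabs, crude_or = crude, chi2_los = chi2_los,
       bias = bias, models = models, model_tables = tables,
       readmission_rate_pct = 100 * mean(analysis$readmit_any))
}

write_pipeline_outputs <- function(out, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(out$survey, file.path(dir, "survey_eligible.csv"),
                   row.names = FALSE)
  utils::write.csv(out$candidates, file.path(dir, "admission_candidates.csv"),
                   row.names = FALSE)
  utils::write.csv(out$linkage$unique_pairs,
                   file.path(dir, "linked_pairs.csv"), row.names = FALSE)
  utils::write.csv(out$analysis, file.path(dir, "analysis_table.csv"),
                   row.names = FALSE)
  for (nm in names(out$stats$model_tables)) {
    utils::write.csv(out$stats$model_tables[[nm]],
                     file.path(dir, paste0("adjusted_or_", nm, ".csv")),
                     row.names = FALSE)
  }
  jsonlite::write_json(out$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  con <- file(file.path(dir, "log.jsonl"), open = "wt")
  on.exit(close(con))
  for (entry in out$manifest$log) {
    writeLines(jsonlite::toJSON(entry, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(dir)
}
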