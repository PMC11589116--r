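# End-to-end orchestration: simulate or ingest -> dosage -> ploidy ->
# family assignment -> aberrations -> statistics -> report, with a
# serialisable run manifest for reproducibility.

#' Build a run configuration
#'
#' @param design synthetic design (`"experiment_1"` / `"experiment_2"`), or
#'   `NULL` when reading data from `paths`.
#' @param paths named list of input paths (`peaks`, `panel`, `parents`,
#'   `meta`, `mortality`, `family_map`) used when `design` is `NULL`.
#' @param sim a [sim_params()] for synthetic runs.
#' @param calibration a [dosage_calibration()].
#' @param genotyping_success_threshold exclusion boundary (default 0.5).
#' @param assignment_tolerance mismatch tolerance (default 1).
#' @param upd_threshold UPD locus-count boundary (default 3).
#' @param out_dir output directory (`NULL` for no file output).
#' @param seed integer seed.
#' @return A `run_config` list.
#' @export
run_config <- function(design = "experiment_1", paths = NULL,
                       sim = sim_params(), calibration = dosage_calibration(),
                       genotyping_success_threshold = 0.5,
                       assignment_tolerance = 1, upd_threshold = 3,
                       out_dir = NULL, seed = 1) {
  structure(list(design = design, paths = paths, sim = sim,
                 calibration = calibration,
                 genotyping_success_threshold = genotyping_success_threshold,
                 assignment_tolerance = assignment_tolerance,
                 upd_threshold = upd_threshold, out_dir = out_dir,
                 seed = seed), class = "run_config")
}

serialize_config <- function(config) {
  list(design = config$design, paths = config$paths,
       calibration = unclass(config$calibration),
       genotyping_success_threshold = config$genotyping_success_threshold,
       assignment_tolerance = config$assignment_tolerance,
       upd_threshold = config$upd_threshold, seed = config$seed,
       package_version = as.character(utils::packageVersion("tripcheck")))
}

#' Run the full analysis pipeline
#'
#' Stages run in dependency order: input (synthetic study or files), MAC-PR
#' dosage classification, informative-locus screening, ploidy calling and
#' the genotyping-success filter, exclusion-based family assignment (parr;
#' sampled eggs keep their hatchery-known family and are assigned only as
#' a QC cross-check), aberration typing, binomial incidence models with
#' drop1 AIC evaluation and separation handling (the affected model is
#' refitted without the offending treatment level and reported
#' side-by-side), and stage-interval mortality rates. When the input is
#' synthetic, a recovery report compares calls against latent truth.
#'
#' @param config a [run_config()].
#' @return A `pipeline_result` list of all stage outputs (written to
#'   `config$out_dir` when set, together with a YAML run manifest).
#' @export
run_pipeline <- function(config = run_config()) {
  if (!is.null(config$design)) {
    cohort <- build_study(config$design, config$sim, config$seed)
    panel <- config$sim$panel
    peaks <- cohort$peaks
    meta <- cohort$meta
    parents <- parent_pairs(cohort$parents$genotypes, cohort$parents$family_map)
    mortality <- cohort$mortality[c("unit_id", "interval", "n_start", "n_dead")]
    mortality_by <- cohort$mortality
  } else {
    p <- config$paths
    panel <- read_panel(p$panel)
    peaks <- read_peak_table(p$peaks, panel)
    meta <- read_sample_meta(p$meta)
    fam_map <- utils::read.table(p$family_map, header = TRUE, sep = "\t",
                                 stringsAsFactors = FALSE)
    parents <- parent_pairs(read_genotype_table(p$parents), fam_map)
    mortality <- if (!is.null(p$mortality)) read_mortality_counts(p$mortality)
      else NULL
    mortality_by <- mortality
    cohort <- NULL
  }
  calls <- classify_peak_table(peaks, panel, config$calibration)
  screen <- screen_informative_loci(calls, panel)
  inf <- informative_markers(screen)
  ploidy_all <- ploidy_table(calls, inf)
  filt <- filter_by_genotyping_success(ploidy_all, length(inf),
                                       config$genotyping_success_threshold)
  ploidy <- filt$retained
  keep_calls <- calls[calls$sample_id %in% ploidy$sample_id, , drop = FALSE]
  assignments <- assign_families(keep_calls, ploidy, parents, panel,
                                 tolerance = config$assignment_tolerance)
  known <- meta[meta$role == "offspring", c("sample_id", "family_id")]
  family_of <- merge(assignments[c("sample_id", "assigned_family")], known,
                     by = "sample_id", all.x = TRUE)
  family_of$family_id <- ifelse(!is.na(family_of$family_id),
                                family_of$family_id,
                                family_of$assigned_family)
  ab <- aberration_table(keep_calls, ploidy, family_of, parents, panel,
                         upd_threshold = config$upd_threshold)
  model_data <- merge(ploidy, meta[meta$role == "offspring", ],
                      by = "sample_id")
  model_data <- model_data[model_data$ploidy_class != "undetermined", ,
                           drop = FALSE]
  model_data$triploid <- as.integer(model_data$ploidy_class == "triploid")
  model_data$aneuploid <- as.integer(model_data$ploidy_class == "aneuploid")
  has_rep <- any(!is.na(model_data$replicate_id))
  fits <- list()
  for (resp in c("triploid", "aneuploid")) {
    spec <- model_spec(resp, c("treatment_psi", "family_id", "stage"),
                       random_intercept = if (has_rep) "replicate_id" else NULL)
    fit <- tryCatch({
      if (has_rep) fit_random_intercept_logit(model_data, spec)
      else fit_binomial_glm(model_data, spec)
    }, error = function(e) e)
    entry <- list(fit = fit)
    if (!inherits(fit, "error")) {
      entry$drop1 <- tryCatch(drop1_aic(fit), error = function(e) e)
      if (fit$separation_flag)
        entry$refit_no_separation <- tryCatch(
          refit_without_separated_levels(fit), error = function(e) e)
    }
    fits[[resp]] <- entry
  }
  mort_rates <- if (!is.null(mortality)) mortality_rates(mortality) else NULL
  report <- summarize_report(ploidy, meta, ab$events, mort_rates)
  recovery <- if (!is.null(cohort)) recovery_report(ploidy, cohort) else NULL
  result <- list(calls = calls, screen = screen,
                 informative_markers = inf, ploidy = ploidy,
                 filter_report = filt$report, assignments = assignments,
                 aberrations = ab$events, findings = ab$findings,
                 fits = fits, mortality = mort_rates, report = report,
                 recovery = recovery, cohort = cohort, config = config)
  class(result) <- "pipeline_result"
  if (!is.null(config$out_dir)) write_pipeline_outputs(result, config$out_dir)
  result
}

model_fit_table <- function(fits) {
  rows <- list()
  for (resp in names(fits)) {
    fit <- fits[[resp]]$fit
    if (inherits(fit, "error")) {
      rows[[resp]] <- data.frame(response = resp, term = "<error>",
                                 estimate = NA_real_, se = NA_real_,
                                 aic = NA_real_, separation = NA,
                                 stringsAsFactors = FALSE)
    } else {
      cf <- fit$coefficients
      rows[[resp]] <- data.frame(response = resp, term = cf$term,
                                 estimate = cf$estimate, se = cf$se,
                                 aic = fit$aic, separation = fit$separation_flag,
                                 stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

write_pipeline_outputs <- function(result, out_dir) {
  tables <- list(locus_calls = result$calls, screen_report = result$screen,
                 ploidy = result$ploidy, filter_report = result$filter_report,
                 assignments = as.data.frame(result$assignments),
                 aberrations = result$aberrations,
                 model_fits = model_fit_table(result$fits))
  if (!is.null(result$mortality)) tables$mortality <- result$mortality
  for (nm in names(result$report)) tables[[paste0("report_", nm)]] <-
    result$report[[nm]]
  if (!is.null(result$recovery)) tables$recovery <- result$recovery$confusion
  write_results(tables, out_dir)
  manifest <- serialize_config(result$config)
  writeLines(yaml::as.yaml(manifest), file.path(out_dir, "run_manifest.yaml"))
  invisible(out_dir)
}

#' Summary tables behind the standard report figures
#'
#' Per treatment x family x stage: ploidy-class counts and proportions
#' (summing to 1 per stratum); aberration-type frequencies; pooled
#' mortality rates per interval.
#'
#' @param ploidy retained `PloidyCall` table.
#' @param meta sample metadata.
#' @param aberrations `AberrationEvent` table (may be empty).
#' @param mortality mortality rate table or `NULL`.
#' @return list of data frames: `ploidy_proportions`,
#'   `aberration_frequencies`, `mortality_pooled`.
#' @export
summarize_report <- function(ploidy, meta, aberrations, mortality = NULL) {
  md <- merge(ploidy, meta[meta$role == "offspring", ], by = "sample_id")
  dt <- data.table::as.data.table(md)
  prop <- dt[, .(n = .N), by = .(treatment_psi, family_id, stage, ploidy_class)]
  prop[, proportion := n / sum(n), by = .(treatment_psi, family_id, stage)]
  data.table::setorder(prop, treatment_psi, family_id, stage, ploidy_class)
  ab_freq <- NULL
  if (!is.null(aberrations) && nrow(aberrations) > 0L) {
    abm <- merge(aberrations, meta[meta$role == "offspring", ],
                 by = "sample_id")
    abdt <- data.table::as.data.table(abm)
    denom <- dt[, .(n_genotyped = .N), by = .(treatment_psi, stage)]
    ab_freq <- abdt[, .(n_events = .N), by = .(treatment_psi, stage, type)]
    ab_freq <- denom[ab_freq, on = c("treatment_psi", "stage")]
    ab_freq[, frequency := n_events / n_genotyped]
    data.table::setorder(ab_freq, treatment_psi, stage, type)
    ab_freq <- as.data.frame(ab_freq)
  } else {
    ab_freq <- data.frame(treatment_psi = numeric(0), stage = character(0),
                          type = character(0), n_genotyped = integer(0),
                          n_events = integer(0), frequency = numeric(0))
  }
  mort_pooled <- if (!is.null(mortality))
    aggregate_mortality(mortality, by = "interval") else NULL
  list(ploidy_proportions = as.data.frame(prop),
       aberration_frequencies = ab_freq,
       mortality_pooled = mort_pooled)
}

# confusion matrix of latent true ploidy class vs MAC-PR call
recovery_report <- function(ploidy, cohort) {
  truth <- cohort$individuals[c("sample_id", "true_ploidy_class",
                                "viability_category")]
  j <- merge(ploidy, truth, by = "sample_id")
  tab <- as.data.frame(table(true = j$true_ploidy_class,
                             called = j$ploidy_class))
  acc <- sum(j$true_ploidy_class == j$ploidy_class) / nrow(j)
  list(confusion = tab, accuracy = acc, joined = j)
}
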