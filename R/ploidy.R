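# Individual-level ploidy classification: aggregate per-locus somy calls
# into diploid / triploid / aneuploid / undetermined, the trisomic
# proportion, the degree-of-aneuploidy summary, and the genotyping-success
# filter.

ploidy_class_of <- function(n_informative_het, n_trisomic) {
  if (n_informative_het == 0L) return("undetermined")
  p <- n_trisomic / n_informative_het
  if (p == 0) "diploid" else if (p == 1) "triploid" else "aneuploid"
}

#' Degree-of-aneuploidy class
#'
#' Aneuploid individuals deviating at exactly one locus — trisomic at only
#' one locus (otherwise diploid) or disomic at only one locus (otherwise
#' triploid) — are distinguished from more intermediate forms.
#'
#' @param n_informative_het,n_trisomic counts from the ploidy call.
#' @return `"single_locus_deviation"` or `"intermediate"`.
#' @export
degree_of_aneuploidy <- function(n_informative_het, n_trisomic) {
  cls <- ploidy_class_of(n_informative_het, n_trisomic)
  if (cls != "aneuploid")
    tc_stop("tripcheck_validation_error",
            "degree_of_aneuploidy is defined only for aneuploid individuals (got %s)", cls)
  if (n_trisomic == 1L || (n_informative_het - n_trisomic) == 1L)
    "single_locus_deviation" else "intermediate"
}

#' Call ploidy for one individual
#'
#' The ploidy of an individual is determined by the proportion p of
#' informative heterozygous markers with a clearly trisomic configuration
#' (AAB, ABB or ABC) rather than disomic (AB): diploid if p = 0, triploid
#' if p = 1, aneuploid if 0 < p < 1. Individuals homozygous (or unscored)
#' at every informative marker are undetermined — dosage cannot be read
#' from a single peak. Individuals with only one informative heterozygous
#' locus are classifiable but flagged low-confidence.
#'
#' @param calls `locus_call_table` rows for one individual.
#' @param informative character vector of dosage-informative marker ids
#'   (see [screen_informative_loci()]).
#' @return A one-row data frame (`PloidyCall`).
#' @export
call_ploidy <- function(calls, informative) {
  calls <- as.data.frame(calls)
  if (nrow(calls) == 0L)
    tc_stop("tripcheck_validation_error",
            "empty call set: individual should have been excluded by the genotyping-success filter")
  scored <- calls$configuration != "no_call"
  inf <- calls$marker_id %in% informative
  resolved <- inf & calls$configuration %in% CONFIGS_RESOLVED & !is.na(calls$somy)
  n_ih <- sum(resolved)
  n_tri <- sum(resolved & calls$somy == 3L)
  p <- if (n_ih > 0L) n_tri / n_ih else NA_real_
  cls <- ploidy_class_of(n_ih, n_tri)
  deg <- if (cls == "aneuploid") degree_of_aneuploidy(n_ih, n_tri) else "none"
  flags <- character(0)
  if (n_ih == 1L) flags <- c(flags, "low_confidence_single_locus")
  if (cls == "undetermined" && sum(scored & inf) > 0L)
    flags <- c(flags, "homozygous_all_informative")
  data.frame(sample_id = calls$sample_id[1],
             n_scored = sum(scored),
             n_scored_informative = sum(scored & inf),
             n_informative_het = n_ih,
             n_trisomic = n_tri,
             trisomic_proportion = p,
             ploidy_class = cls,
             aneuploidy_degree_class = deg,
             flags = paste(flags, collapse = ";"),
             stringsAsFactors = FALSE)
}

#' Ploidy calls for a whole cohort
#'
#' Vectorised equivalent of applying [call_ploidy()] per individual.
#'
#' @param calls a `locus_call_table`.
#' @param informative character vector of informative marker ids.
#' @return A `PloidyCall` data frame, one row per sample.
#' @export
ploidy_table <- function(calls, informative) {
  dt <- data.table::as.data.table(as.data.frame(calls))
  dt[, scored := configuration != "no_call"]
  dt[, inf := marker_id %in% informative]
  dt[, resolved := inf & configuration %in% CONFIGS_RESOLVED & !is.na(somy)]
  tab <- dt[, .(n_scored = sum(scored),
                n_scored_informative = sum(scored & inf),
                n_informative_het = sum(resolved),
                n_trisomic = sum(resolved & somy == 3L)),
            by = sample_id]
  tab[, trisomic_proportion := data.table::fifelse(
    n_informative_het > 0L, n_trisomic / n_informative_het, NA_real_)]
  tab[, ploidy_class := data.table::fcase(
    n_informative_het == 0L, "undetermined",
    n_trisomic == 0L, "diploid",
    n_trisomic == n_informative_het, "triploid",
    default = "aneuploid")]
  tab[, aneuploidy_degree_class := data.table::fcase(
    ploidy_class != "aneuploid", "none",
    n_trisomic == 1L | (n_informative_het - n_trisomic) == 1L, "single_locus_deviation",
    default = "intermediate")]
  tab[, flags := data.table::fifelse(n_informative_het == 1L,
                                     "low_confidence_single_locus", "")]
  data.table::setorder(tab, sample_id)
  as.data.frame(tab)
}

#' Exclude individuals with low genotyping success
#'
#' Individuals are excluded when their scored fraction of the informative
#' marker panel falls strictly below the threshold (default 50%; an
#' individual scoring exactly the threshold is retained, reading "< 50%"
#' strictly). Success is computed over the informative marker set by
#' default, or over the whole panel with `mode = "panel"`.
#'
#' @param ploidy a `PloidyCall` data frame from [ploidy_table()].
#' @param panel_size number of markers the success fraction is computed
#'   over (e.g. 20 informative markers).
#' @param threshold exclusion boundary in (0, 1], default 0.5.
#' @param mode `"informative"` (default) or `"panel"`.
#' @return list with `retained` (filtered `PloidyCall` table) and `report`
#'   (a `CohortFilterReport` row).
#' @export
filter_by_genotyping_success <- function(ploidy, panel_size, threshold = 0.5,
                                         mode = c("informative", "panel")) {
  mode <- match.arg(mode)
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1)
    tc_stop("tripcheck_config_error", "threshold must lie in (0, 1], got %s",
            format(threshold))
  scored <- if (mode == "informative") ploidy$n_scored_informative else ploidy$n_scored
  keep <- scored / panel_size >= threshold
  report <- data.frame(threshold = threshold, panel_size = panel_size,
                       n_input = nrow(ploidy), n_retained = sum(keep),
                       n_excluded = sum(!keep))
  list(retained = ploidy[keep, , drop = FALSE], report = report)
}
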