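# MAC-PR allele-dosage inference: copy numbers, allelic configuration
# (AB / AAB / ABB / ABC) and somy per heterozygous locus from relative
# peak heights, plus the informative-locus screening protocol.

#' Dosage calibration for peak-height ratio classification
#'
#' The ratio r = height(smaller-size allele) / height(larger-size allele)
#' is mapped through three disjoint bands: `one_two` (copies 1:2, ABB),
#' `balanced` (1:1, AB) and `two_one` (2:1, AAB). Ratios falling in the
#' guard gaps between bands — or exactly on a band boundary — are left
#' unresolved and flagged, never guessed. Defaults centre the bands at the
#' theoretical ratios 0.5, 1 and 2.
#'
#' @param balanced,two_one,one_two numeric length-2 (low, high) open
#'   intervals on r.
#' @param min_peak_height_rfu peaks below this height are discarded before
#'   classification (default 100 RFU, common fragment-analysis practice).
#' @param max_stutter_fraction a peak one repeat motif below a retained peak
#'   is treated as stutter when its height is below this fraction of the
#'   parent peak (default 0.15).
#' @param size_bias_slope optional differential-amplification correction:
#'   observed heights are multiplied by `1 + size_bias_slope * (size - mean
#'   size)` before ratio computation; default 0 (off).
#' @return A `dosage_calibration` object.
#' @export
dosage_calibration <- function(balanced = c(0.75, 1.40),
                               two_one = c(1.60, 2.60),
                               one_two = c(0.38, 0.63),
                               min_peak_height_rfu = 100,
                               max_stutter_fraction = 0.15,
                               size_bias_slope = 0) {
  stopifnot(length(balanced) == 2L, length(two_one) == 2L, length(one_two) == 2L)
  if (!(one_two[2] < balanced[1] && balanced[2] < two_one[1]))
    tc_stop("tripcheck_config_error",
            "calibration bands must be disjoint and ordered: one_two < balanced < two_one")
  if (max_stutter_fraction <= 0 || max_stutter_fraction >= 1)
    tc_stop("tripcheck_config_error", "max_stutter_fraction must be in (0,1)")
  structure(list(balanced = balanced, two_one = two_one, one_two = one_two,
                 min_peak_height_rfu = min_peak_height_rfu,
                 max_stutter_fraction = max_stutter_fraction,
                 size_bias_slope = size_bias_slope),
            class = "dosage_calibration")
}

#' Remove stutter peaks for one sample x marker
#'
#' A peak exactly one repeat motif below a retained peak and with height
#' below `max_stutter_fraction` times that peak's height is removed.
#' Pure filter: peaks are never modified, only dropped; removed peaks are
#' returned in the `removed` attribute.
#'
#' @param peaks data frame with `allele_size_bp`, `height_rfu` for one
#'   sample x marker.
#' @param motif_bp repeat motif length (bp) of the marker.
#' @param calibration a [dosage_calibration()].
#' @return The retained peaks, with attribute `removed`.
#' @export
filter_stutter <- function(peaks, motif_bp, calibration = dosage_calibration()) {
  if (nrow(peaks) <= 1L) {
    attr(peaks, "removed") <- peaks[0, , drop = FALSE]
    return(peaks)
  }
  keep <- rep(TRUE, nrow(peaks))
  # evaluate candidates in descending size so a stutter peak cannot shelter
  # its own stutter; repeat until stable (cascades are rare and shallow)
  repeat {
    changed <- FALSE
    for (i in order(-peaks$allele_size_bp)) {
      if (!keep[i]) next
      parent <- keep & abs(peaks$allele_size_bp - (peaks$allele_size_bp[i] + motif_bp)) < 1e-6
      if (any(parent) &&
          peaks$height_rfu[i] < calibration$max_stutter_fraction * max(peaks$height_rfu[parent])) {
        keep[i] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  out <- peaks[keep, , drop = FALSE]
  attr(out, "removed") <- peaks[!keep, , drop = FALSE]
  out
}

band_of <- function(r, calibration) {
  # open intervals: boundary values are unresolved by design (conservative)
  if (is.na(r)) return("unresolved")
  if (r > calibration$balanced[1] && r < calibration$balanced[2]) return("AB")
  if (r > calibration$two_one[1] && r < calibration$two_one[2]) return("AAB")
  if (r > calibration$one_two[1] && r < calibration$one_two[2]) return("ABB")
  "unresolved"
}

locus_call_row <- function(sample_id, marker_id, alleles = numeric(0),
                           copies = numeric(0), somy = NA_integer_,
                           configuration = "no_call", ratio = NA_real_,
                           qc = character(0)) {
  data.frame(sample_id = sample_id, marker_id = marker_id,
             alleles = join_num_field(list(alleles)),
             copy_numbers = join_num_field(list(copies)),
             somy = somy, configuration = configuration, ratio = ratio,
             qc_flags = paste(qc, collapse = ";"), stringsAsFactors = FALSE)
}

#' Classify one locus from its electropherogram peaks (MAC-PR)
#'
#' Applies the minimum-height and stutter filters, then infers per-allele
#' copy number from relative peak heights: one peak gives a homozygous
#' pattern with unknown somy (dosage cannot be determined from a single
#' peak); three peaks force configuration ABC (somy 3); two peaks are
#' classified by mapping the height ratio through the calibration bands to
#' AB (somy 2), AAB or ABB (somy 3), or left unresolved with a QC flag.
#'
#' @param peaks data frame with `allele_size_bp`, `height_rfu` (and
#'   optionally `sample_id`, `marker_id`) for one sample x marker.
#' @param motif_bp repeat motif length (bp) of the marker.
#' @param calibration a [dosage_calibration()].
#' @param sample_id,marker_id identifiers used when absent from `peaks`.
#' @return A one-row `locus_call_table` data frame.
#' @export
classify_locus <- function(peaks, motif_bp, calibration = dosage_calibration(),
                           sample_id = NULL, marker_id = NULL) {
  sample_id <- sample_id %||% peaks$sample_id[1] %||% "?"
  marker_id <- marker_id %||% peaks$marker_id[1] %||% "?"
  qc <- character(0)
  pk <- peaks[!is.na(peaks$height_rfu) &
                peaks$height_rfu >= calibration$min_peak_height_rfu, , drop = FALSE]
  if (nrow(pk) < nrow(peaks)) qc <- c(qc, "low_peaks_removed")
  pk <- filter_stutter(pk, motif_bp, calibration)
  if (nrow(attr(pk, "removed")) > 0L) qc <- c(qc, "stutter_removed")
  n <- nrow(pk)
  if (n == 0L)
    return(locus_call_row(sample_id, marker_id, qc = c(qc, "no_signal")))
  if (n > 3L)
    return(locus_call_row(sample_id, marker_id, qc = c(qc, "excess_peaks")))
  pk <- pk[order(pk$allele_size_bp), , drop = FALSE]
  if (calibration$size_bias_slope != 0) {
    pk$height_rfu <- pk$height_rfu *
      (1 + calibration$size_bias_slope * (pk$allele_size_bp - mean(pk$allele_size_bp)))
  }
  if (n == 1L)
    return(locus_call_row(sample_id, marker_id, alleles = pk$allele_size_bp,
                          configuration = "homozygous", qc = qc))
  if (n == 3L)
    return(locus_call_row(sample_id, marker_id, alleles = pk$allele_size_bp,
                          copies = c(1, 1, 1), somy = 3L, configuration = "ABC",
                          qc = qc))
  r <- pk$height_rfu[1] / pk$height_rfu[2]
  cfg <- band_of(r, calibration)
  copies <- switch(cfg, AB = c(1, 1), AAB = c(2, 1), ABB = c(1, 2), numeric(0))
  somy <- if (cfg == "unresolved") NA_integer_ else as.integer(sum(copies))
  if (cfg == "unresolved") qc <- c(qc, "unresolved_ratio")
  locus_call_row(sample_id, marker_id, alleles = pk$allele_size_bp,
                 copies = copies, somy = somy, configuration = cfg,
                 ratio = r, qc = qc)
}

#' Classify every sample x marker locus in a peak table
#'
#' Vectorised cohort version of [classify_locus()] (identical rules),
#' suitable for tens of thousands of loci.
#'
#' @param peaks a `peak_table`.
#' @param panel a [marker_panel()]; markers absent from the panel are
#'   classified with motif taken as 4 bp and flagged `unknown_marker`.
#' @param calibration a [dosage_calibration()].
#' @return A `locus_call_table` data frame, one row per sample x marker.
#' @export
classify_peak_table <- function(peaks, panel, calibration = dosage_calibration()) {
  dt <- data.table::as.data.table(peaks[c("sample_id", "marker_id",
                                          "allele_size_bp", "height_rfu")])
  motif <- panel$repeat_motif_bp[match(dt$marker_id, panel$marker_id)]
  dt[, motif := data.table::fifelse(is.na(motif), 4L, as.integer(motif))]
  dt[, unknown_marker := is.na(panel$repeat_motif_bp[match(marker_id, panel$marker_id)])]
  groups <- unique(dt[, c("sample_id", "marker_id")])
  dt[, low := is.na(height_rfu) | height_rfu < calibration$min_peak_height_rfu]
  f <- dt[!(low)]
  # stutter: drop peaks one motif below a higher retained peak; two passes so
  # that a removed stutter cannot itself shelter a lower stutter peak
  for (pass in 1:2) {
    parents <- f[, .(sample_id, marker_id, parent_size = allele_size_bp,
                     parent_h = height_rfu)]
    f[, stutter_pos := allele_size_bp + motif]
    m <- parents[f, on = c("sample_id", "marker_id", parent_size = "stutter_pos"),
                 allow.cartesian = TRUE]
    m <- m[!is.na(parent_h)]
    if (nrow(m) > 0L) {
      agg <- m[, .(max_parent = max(parent_h)),
               by = .(sample_id, marker_id, allele_size_bp = parent_size - motif)]
      f <- agg[f, on = c("sample_id", "marker_id", "allele_size_bp")]
    } else {
      f[, max_parent := NA_real_]
    }
    f[, is_stutter := !is.na(max_parent) &
          height_rfu < calibration$max_stutter_fraction * max_parent]
    f <- f[!(is_stutter)][, c("max_parent", "is_stutter", "stutter_pos") := NULL]
  }
  data.table::setorder(f, sample_id, marker_id, allele_size_bp)
  if (calibration$size_bias_slope != 0) {
    f[, height_rfu := height_rfu *
        (1 + calibration$size_bias_slope * (allele_size_bp - mean(allele_size_bp))),
      by = .(sample_id, marker_id)]
  }
  calls <- f[, {
    n <- .N
    if (n > 3L) {
      list(alleles = "-", copy_numbers = "-", somy = NA_integer_,
           configuration = "no_call", ratio = NA_real_, qc_flags = "excess_peaks")
    } else if (n == 1L) {
      list(alleles = join_num_field(list(allele_size_bp)), copy_numbers = "-",
           somy = NA_integer_, configuration = "homozygous", ratio = NA_real_,
           qc_flags = "")
    } else if (n == 3L) {
      list(alleles = join_num_field(list(allele_size_bp)), copy_numbers = "1;1;1",
           somy = 3L, configuration = "ABC", ratio = NA_real_, qc_flags = "")
    } else {
      r <- height_rfu[1] / height_rfu[2]
      cfg <- band_of(r, calibration)
      cps <- switch(cfg, AB = "1;1", AAB = "2;1", ABB = "1;2", "-")
      list(alleles = join_num_field(list(allele_size_bp)), copy_numbers = cps,
           somy = if (cfg == "unresolved") NA_integer_ else
             if (cfg == "AB") 2L else 3L,
           configuration = cfg, ratio = r,
           qc_flags = if (cfg == "unresolved") "unresolved_ratio" else "")
    }
  }, by = .(sample_id, marker_id)]
  out <- merge(data.table::as.data.table(groups), calls,
               by = c("sample_id", "marker_id"), all.x = TRUE)
  out[is.na(configuration),
      `:=`(alleles = "-", copy_numbers = "-", configuration = "no_call",
           qc_flags = "no_signal")]
  unk <- unique(dt[unknown_marker == TRUE, c("sample_id", "marker_id")])
  if (nrow(unk) > 0L) {
    unk[, flag := "unknown_marker"]
    out <- unk[out, on = c("sample_id", "marker_id")]
    out[!is.na(flag), qc_flags := data.table::fifelse(
      nzchar(qc_flags), paste(qc_flags, flag, sep = ";"), flag)]
    out[, flag := NULL]
  }
  data.table::setorder(out, sample_id, marker_id)
  out <- as.data.frame(out)
  out$qc_flags[is.na(out$qc_flags)] <- ""
  class(out) <- c("locus_call_table", "data.frame")
  out
}

#' Screen markers for dosage informativeness
#'
#' Background noise — artifact peaks and stutter — makes some markers
#' unreliable for dosage inference. A marker is flagged non-informative when
#' too many of its two-peak heterozygous calls fall in the unresolved guard
#' gaps, when too many of its heterozygous calls carry alleles one repeat
#' motif apart (where true-allele and stutter signal merge), or when it has
#' no heterozygous calls at all. Non-informative markers are excluded from
#' somy aggregation but remain usable for family assignment and aberration
#' typing.
#'
#' @param calls a `locus_call_table` for a cohort (at least 2 samples).
#' @param panel a [marker_panel()] (motif lengths are needed for the
#'   stutter-conflict rate).
#' @param max_fraction_unresolved maximum tolerated fraction of unresolved
#'   two-peak calls (default 0.25).
#' @param max_stutter_conflict_rate maximum tolerated fraction of
#'   heterozygous calls with alleles one motif apart (default 0.25).
#' @return A data frame with one `LocusScreenReport` row per marker.
#' @export
screen_informative_loci <- function(calls, panel,
                                    max_fraction_unresolved = 0.25,
                                    max_stutter_conflict_rate = 0.25) {
  dt <- data.table::as.data.table(as.data.frame(calls))
  if (length(unique(dt$sample_id)) < 2L)
    tc_stop("tripcheck_validation_error",
            "informative-locus screening requires a cohort of >= 2 samples")
  dt[, motif := panel$repeat_motif_bp[match(marker_id, panel$marker_id)]]
  al <- split_num_field(dt$alleles)
  dt[, n_alleles := lengths(al)]
  dt[, min_gap := vapply(al, function(a)
    if (length(a) >= 2L) min(diff(sort(a))) else NA_real_, numeric(1))]
  rep_tbl <- dt[, {
    het <- n_alleles >= 2L
    n_het <- sum(het)
    two_peak <- configuration %in% c("AB", "AAB", "ABB", "unresolved") & n_alleles == 2L
    n_two <- sum(two_peak)
    fr_unres <- if (n_two > 0L) sum(configuration == "unresolved" & two_peak) / n_two else 0
    st_rate <- if (n_het > 0L)
      sum(het & !is.na(min_gap) & abs(min_gap - motif[1]) < 1e-6) / n_het else 0
    list(n_samples_evaluated = .N,
         n_heterozygous = n_het,
         fraction_unresolved = fr_unres,
         stutter_conflict_rate = st_rate)
  }, by = marker_id]
  rep_tbl[, flag := ""]
  rep_tbl[n_heterozygous == 0L, flag := "no_heterozygotes"]
  rep_tbl[, informative := n_heterozygous > 0L &
            fraction_unresolved <= max_fraction_unresolved &
            stutter_conflict_rate <= max_stutter_conflict_rate]
  out <- as.data.frame(rep_tbl)
  out[order(out$marker_id), , drop = FALSE]
}

#' Markers flagged informative by a screen report
#' @param screen output of [screen_informative_loci()].
#' @return Character vector of informative marker ids.
#' @export
informative_markers <- function(screen) {
  sort(screen$marker_id[screen$informative])
}
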