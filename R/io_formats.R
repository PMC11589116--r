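# Reading and writing the tabular interchange formats: marker panels,
# fragment-analysis peak tables, genotype tables, sample metadata and
# mortality counts. All files are plain delimited text (comma or tab,
# auto-detected), UTF-8, decimal point.

VALID_TREATMENTS <- c(0, 6500, 7500, 8500, 9500)
VALID_STAGES <- c("egg", "parr", "parent")
VALID_ROLES <- c("dam", "sire", "offspring")
VALID_INTERVALS <- c("fertilization_to_eyed_egg", "eyed_egg_to_start_feed",
                     "start_feed_to_parr")
CONFIGS_RESOLVED <- c("AB", "AAB", "ABB", "ABC")

detect_delim <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0L) return("\t")
  if (lengths(regmatches(first, gregexpr("\t", first))) > 0L) "\t" else ","
}

read_delim_file <- function(path) {
  if (!file.exists(path)) tc_stop("tripcheck_io_error", "file not found: %s", path)
  d <- detect_delim(path)
  utils::read.table(path, header = TRUE, sep = d, stringsAsFactors = FALSE,
                    check.names = FALSE, fileEncoding = "UTF-8",
                    blank.lines.skip = TRUE)
}

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    tc_stop("tripcheck_format_error",
            "%s is missing mandatory column(s): %s", what,
            paste(missing, collapse = ", "))
  }
}

#' Construct and validate a microsatellite marker panel
#'
#' A panel describes the markers genotyped on a cohort: the repeat motif
#' length in base pairs (needed by the slippage/bp-shift rule and the
#' stutter filter) and the expected fragment-size range.
#'
#' @param marker_id character vector of unique marker names.
#' @param repeat_motif_bp integer motif length per marker, one of 2--6 bp.
#' @param size_min_bp,size_max_bp numeric fragment-size bounds (bp).
#' @param multiplex_group optional PCR multiplex label.
#' @return A `marker_panel` data frame.
#' @export
marker_panel <- function(marker_id, repeat_motif_bp, size_min_bp, size_max_bp,
                         multiplex_group = "mplex1") {
  p <- data.frame(marker_id = as.character(marker_id),
                  repeat_motif_bp = as.integer(repeat_motif_bp),
                  size_min_bp = as.numeric(size_min_bp),
                  size_max_bp = as.numeric(size_max_bp),
                  multiplex_group = as.character(multiplex_group),
                  stringsAsFactors = FALSE)
  if (anyDuplicated(p$marker_id))
    tc_stop("tripcheck_validation_error", "duplicate marker_id in panel")
  if (!all(p$repeat_motif_bp %in% 2:6))
    tc_stop("tripcheck_validation_error", "repeat_motif_bp must be in 2..6")
  if (any(p$size_min_bp >= p$size_max_bp))
    tc_stop("tripcheck_validation_error", "size_min_bp must be < size_max_bp")
  class(p) <- c("marker_panel", "data.frame")
  p
}

#' Read a marker-panel definition file
#'
#' @param path delimited text with columns `marker_id`, `repeat_motif_bp`,
#'   `size_min_bp`, `size_max_bp` and optionally `multiplex_group`.
#' @return A validated [marker_panel()].
#' @export
read_panel <- function(path) {
  df <- read_delim_file(path)
  require_columns(df, c("marker_id", "repeat_motif_bp", "size_min_bp", "size_max_bp"),
                  "panel file")
  marker_panel(df$marker_id, df$repeat_motif_bp, df$size_min_bp, df$size_max_bp,
               if ("multiplex_group" %in% names(df)) df$multiplex_group else "mplex1")
}

#' Read a fragment-analysis peak table
#'
#' Accepts either the long dialect (one peak per row: `sample_id`,
#' `marker_id`, `allele_size_bp`, `height_rfu`) or a wide genotyping-software
#' export (`sample_id`, `marker_id`, `allele1`, `height1`, `allele2`,
#' `height2`, optionally `allele3`, `height3`); the dialect is auto-detected
#' from the header. Rows referring to markers absent from the panel, or with
#' allele sizes outside the panel range, are loaded but reported in the
#' `diagnostics` attribute — no row is silently dropped.
#'
#' @param path file path.
#' @param panel a [marker_panel()].
#' @return A `peak_table` data frame (`sample_id`, `marker_id`,
#'   `allele_size_bp`, `height_rfu`) with a `diagnostics` attribute.
#' @export
read_peak_table <- function(path, panel) {
  df <- read_delim_file(path)
  long_cols <- c("sample_id", "marker_id", "allele_size_bp", "height_rfu")
  wide_cols <- c("sample_id", "marker_id", "allele1", "height1")
  if (all(long_cols %in% names(df))) {
    out <- df[long_cols]
    out$src_row <- seq_len(nrow(df))
  } else if (all(wide_cols %in% names(df))) {
    pieces <- list()
    for (k in 1:3) {
      ac <- paste0("allele", k); hc <- paste0("height", k)
      if (all(c(ac, hc) %in% names(df))) {
        pieces[[k]] <- data.frame(sample_id = df$sample_id, marker_id = df$marker_id,
                                  allele_size_bp = df[[ac]], height_rfu = df[[hc]],
                                  src_row = seq_len(nrow(df)),
                                  stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, pieces)
    out <- out[!is.na(out$allele_size_bp), , drop = FALSE]
    out <- out[order(out$src_row, out$allele_size_bp), , drop = FALSE]
  } else {
    tc_stop("tripcheck_format_error",
            "peak table is missing mandatory column(s): %s (long) or %s (wide)",
            paste(setdiff(long_cols, names(df)), collapse = ", "),
            paste(setdiff(wide_cols, names(df)), collapse = ", "))
  }
  out$sample_id <- as.character(out$sample_id)
  out$marker_id <- as.character(out$marker_id)
  out$allele_size_bp <- as.numeric(out$allele_size_bp)
  out$height_rfu <- as.numeric(out$height_rfu)
  neg <- which(!is.na(out$height_rfu) & out$height_rfu < 0)
  if (length(neg) > 0L) {
    tc_stop("tripcheck_validation_error",
            "negative height_rfu at input row %d", out$src_row[neg[1]])
  }
  diags <- list()
  unknown <- !(out$marker_id %in% panel$marker_id)
  if (any(unknown)) {
    diags[[length(diags) + 1L]] <- data.frame(
      src_row = out$src_row[unknown], issue = "unknown_marker",
      detail = out$marker_id[unknown], stringsAsFactors = FALSE)
  }
  idx <- match(out$marker_id, panel$marker_id)
  oob <- !unknown & !is.na(out$allele_size_bp) &
    (out$allele_size_bp < panel$size_min_bp[idx] |
       out$allele_size_bp > panel$size_max_bp[idx])
  if (any(oob)) {
    diags[[length(diags) + 1L]] <- data.frame(
      src_row = out$src_row[oob], issue = "size_out_of_range",
      detail = as.character(out$allele_size_bp[oob]), stringsAsFactors = FALSE)
  }
  if (nrow(out) == 0L) warning("peak table is empty (valid header, no data rows)")
  rownames(out) <- NULL
  out$src_row <- NULL
  attr(out, "diagnostics") <- if (length(diags)) do.call(rbind, diags) else
    data.frame(src_row = integer(0), issue = character(0), detail = character(0))
  class(out) <- c("peak_table", "data.frame")
  out
}

# derive somy/configuration from parsed allele and copy-number lists
fill_genotype_fields <- function(alleles, copies) {
  n_all <- length(alleles)
  if (n_all == 0L) {
    return(list(somy = NA_integer_, configuration = "no_call"))
  }
  if (n_all == 3L && (length(copies) == 0L)) copies <- c(1, 1, 1)
  if (length(copies) > 0L) {
    if (length(copies) != n_all)
      tc_stop("tripcheck_validation_error",
              "allele/copy-number length mismatch (%d alleles, %d copies)",
              n_all, length(copies))
    somy <- as.integer(sum(copies))
    cfg <- configuration_label(n_all, copies)
    return(list(somy = somy, configuration = cfg))
  }
  if (n_all == 1L) return(list(somy = NA_integer_, configuration = "homozygous"))
  list(somy = NA_integer_, configuration = "unresolved")
}

configuration_label <- function(n_alleles, copies) {
  if (n_alleles == 1L) return("homozygous")
  if (n_alleles == 2L) {
    if (all(copies == c(1, 1))) return("AB")
    if (all(copies == c(2, 1))) return("AAB")
    if (all(copies == c(1, 2))) return("ABB")
    return("unresolved")
  }
  if (n_alleles == 3L && all(copies == c(1, 1, 1))) return("ABC")
  "unresolved"
}

#' Read a genotype (locus-call) table
#'
#' Each row carries one individual x marker call: semicolon-separated allele
#' sizes and, optionally, semicolon-separated per-allele copy numbers
#' (`-` or empty when dosage is unknown, as for homozygous markers where
#' copy number cannot be determined by fragment analysis). Somy and
#' allelic configuration are filled in when copy numbers are present;
#' three-allele calls are forced to configuration ABC (copies 1;1;1).
#'
#' @param path file path; columns `sample_id`, `marker_id`, `alleles`,
#'   optionally `copy_numbers`.
#' @return A `locus_call_table` data frame with columns `sample_id`,
#'   `marker_id`, `alleles`, `copy_numbers`, `somy`, `configuration`,
#'   `ratio`, `qc_flags`.
#' @export
read_genotype_table <- function(path) {
  df <- read_delim_file(path)
  require_columns(df, c("sample_id", "marker_id", "alleles"), "genotype table")
  al <- split_num_field(df$alleles)
  cp <- if ("copy_numbers" %in% names(df)) split_num_field(df$copy_numbers) else
    rep(list(numeric(0)), nrow(df))
  # keep allele order sorted ascending, copies aligned
  for (i in seq_along(al)) {
    o <- order(al[[i]])
    if (length(cp[[i]]) == length(al[[i]])) cp[[i]] <- cp[[i]][o]
    al[[i]] <- al[[i]][o]
  }
  filled <- mapply(fill_genotype_fields, al, cp, SIMPLIFY = FALSE)
  cp <- mapply(function(a, c0) {
    if (length(a) == 3L && length(c0) == 0L) c(1, 1, 1) else c0
  }, al, cp, SIMPLIFY = FALSE)
  out <- data.frame(
    sample_id = as.character(df$sample_id),
    marker_id = as.character(df$marker_id),
    alleles = join_num_field(al),
    copy_numbers = join_num_field(cp),
    somy = vapply(filled, function(x) x$somy, integer(1)),
    configuration = vapply(filled, function(x) x$configuration, character(1)),
    ratio = if ("ratio" %in% names(df)) as.numeric(df$ratio) else NA_real_,
    qc_flags = if ("qc_flags" %in% names(df)) as.character(df$qc_flags) else "",
    stringsAsFactors = FALSE)
  out$qc_flags[is.na(out$qc_flags)] <- ""
  class(out) <- c("locus_call_table", "data.frame")
  out
}

#' Read a sample-metadata table
#'
#' @param path file path; columns `sample_id`, `experiment`, `stage`,
#'   `treatment_psi`, `family_id`, `replicate_id`, `role`. Unknown stage,
#'   role or treatment labels are rejected, not coerced.
#' @return A validated data frame.
#' @export
read_sample_meta <- function(path) {
  df <- read_delim_file(path)
  require_columns(df, c("sample_id", "experiment", "stage", "treatment_psi",
                        "family_id", "role"), "sample metadata")
  df$sample_id <- as.character(df$sample_id)
  df$stage <- as.character(df$stage)
  df$role <- as.character(df$role)
  if (!all(df$stage %in% VALID_STAGES))
    tc_stop("tripcheck_validation_error", "unknown stage label(s): %s",
            paste(unique(setdiff(df$stage, VALID_STAGES)), collapse = ", "))
  if (!all(df$role %in% VALID_ROLES))
    tc_stop("tripcheck_validation_error", "unknown role label(s): %s",
            paste(unique(setdiff(df$role, VALID_ROLES)), collapse = ", "))
  tr <- suppressWarnings(as.numeric(df$treatment_psi))
  bad <- df$role == "offspring" & !(tr %in% VALID_TREATMENTS)
  if (any(bad))
    tc_stop("tripcheck_validation_error", "unknown treatment_psi value(s): %s",
            paste(unique(df$treatment_psi[bad]), collapse = ", "))
  parent <- df$role %in% c("dam", "sire")
  if (any(parent & !is.na(tr)))
    tc_stop("tripcheck_validation_error", "parents must not carry a treatment")
  df$treatment_psi <- tr
  if (!"replicate_id" %in% names(df)) df$replicate_id <- NA_character_
  exp1_off <- df$role == "offspring" & df$experiment == 1
  if (any(exp1_off & (is.na(df$replicate_id) | !nzchar(df$replicate_id))))
    tc_stop("tripcheck_validation_error",
            "Experiment 1 offspring must carry a replicate_id")
  df
}

#' Read a stage-interval mortality count table
#'
#' @param path file path; columns `unit_id`, `interval`, `n_start`, `n_dead`.
#'   Intervals must be one of `fertilization_to_eyed_egg`,
#'   `eyed_egg_to_start_feed`, `start_feed_to_parr`.
#' @return A validated data frame.
#' @export
read_mortality_counts <- function(path) {
  df <- read_delim_file(path)
  require_columns(df, c("unit_id", "interval", "n_start", "n_dead"),
                  "mortality table")
  if (!all(df$interval %in% VALID_INTERVALS))
    tc_stop("tripcheck_validation_error", "unknown interval label(s): %s",
            paste(unique(setdiff(df$interval, VALID_INTERVALS)), collapse = ", "))
  if (any(df$n_dead < 0 | df$n_dead > df$n_start))
    tc_stop("tripcheck_validation_error", "n_dead must satisfy 0 <= n_dead <= n_start")
  df
}

#' Write a genotype (locus-call) table
#'
#' Inverse of [read_genotype_table()]; writing then reading reproduces the
#' in-memory structure exactly.
#'
#' @param calls a `locus_call_table`.
#' @param path output path (tab-delimited).
#' @export
write_genotype_table <- function(calls, path) {
  cols <- c("sample_id", "marker_id", "alleles", "copy_numbers", "somy",
            "configuration", "ratio", "qc_flags")
  df <- as.data.frame(calls)[intersect(cols, names(calls))]
  df <- df[order(df$sample_id, df$marker_id), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Write pipeline result tables as delimited text
#'
#' Each table is written as `<name>.tsv` with a deterministic column order
#' and stable row ordering (by `sample_id` and `marker_id` when present),
#' so re-running on the same inputs yields byte-identical outputs.
#'
#' @param tables named list of data frames.
#' @param out_dir output directory, created if needed.
#' @return Invisibly, the vector of files written.
#' @export
write_results <- function(tables, out_dir) {
  stopifnot(is.list(tables), !is.null(names(tables)))
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok || file.access(out_dir, 2) != 0)
    tc_stop("tripcheck_io_error", "output directory is not writable: %s", out_dir)
  paths <- character(0)
  for (nm in names(tables)) {
    df <- as.data.frame(tables[[nm]])
    key <- intersect(c("sample_id", "marker_id", "unit_id", "treatment_psi",
                       "family_id", "term"), names(df))
    if (length(key) > 0L && nrow(df) > 0L)
      df <- df[do.call(order, df[key]), , drop = FALSE]
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE,
                       fileEncoding = "UTF-8")
    paths <- c(paths, p)
  }
  invisible(paths)
}
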