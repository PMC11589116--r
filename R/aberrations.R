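# Typing of inheritance aberrations from offspring-vs-parent genotype
# comparison: missing maternal/paternal alleles, uniparental disomy
# (maternal absence across >3 loci), double-paternal trisomies, and
# repeat-slippage base-pair shifts.

UPD_LOCUS_THRESHOLD <- 3L  # "multiple" means strictly more loci than this

#' Per-locus mismatch findings for one offspring against its parents
#'
#' Each scored locus is labelled `ok`, `ambiguous` (a normal gamete
#' combination explains the call but a single-parent explanation exists
#' too, e.g. at shared parental alleles — never reported as an error),
#' `maternal_allele_missing`, `paternal_allele_missing`, `double_paternal`
#' (a trisomic locus with two copies attributable only to the sire, which
#' polar-body retention cannot produce), `bp_shift_candidate` (compatible
#' after shifting one allele copy by 1-2 repeat motifs; takes precedence
#' over missing-parent explanations), or `incompatible_other`. Unscored
#' loci are skipped with finding `unscored`.
#'
#' @param calls `locus_call_table` rows for one offspring.
#' @param dam_geno,sire_geno `locus_call_table` rows for its parents.
#' @param panel a [marker_panel()].
#' @param context `"diploid"`, `"triploid"` or `"unknown"` (homozygous-locus
#'   interpretation).
#' @return A data frame with one row per marker: `finding`, `has_dam_only`,
#'   offspring and parental alleles.
#' @export
detect_locus_mismatches <- function(calls, dam_geno, sire_geno, panel,
                                    context = "unknown") {
  calls <- as.data.frame(calls)
  dam <- stats::setNames(as.list(split_num_field(dam_geno$alleles)),
                         dam_geno$marker_id)
  sire <- stats::setNames(as.list(split_num_field(sire_geno$alleles)),
                          sire_geno$marker_id)
  al <- split_num_field(calls$alleles)
  cp <- split_num_field(calls$copy_numbers)
  motif <- panel$repeat_motif_bp[match(calls$marker_id, panel$marker_id)]
  motif[is.na(motif)] <- 4
  out <- vector("list", nrow(calls))
  for (i in seq_len(nrow(calls))) {
    m <- calls$marker_id[i]
    if (calls$configuration[i] == "no_call") {
      r <- list(finding = "unscored", has_dam_only = FALSE)
    } else {
      r <- locus_finding(al[[i]], cp[[i]], dam[[m]] %||% numeric(0),
                         sire[[m]] %||% numeric(0), context, motif[i])
    }
    out[[i]] <- data.frame(
      sample_id = calls$sample_id[i], marker_id = m,
      finding = r$finding, has_dam_only = r$has_dam_only,
      offspring_alleles = calls$alleles[i],
      dam_alleles = join_num_field(list(dam[[m]] %||% numeric(0))),
      sire_alleles = join_num_field(list(sire[[m]] %||% numeric(0))),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Parental origin of the duplicated copy at a trisomic locus
#'
#' Enumerates gamete combinations: if the trisomic multiset can only be
#' formed as a maternal dyad plus one paternal allele the extra copy is
#' maternal; if only as one maternal allele plus two paternal copies it is
#' paternal; if both explanations exist (shared alleles) the origin is
#' ambiguous.
#'
#' @param off_alleles,off_copies resolved trisomic genotype (copy numbers
#'   summing to 3).
#' @param dam,sire parental allele vectors.
#' @return `"maternal"`, `"paternal"`, `"ambiguous"`, or `"unexplained"`
#'   when no two-parent combination forms the multiset. Unresolved copy
#'   numbers give `"ambiguous"` with attribute `unresolved_dosage`.
#' @export
classify_extra_allele_origin <- function(off_alleles, off_copies, dam, sire) {
  if (length(off_copies) != length(off_alleles) || anyNA(off_copies) ||
      sum(off_copies) != 3) {
    out <- "ambiguous"
    attr(out, "unresolved_dosage") <- TRUE
    return(out)
  }
  M <- rep(as.numeric(off_alleles), times = off_copies)
  K <- allele_key(M)
  maternal_dyad <- K %in% normal_sets(dam, sire, 3L)
  paternal_dyad <- K %in% double_paternal_sets(dam, sire)
  if (maternal_dyad && paternal_dyad) "ambiguous"
  else if (maternal_dyad) "maternal"
  else if (paternal_dyad) "paternal"
  else "unexplained"
}

#' Collapse per-locus findings into typed aberration events
#'
#' Maternal-missing findings across more than `upd_threshold` loci collapse
#' into a single uniparental-disomy event (`missing_maternal_multi`);
#' at 1 to `upd_threshold` loci they form a `missing_maternal_few` event.
#' Paternal-missing, double-paternal-trisomy and bp-shift findings form
#' their own events, and several event types may coexist on one
#' individual. When an individual shows maternal-missing loci and carries
#' no dam-only allele anywhere (pervasive homozygosity / parent-shared
#' alleles elsewhere), the `total_maternal_absence` flag is set — such
#' individuals may be androgenetic haploids or doubled haploids, which
#' fragment-length genotyping cannot resolve; the flag is reported, never
#' resolved further.
#'
#' @param findings output of [detect_locus_mismatches()] for one individual.
#' @param upd_threshold the "multiple loci" boundary (default 3: 4+ loci
#'   collapse to UPD, 3 or fewer stay `missing_maternal_few`).
#' @return An `AberrationEvent` data frame (possibly 0 rows).
#' @export
aggregate_aberrations <- function(findings, upd_threshold = UPD_LOCUS_THRESHOLD) {
  f <- as.data.frame(findings)
  sample_id <- f$sample_id[1] %||% NA_character_
  ev <- list()
  add <- function(type, loci, flags = "") {
    detail <- paste(sprintf("%s[off=%s|dam=%s|sire=%s]", f$marker_id,
                            f$offspring_alleles, f$dam_alleles, f$sire_alleles)[
                              f$marker_id %in% loci], collapse = ",")
    ev[[length(ev) + 1L]] <<- data.frame(
      sample_id = sample_id, type = type, n_loci = length(loci),
      loci = paste(loci, collapse = ";"), detail = detail, flags = flags,
      stringsAsFactors = FALSE)
  }
  mat <- f$marker_id[f$finding == "maternal_allele_missing"]
  if (length(mat) > 0L) {
    flags <- if (!any(f$has_dam_only[f$finding != "unscored"]))
      "total_maternal_absence" else ""
    add(if (length(mat) > upd_threshold) "missing_maternal_multi"
        else "missing_maternal_few", mat, flags)
  }
  pat <- f$marker_id[f$finding == "paternal_allele_missing"]
  if (length(pat) > 0L) add("missing_paternal", pat)
  dp <- f$marker_id[f$finding == "double_paternal"]
  if (length(dp) > 0L) add("double_paternal_trisomy", dp)
  sh <- f$marker_id[f$finding == "bp_shift_candidate"]
  if (length(sh) > 0L) add("bp_shift", sh)
  if (length(ev) == 0L)
    return(data.frame(sample_id = character(0), type = character(0),
                      n_loci = integer(0), loci = character(0),
                      detail = character(0), flags = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, ev)
}

#' Aberration events for a whole cohort
#'
#' Runs per-locus mismatch detection against each offspring's assigned (or
#' hatchery-known) family and aggregates typed events. Trisomic loci in
#' mostly-diploid individuals are additionally origin-typed
#' ([classify_extra_allele_origin()]): paternal duplications become
#' `double_paternal_trisomy` events and ambiguous ones
#' `extra_allele_ambiguous_origin` events (maternal duplications are
#' consistent with ordinary nondisjunction of the dam's gamete and are not
#' error events).
#'
#' @param calls offspring `locus_call_table`.
#' @param ploidy `PloidyCall` data frame (ploidy context per individual).
#' @param family_of data frame `sample_id`, `family_id` (from assignment or
#'   hatchery records).
#' @param parents a [parent_pairs()] object.
#' @param panel a [marker_panel()].
#' @param upd_threshold see [aggregate_aberrations()].
#' @return list with `events` (all `AberrationEvent` rows) and `findings`
#'   (the per-locus table).
#' @export
aberration_table <- function(calls, ploidy, family_of, parents, panel,
                             upd_threshold = UPD_LOCUS_THRESHOLD) {
  dt <- data.table::as.data.table(as.data.frame(calls))
  fam <- data.table::as.data.table(family_of[, c("sample_id", "family_id")])
  dt <- fam[dt, on = "sample_id"]
  dt <- dt[!is.na(family_id) & configuration != "no_call"]
  ctx <- data.table::data.table(
    sample_id = ploidy$sample_id,
    context = data.table::fcase(ploidy$ploidy_class == "diploid", "diploid",
                                ploidy$ploidy_class == "triploid", "triploid",
                                default = "unknown"),
    p_tri = ploidy$trisomic_proportion)
  dt <- ctx[dt, on = "sample_id"]
  dt[is.na(context), context := "unknown"]
  dt[, motif := panel$repeat_motif_bp[match(marker_id, panel$marker_id)]]
  dt[is.na(motif), motif := 4]
  plt <- parent_locus_table(parents)
  dt <- plt[dt, on = c("family_id", "marker_id")]
  dt[is.na(dam_alleles), `:=`(dam_alleles = "-", sire_alleles = "-")]
  u <- eval_findings_unique(as.data.frame(
    dt[, c("alleles", "copy_numbers", "dam_alleles", "sire_alleles",
           "context", "motif")]))
  dt <- data.table::as.data.table(u)[dt,
    on = c("alleles", "copy_numbers", "dam_alleles", "sire_alleles",
           "context", "motif")]
  findings <- as.data.frame(dt[, .(sample_id, marker_id, finding, has_dam_only,
                                   offspring_alleles = alleles, dam_alleles,
                                   sire_alleles)])
  ev_list <- lapply(split(findings, findings$sample_id), aggregate_aberrations,
                    upd_threshold = upd_threshold)
  events <- do.call(rbind, c(ev_list, list(aggregate_aberrations(
    data.frame(sample_id = character(0), marker_id = character(0),
               finding = character(0), has_dam_only = logical(0),
               offspring_alleles = character(0), dam_alleles = character(0),
               sire_alleles = character(0))))))
  # origin-type spontaneous trisomies in mostly-diploid individuals
  tri <- dt[!is.na(p_tri) & p_tri > 0 & p_tri <= 0.5 & somy == 3L &
              configuration %in% c("AAB", "ABB", "ABC") & finding %in%
              c("ok", "ambiguous")]
  if (nrow(tri) > 0L) {
    al <- split_num_field(tri$alleles); cp <- split_num_field(tri$copy_numbers)
    da <- split_num_field(tri$dam_alleles); si <- split_num_field(tri$sire_alleles)
    org <- vapply(seq_len(nrow(tri)), function(i)
      as.character(classify_extra_allele_origin(al[[i]], cp[[i]], da[[i]], si[[i]])),
      character(1))
    amb <- tri[org == "ambiguous"]
    if (nrow(amb) > 0L) {
      extra <- amb[, .(type = "extra_allele_ambiguous_origin", n_loci = .N,
                       loci = paste(sort(marker_id), collapse = ";"),
                       detail = paste(sprintf("%s[off=%s]", marker_id, alleles),
                                      collapse = ","),
                       flags = ""), by = sample_id]
      events <- rbind(events, as.data.frame(extra))
    }
  }
  rownames(events) <- NULL
  events <- events[order(events$sample_id, events$type), , drop = FALSE]
  list(events = events, findings = findings)
}
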