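# Exclusion-based family assignment for half-sibling diploid/triploid
# cohorts: count incompatible loci against every candidate parent pair and
# assign where exactly one family survives the mismatch tolerance.

#' Bundle parental genotypes into per-family parent pairs
#'
#' @param parent_calls a `locus_call_table` holding the parents' genotypes
#'   (diploid: at most two alleles per locus).
#' @param family_map data frame with columns `family_id`, `dam_id`,
#'   `sire_id` (the sire is shared across families in a half-sib design).
#' @return A `parent_pairs` object.
#' @export
parent_pairs <- function(parent_calls, family_map) {
  pc <- as.data.frame(parent_calls)
  al <- split_num_field(pc$alleles)
  if (any(lengths(al) > 2L))
    tc_stop("tripcheck_validation_error",
            "parents must be diploid (> 2 alleles found at a locus)")
  geno <- data.frame(sample_id = pc$sample_id, marker_id = pc$marker_id,
                     alleles = join_num_field(al), stringsAsFactors = FALSE)
  need <- unique(c(family_map$dam_id, family_map$sire_id))
  absent <- setdiff(need, geno$sample_id)
  if (length(absent) > 0L)
    tc_stop("tripcheck_validation_error", "no genotype rows for parent(s): %s",
            paste(absent, collapse = ", "))
  structure(list(genotypes = geno, family_map = as.data.frame(family_map)),
            class = "parent_pairs")
}

# long table: family_id, marker_id, dam_alleles, sire_alleles
parent_locus_table <- function(parents) {
  g <- data.table::as.data.table(parents$genotypes)
  fm <- data.table::as.data.table(parents$family_map)
  dams <- g[fm, on = c(sample_id = "dam_id"), allow.cartesian = TRUE,
            .(family_id, marker_id, dam_alleles = alleles)]
  sires <- g[fm, on = c(sample_id = "sire_id"), allow.cartesian = TRUE,
             .(family_id, marker_id, sire_alleles = alleles)]
  merge(dams, sires, by = c("family_id", "marker_id"))
}

#' Assign offspring to families by exclusion
#'
#' For every offspring x family the number of incompatible loci is counted
#' under the offspring's ploidy context (diploid, triploid, or
#' presence-based for aneuploid/undetermined individuals). A locus that is
#' only explicable by a 1-2 repeat-motif shift of a single allele copy is
#' excused (up to `max_shift_excused` loci, then counted as a mismatch) —
#' slippage mutations are common and benign, and should not exclude the
#' true family. Status follows strict exclusion logic: `unique` when
#' exactly one family has mismatches at or below the tolerance,
#' `ambiguous_tie` when several do (never broken randomly), `unassigned`
#' when none does. An assigned offspring showing no unambiguous maternal
#' signal across 5+ scored loci is flagged questionable.
#'
#' @param calls offspring `locus_call_table`.
#' @param ploidy a `PloidyCall` data frame (for the ploidy context).
#' @param parents a [parent_pairs()] object.
#' @param panel a [marker_panel()] (motif lengths for the shift rule).
#' @param tolerance maximum incompatible loci for a family to remain a
#'   candidate (default 1, absorbing single-locus mutations/UPD).
#' @param max_shift_excused bp-shift loci excused per offspring (default 1).
#' @return An `AssignmentResult` data frame with per-family mismatch counts
#'   in attribute `mismatch_matrix`.
#' @export
assign_families <- function(calls, ploidy, parents, panel, tolerance = 1,
                            max_shift_excused = 1) {
  dt <- data.table::as.data.table(as.data.frame(calls))
  dt <- dt[configuration != "no_call"]
  if (nrow(dt) == 0L)
    tc_stop("tripcheck_validation_error", "zero scored loci: nothing to assign")
  ctx <- data.table::data.table(
    sample_id = ploidy$sample_id,
    context = data.table::fcase(ploidy$ploidy_class == "diploid", "diploid",
                                ploidy$ploidy_class == "triploid", "triploid",
                                default = "unknown"))
  dt <- ctx[dt, on = "sample_id"]
  dt[is.na(context), context := "unknown"]
  dt[, motif := panel$repeat_motif_bp[match(marker_id, panel$marker_id)]]
  dt[is.na(motif), motif := 4]
  plt <- parent_locus_table(parents)
  grid <- plt[dt, on = "marker_id", allow.cartesian = TRUE]
  grid <- grid[!is.na(family_id)]
  u <- eval_findings_unique(as.data.frame(
    grid[, c("alleles", "copy_numbers", "dam_alleles", "sire_alleles",
             "context", "motif")]))
  grid <- data.table::as.data.table(u)[grid,
    on = c("alleles", "copy_numbers", "dam_alleles", "sire_alleles",
           "context", "motif")]
  per_fam <- grid[, .(
    n_incompatible = sum(compat == "incompatible"),
    n_shift = sum(compat == "shift"),
    n_evaluated = sum(compat != "uninformative"),
    n_dam_only = sum(compat != "uninformative" & has_dam_only)),
    by = .(sample_id, family_id)]
  per_fam[, mismatches := n_incompatible + pmax(0L, n_shift - max_shift_excused)]
  res <- per_fam[, {
    ok <- mismatches <= tolerance
    min_m <- min(mismatches)
    status <- if (sum(ok) == 1L) "unique" else if (sum(ok) >= 2L)
      "ambiguous_tie" else "unassigned"
    best <- if (status == "unique") family_id[ok] else NA_character_
    bi <- which.min(mismatches)
    flags <- character(0)
    if (!is.na(best) && n_evaluated[bi] >= 5L && n_dam_only[bi] == 0L)
      flags <- c(flags, "questionable_no_maternal_signal")
    list(assigned_family = best, status = status, min_mismatch = min_m,
         n_candidates = sum(ok),
         n_shift_excused = min(n_shift[bi], max_shift_excused),
         flags = paste(flags, collapse = ";"))
  }, by = sample_id]
  data.table::setorder(res, sample_id)
  out <- as.data.frame(res)
  mm <- data.table::dcast(per_fam, sample_id ~ family_id,
                          value.var = "mismatches")
  attr(out, "mismatch_matrix") <- as.data.frame(mm)
  class(out) <- c("assignment_result", "data.frame")
  out
}

#' Assign a single offspring to a family
#'
#' Convenience wrapper around [assign_families()] for one individual.
#'
#' @inheritParams assign_families
#' @param offspring_calls `locus_call_table` rows for one individual.
#' @param ploidy_class the individual's ploidy class string.
#' @return One `AssignmentResult` row.
#' @export
assign_family <- function(offspring_calls, ploidy_class, parents, panel,
                          tolerance = 1, max_shift_excused = 1) {
  pl <- data.frame(sample_id = offspring_calls$sample_id[1],
                   ploidy_class = ploidy_class, stringsAsFactors = FALSE)
  assign_families(offspring_calls, pl, parents, panel, tolerance,
                  max_shift_excused)
}
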