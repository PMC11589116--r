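# Shared pedigree-compatibility engine: enumerate the gamete combinations a
# diploid dam x sire pair can produce under a given ploidy context and match
# offspring allele multisets against them. Used by both exclusion-based
# family assignment and aberration typing, with memoisation over unique
# (marker, family, genotype) combinations.

expand_parent <- function(alleles) {
  a <- as.numeric(alleles)
  if (length(a) == 1L) c(a, a) else a[1:2]
}

multiset_keys <- function(lst) unique(vapply(lst, allele_key, character(1)))

# all multisets of size n drawn from a single diploid parent (selfed pool)
single_parent_sets <- function(par, n) {
  g <- expand_parent(par)
  if (n == 2L) {
    combos <- list(c(g[1], g[1]), c(g[1], g[2]), c(g[2], g[2]))
  } else {
    combos <- list()
    for (i in 1:2) for (j in 1:2) for (k in 1:2)
      combos[[length(combos) + 1L]] <- c(g[i], g[j], g[k])
  }
  multiset_keys(combos)
}

normal_sets <- function(dam, sire, n) {
  d <- expand_parent(dam); s <- expand_parent(sire)
  combos <- list()
  if (n == 2L) {
    for (i in 1:2) for (j in 1:2) combos[[length(combos) + 1L]] <- c(d[i], s[j])
  } else {
    # triploid via second-polar-body retention: a maternal dyad plus one
    # paternal allele; the dyad may be homozygous or (post-crossover)
    # heterozygous, so any pair from the dam's two alleles is admissible
    for (i in 1:2) for (j in 1:2) for (k in 1:2)
      combos[[length(combos) + 1L]] <- c(d[i], d[j], s[k])
  }
  multiset_keys(combos)
}

double_paternal_sets <- function(dam, sire) {
  d <- expand_parent(dam); s <- expand_parent(sire)
  combos <- list()
  for (i in 1:2) for (j in 1:2) for (k in 1:2)
    combos[[length(combos) + 1L]] <- c(d[i], s[j], s[k])
  multiset_keys(combos)
}

# shifted variants of a multiset: one copy of one NON-parental allele moved
# by 1-2 motifs (slippage creates novel alleles; an allele already present
# in a parent needs no shift explanation)
shifted_keys <- function(m, motif, pool) {
  keys <- character(0)
  for (i in seq_along(m)) {
    if (m[i] %in% pool) next
    for (delta in c(-2, -1, 1, 2) * motif) {
      m2 <- m
      m2[i] <- m2[i] + delta
      keys <- c(keys, allele_key(m2))
    }
  }
  unique(keys)
}

# Core per-locus evaluation. Returns a list:
#   compat  : compatible | shift | incompatible | uninformative
#   finding : ok | ambiguous | maternal_allele_missing | paternal_allele_missing |
#             double_paternal | bp_shift_candidate | incompatible_other | unscored
#   has_dam_only : offspring carries an allele found in the dam but not the sire
locus_finding <- function(off_alleles, off_copies, dam, sire, context, motif) {
  if (length(off_alleles) == 0L)
    return(list(compat = "uninformative", finding = "unscored", has_dam_only = FALSE))
  if (length(dam) == 0L || length(sire) == 0L)
    return(list(compat = "uninformative", finding = "unscored", has_dam_only = FALSE))
  d <- expand_parent(dam); s <- expand_parent(sire)
  dam_only <- setdiff(d, s)
  has_dam_only <- any(off_alleles %in% dam_only)

  M <- NULL
  if (length(off_copies) == length(off_alleles) && length(off_copies) > 0L &&
      !anyNA(off_copies)) {
    M <- rep(off_alleles, times = off_copies)
  } else if (length(off_alleles) == 1L && context %in% c("diploid", "triploid")) {
    M <- rep(off_alleles, if (context == "diploid") 2L else 3L)
  }

  if (!is.null(M) && length(M) %in% c(2L, 3L)) {
    n <- length(M); K <- allele_key(M)
    norm <- normal_sets(dam, sire, n)
    mat_missing <- single_parent_sets(sire, n)
    pat_missing <- single_parent_sets(dam, n)
    if (K %in% norm) {
      amb <- K %in% mat_missing || K %in% pat_missing
      return(list(compat = "compatible",
                  finding = if (amb) "ambiguous" else "ok",
                  has_dam_only = has_dam_only))
    }
    if (any(shifted_keys(M, motif, c(d, s)) %in% norm))
      return(list(compat = "shift", finding = "bp_shift_candidate",
                  has_dam_only = has_dam_only))
    if (n == 3L && K %in% double_paternal_sets(dam, sire))
      return(list(compat = "incompatible", finding = "double_paternal",
                  has_dam_only = has_dam_only))
    if (K %in% mat_missing)
      return(list(compat = "incompatible", finding = "maternal_allele_missing",
                  has_dam_only = has_dam_only))
    if (K %in% pat_missing)
      return(list(compat = "incompatible", finding = "paternal_allele_missing",
                  has_dam_only = has_dam_only))
    return(list(compat = "incompatible", finding = "incompatible_other",
                has_dam_only = has_dam_only))
  }

  # presence mode: dosage unresolved, every offspring allele must occur in
  # the parental pool; single-parent explanations are reported but (being
  # unprovable without dosage) do not exclude the family
  pool <- unique(c(d, s))
  absent <- setdiff(off_alleles, pool)
  if (length(absent) > 0L) {
    shifted_ok <- all(vapply(absent, function(a)
      any((a + c(-2, -1, 1, 2) * motif) %in% pool), logical(1)))
    if (shifted_ok)
      return(list(compat = "shift", finding = "bp_shift_candidate",
                  has_dam_only = has_dam_only))
    return(list(compat = "incompatible", finding = "incompatible_other",
                has_dam_only = has_dam_only))
  }
  in_dam <- any(off_alleles %in% d); in_sire <- any(off_alleles %in% s)
  all_in_dam <- all(off_alleles %in% d); all_in_sire <- all(off_alleles %in% s)
  finding <- if (!in_dam) "maternal_allele_missing" else
    if (!in_sire) "paternal_allele_missing" else
      if (all_in_dam || all_in_sire) "ambiguous" else "ok"
  list(compat = "compatible", finding = finding, has_dam_only = has_dam_only)
}

#' Is an offspring locus call compatible with a parent pair?
#'
#' Diploid context: the offspring allele multiset must be formable as one
#' dam allele plus one sire allele. Triploid context: as a maternal dyad
#' (any pair from the dam's two alleles, dosage-consistent when copy
#' numbers are resolved) plus one sire allele. When dosage is unresolved
#' the check falls back to allele presence in the parental pool.
#'
#' @param off_alleles,off_copies offspring alleles and per-allele copy
#'   numbers (copies may be `NULL`/`NA` when unresolved).
#' @param dam,sire parental allele vectors (length 1 homozygous or 2).
#' @param context `"diploid"`, `"triploid"` or `"unknown"`.
#' @param motif_bp repeat motif length, used to recognise single-slippage
#'   (bp-shift) explanations.
#' @return `"compatible"`, `"incompatible"` or `"uninformative"`, with
#'   attribute `bp_shift_candidate` set when the locus is only compatible
#'   after shifting one allele copy by 1-2 repeat motifs.
#' @export
locus_compatible <- function(off_alleles, off_copies, dam, sire,
                             context = "unknown", motif_bp = 4) {
  r <- locus_finding(as.numeric(off_alleles),
                     if (is.null(off_copies)) numeric(0) else as.numeric(off_copies),
                     as.numeric(dam), as.numeric(sire), context, motif_bp)
  out <- switch(r$compat, compatible = "compatible", shift = "incompatible",
                incompatible = "incompatible", "uninformative")
  attr(out, "bp_shift_candidate") <- identical(r$compat, "shift")
  out
}

# Memoised evaluation over unique (marker, family, genotype, context) rows.
# `tbl` needs columns: alleles, copy_numbers (";"-joined strings),
# dam_alleles, sire_alleles (";"-joined), context, motif.
eval_findings_unique <- function(tbl) {
  u <- unique(tbl[, c("alleles", "copy_numbers", "dam_alleles", "sire_alleles",
                      "context", "motif")])
  al <- split_num_field(u$alleles)
  cp <- split_num_field(u$copy_numbers)
  da <- split_num_field(u$dam_alleles)
  si <- split_num_field(u$sire_alleles)
  res <- vector("list", nrow(u))
  for (i in seq_len(nrow(u)))
    res[[i]] <- locus_finding(al[[i]], cp[[i]], da[[i]], si[[i]],
                              u$context[i], u$motif[i])
  u$compat <- vapply(res, `[[`, character(1), "compat")
  u$finding <- vapply(res, `[[`, character(1), "finding")
  u$has_dam_only <- vapply(res, `[[`, logical(1), "has_dam_only")
  u
}
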