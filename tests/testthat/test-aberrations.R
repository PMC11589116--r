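# Inheritance-aberration typing: per-locus findings, UPD collapse,
# extra-allele origin, precedence of the bp-shift explanation, and recovery
# of planted aberrations from a simulated cohort.

ab_panel <- function(n = 20) marker_panel(sprintf("L%02d", 1:n), 4L,
                                          90, 400)

mk_call_row <- function(sample_id, marker_id, alleles, copies) {
  al <- strsplit(alleles, ";")[[1]]
  cp <- if (copies == "-") character(0) else strsplit(copies, ";")[[1]]
  cfg <- if (length(al) == 1) "homozygous" else
    if (copies == "1;1") "AB" else if (copies == "2;1") "AAB" else
      if (copies == "1;2") "ABB" else if (copies == "1;1;1") "ABC" else "unresolved"
  somy <- if (length(cp) > 0) sum(as.numeric(cp)) else NA_integer_
  data.frame(sample_id = sample_id, marker_id = marker_id, alleles = alleles,
             copy_numbers = copies, somy = as.integer(somy),
             configuration = cfg, ratio = NA_real_, qc_flags = "",
             stringsAsFactors = FALSE)
}

par_row <- function(id, marker, alleles)
  mk_call_row(id, marker, alleles, if (grepl(";", alleles)) "1;1" else "2")

test_that("per-locus findings separate missing-parent, double-paternal, shift and ambiguous", {
  panel <- ab_panel(4)
  dam <- do.call(rbind, lapply(1:4, function(i)
    par_row("D", sprintf("L%02d", i), "131;139")))
  sire <- do.call(rbind, lapply(1:4, function(i)
    par_row("S", sprintf("L%02d", i), "143;147")))
  off <- rbind(mk_call_row("O", "L01", "143;147", "1;1"),   # both paternal
               mk_call_row("O", "L02", "131;143", "1;2"),   # two paternal copies
               mk_call_row("O", "L03", "135;143", "1;1"),   # 135 = 131 + 1 motif
               mk_call_row("O", "L04", "131;139", "1;1"))   # both maternal
  f <- detect_locus_mismatches(off, dam, sire, panel, context = "diploid")
  expect_equal(f$finding[f$marker_id == "L01"], "maternal_allele_missing")
  expect_equal(f$finding[f$marker_id == "L02"], "double_paternal")
  expect_equal(f$finding[f$marker_id == "L03"], "bp_shift_candidate")
  expect_equal(f$finding[f$marker_id == "L04"], "paternal_allele_missing")
})

test_that("shared parental alleles yield ambiguous findings, not false positives", {
  panel <- ab_panel(1)
  dam <- par_row("D", "L01", "131;139")
  sire <- par_row("S", "L01", "139;147")
  off <- mk_call_row("O", "L01", "139;147", "1;1")
  f <- detect_locus_mismatches(off, dam, sire, panel, context = "diploid")
  expect_equal(f$finding, "ambiguous")
  # and a normally-explained call stays ok
  ok <- detect_locus_mismatches(mk_call_row("O", "L01", "131;147", "1;1"),
                                dam, sire, panel, context = "diploid")
  expect_equal(ok$finding, "ok")
})

test_that("no aberration is emitted where a standard gamete combination explains the call", {
  set.seed(77)
  panel <- ab_panel(1)
  pool <- seq(100, 132, by = 4)
  for (i in 1:200) {
    dam <- sort(sample(pool, 2)); sire <- sort(sample(pool, 2))
    ploidy <- sample(2:3, 1)
    m <- if (ploidy == 2) c(sample(dam, 1), sample(sire, 1)) else
      c(sample(dam, 2, replace = TRUE), sample(sire, 1))
    tab <- table(m)
    off <- mk_call_row("O", "L01", paste(names(tab), collapse = ";"),
                       paste(as.integer(tab), collapse = ";"))
    f <- detect_locus_mismatches(off, par_row("D", "L01", paste(dam, collapse = ";")),
                                 par_row("S", "L01", paste(sire, collapse = ";")),
                                 panel)
    expect_true(f$finding %in% c("ok", "ambiguous"))
  }
})

test_that("extra-allele origin matches brute-force enumeration", {
  expect_equal(as.character(classify_extra_allele_origin(
    c(131, 143), c(2, 1), c(131, 139), c(143, 147))), "maternal")
  expect_equal(as.character(classify_extra_allele_origin(
    c(131, 143), c(1, 2), c(131, 139), c(143, 147))), "paternal")
  expect_equal(as.character(classify_extra_allele_origin(
    c(131, 139), c(1, 2), c(131, 139), c(139, 147))), "ambiguous")
  set.seed(88)
  pool <- seq(100, 128, by = 4)
  for (i in 1:200) {
    dam <- sample(pool, 2, replace = TRUE); sire <- sample(pool, 2, replace = TRUE)
    m <- sample(pool, 3, replace = TRUE)
    tab <- table(m)
    got <- as.character(classify_extra_allele_origin(
      as.numeric(names(tab)), as.integer(tab), dam, sire))
    expect_equal(got, oracle_origin(m, dam, sire))
  }
})

test_that("maternal-absence collapses to UPD strictly above 3 loci", {
  panel <- ab_panel(6)
  dam <- do.call(rbind, lapply(1:6, function(i)
    par_row("D", sprintf("L%02d", i), "131;139")))
  sire <- do.call(rbind, lapply(1:6, function(i)
    par_row("S", sprintf("L%02d", i), "143;147")))
  off_n <- function(k) do.call(rbind, lapply(1:6, function(i)
    if (i <= k) mk_call_row("O", sprintf("L%02d", i), "143;147", "1;1")
    else mk_call_row("O", sprintf("L%02d", i), "131;143", "1;1")))
  f4 <- detect_locus_mismatches(off_n(4), dam, sire, panel, "diploid")
  ev4 <- aggregate_aberrations(f4)
  expect_equal(ev4$type, "missing_maternal_multi")
  expect_equal(ev4$n_loci, 4L)
  f3 <- detect_locus_mismatches(off_n(3), dam, sire, panel, "diploid")
  ev3 <- aggregate_aberrations(f3)
  expect_equal(ev3$type, "missing_maternal_few")
})

test_that("pervasive homozygosity with no dam-only allele sets total_maternal_absence", {
  # half the loci homozygous for a sire-only allele, half homozygous for an
  # allele shared by both parents: total absence of maternal DNA signal
  panel <- ab_panel(20)
  dam <- do.call(rbind, lapply(1:20, function(i)
    par_row("D", sprintf("L%02d", i), if (i <= 10) "131;139" else "139;147")))
  sire <- do.call(rbind, lapply(1:20, function(i)
    par_row("S", sprintf("L%02d", i), "143;147")))
  off <- do.call(rbind, lapply(1:20, function(i)
    mk_call_row("O", sprintf("L%02d", i), if (i <= 10) "143" else "147", "-")))
  f <- detect_locus_mismatches(off, dam, sire, panel, context = "unknown")
  ev <- aggregate_aberrations(f)
  expect_equal(ev$type, "missing_maternal_multi")
  expect_equal(ev$n_loci, 10L)
  expect_match(ev$flags, "total_maternal_absence")
})

test_that("several aberration types may coexist on one individual", {
  panel <- ab_panel(3)
  dam <- do.call(rbind, lapply(1:3, function(i)
    par_row("D", sprintf("L%02d", i), "131;139")))
  sire <- do.call(rbind, lapply(1:3, function(i)
    par_row("S", sprintf("L%02d", i), "143;147")))
  off <- rbind(mk_call_row("O", "L01", "135;143", "1;1"),  # bp shift
               mk_call_row("O", "L02", "131;143", "1;2"),  # double paternal
               mk_call_row("O", "L03", "131;147", "1;1"))  # normal
  ev <- aggregate_aberrations(detect_locus_mismatches(off, dam, sire, panel,
                                                      "diploid"))
  expect_setequal(ev$type, c("bp_shift", "double_paternal_trisomy"))
})

test_that("planted aberrations are recovered with high recall and near-zero false positives", {
  p <- sim_params(upd_rate = 0.10, slippage_rate = 0.10,
                  androgenesis_rate = 0)
  par <- simulate_parents(p, seed = 601)
  w <- par$wide
  pp <- parent_pairs(par$genotypes, par$family_map)
  offs <- lapply(1:3, function(f) {
    simulate_offspring(w[w$sample_id == sprintf("DAM%02d", f), ],
                       w[w$sample_id == "SIRE1", ], 0, p, seed = 610 + f,
                       n = 250, family_id = sprintf("F%02d", f),
                       id_prefix = sprintf("AB%d_", f))
  })
  truth <- do.call(rbind, lapply(offs, `[[`, "truth"))
  ind <- do.call(rbind, lapply(offs, `[[`, "individuals"))
  pk <- synthesize_peaks(truth, p, seed = 650)
  calls <- classify_peak_table(pk, p$panel)
  scr <- screen_informative_loci(calls, p$panel)
  pt <- ploidy_table(calls, informative_markers(scr))
  fam <- ind[c("sample_id", "family_id")]
  ab <- aberration_table(calls, pt, fam, pp, p$panel)
  ev <- ab$events

  # parent allele pools per marker, for identifiability of planted events
  pool_of <- split(
    as.numeric(unlist(strsplit(par$genotypes$alleles, ";"))),
    rep(par$genotypes$marker_id,
        lengths(strsplit(par$genotypes$alleles, ";"))))
  dam_ids <- sprintf("DAM%02d", 1:3)

  # UPD recall: planted UPD individuals whose maternal-missing loci carry a
  # sire allele the dam does not share at > 3 loci must raise a multi event
  tdt <- data.table::as.data.table(truth)
  upd_ind <- ind$sample_id[ind$is_upd]
  if (length(upd_ind) > 0) {
    det <- vapply(upd_ind, function(s) {
      fid <- ind$family_id[ind$sample_id == s]
      did <- sprintf("DAM%02d", as.integer(sub("F", "", fid)))
      loci <- tdt[sample_id == s, .(mat = sum(origin == "maternal"),
                                    a = allele[1]), by = marker_id]
      pg <- par$genotypes
      n_det <- 0L
      for (i in which(loci$mat == 0)) {
        m <- loci$marker_id[i]
        dal <- as.numeric(strsplit(pg$alleles[pg$sample_id == did &
                                                pg$marker_id == m], ";")[[1]])
        if (!(loci$a[i] %in% dal)) n_det <- n_det + 1L
      }
      n_det
    }, integer(1))
    idents <- upd_ind[det > 3]
    if (length(idents) > 0) {
      hit <- vapply(idents, function(s)
        any(ev$sample_id == s & ev$type == "missing_maternal_multi"),
        logical(1))
      expect_gte(mean(hit), 0.95)
    }
  }

  # bp-shift recall among planted slippages whose shifted allele is
  # distinguishable from every parental allele at a scored locus
  slip_loci <- unique(tdt[slipped == TRUE, .(sample_id, marker_id)])
  if (nrow(slip_loci) > 0) {
    scored <- calls[calls$configuration != "no_call",
                    c("sample_id", "marker_id")]
    slip_loci <- merge(slip_loci, scored, by = c("sample_id", "marker_id"))
    ident <- vapply(seq_len(nrow(slip_loci)), function(i) {
      s <- slip_loci$sample_id[i]; m <- slip_loci$marker_id[i]
      a <- tdt[sample_id == s & marker_id == m, allele]
      any(!(a %in% pool_of[[m]]))
    }, logical(1))
    sl <- slip_loci[ident, ]
    if (nrow(sl) > 0) {
      hit <- vapply(seq_len(nrow(sl)), function(i) {
        rows <- ev[ev$sample_id == sl$sample_id[i] & ev$type == "bp_shift", ]
        nrow(rows) > 0 && grepl(sl$marker_id[i], rows$loci[1])
      }, logical(1))
      expect_gte(mean(hit), 0.95)
      # precedence: a shift-explicable locus is never typed maternal-missing
      mm_ev <- ev[ev$type %in% c("missing_maternal_few",
                                 "missing_maternal_multi"), ]
      for (i in seq_len(nrow(sl))) {
        if (ind$is_upd[ind$sample_id == sl$sample_id[i]]) next
        rows <- mm_ev[mm_ev$sample_id == sl$sample_id[i], ]
        if (nrow(rows) > 0)
          expect_false(grepl(sl$marker_id[i], rows$loci[1]))
      }
    }
  }

  # false positives: individuals with no planted event and no nondisjunction
  clean <- ind$sample_id[!ind$is_upd & !ind$is_androgenesis &
                           !ind$has_slippage &
                           ind$true_ploidy_class == "diploid"]
  bad_types <- c("missing_maternal_few", "missing_maternal_multi",
                 "missing_paternal", "double_paternal_trisomy", "bp_shift")
  fp <- ev[ev$sample_id %in% clean & ev$type %in% bad_types, ]
  expect_lte(length(unique(fp$sample_id)) / length(clean), 0.01)
})
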