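# MAC-PR dosage classification: band mapping, stutter filtering,
# informative-locus screening, and agreement between the scalar and
# vectorised classifiers.

test_that("classify_locus maps peak counts and height ratios to configurations", {
  # near-balanced two peaks -> AB, somy 2
  ab <- classify_locus(exact_peaks(c(131, 139), c(1.500, 1.480)), 4)
  expect_equal(ab$configuration, "AB")
  expect_equal(ab$somy, 2L)
  # 2:1 ratio -> AAB with copies 2;1 (2400/1150 = 2.09 inside the 2:1 band)
  aab <- classify_locus(data.frame(allele_size_bp = c(210, 214),
                                   height_rfu = c(2400, 1150)), 4)
  expect_equal(aab$configuration, "AAB")
  expect_equal(aab$somy, 3L)
  expect_equal(aab$copy_numbers, "2;1")
  # three peaks -> ABC, somy 3
  abc <- classify_locus(data.frame(allele_size_bp = c(150, 154, 162),
                                   height_rfu = c(900, 880, 910)), 4)
  expect_equal(abc$configuration, "ABC")
  expect_equal(abc$somy, 3L)
  # single peak -> homozygous pattern, somy unknown
  hom <- classify_locus(data.frame(allele_size_bp = 131, height_rfu = 2000), 4)
  expect_equal(hom$configuration, "homozygous")
  expect_true(is.na(hom$somy))
})

test_that("no-signal and excess-peak loci become flagged no-calls", {
  none <- classify_locus(data.frame(allele_size_bp = 131, height_rfu = 40), 4)
  expect_equal(none$configuration, "no_call")
  expect_match(none$qc_flags, "no_signal")
  many <- classify_locus(data.frame(allele_size_bp = c(100, 110, 120, 130),
                                    height_rfu = rep(1000, 4)), 4)
  expect_equal(many$configuration, "no_call")
  expect_match(many$qc_flags, "excess_peaks")
})

test_that("stutter peaks one motif below are removed only when low enough", {
  cal <- dosage_calibration()
  st <- filter_stutter(data.frame(allele_size_bp = c(210, 214),
                                  height_rfu = c(240, 2000)), 4, cal)
  expect_equal(st$allele_size_bp, 214)            # 240/2000 = 0.12 < 0.15
  expect_equal(attr(st, "removed")$allele_size_bp, 210)
  keep <- filter_stutter(data.frame(allele_size_bp = c(210, 214),
                                    height_rfu = c(800, 2000)), 4, cal)
  expect_equal(nrow(keep), 2L)                    # 0.40 > 0.15: true allele
  nothing <- data.frame(allele_size_bp = c(131, 139),
                        height_rfu = c(1500, 1480))
  expect_equal(nrow(filter_stutter(nothing, 4, cal)), 2L)  # identity
})

test_that("ratios exactly on a band boundary are unresolved, not guessed", {
  cal <- dosage_calibration()
  on_edge <- classify_locus(data.frame(allele_size_bp = c(131, 139),
                                       height_rfu = c(1400, 1000)), 4, cal)
  expect_equal(on_edge$configuration, "unresolved")
  expect_match(on_edge$qc_flags, "unresolved_ratio")
  in_gap <- classify_locus(data.frame(allele_size_bp = c(131, 139),
                                      height_rfu = c(1500, 1000)), 4, cal)
  expect_equal(in_gap$configuration, "unresolved")
})

test_that("classification is monotone in the height ratio", {
  # increasing the smaller-size allele's height walks ABB -> AB -> AAB and
  # never reverses (unresolved gaps are allowed between bands)
  ord <- c(ABB = 1, AB = 2, AAB = 3)
  last <- 0
  for (h in seq(400, 2600, by = 25)) {
    call <- classify_locus(data.frame(allele_size_bp = c(131, 139),
                                      height_rfu = c(h, 1000)), 4)
    lvl <- unname(ord[call$configuration])
    if (!is.na(lvl)) {
      expect_gte(lvl, last)
      last <- lvl
    }
  }
  expect_equal(last, 3)
})

test_that("noise-free peaks with heights proportional to copy number recover every configuration", {
  cases <- list(list(a = c(131, 139), cp = c(1, 1), cfg = "AB"),
                list(a = c(131, 139), cp = c(2, 1), cfg = "AAB"),
                list(a = c(131, 139), cp = c(1, 2), cfg = "ABB"),
                list(a = c(131, 139, 147), cp = c(1, 1, 1), cfg = "ABC"))
  for (base in c(300, 1000, 4000)) {
    for (cs in cases) {
      call <- classify_locus(exact_peaks(cs$a, cs$cp, base), 4)
      expect_equal(call$configuration, cs$cfg)
      expect_equal(call$somy, as.integer(sum(cs$cp)))
    }
  }
})

test_that("copy numbers sum to somy for every resolved call (conservation)", {
  p <- sim_params()
  par <- simulate_parents(p, seed = 5)
  w <- par$wide
  off <- simulate_offspring(w[w$sample_id == "DAM02", ],
                            w[w$sample_id == "SIRE1", ], 7500, p, seed = 6,
                            n = 60, family_id = "F02", id_prefix = "MC")
  pk <- synthesize_peaks(off$truth, p, seed = 7)
  calls <- classify_peak_table(pk, p$panel)
  res <- calls[calls$configuration %in% c("AB", "AAB", "ABB", "ABC"), ]
  sums <- vapply(strsplit(res$copy_numbers, ";"),
                 function(v) sum(as.numeric(v)), numeric(1))
  expect_true(all(sums == res$somy))
})

test_that("the vectorised cohort classifier agrees with classify_locus locus by locus", {
  p <- sim_params()
  par <- simulate_parents(p, seed = 9)
  w <- par$wide
  off <- simulate_offspring(w[w$sample_id == "DAM01", ],
                            w[w$sample_id == "SIRE1", ], 7500, p, seed = 10,
                            n = 25, family_id = "F01", id_prefix = "VC")
  pk <- synthesize_peaks(off$truth, p, seed = 11)
  cal <- dosage_calibration()
  vec <- classify_peak_table(pk, p$panel, cal)
  for (i in sample.int(nrow(vec), 120)) {
    sub <- pk[pk$sample_id == vec$sample_id[i] &
                pk$marker_id == vec$marker_id[i], , drop = FALSE]
    motif <- p$panel$repeat_motif_bp[p$panel$marker_id == vec$marker_id[i]]
    one <- classify_locus(sub, motif, cal)
    expect_equal(vec$configuration[i], one$configuration)
    expect_equal(vec$alleles[i], one$alleles)
    expect_equal(vec$somy[i], one$somy)
  }
})

test_that("screening flags unresolved-heavy, stutter-conflicted and homozygous-only markers", {
  panel <- marker_panel(c("M1", "M2", "M3"), c(4L, 4L, 4L),
                        rep(90, 3), rep(300, 3))
  mk_call <- function(s, m, alleles, cfg, somy = NA_integer_) {
    data.frame(sample_id = s, marker_id = m, alleles = alleles,
               copy_numbers = "-", somy = somy, configuration = cfg,
               ratio = NA_real_, qc_flags = "", stringsAsFactors = FALSE)
  }
  calls <- rbind(
    # M1: 40% of two-peak calls unresolved (threshold 25%) -> out
    do.call(rbind, lapply(1:6, function(i)
      mk_call(paste0("S", i), "M1", "100;108",
              if (i <= 4) "AB" else "unresolved", if (i <= 4) 2L else NA))),
    mk_call("S7", "M1", "100;108", "unresolved"),
    mk_call("S8", "M1", "100;108", "unresolved"),
    mk_call("S9", "M1", "100;108", "AB", 2L),
    mk_call("S10", "M1", "100;108", "AB", 2L),
    # M2: clean AB calls but alleles one motif apart in half of them -> out
    do.call(rbind, lapply(1:10, function(i)
      mk_call(paste0("S", i), "M2", if (i <= 5) "100;104" else "100;112",
              "AB", 2L))),
    # M3: every call homozygous -> no heterozygotes flag
    do.call(rbind, lapply(1:10, function(i)
      mk_call(paste0("S", i), "M3", "100", "homozygous"))))
  rep <- screen_informative_loci(calls, panel)
  expect_false(rep$informative[rep$marker_id == "M1"])
  expect_equal(rep$fraction_unresolved[rep$marker_id == "M1"], 0.4)
  expect_false(rep$informative[rep$marker_id == "M2"])
  expect_false(rep$informative[rep$marker_id == "M3"])
  expect_equal(rep$flag[rep$marker_id == "M3"], "no_heterozygotes")
  # a clean marker passes
  clean <- do.call(rbind, lapply(1:10, function(i)
    mk_call(paste0("S", i), "M2", "100;112", "AB", 2L)))
  rep2 <- screen_informative_loci(rbind(clean, calls[calls$marker_id == "M3", ]),
                                  panel)
  expect_true(rep2$informative[rep2$marker_id == "M2"])
})
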