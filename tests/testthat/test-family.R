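# Exclusion-based family assignment for half-sib diploid/triploid cohorts.

test_that("locus compatibility follows gamete enumeration per ploidy context", {
  # one allele from each parent
  expect_equal(as.character(locus_compatible(c(139, 143), c(1, 1),
                                             c(131, 139), c(143, 147),
                                             "diploid")), "compatible")
  # two maternal copies via polar-body retention plus one paternal
  expect_equal(as.character(locus_compatible(c(131, 143), c(2, 1),
                                             c(131, 139), c(143, 147),
                                             "triploid")), "compatible")
  # allele absent from both parents excludes in any context
  for (ctx in c("diploid", "triploid", "unknown"))
    expect_equal(as.character(locus_compatible(c(151, 143), c(1, 1),
                                               c(131, 139), c(143, 147), ctx)),
                 "incompatible")
  # shared allele: compatible (origin ambiguity is not exclusion)
  expect_equal(as.character(locus_compatible(c(139, 147), c(2, 1),
                                             c(131, 139), c(139, 147),
                                             "triploid")), "compatible")
  # unresolved dosage falls back to presence: compatible within the pool
  expect_equal(as.character(locus_compatible(c(139, 143), NULL,
                                             c(131, 139), c(143, 147),
                                             "unknown")), "compatible")
})

test_that("locus_compatible agrees with brute-force gamete enumeration", {
  set.seed(401)
  pool <- seq(100, 140, by = 4)
  for (i in 1:300) {
    dam <- sort(sample(pool, 2, replace = TRUE))
    sire <- sort(sample(pool, 2, replace = TRUE))
    ploidy <- sample(2:3, 1)
    # random offspring multiset, half the time a true cross product
    if (runif(1) < 0.5) {
      m <- if (ploidy == 2) c(sample(dam, 1), sample(sire, 1)) else
        c(sample(dam, 2, replace = TRUE), sample(sire, 1))
    } else {
      m <- sample(pool, ploidy, replace = TRUE)
    }
    tab <- table(m)
    got <- locus_compatible(as.numeric(names(tab)), as.integer(tab), dam, sire,
                            if (ploidy == 2) "diploid" else "triploid",
                            motif_bp = 1000)  # motif huge: no shift rescue
    want <- oracle_compatible(m, dam, sire, ploidy)
    expect_equal(as.character(got) == "compatible", want)
  }
})

mk_geno <- function(sample_id, marker_id, alleles, copies) {
  data.frame(sample_id = sample_id, marker_id = marker_id, alleles = alleles,
             copy_numbers = copies, somy = NA_integer_, configuration = "AB",
             ratio = NA_real_, qc_flags = "", stringsAsFactors = FALSE)
}

toy_parents <- function() {
  g <- rbind(
    mk_geno("D1", c("M1", "M2"), c("100;108", "200;208"), c("1;1", "1;1")),
    mk_geno("D2", c("M1", "M2"), c("116;124", "216;224"), c("1;1", "1;1")),
    mk_geno("D3", c("M1", "M2"), c("132;140", "232;240"), c("1;1", "1;1")),
    mk_geno("S", c("M1", "M2"), c("148;156", "248;256"), c("1;1", "1;1")))
  parent_pairs(g, data.frame(family_id = c("F1", "F2", "F3"),
                             dam_id = c("D1", "D2", "D3"), sire_id = "S"))
}

toy_panel <- function() marker_panel(c("M1", "M2"), c(4L, 4L),
                                     c(90, 190), c(190, 290))

test_that("assign_family is unique when one family fits and unassigned when none does", {
  off <- mk_geno("O1", c("M1", "M2"), c("132;148", "240;256"), c("1;1", "1;1"))
  res <- assign_family(off, "diploid", toy_parents(), toy_panel(),
                       tolerance = 0)
  expect_equal(res$status, "unique")
  expect_equal(res$assigned_family, "F3")
  # exclusion soundness: assigned family has <= tolerance mismatches
  mm <- attr(res, "mismatch_matrix")
  expect_lte(mm$F3, 0)
  # alien alleles at one locus in every family, tolerance 0 -> unassigned
  off2 <- mk_geno("O2", c("M1", "M2"), c("999;148", "240;256"), c("1;1", "1;1"))
  res2 <- assign_family(off2, "diploid", toy_parents(), toy_panel(),
                        tolerance = 0, max_shift_excused = 0)
  expect_equal(res2$status, "unassigned")
  expect_true(is.na(res2$assigned_family))
})

test_that("family order never changes the assignment (symmetry)", {
  off <- mk_geno("O1", c("M1", "M2"), c("116;148", "224;248"), c("1;1", "1;1"))
  p <- toy_parents()
  res1 <- assign_family(off, "diploid", p, toy_panel())
  p2 <- p; p2$family_map <- p$family_map[c(3, 1, 2), ]
  res2 <- assign_family(off, "diploid", p2, toy_panel())
  expect_equal(res1$assigned_family, res2$assigned_family)
  expect_equal(res1$status, res2$status)
})

test_that("half-sib assignment recovers the true family >= 99% for diploids and triploids", {
  res <- exp1_pipeline()
  truth <- res$cohort$individuals[c("sample_id", "family_id",
                                    "true_ploidy_class")]
  names(truth)[2] <- "true_family"
  j <- merge(as.data.frame(res$assignments), truth, by = "sample_id")
  j <- merge(j, res$ploidy[c("sample_id", "ploidy_class")], by = "sample_id")
  clean <- j[j$true_ploidy_class %in% c("diploid", "triploid"), ]
  acc <- mean(clean$status == "unique" & clean$assigned_family == clean$true_family)
  expect_gte(acc, 0.99)
  # exclusion soundness across the cohort
  mm <- attr(res$assignments, "mismatch_matrix")
  assigned <- as.data.frame(res$assignments)
  assigned <- assigned[assigned$status == "unique", ]
  idx <- match(assigned$sample_id, mm$sample_id)
  picked <- mapply(function(i, f) mm[i, f], idx, assigned$assigned_family)
  expect_true(all(picked <= res$config$assignment_tolerance))
})

test_that("assignment accuracy degrades as dam allele sharing increases", {
  run_acc <- function(n_alleles, seed) {
    p <- sim_params()
    fr <- p$allele_freqs
    for (m in names(fr)) {
      k <- min(n_alleles, length(fr[[m]]$sizes))
      fr[[m]] <- list(sizes = fr[[m]]$sizes[1:k],
                      freqs = rep(1 / k, k))
    }
    p$allele_freqs <- fr
    par <- simulate_parents(p, seed)
    w <- par$wide
    pp <- parent_pairs(par$genotypes, par$family_map)
    offs <- list()
    for (f in 1:4) {
      dam <- w[w$sample_id == sprintf("DAM%02d", f), ]
      o <- simulate_offspring(dam, w[w$sample_id == "SIRE1", ], 9500, p,
                              seed = seed + f, n = 25,
                              family_id = sprintf("F%02d", f),
                              id_prefix = sprintf("F%02d_", f))
      offs[[f]] <- o
    }
    truth <- do.call(rbind, lapply(offs, `[[`, "truth"))
    ind <- do.call(rbind, lapply(offs, `[[`, "individuals"))
    pk <- synthesize_peaks(truth, p, seed = seed + 99)
    calls <- classify_peak_table(pk, p$panel)
    scr <- screen_informative_loci(calls, p$panel)
    pt <- ploidy_table(calls, informative_markers(scr))
    asn <- assign_families(calls, pt, pp, p$panel)
    j <- merge(as.data.frame(asn), ind[c("sample_id", "family_id")],
               by = "sample_id")
    mean(j$status == "unique" & j$assigned_family == j$family_id)
  }
  acc_distinct <- mean(vapply(1:2, function(s) run_acc(8, 500 + s), numeric(1)))
  acc_shared <- mean(vapply(1:2, function(s) run_acc(2, 500 + s), numeric(1)))
  expect_lt(acc_shared, acc_distinct)
  expect_gt(acc_distinct, 0.9)
})
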