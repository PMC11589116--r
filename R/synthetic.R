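# Forward simulator of the half-sib, pressure-gradient breeding design:
# parental genotypes, meiosis-II polar-body retention as a logistic
# function of pressure, partial retention loss, family-specific and
# pressure-stress nondisjunction, UPD and androgenesis events, repeat
# slippage, electropherogram peak synthesis with stutter, and viability
# selection between the eyed-egg and parr stages. Full latent truth is
# retained so every downstream stage can be tested against it.

#' Default 30-marker microsatellite panel for simulation
#'
#' Markers 1-20 are designed dosage-informative (allele ladders spaced two
#' repeat motifs apart, so stutter never overlaps a true allele); markers
#' 21-30 carry few alleles spaced one motif apart and mimic the
#' stutter-conflicted loci that fail dosage screening in practice.
#'
#' @param n_markers total marker count (default 30).
#' @param n_informative markers with clean dosage design (default 20).
#' @return A [marker_panel()].
#' @export
default_panel <- function(n_markers = 30, n_informative = 20) {
  ids <- sprintf("Loc%02d", seq_len(n_markers))
  motif <- rep(c(4L, 2L, 3L, 4L, 2L), length.out = n_markers)
  base <- 100 + (seq_len(n_markers) - 1) * 9
  marker_panel(ids, motif, base - 2, base + 80,
               paste0("mplex", rep(1:5, length.out = n_markers)))
}

#' Default allele-frequency model for a panel
#'
#' @param panel a [marker_panel()].
#' @param n_informative markers with the informative design.
#' @return Named list per marker: `sizes`, `freqs`.
#' @export
default_allele_freqs <- function(panel, n_informative = 20) {
  out <- list()
  for (i in seq_len(nrow(panel))) {
    motif <- panel$repeat_motif_bp[i]
    base <- panel$size_min_bp[i] + 2
    if (i <= n_informative) {
      n_all <- 5 + (i %% 4)          # 5-8 alleles
      sizes <- base + (0:(n_all - 1)) * 2 * motif
    } else {
      n_all <- 2 + (i %% 2)          # 2-3 alleles, one motif apart
      sizes <- base + (0:(n_all - 1)) * motif
    }
    fr <- 1 / seq_len(n_all)
    out[[panel$marker_id[i]]] <- list(sizes = sizes, freqs = fr / sum(fr))
  }
  out
}

#' Simulation parameters for the half-sib pressure-gradient design
#'
#' Defaults encode the study conditions the package is designed around:
#' 12 dams crossed to one shared sire; a 30-marker panel of which ~20 are
#' dosage-informative; pressure treatments 0/6500/7500/8500/9500 PSI with
#' logistic polar-body-retention probability (midpoint 7500 PSI, scale
#' 400); family-specific per-locus nondisjunction rates placing control
#' aneuploidy near 12-17%; a pressure-stress nondisjunction term peaking
#' at sub-optimal pressures; a partial-retention-loss channel (each
#' retained maternal copy lost per locus with probability decreasing in
#' PSI); rare UPD and androgenesis events; repeat slippage in ~2.5% of
#' individuals (single-motif steps dominating); multiplicative lognormal
#' peak-height noise and 10% stutter; and viability selection that purges
#' intermediate aneuploids and maternal-DNA-loss individuals between the
#' eyed-egg and parr stages.
#'
#' @param ... overrides for any default component.
#' @return A `sim_params` list.
#' @export
sim_params <- function(...) {
  panel <- default_panel()
  p <- list(
    n_dams = 12L,
    panel = panel,
    allele_freqs = default_allele_freqs(panel),
    retention_midpoint = 7500, retention_scale = 400,
    family_nondisjunction = stats::setNames(
      c(0.009, 0.010, 0.002, 0.006, 0.005, 0.009,
        0.004, 0.006, 0.005, 0.004, 0.0085, 0.0095),
      sprintf("F%02d", 1:12)),
    stress_max = 0.015, stress_peak = 6800, stress_width = 1200,
    loss_max = 0.05, loss_mid = 7000, loss_scale = 500,
    upd_rate = 0.004, upd_loci_range = c(4L, 8L),
    androgenesis_rate = 0.002,
    slippage_rate = 0.025, slippage_two_step_prob = 0.1,
    base_height = 1000, height_sdlog = 0.07,
    stutter_fraction = 0.10, dropout_rate = 0.02,
    viability = list(baseline = 0.93, single_locus = 0.20,
                     intermediate = 0.04, maternal_loss = 0.03,
                     androgenesis = 0.02, w_startfeed = 0.7),
    egg_mort_base = 0.02, egg_mort_max = 0.04,
    egg_mort_mid = 7000, egg_mort_scale = 800)
  dots <- list(...)
  bad <- setdiff(names(dots), names(p))
  if (length(bad) > 0L)
    tc_stop("tripcheck_config_error", "unknown sim_params field(s): %s",
            paste(bad, collapse = ", "))
  p[names(dots)] <- dots
  probs <- c(p$family_nondisjunction, p$upd_rate, p$androgenesis_rate,
             p$slippage_rate, p$stutter_fraction, p$dropout_rate,
             unlist(p$viability), p$stress_max, p$loss_max)
  if (any(probs < 0 | probs > 1))
    tc_stop("tripcheck_config_error", "all probabilities must lie in [0,1]")
  structure(p, class = "sim_params")
}

#' Polar-body retention probability at a given pressure
#'
#' Monotone logistic curve in PSI.
#' @param psi hydrostatic pressure (PSI).
#' @param params a [sim_params()].
#' @return Retention probability in `[0, 1]`.
#' @export
retention_curve <- function(psi, params = sim_params()) {
  stats::plogis((psi - params$retention_midpoint) / params$retention_scale)
}

stress_nondisjunction <- function(psi, params) {
  params$stress_max * exp(-((psi - params$stress_peak) / params$stress_width)^2) *
    as.numeric(psi > 0)
}

retained_copy_loss <- function(psi, params) {
  params$loss_max * stats::plogis(-(psi - params$loss_mid) / params$loss_scale)
}

#' Simulate the half-sib parents
#'
#' One shared sire and `n_dams` diploid dams, drawn per marker from the
#' allele-frequency model. Markers with a single allele draw warnings
#' (they will be uninformative).
#'
#' @param params a [sim_params()].
#' @param seed integer seed (bit-reproducible).
#' @return list with `genotypes` (a `locus_call_table`), `family_map`
#'   (`family_id`, `dam_id`, `sire_id`) and the internal wide table `wide`.
#' @export
simulate_parents <- function(params = sim_params(), seed = 1) {
  panel <- params$panel
  ids <- c("SIRE1", sprintf("DAM%02d", seq_len(params$n_dams)))
  wide <- with_substream(seed, "parents", {
    rows <- list()
    for (m in panel$marker_id) {
      fr <- params$allele_freqs[[m]]
      if (length(fr$sizes) < 2L)
        warning(sprintf("marker %s has < 2 alleles; it will be uninformative", m))
      a1 <- sample(fr$sizes, length(ids), replace = TRUE, prob = fr$freqs)
      a2 <- sample(fr$sizes, length(ids), replace = TRUE, prob = fr$freqs)
      rows[[m]] <- data.table::data.table(sample_id = ids, marker_id = m,
                                          a1 = pmin(a1, a2), a2 = pmax(a1, a2))
    }
    data.table::rbindlist(rows)
  })
  geno <- wide[, .(sample_id, marker_id,
                   alleles = ifelse(a1 == a2, as.character(a1),
                                    paste(a1, a2, sep = ";")),
                   copy_numbers = ifelse(a1 == a2, "2", "1;1"))]
  geno[, somy := 2L]
  geno[, configuration := ifelse(grepl(";", alleles), "AB", "homozygous")]
  geno[, ratio := NA_real_]
  geno[, qc_flags := ""]
  genotypes <- as.data.frame(geno)
  class(genotypes) <- c("locus_call_table", "data.frame")
  family_map <- data.frame(family_id = sprintf("F%02d", seq_len(params$n_dams)),
                           dam_id = sprintf("DAM%02d", seq_len(params$n_dams)),
                           sire_id = "SIRE1", stringsAsFactors = FALSE)
  list(genotypes = genotypes, family_map = family_map,
       wide = as.data.frame(wide))
}

pick_allele <- function(a1, a2) ifelse(stats::runif(length(a1)) < 0.5, a1, a2)

#' Simulate latent offspring for one family x treatment unit
#'
#' With probability `retention_curve(psi)` the offspring receives the
#' triploid template (a maternal dyad from second-polar-body retention
#' plus one paternal copy per locus), otherwise the diploid template.
#' Retained maternal copies are then lost per locus with the
#' pressure-dependent partial-loss probability; per-locus nondisjunction
#' (family rate plus pressure-stress term) adds a copy in diploid
#' templates (extra copy maternal or paternal — paternal only possible
#' because no retention occurred) or removes one in triploid templates;
#' rare whole-genome events plant UPD blocks (maternal alleles replaced by
#' duplicated paternal ones across 4-8 loci) and androgenesis (maternal
#' set absent at every locus); finally repeat slippage mutates one
#' inherited copy by 1-2 motifs in a small fraction of individuals.
#'
#' @param dam_wide,sire_wide one parent's rows of the `wide` genotype
#'   table from [simulate_parents()] (`marker_id`, `a1`, `a2`).
#' @param psi treatment pressure (PSI).
#' @param params a [sim_params()].
#' @param seed integer seed.
#' @param n number of offspring.
#' @param family_id family label (selects the nondisjunction rate; unknown
#'   labels fall back to the mean rate).
#' @param id_prefix prefix for generated sample ids.
#' @return list with `individuals` (latent per-individual truth) and
#'   `truth` (long per-copy contributions: sample, marker, allele, origin).
#' @export
simulate_offspring <- function(dam_wide, sire_wide, psi, params = sim_params(),
                               seed = 1, n = 100, family_id = "F01",
                               id_prefix = "OFF") {
  dam <- data.table::as.data.table(dam_wide)
  sire <- data.table::as.data.table(sire_wide)
  markers <- dam$marker_id
  M <- length(markers)
  q_fam <- params$family_nondisjunction[family_id]
  if (is.na(q_fam)) q_fam <- mean(params$family_nondisjunction)
  q <- q_fam + stress_nondisjunction(psi, params)
  ret_p <- retention_curve(psi, params)
  loss_p <- retained_copy_loss(psi, params)
  motif <- params$panel$repeat_motif_bp[match(markers, params$panel$marker_id)]
  motif[is.na(motif)] <- 4

  with_substream(seed, "offspring", {
    ids <- sprintf("%s%04d", id_prefix, seq_len(n))
    retention <- stats::rbinom(n, 1, ret_p) == 1L
    g <- data.table::CJ(sample_id = ids, marker_id = markers, sorted = FALSE)
    g[, idx := match(marker_id, markers)]
    g[, motif := motif[idx]]
    g[, ret := retention[match(sample_id, ids)]]
    g[, da1 := dam$a1[idx]]; g[, da2 := dam$a2[idx]]
    g[, sa1 := sire$a1[idx]]; g[, sa2 := sire$a2[idx]]
    g[, m1 := pick_allele(da1, da2)]
    g[, m2 := data.table::fifelse(ret, pick_allele(da1, da2), NA_real_)]
    g[, p1 := pick_allele(sa1, sa2)]
    # partial retention loss: the retained maternal copy drops out per locus
    g[ret == TRUE & stats::runif(.N) < loss_p, m2 := NA_real_]
    # per-locus nondisjunction
    g[, nd := stats::runif(.N) < q]
    g[, extra := NA_real_]
    g[, extra_origin := NA_character_]
    tri_now <- g$ret & !is.na(g$m2)
    # trisomic template: nondisjunction sheds one maternal copy (the study's
    # aberration spectrum shows maternal, not paternal, losses under pressure)
    g[nd & tri_now, m2 := NA_real_]
    # diploid template: add an extra copy from one parent's allele pool;
    # a paternally derived extra copy is only possible without retention
    add <- g$nd & !tri_now
    add_mat <- add & stats::runif(nrow(g)) < 0.5
    g[add & add_mat, `:=`(extra = pick_allele(da1, da2),
                          extra_origin = "maternal")]
    g[add & !add_mat, `:=`(extra = pick_allele(sa1, sa2),
                           extra_origin = "paternal")]
    # whole-genome events (only meaningful for non-retained individuals)
    upd_ids <- ids[!retention & stats::runif(n) < params$upd_rate]
    andro_ids <- setdiff(ids[!retention & stats::runif(n) < params$androgenesis_rate],
                         upd_ids)
    if (length(upd_ids) > 0L) {
      k <- sample(seq(params$upd_loci_range[1], params$upd_loci_range[2]),
                  length(upd_ids), replace = TRUE)
      for (i in seq_along(upd_ids)) {
        loci <- sample(markers, k[i])
        sel <- g$sample_id == upd_ids[i] & g$marker_id %in% loci
        g[sel, `:=`(m1 = NA_real_, m2 = NA_real_, extra = p1,
                    extra_origin = "paternal", nd = FALSE)]
      }
    }
    if (length(andro_ids) > 0L) {
      sel <- g$sample_id %in% andro_ids
      g[sel, `:=`(m1 = NA_real_, m2 = NA_real_, extra = p1,
                  extra_origin = "paternal", nd = FALSE)]
    }
    # repeat slippage: one copy at one locus shifts by 1-2 motifs
    slip_ids <- ids[stats::runif(n) < params$slippage_rate]
    g[, slipped := FALSE]
    for (sid in slip_ids) {
      row <- which(g$sample_id == sid)[sample.int(M, 1L)]
      copies <- c("m1", "m2", "p1", "extra")
      avail <- copies[!is.na(unlist(g[row, c("m1", "m2", "p1", "extra"),
                                      with = FALSE]))]
      if (length(avail) == 0L) next
      cp <- sample(avail, 1L)
      step <- sample(c(1L, 2L), 1L, prob = c(1 - params$slippage_two_step_prob,
                                             params$slippage_two_step_prob))
      delta <- sample(c(-1, 1), 1L) * step * g$motif[row]
      data.table::set(g, row, cp, g[[cp]][row] + delta)
      data.table::set(g, row, "slipped", TRUE)
    }

    g[, n_copies := (!is.na(m1)) + (!is.na(m2)) + (!is.na(p1)) + (!is.na(extra))]
    ind <- g[, .(n_loci = .N,
                 n_trisomic_true = sum(n_copies == 3L),
                 n_disomic_true = sum(n_copies == 2L),
                 has_slippage = any(slipped)),
             by = sample_id]
    ret_vec <- retention
    ind[, retention := ret_vec[match(sample_id, ids)]]
    ind[, is_upd := sample_id %in% upd_ids]
    ind[, is_androgenesis := sample_id %in% andro_ids]
    ind[, true_ploidy_class := data.table::fcase(
      n_trisomic_true == 0L, "diploid",
      n_disomic_true == 0L, "triploid",
      default = "aneuploid")]
    ind[, deviant_loci := pmin(n_trisomic_true, n_disomic_true)]
    ind[, viability_category := data.table::fcase(
      is_androgenesis, "androgenesis",
      is_upd, "maternal_loss",
      true_ploidy_class != "aneuploid", "baseline",
      deviant_loci == 1L, "single_locus",
      default = "intermediate")]
    ind[, `:=`(family_id = family_id, treatment_psi = psi)]

    long <- data.table::rbindlist(list(
      g[!is.na(m1), .(sample_id, marker_id, allele = m1, origin = "maternal",
                      slipped)],
      g[!is.na(m2), .(sample_id, marker_id, allele = m2, origin = "maternal",
                      slipped)],
      g[!is.na(p1), .(sample_id, marker_id, allele = p1, origin = "paternal",
                      slipped)],
      g[!is.na(extra), .(sample_id, marker_id, allele = extra,
                         origin = extra_origin, slipped)]))
    data.table::setorder(long, sample_id, marker_id, allele)
    list(individuals = as.data.frame(ind), truth = as.data.frame(long))
  })
}

#' Synthesise electropherogram peaks from latent allele copies
#'
#' The generative inverse of dosage classification: identical alleles merge
#' their copies into one peak whose height is `base_height * copy_number *
#' lognormal(0, sdlog)`; each peak spawns a stutter peak one motif below at
#' the stutter fraction (merged into a real allele peak when positions
#' coincide); whole loci drop out with the dropout probability.
#'
#' @param truth long contribution table from [simulate_offspring()].
#' @param params a [sim_params()].
#' @param seed integer seed.
#' @return A `peak_table` data frame.
#' @export
synthesize_peaks <- function(truth, params = sim_params(), seed = 1) {
  dt <- data.table::as.data.table(truth)
  panel <- params$panel
  with_substream(seed, "peaks", {
    pk <- dt[, .(copies = .N), by = .(sample_id, marker_id, allele)]
    pk[, height := params$base_height * copies *
         exp(stats::rnorm(.N, 0, params$height_sdlog))]
    if (params$stutter_fraction > 0) {
      st <- pk[, .(sample_id, marker_id,
                   allele = allele -
                     panel$repeat_motif_bp[match(marker_id, panel$marker_id)],
                   height = height * params$stutter_fraction *
                     exp(stats::rnorm(.N, 0, params$height_sdlog)))]
      pk <- data.table::rbindlist(list(pk[, .(sample_id, marker_id, allele, height)],
                                       st))
    } else {
      pk <- pk[, .(sample_id, marker_id, allele, height)]
    }
    pk <- pk[, .(height_rfu = sum(height)), by = .(sample_id, marker_id, allele)]
    if (params$dropout_rate > 0) {
      loci <- unique(pk[, .(sample_id, marker_id)])
      loci[, drop := stats::runif(.N) < params$dropout_rate]
      pk <- loci[pk, on = c("sample_id", "marker_id")][drop == FALSE]
    }
    out <- as.data.frame(pk[, .(sample_id, marker_id,
                                allele_size_bp = allele, height_rfu)])
    out <- out[order(out$sample_id, out$marker_id, out$allele_size_bp), ]
    rownames(out) <- NULL
    class(out) <- c("peak_table", "data.frame")
    out
  })
}

#' Viability selection between the eyed-egg and parr stages
#'
#' Each individual survives with the probability of its latent viability
#' category (diploids/triploids at baseline; single-locus deviants mildly
#' reduced; intermediate aneuploids, maternal-DNA-loss and androgenetic
#' individuals strongly reduced). Deaths are split between the eyed-egg to
#' start-feed interval (where mortality peaks) and start-feed to parr.
#'
#' @param individuals latent individual table from [simulate_offspring()].
#' @param params a [sim_params()].
#' @param seed integer seed.
#' @return list with `survivors` (individuals, stage set to `parr`),
#'   `deaths`, and `mortality` (interval counts for the unit).
#' @export
apply_viability_selection <- function(individuals, params = sim_params(),
                                      seed = 1) {
  v <- params$viability
  ind <- as.data.frame(individuals)
  pr <- unname(unlist(v[ind$viability_category]))
  with_substream(seed, "viability", {
    alive <- stats::runif(nrow(ind)) < pr
    died_early <- !alive & (stats::runif(nrow(ind)) < v$w_startfeed)
    survivors <- ind[alive, , drop = FALSE]
    survivors$stage <- "parr"
    deaths <- ind[!alive, , drop = FALSE]
    n0 <- nrow(ind)
    n_early <- sum(died_early)
    n_late <- sum(!alive) - n_early
    mortality <- data.frame(
      interval = c("eyed_egg_to_start_feed", "start_feed_to_parr"),
      n_start = c(n0, n0 - n_early),
      n_dead = c(n_early, n_late), stringsAsFactors = FALSE)
    list(survivors = survivors, deaths = deaths, mortality = mortality)
  })
}

#' Build a complete synthetic study
#'
#' Reproduces the sampling ledger of the two experimental designs.
#' `experiment_1`: 3 families x 5 pressure treatments x 2 replicates, 15
#' eyed eggs sampled per family-treatment-replicate (450 eggs) and 100
#' reared per family-treatment-replicate (3000 individuals).
#' `experiment_2`: 12 families x 2 treatments (0 / 9500 PSI), 20 eggs
#' sampled per family-treatment unit (480 eggs) and 100 reared per
#' family-treatment (2400 juveniles). Genotype peaks are synthesised for
#' all sampled eggs and all surviving parr; mortality counts cover the
#' three stage intervals per unit.
#'
#' @param design `"experiment_1"` or `"experiment_2"`.
#' @param params a [sim_params()].
#' @param seed single integer seed; all stages derive substreams from it.
#' @return A `sim_cohort` list: `parents`, `individuals` (latent truth,
#'   with stage and viability outcome), `truth` (per-copy contributions),
#'   `peaks` (for genotyped individuals), `meta`, `mortality`, `ledger`,
#'   `params`, `design`, `seed`.
#' @export
build_study <- function(design = c("experiment_1", "experiment_2"),
                        params = sim_params(), seed = 1) {
  design <- match.arg(design)
  parents <- simulate_parents(params, seed)
  wide <- data.table::as.data.table(parents$wide)
  fm <- parents$family_map
  if (design == "experiment_1") {
    families <- fm$family_id[1:3]
    treatments <- c(0, 6500, 7500, 8500, 9500)
    replicates <- c("a", "b")
    n_sample <- 15L; n_rear <- 100L; n_initial <- 250L
    experiment <- 1L
  } else {
    families <- fm$family_id[1:12]
    treatments <- c(0, 9500)
    replicates <- ""
    n_sample <- 20L; n_rear <- 100L; n_initial <- 350L
    experiment <- 2L
  }
  units <- expand.grid(family_id = families, treatment_psi = treatments,
                       replicate = replicates, stringsAsFactors = FALSE)
  units <- units[order(units$family_id, units$treatment_psi, units$replicate), ]
  sire_w <- wide[sample_id == "SIRE1"]
  ind_list <- list(); truth_list <- list(); mort_list <- list()
  for (i in seq_len(nrow(units))) {
    u <- units[i, ]
    unit_tag <- paste0(u$family_id, "_", u$treatment_psi,
                       if (nzchar(u$replicate)) paste0("_", u$replicate) else "")
    dam_id <- fm$dam_id[fm$family_id == u$family_id]
    dam_w <- wide[sample_id == dam_id]
    sim <- simulate_offspring(dam_w, sire_w, u$treatment_psi, params,
                              seed = substream(seed, paste0("unit_", unit_tag)),
                              n = n_sample + n_rear, family_id = u$family_id,
                              id_prefix = paste0("E", experiment, "_", unit_tag, "_"))
    ind <- sim$individuals
    ind$replicate_id <- if (nzchar(u$replicate))
      paste0(u$treatment_psi, u$replicate) else NA_character_
    ind$unit_id <- unit_tag
    ind$cohort_role <- c(rep("sampled_egg", n_sample), rep("reared", n_rear))
    ind$stage <- ifelse(ind$cohort_role == "sampled_egg", "egg", "reared")
    reared <- ind[ind$cohort_role == "reared", , drop = FALSE]
    vs <- apply_viability_selection(reared, params,
                                    seed = substream(seed, paste0("via_", unit_tag)))
    ind$stage[ind$sample_id %in% vs$survivors$sample_id] <- "parr"
    ind$survived <- ind$stage %in% c("egg", "parr")
    # fertilization -> eyed egg mortality: treatment-dependent base rate on
    # the nominal initial egg number, recorded for the ledger only
    em <- params$egg_mort_base + params$egg_mort_max *
      stats::plogis((u$treatment_psi - params$egg_mort_mid) / params$egg_mort_scale)
    n_dead_egg <- with_substream(seed, paste0("eggmort_", unit_tag),
                                 stats::rbinom(1, n_initial, em))
    mort <- rbind(
      data.frame(interval = "fertilization_to_eyed_egg", n_start = n_initial,
                 n_dead = n_dead_egg, stringsAsFactors = FALSE),
      vs$mortality)
    mort$unit_id <- unit_tag
    mort$family_id <- u$family_id
    mort$treatment_psi <- u$treatment_psi
    ind_list[[i]] <- ind
    truth_list[[i]] <- sim$truth
    mort_list[[i]] <- mort
  }
  individuals <- do.call(rbind, ind_list)
  truth <- do.call(rbind, truth_list)
  mortality <- do.call(rbind, mort_list)
  genotyped <- individuals$sample_id[individuals$stage %in% c("egg", "parr")]
  truth_dt <- data.table::as.data.table(truth)
  peaks <- synthesize_peaks(truth_dt[sample_id %in% genotyped], params,
                            seed = substream(seed, "study_peaks"))
  meta_off <- data.frame(
    sample_id = individuals$sample_id,
    experiment = experiment,
    stage = ifelse(individuals$stage == "reared", "egg", individuals$stage),
    treatment_psi = individuals$treatment_psi,
    family_id = individuals$family_id,
    replicate_id = individuals$replicate_id,
    role = "offspring", stringsAsFactors = FALSE)
  meta_off <- meta_off[meta_off$sample_id %in% genotyped, , drop = FALSE]
  meta_par <- data.frame(
    sample_id = unique(c(fm$sire_id, fm$dam_id)),
    experiment = experiment, stage = "parent", treatment_psi = NA_real_,
    family_id = NA_character_, replicate_id = NA_character_,
    role = NA_character_, stringsAsFactors = FALSE)
  meta_par$role <- ifelse(grepl("^SIRE", meta_par$sample_id), "sire", "dam")
  ledger <- data.frame(
    design = design,
    n_units = nrow(units),
    n_sampled_eggs = sum(individuals$cohort_role == "sampled_egg"),
    n_reared = sum(individuals$cohort_role == "reared"),
    n_surviving_parr = sum(individuals$stage == "parr"),
    n_genotyped = length(genotyped), stringsAsFactors = FALSE)
  structure(list(parents = parents, individuals = individuals, truth = truth,
                 peaks = peaks, meta = rbind(meta_off, meta_par),
                 mortality = mortality, ledger = ledger, params = params,
                 design = design, seed = seed),
            class = "sim_cohort")
}
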