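# Shared fixtures: built in code at test time, cached across test files.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, builder(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# full default Experiment 1 synthetic study + pipeline result (heavy; built
# once and reused by the synthetic, pipeline and acceptance tests)
exp1_pipeline <- function() cached("exp1_pipeline", function() {
  run_pipeline(run_config(design = "experiment_1", seed = 20240101))
})

tiny_panel <- function() {
  marker_panel(c("Ssa197", "SsaF43"), c(4L, 4L), c(100, 180), c(180, 260))
}

write_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# noise-free peaks for a configuration: heights exactly proportional to copies
exact_peaks <- function(alleles, copies, base = 1000) {
  data.frame(sample_id = "S1", marker_id = "Ssa197",
             allele_size_bp = alleles, height_rfu = base * copies,
             stringsAsFactors = FALSE)
}

# --- independent oracles (plain nested-loop implementations) ---

# brute-force offspring/parent compatibility by gamete enumeration
oracle_compatible <- function(off_multiset, dam, sire, ploidy) {
  d <- if (length(dam) == 1L) rep(dam, 2) else dam
  s <- if (length(sire) == 1L) rep(sire, 2) else sire
  key <- paste(sort(off_multiset), collapse = "/")
  if (ploidy == 2L) {
    for (i in 1:2) for (j in 1:2)
      if (paste(sort(c(d[i], s[j])), collapse = "/") == key) return(TRUE)
  } else {
    for (i in 1:2) for (j in 1:2) for (k in 1:2)
      if (paste(sort(c(d[i], d[j], s[k])), collapse = "/") == key) return(TRUE)
  }
  FALSE
}

# brute-force extra-allele origin for a trisomic multiset
oracle_origin <- function(off_multiset, dam, sire) {
  d <- if (length(dam) == 1L) rep(dam, 2) else dam
  s <- if (length(sire) == 1L) rep(sire, 2) else sire
  key <- paste(sort(off_multiset), collapse = "/")
  mat <- FALSE; pat <- FALSE
  for (i in 1:2) for (j in 1:2) for (k in 1:2) {
    if (paste(sort(c(d[i], d[j], s[k])), collapse = "/") == key) mat <- TRUE
    if (paste(sort(c(d[i], s[j], s[k])), collapse = "/") == key) pat <- TRUE
  }
  if (mat && pat) "ambiguous" else if (mat) "maternal" else if (pat) "paternal"
  else "unexplained"
}
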