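# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

tc_stop <- function(class, fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "tripcheck_error", "error")))
}

#' @keywords internal
split_num_field <- function(x, sep = ";") {
  lapply(strsplit(as.character(x), sep, fixed = TRUE), function(v) {
    v <- trimws(v)
    v <- v[nzchar(v)]
    if (length(v) == 0L || all(v %in% c("-", "NA", "."))) return(numeric(0))
    suppressWarnings(as.numeric(v))
  })
}

join_num_field <- function(x, sep = ";") {
  vapply(x, function(v) {
    if (length(v) == 0L || all(is.na(v))) "-" else paste(format(v, trim = TRUE, scientific = FALSE), collapse = sep)
  }, character(1))
}

# deterministic sub-seed for a named stage, kept within 32-bit integer range
substream <- function(seed, key) {
  h <- sum(utf8ToInt(key) * seq_along(utf8ToInt(key)))
  as.integer((as.numeric(seed) %% 1e6 * 1009 + h * 97) %% 2147483629 + 1)
}

with_substream <- function(seed, key, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(substream(seed, key))
  force(expr)
}

# sorted multiset key for allele vectors, used for compatibility memoisation
allele_key <- function(alleles) paste(sort(round(as.numeric(alleles), 3)), collapse = "/")
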