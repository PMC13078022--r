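# Internal helpers shared across modules.

# Deterministic 31-bit hash of a string, used to derive independent RNG
# substreams from (master seed, label) so per-pair results do not depend on
# iteration order. Exact doubles: intermediate values stay < 2^53.
hash31 <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  h <- 0
  for (code in utf8ToInt(x)) {
    h <- (h * 131 + code) %% 2147483647
  }
  h
}

# Seed for a named substream of a master seed (always a valid 32-bit int).
derive_seed <- function(master_seed, label) {
  as.integer((as.double(master_seed) %% 2147483647 + hash31(label)) %% 2147483647)
}

# Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
# RNG stream is left untouched.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# sample() treats a length-1 numeric as 1:n; this never does.
sample1 <- function(x) x[sample.int(length(x), 1)]

# Canonical variant identifier chrom:pos:ref:alt.
make_variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

# Canonical (sorted) biopsy pair.
canonical_pair <- function(a, b) {
  swap <- a > b
  tibble(
    biopsy_a = ifelse(swap, b, a),
    biopsy_b = ifelse(swap, a, b)
  )
}

assert_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s is missing required column%s: %s",
      what, if (length(missing) > 1) "s" else "", paste(missing, collapse = ", ")
    ), class = "mfclone_format_error")
  }
  invisible(df)
}

validation_error <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "mfclone_validation_error")
}

format_error <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "mfclone_format_error")
}
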