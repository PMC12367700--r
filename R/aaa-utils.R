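# Internal helpers shared across modules.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Derive a reproducible child seed from a parent seed and a stream label.
# Keeps independent stages decoupled: adding accessions or stages does not
# perturb draws made by earlier ones.  Result stays below 2^31.
derive_seed <- function(seed, ...) {
  label <- paste(c(seed, ...), collapse = "/")
  bytes <- utf8ToInt(label)
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483629
  as.integer(h)
}

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's RNG afterwards.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

assert_count <- function(x, name, min = 0) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != floor(x)) {
    abort(sprintf("`%s` must be a single integer >= %d", name, min))
  }
  invisible(as.integer(x))
}

assert_fraction <- function(x, name, lo = 0, hi = 1) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < lo || x > hi) {
    abort(sprintf("`%s` must be a single number in [%g, %g]", name, lo, hi))
  }
  invisible(as.numeric(x))
}

# Split a sequence string into single characters.
chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# Split a CDS into codons (length must be a multiple of 3).
codon_split <- function(cds) {
  n <- nchar(cds)
  if (n %% 3L != 0L) abort("CDS length is not a multiple of 3")
  substring(cds, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
}
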