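# Internal helpers: seed derivation and scoped RNG.

# Stable 31-bit seed derived from a master seed and any string tokens
# (FNV-1a over the concatenated tokens). One master seed reproducibly fans
# out to per-module, per-case seeds without correlated streams.
deriveSeed <- function(master, ...) {
  tokens <- paste(c(format(master, scientific = FALSE), ...), collapse = "/")
  bytes <- utf8ToInt(tokens)
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  as.integer(h) + 1L
}

# Evaluate expr with a local RNG state; the caller's stream is untouched.
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# voxel volume in mL
voxelVolumeML <- function(spacing) prod(spacing) / 1000
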