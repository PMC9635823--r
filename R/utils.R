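`%||%` <- function(x, y) if (is.null(x)) y else x

# Run code under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards. seed = NULL runs in the ambient stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Derive a stream-specific child seed from a base seed, staying inside the
# 32-bit integer range.
child_seed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 48271 + 1111 * stream) %% 2147483647L)
}

stop_pk <- function(...) abort(paste0(...), class = "paleokin_error")

is_x_chrom <- function(chrom) chrom %in% c("X", "23", "chrX")
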