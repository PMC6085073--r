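# Internal helpers shared across modules.

# Run code with a private RNG state so simulators are deterministic given
# their seed without clobbering the caller's stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

# i0: 0-based integers -> fixed-length DNA strings (base-4 expansion).
umi_strings <- function(i0, len) {
  bases <- c("A", "C", "G", "T")
  cols <- lapply(seq_len(len), function(k) {
    bases[((i0 %/% 4^(len - k)) %% 4) + 1L]
  })
  do.call(paste0, cols)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
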