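## run expr with a private, seeded RNG stream, restoring the caller's state
.withSeed <- function(seed, expr) {
  if (missing(seed) || is.null(seed)) stop("an explicit integer seed is required")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## the 20 standard amino-acid one-letter codes (default symbol universe)
.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
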