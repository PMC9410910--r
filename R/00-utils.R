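#' @importFrom stats rbinom rnbinom rpois runif rnorm aov anova lm pf
#'   TukeyHSD binom.test fisher.test t.test quantile sd setNames
#' @importFrom utils write.table read.table head
#' @import data.table
NULL

BASES <- c("A", "C", "G", "T")
COMP <- c(A = "T", C = "G", G = "C", T = "A")

## Six pyrimidine-collapsed substitution classes, COSMIC order.
PYR_CLASSES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

## Twelve strand-resolved classes (reference-strand ref>alt).
STRAND_CLASSES <- c(
  "A>C", "A>G", "A>T", "C>A", "C>G", "C>T",
  "G>A", "G>C", "G>T", "T>A", "T>C", "T>G"
)

#' The 96 trinucleotide mutation channels in COSMIC order
#'
#' Channels are labelled `"A[C>A]A"` style: substitution class on the
#' pyrimidine strand with its 5' and 3' flanking bases.
#'
#' @return Character vector of length 96.
#' @export
trinuc_channels <- function() {
  out <- character(0)
  for (cl in PYR_CLASSES) {
    for (f5 in BASES) {
      for (f3 in BASES) {
        out <- c(out, paste0(f5, "[", cl, "]", f3))
      }
    }
  }
  out
}

#' Reverse complement of a DNA string
#' @param x character vector of DNA strings over ACGTN.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    ch <- rev(strsplit(s, "", fixed = TRUE)[[1]])
    comp <- c(COMP, N = "N")[ch]
    paste0(comp, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

## Run code under a temporary RNG state; restores the caller's stream.
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Derive a reproducible child seed from a parent seed
#'
#' One global seed expands to per-stage child seeds by a fixed counter
#' scheme so pipeline stages can be rerun in isolation. Results stay in
#' the 32-bit signed integer range.
#'
#' @param seed integer parent seed.
#' @param k integer stage counter (>= 0).
#' @return integer child seed.
#' @export
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 1009 * as.numeric(k)) %% 2147483629L)
}

## positions are 0-based throughout the package internals
stopifnot_scalar <- function(x, name) {
  if (length(x) != 1L || is.na(x)) stop(sprintf("'%s' must be a scalar", name))
}
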