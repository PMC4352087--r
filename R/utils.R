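## Internal helpers shared across modules.
##
## Coordinate convention: 0-based, half-open [start, end) everywhere in
## internal arithmetic; 1-based fully-closed only where a format demands it
## (SAM POS, FASTA subsetting through Biostrings) or in printed reports.

#' @import methods
#' @importFrom stats median rnorm rpois runif setNames aggregate
#' @importFrom utils write.table head tail
#' @importClassesFrom Biostrings DNAStringSet
NULL

## subsequence of a DNAString by 0-based half-open interval
.subseq0 <- function(x, start, end) {
  Biostrings::subseq(x, start = start + 1L, end = end)
}

.as_chr0 <- function(x, start, end) as.character(.subseq0(x, start, end))

## deterministic child seed for a named sub-stream, kept below 2^31
.childSeed <- function(seed, stream) {
  stopifnot(length(stream) == 1L)
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  (as.integer(seed) * 1103L + as.integer(h %% 104729)) %% 2147483647L
}

## run `expr` under a temporary RNG state seeded with `seed`
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## random ACGT string of length n (uses current RNG stream)
.randomDna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## gel-style display size: bp -> kb, truncated to 0.1 kb (a 7483 bp fragment
## runs as a "7.4 kb" band)
.displayKb <- function(bp) floor(bp / 100) / 10

## reverse complement of a character vector of DNA strings
.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## all 0-based start positions of exact occurrences of `pattern` in `subject`
## (DNAString); plus-strand only
.matchStarts0 <- function(pattern, subject) {
  Biostrings::start(Biostrings::matchPattern(pattern, subject)) - 1L
}

## number of mismatches between two equal-length character DNA strings
.nMismatch <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  if (nchar(a) == 0L) return(0L)
  sum(utf8ToInt(a) != utf8ToInt(b))
}

## stop() with a stage tag, used by the pipeline for stage-attributable errors
.stageStop <- function(stage, ...) {
  stop(sprintf("[%s] %s", stage, paste0(...)), call. = FALSE)
}
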