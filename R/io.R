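#' @include simulate.R
NULL

#' Write the parent reference as FASTA
#' @param model a \linkS4class{LocusModel}.
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeParentFasta <- function(model, path) {
  Biostrings::writeXStringSet(parentSeqs(model), path)
  invisible(path)
}

#' Write simulated reads as a paired FASTQ file pair
#'
#' Files are named \code{<prefix>_1.fastq} / \code{<prefix>_2.fastq} with
#' the conventional \code{/1} and \code{/2} read-name suffixes and constant
#' base quality (quality modeling is out of scope of the simulator).
#'
#' @param sim result of [simulateReads()].
#' @param dir output directory (created if needed).
#' @param prefix file prefix; defaults to the sample label.
#' @return character(2) of the file paths, invisibly.
#' @export
writeSimFastq <- function(sim, dir, prefix = sim$sample) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(prefix, "_", 1:2, ".fastq"))
  for (m in 1:2) {
    reads <- sim[[paste0("reads", m)]]
    names(reads) <- paste0(names(reads), "/", m)
    qual <- Biostrings::BStringSet(rep(strrep("I", sim$readLen),
                                       length(reads)))
    Biostrings::writeXStringSet(reads, paths[m], format = "fastq",
                                qualities = qual)
  }
  invisible(paths)
}

#' Write truth alignments as SAM-like text
#'
#' Emits a valid minimal SAM file (header plus 11 mandatory columns) against
#' the parent reference, with CIGAR strings restricted to M and S
#' operations. Records are coordinate-sorted.
#'
#' @param sim result of [simulateReads()].
#' @param model the \linkS4class{LocusModel} (for the header).
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeSimSam <- function(sim, model, path) {
  a <- sim$alignments
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(parentSeqs(model)),
                   Biostrings::width(parentSeqs(model))))
  o <- order(a$chrom, a$pos)
  a <- a[o, , drop = FALSE]
  flag <- 1L + 2L + 16L * (a$strand == "-") + 32L * (a$mateStrand == "-") +
    64L * (a$mate == 1L) + 128L * (a$mate == 2L)
  rec <- paste(a$qname, flag, a$chrom, a$pos + 1L, 60L, a$cigar,
               ifelse(a$mateChrom == a$chrom, "=", a$mateChrom),
               a$matePos + 1L, 0L, a$seq, strrep("I", nchar(a$seq)),
               sep = "\t")
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' Read SAM-like alignments into the package's alignment table
#'
#' Parses a SAM text file (only M/S CIGAR operations are meaningful to the
#' downstream stages; others are rejected) into the data.frame layout
#' produced by [simulateReads()].
#'
#' @param path SAM file.
#' @param sample sample label to record.
#' @return alignment data.frame (0-based \code{pos}).
#' @export
readSamLike <- function(path, sample = "sample") {
  ln <- readLines(path)
  ln <- ln[!startsWith(ln, "@")]
  if (!length(ln))
    return(data.frame(qname = character(), sample = character(),
                      chrom = character(), pos = integer(),
                      strand = character(), cigar = character(),
                      seq = character()))
  f <- strsplit(ln, "\t", fixed = TRUE)
  get <- function(i) vapply(f, `[[`, "", i)
  cigar <- get(6)
  if (any(grepl("[^0-9MS]", cigar)))
    stop("only M and S CIGAR operations are supported")
  flag <- as.integer(get(2))
  data.frame(qname = get(1), sample = sample, chrom = get(3),
             pos = as.integer(get(4)) - 1L,
             strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
             cigar = cigar, seq = get(10), stringsAsFactors = FALSE)
}

#' Write scenario truth as JSON
#'
#' Records the scenario parameters, the true junction coordinates and
#' per-molecule copy weights -- the ground truth a benchmark compares
#' detector output against.
#'
#' @param build a \linkS4class{GenomeBuild}.
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeTruthJson <- function(build, path) {
  sc <- build@scenario; m <- build@model
  truth <- list(
    scenario = list(copiesPerAllele = sc@copiesPerAllele,
                    episomeCount = sc@episomeCount,
                    aneuploidy = as.list(sc@aneuploidy),
                    rdnaFactor = sc@rdnaFactor, seed = sc@seed),
    junction = list(chrom = m@unitChrom, leftBp = m@unitStart,
                    rightBp = m@unitEnd, unitLength = unitLength(m)),
    molecules = data.frame(name = names(build@seqs),
                           length = Biostrings::width(build@seqs),
                           weight = build@weights,
                           circular = build@circular))
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write model feature annotations as BED
#' @param model a \linkS4class{LocusModel}.
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeFeatureBed <- function(model, path) {
  gr <- featureRanges(model)
  gr$name <- names(gr)
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Write a log-ratio track as bedGraph
#' @param track a \linkS4class{LogRatioTrack}.
#' @param path output file.
#' @param what \code{"log2"} (raw) or \code{"smoothed"}.
#' @return the path, invisibly.
#' @export
writeBedGraph <- function(track, path, what = c("log2", "smoothed")) {
  what <- match.arg(what)
  w <- track@windows
  keep <- !w$masked & !is.na(w[[what]])
  gr <- GenomicRanges::GRanges(w$chrom[keep],
                               IRanges::IRanges(w$start[keep] + 1L,
                                                w$end[keep]),
                               score = w[[what]][keep])
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Write a junction call as a BEDPE line
#' @param call a \linkS4class{JunctionCall}.
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeJunctionBedpe <- function(call, path) {
  writeLines(paste(call@chrom, call@rightBp, call@rightBp + 1L,
                   call@chrom, call@leftBp, call@leftBp + 1L,
                   "junction", call@supportLeft + call@supportRight,
                   "+", "+", sep = "\t"), path)
  invisible(path)
}
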