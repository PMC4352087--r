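#' @include AllClasses.R
NULL

#' Create a scenario specification
#'
#' @param copiesPerAllele integer(2): tandem copies of the amplifiable unit
#'   on each homolog of the locus chromosome (1,1 = parental single copy;
#'   0 = clean deletion allele, used as a negative control).
#' @param episomeCount mean circular episomes per cell; real-valued because a
#'   culture is a population (a mixed culture can average e.g. 2.5 copies).
#' @param aneuploidy named vector of chromosome copy counts; chromosomes not
#'   named are disomic.
#' @param rdnaFactor multiplicative copy factor for the rDNA proxy region
#'   (0.5 emulates loss of half the repeat copies).
#' @param seed integer seed used by default when simulating reads from this
#'   scenario.
#' @return a \linkS4class{ScenarioSpec}.
#' @examples
#' ScenarioSpec(copiesPerAllele = c(9, 9), aneuploidy = c(chrT = 3),
#'              rdnaFactor = 0.5)
#' @export
ScenarioSpec <- function(copiesPerAllele = c(1L, 1L), episomeCount = 0,
                         aneuploidy = numeric(), rdnaFactor = 1, seed = 1L) {
  new("ScenarioSpec", copiesPerAllele = as.integer(copiesPerAllele),
      episomeCount = as.numeric(episomeCount),
      aneuploidy = aneuploidy, rdnaFactor = as.numeric(rdnaFactor),
      seed = as.integer(seed))
}

#' Named scenario presets
#'
#' Archetypes of the strains whose locus topology the package discriminates:
#' \describe{
#'   \item{parent}{single copy per allele, no episome (the unevolved recombinant).}
#'   \item{deletion}{one allele deleted, one single copy (negative control).}
#'   \item{episome}{both chromosomal alleles single copy plus a
#'     self-replicating circular episome (an early-adaptation isolate
#'     that carries the amplification only as eccDNA).}
#'   \item{circle_plus_single}{an episome alongside one deleted and one
#'     intact single-copy allele.}
#'   \item{tandem_one}{tandem array in one allele, single copy in the other
#'     (a mid-adaptation isolate).}
#'   \item{tandem_both}{nine tandem copies in both alleles, trisomy of the
#'     aneuploidy-target chromosome and a halved rDNA proxy
#'     (the fully evolved strain).}
#' }
#'
#' @param name preset name (see Details).
#' @param seed seed recorded in the spec.
#' @return a \linkS4class{ScenarioSpec}.
#' @examples
#' scenarioPreset("tandem_both")
#' @export
scenarioPreset <- function(name = c("parent", "deletion", "episome",
                                    "circle_plus_single", "tandem_one",
                                    "tandem_both"),
                           seed = 1L) {
  switch(match.arg(name),
    parent = ScenarioSpec(c(1L, 1L), seed = seed),
    deletion = ScenarioSpec(c(0L, 1L), seed = seed),
    episome = ScenarioSpec(c(1L, 1L), episomeCount = 5, seed = seed),
    circle_plus_single = ScenarioSpec(c(1L, 0L), episomeCount = 5,
                                      seed = seed),
    tandem_one = ScenarioSpec(c(5L, 1L), seed = seed),
    tandem_both = ScenarioSpec(c(9L, 9L), aneuploidy = c(chrT = 3),
                               rdnaFactor = 0.5, seed = seed))
}

#' Realize a scenario as a sample genome
#'
#' Builds the sample molecules declared by a \linkS4class{ScenarioSpec} from
#' the parent reference of a \linkS4class{LocusModel}, together with the
#' piecewise coordinate map back to the parent. Tandem arrays are exact
#' head-to-tail repeats of the unit: because the junction-side 8 bp
#' microhomology motif ends exactly at the 3' unit boundary, the motif copy
#' abutting each junction is shared between consecutive units (no bases are
#' inserted or duplicated at the join), so an n-copy allele is exactly
#' \code{n * unitLength} bp longer than a deletion allele. Episomes are
#' circular molecules of exactly one unit length with copy weight
#' \code{episomeCount}. The rDNA proxy is realized as a sampling-weight
#' region rather than literal repeats: depth is the signal the downstream
#' analysis consumes.
#'
#' The identity scenario (1 copy per allele, no episome, all-disomic,
#' rdnaFactor 1) reproduces the parent genome byte-identically.
#'
#' @param model a \linkS4class{LocusModel}.
#' @param spec a \linkS4class{ScenarioSpec}.
#' @return a validated \linkS4class{GenomeBuild}.
#' @examples
#' model <- buildLocusModel(chromLength = 40000, unitLength = 3000,
#'                          boundaryFragment = 2000, hindToEnd = 1200,
#'                          outsideFragment = 5000, p3Product = 4500,
#'                          auxChromLength = 0, rdnaChromLength = 0)
#' build <- applyScenario(model, scenarioPreset("episome"))
#' molecules(build)
#' @export
applyScenario <- function(model, spec) {
  stopifnot(is(model, "LocusModel"), is(spec, "ScenarioSpec"))
  validObject(spec)
  u5 <- model@unitStart; u3 <- model@unitEnd; U <- unitLength(model)
  chrA <- model@parentSeqs[[model@unitChrom]]
  unitSeq <- .as_chr0(chrA, u5, u3)
  flankL <- .as_chr0(chrA, 0L, u5)
  flankR <- .as_chr0(chrA, u3, length(chrA))

  seqs <- character(); circ <- logical(); wt <- numeric()
  rw <- list(); cm <- list()
  ploidy <- function(chrom) {
    p <- spec@aneuploidy[chrom]
    if (is.na(p)) 2 else as.numeric(p)
  }
  addBlock <- function(mol, start, end, chrom, parentStart) {
    cm[[length(cm) + 1L]] <<- data.frame(
      molecule = mol, start = start, end = end, chrom = chrom,
      parentStart = parentStart, strand = "+", stringsAsFactors = FALSE)
  }

  for (chrom in names(model@parentSeqs)) {
    if (chrom == model@unitChrom) {
      pl <- ploidy(chrom)
      for (a in 1:2) {
        n <- spec@copiesPerAllele[a]
        mol <- sprintf("%s_allele%d", chrom, a)
        seqs[mol] <- paste0(flankL, strrep(unitSeq, n), flankR)
        circ[mol] <- FALSE; wt[mol] <- pl / 2
        rw[[mol]] <- data.frame(start = integer(), end = integer(),
                                weight = numeric())
        addBlock(mol, 0L, u5, chrom, 0L)
        if (n > 0L) for (k in seq_len(n))
          addBlock(mol, u5 + (k - 1L) * U, u5 + k * U, chrom, u5)
        addBlock(mol, u5 + n * U, u5 + n * U + (length(chrA) - u3), chrom, u3)
      }
    } else {
      seqs[chrom] <- as.character(model@parentSeqs[[chrom]])
      circ[chrom] <- FALSE; wt[chrom] <- ploidy(chrom)
      rw[[chrom]] <-
        if (length(model@rdnaChrom) && chrom == model@rdnaChrom &&
            spec@rdnaFactor != 1)
          data.frame(start = model@rdnaStart, end = model@rdnaEnd,
                     weight = spec@rdnaFactor)
        else data.frame(start = integer(), end = integer(),
                        weight = numeric())
      addBlock(chrom, 0L, nchar(seqs[chrom]), chrom, 0L)
    }
  }
  if (spec@episomeCount > 0) {
    seqs["episome"] <- unitSeq
    circ["episome"] <- TRUE; wt["episome"] <- spec@episomeCount
    rw[["episome"]] <- data.frame(start = integer(), end = integer(),
                                  weight = numeric())
    addBlock("episome", 0L, U, model@unitChrom, u5)
  }

  new("GenomeBuild", model = model, scenario = spec,
      seqs = Biostrings::DNAStringSet(seqs), circular = unname(circ),
      weights = unname(wt), regionWeights = rw,
      coordMap = do.call(rbind, cm))
}
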