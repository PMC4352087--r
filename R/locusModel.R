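#' @include AllGenerics.R
NULL

## Recognition sequences of the two modeled enzymes. "hindIII-like" cuts once
## inside the unit (A^AGCTT); "sacII-like" cuts only outside it (CCGC^GG).
.HIND_REC <- "AAGCTT"; .HIND_CUT <- 1L
.SAC_REC <- "CCGCGG"; .SAC_CUT <- 4L

## Planted boundary microhomologies: the 8 bp junction-side motif ends
## exactly at the 3' unit boundary and recurs 21 bp downstream of the 5'
## boundary; the 7 bp motif flanks the unit at -14 / +15 (motif start
## relative to the respective boundary).
.MH_JUNCTION <- "GGAAAGGG"
.MH_FLANK <- "TATGATG"

#' Build a parameterized locus model on a toy parent reference
#'
#' Constructs the parent genome used by every other stage: a locus chromosome
#' (\code{chrA}) carrying one copy of the amplifiable unit with all geometry
#' planted (microhomology motifs, a single intra-unit "hindIII-like" cutter
#' plus external sites, flanking "sacII-like" outside-cutter sites, three
#' primer sets and two Southern probes), an optional aneuploidy-target
#' chromosome (\code{chrT}) and an optional chromosome (\code{chrR}) carrying
#' a 20 kb tandem-repeat proxy region whose sampled depth can be scaled.
#'
#' The background is i.i.d. uniform ACGT from a seeded generator, then
#' deterministically patched so that the model invariants hold by
#' construction: no spurious enzyme-recognition, primer-site or probe
#' occurrences on the locus chromosome, no spurious motif occurrences within
#' 100 bp of the unit boundaries, no off-plan common substrings of 5 bp or
#' more between the two breakpoint windows, and no homology immediately
#' across the breakpoints (so the junction coordinate is unambiguous and the
#' leftmost-shift convention is trivially exact).
#'
#' Distances are chosen so the classic diagnostic sizes fall out of the
#' geometry: with the defaults the single-cutter boundary fragment is
#' 4,300 bp, the outside-cutter single-copy fragment 11,000 bp, and the
#' P1 / P2 / P3 products 1,700 / 1,100 / 9,400 bp.
#'
#' @param unitLength length of the amplifiable unit in bp (>= 2000);
#'   default 7483.
#' @param chromLength length of the locus chromosome; the unit is centred on
#'   it (5' boundary snapped to a 500 bp grid).
#' @param hindToEnd distance from the intra-unit cut to the 3' unit boundary.
#' @param boundaryFragment single-cutter boundary fragment size (intra-unit
#'   cut to first external cut downstream); must exceed \code{hindToEnd}.
#' @param hindLeftGap distance from the external upstream hindIII-like site
#'   to the 5' boundary.
#' @param sacLeftGap distance from the upstream sacII-like site to the 5'
#'   boundary.
#' @param outsideFragment outside-cutter fragment size for a single-copy
#'   locus; must exceed \code{unitLength + sacLeftGap}.
#' @param p1Product,r1Inset P1 junction-product size and the distance from
#'   the 5' boundary to the 3' end of its reverse-primer site.
#' @param p2Product,r2Inset P2 product size and reverse-primer inset.
#' @param p3Product,p3LeftGap P3 single-copy product size and distance from
#'   its forward primer to the 5' boundary; must satisfy
#'   \code{p3Product >= unitLength + p3LeftGap + primerLen}.
#' @param internalFragment size of the single-cutter internal fragment; it is
#'   structurally equal to \code{unitLength}, so any other request is a
#'   geometry conflict and raises an error.
#' @param primerLen primer length in bp.
#' @param probeLen Southern probe length (auto-shrunk on small geometries).
#' @param auxChromLength length of the aneuploidy-target chromosome
#'   \code{chrT} (0 omits it).
#' @param rdnaChromLength,rdnaStart,rdnaLength geometry of the rDNA proxy
#'   chromosome \code{chrR} (a \code{rdnaChromLength} of 0 omits it).
#' @param seed integer seed for the background sequence.
#' @return a validated \linkS4class{LocusModel}.
#' @examples
#' model <- buildLocusModel(chromLength = 40000, unitLength = 3000,
#'                          boundaryFragment = 2000, hindToEnd = 1200,
#'                          outsideFragment = 5000, p3Product = 4500,
#'                          auxChromLength = 0, rdnaChromLength = 0)
#' unitLength(model)
#' cutSites(model, "hindIII-like")
#' @export
buildLocusModel <- function(unitLength = 7483L,
                            chromLength = 300000L,
                            hindToEnd = 3000L,
                            boundaryFragment = 4300L,
                            hindLeftGap = 3000L,
                            sacLeftGap = 2000L,
                            outsideFragment = 11000L,
                            p1Product = 1700L,
                            r1Inset = 700L,
                            p2Product = 1100L,
                            r2Inset = 720L,
                            p3Product = 9400L,
                            p3LeftGap = 1000L,
                            internalFragment = NULL,
                            primerLen = 20L,
                            probeLen = 500L,
                            auxChromLength = 200000L,
                            rdnaChromLength = 200000L,
                            rdnaStart = 80000L,
                            rdnaLength = 20000L,
                            seed = 1L) {
  unitLength <- as.integer(unitLength)
  conflict <- function(...) stop("geometry conflict: ", sprintf(...),
                                 call. = FALSE)
  if (unitLength < 2000L)
    conflict("unitLength (%d) must be at least 2000 bp", unitLength)
  if (!is.null(internalFragment) && internalFragment != unitLength)
    conflict(paste("requested internal single-cutter fragment (%d) must equal",
                   "the repeat-unit length (%d): one cut per unit yields",
                   "unit-length internal fragments"),
             as.integer(internalFragment), unitLength)
  if (boundaryFragment <= hindToEnd)
    conflict("boundaryFragment (%d) must exceed hindToEnd (%d)",
             boundaryFragment, hindToEnd)
  if (hindToEnd <= 0L || hindToEnd >= unitLength)
    conflict("hindToEnd (%d) must place the cut inside the unit (%d bp)",
             hindToEnd, unitLength)
  if (outsideFragment <= unitLength + sacLeftGap)
    conflict("outsideFragment (%d) must exceed unitLength + sacLeftGap (%d)",
             outsideFragment, unitLength + sacLeftGap)
  f1ToEnd <- p1Product - r1Inset
  if (f1ToEnd < primerLen || f1ToEnd >= unitLength ||
      r1Inset < primerLen || r1Inset >= unitLength)
    conflict("P1 primers (product %d, inset %d) do not fit inside the unit",
             p1Product, r1Inset)
  p2Up <- p2Product - r2Inset
  if (p2Up < primerLen || r2Inset < primerLen + r1Inset)
    conflict("P2 geometry invalid (product %d, inset %d)", p2Product, r2Inset)
  if (p3LeftGap < primerLen)
    conflict("p3LeftGap (%d) shorter than a primer", p3LeftGap)
  if (p3Product < unitLength + p3LeftGap + primerLen)
    conflict(paste("p3Product (%d) cannot span the unit: needs at least",
                   "unitLength + p3LeftGap + primerLen = %d"),
             p3Product, unitLength + p3LeftGap + primerLen)

  u5 <- ((chromLength %/% 2L) %/% 500L) * 500L
  u3 <- u5 + unitLength
  leftExtent <- max(hindLeftGap, sacLeftGap + 6L, p3LeftGap, p2Up, 121L)
  rightExtent <- max(boundaryFragment - hindToEnd + 6L,
                     outsideFragment - sacLeftGap + 6L,
                     p3Product - p3LeftGap, 30L)
  if (u5 - leftExtent < 200L || u3 + rightExtent > chromLength - 200L)
    conflict(paste("chromLength (%d) too short for the requested extents",
                   "(need %d upstream and %d downstream of the unit)"),
             chromLength, leftExtent, rightExtent)

  ## planted positions (0-based starts)
  h <- u3 - hindToEnd
  hindSites <- c(u5 - hindLeftGap, h, h + boundaryFragment)
  sacSites <- c(u5 - sacLeftGap, u5 - sacLeftGap + outsideFragment)
  mhPlan <- data.frame(
    motif = c(.MH_JUNCTION, .MH_FLANK),
    startA = c(u5 + 21L, u5 - 14L),
    startB = c(u3 - nchar(.MH_JUNCTION), u3 + 15L),
    stringsAsFactors = FALSE)
  mhPlan$offsetA <- mhPlan$startA - u5
  mhPlan$offsetB <- mhPlan$startB - u3

  planted <- rbind(
    data.frame(start = hindSites, end = hindSites + nchar(.HIND_REC)),
    data.frame(start = sacSites, end = sacSites + nchar(.SAC_REC)),
    data.frame(start = c(mhPlan$startA, mhPlan$startB),
               end = c(mhPlan$startA, mhPlan$startB) +
                 nchar(c(mhPlan$motif, mhPlan$motif))))
  planted <- planted[order(planted$start), ]
  if (any(planted$start[-1] < planted$end[-nrow(planted)]))
    conflict("planted motif/enzyme placements overlap; adjust the geometry")

  ## primer sites and probes (reference intervals, not planted sequence)
  primerSites <- data.frame(
    set = rep(c("P1", "P2", "P3"), each = 2L),
    role = rep(c("fwd", "rev"), 3L),
    start = c(u3 - f1ToEnd, u5 + r1Inset - primerLen,
              u5 - p2Up, u5 + r2Inset - primerLen,
              u5 - p3LeftGap, u5 - p3LeftGap + p3Product - primerLen),
    stringsAsFactors = FALSE)
  primerSites$end <- primerSites$start + primerLen
  primerSites$strand <- rep(c("+", "-"), 3L)

  pl <- min(probeLen, max(50L, hindToEnd %/% 3L), max(50L, sacLeftGap %/% 3L))
  probes <- data.frame(
    name = c("inside", "outside"),
    chrom = "chrA",
    start = c(h + (hindToEnd - pl) %/% 2L,
              sacSites[1] + (sacLeftGap - pl) %/% 2L),
    stringsAsFactors = FALSE)
  probes$end <- probes$start + pl

  ## feature placeholders inside the unit
  revLen <- min(1500L, unitLength %/% 5L)
  features <- data.frame(
    name = c("REV1-like", "tRNA-like", "ARS-like", "XylA-like"),
    chrom = "chrA",
    start = c(u5 + 100L, u5 + 100L + revLen + 100L,
              u5 + 100L + revLen + 280L,
              max(h + 1L, probes$start[1] - 200L)),
    stringsAsFactors = FALSE)
  features$end <- c(features$start[1] + revLen, features$start[2] + 80L,
                    features$start[3] + 236L,
                    min(u3 - 30L, probes$end[1] + 200L))

  ## ---- background generation and deterministic patching --------------------
  chrA <- .withSeed(.childSeed(seed, "chrA"), {
    x <- sample(c("A", "C", "G", "T"), chromLength, replace = TRUE)
    for (i in seq_along(hindSites))
      x[hindSites[i] + seq_len(nchar(.HIND_REC))] <-
        strsplit(.HIND_REC, "")[[1]]
    for (i in seq_along(sacSites))
      x[sacSites[i] + seq_len(nchar(.SAC_REC))] <- strsplit(.SAC_REC, "")[[1]]
    for (i in seq_len(nrow(mhPlan))) {
      m <- strsplit(mhPlan$motif[i], "")[[1]]
      x[mhPlan$startA[i] + seq_along(m)] <- m
      x[mhPlan$startB[i] + seq_along(m)] <- m
    }
    x
  })
  chrA <- .withSeed(.childSeed(seed, "patch"),
                    .patchLocusBackground(chrA, u5, u3, planted, mhPlan,
                                          primerSites, probes))
  seqs <- list(chrA = paste(chrA, collapse = ""))

  if (auxChromLength > 0L)
    seqs$chrT <- .withSeed(.childSeed(seed, "chrT"),
                           .randomDna(auxChromLength))
  if (rdnaChromLength > 0L) {
    if (rdnaStart + rdnaLength > rdnaChromLength)
      conflict("rDNA proxy region exceeds chrR length")
    seqs$chrR <- .withSeed(.childSeed(seed, "chrR"),
                           .randomDna(rdnaChromLength))
  }

  new("LocusModel",
      parentSeqs = Biostrings::DNAStringSet(unlist(seqs)),
      unitChrom = "chrA", unitStart = as.integer(u5), unitEnd = as.integer(u3),
      features = features, microhomologyPlan = mhPlan,
      enzymeSites = list(
        "hindIII-like" = list(recognition = .HIND_REC, cutOffset = .HIND_CUT,
                              sites = as.integer(hindSites)),
        "sacII-like" = list(recognition = .SAC_REC, cutOffset = .SAC_CUT,
                            sites = as.integer(sacSites))),
      primerSites = primerSites, probes = probes,
      rdnaChrom = if (rdnaChromLength > 0L) "chrR" else character(),
      rdnaStart = as.integer(rdnaStart),
      rdnaEnd = as.integer(rdnaStart + rdnaLength),
      geometry = list(unitLength = unitLength, chromLength = chromLength,
                      hindToEnd = hindToEnd, boundaryFragment = boundaryFragment,
                      sacLeftGap = sacLeftGap, outsideFragment = outsideFragment,
                      p1Product = p1Product, p2Product = p2Product,
                      p3Product = p3Product, primerLen = primerLen,
                      auxChromLength = auxChromLength,
                      rdnaChromLength = rdnaChromLength),
      seed = as.integer(seed))
}

## Deterministic rejection-patching of the locus-chromosome background.
## `x` is a character vector of single bases. Iterates scan-and-mutate until
## no spurious occurrence remains (see buildLocusModel docs for the list of
## guarantees). Mutations never touch planted bases.
.patchLocusBackground <- function(x, u5, u3, planted, mhPlan, primerSites,
                                  probes) {
  isProtected <- logical(length(x))
  for (i in seq_len(nrow(planted)))
    isProtected[(planted$start[i] + 1L):planted$end[i]] <- TRUE
  bases <- c("A", "C", "G", "T")
  mutateIn <- function(start0, len) {
    ## replace one randomly chosen unprotected base in [start0, start0+len)
    ## with a randomly drawn different base; randomizing both the position
    ## and the letter lets the scan-and-patch loop escape configurations
    ## where the constraints on any single base are jointly unsatisfiable.
    ## TRUE on success.
    cand <- (start0 + seq_len(len) - 1L)
    cand <- cand[!isProtected[cand + 1L]]
    if (!length(cand)) return(FALSE)
    p <- if (length(cand) == 1L) cand else sample(cand, 1L)
    x[p + 1L] <<- sample(setdiff(bases, x[p + 1L]), 1L)
    TRUE
  }
  plantedStarts <- planted$start

  for (iter in 1:500) {
    dirty <- FALSE
    seqStr <- Biostrings::DNAString(paste(x, collapse = ""))

    ## (a) spurious enzyme recognitions anywhere on the chromosome
    for (rec in c(.HIND_REC, .SAC_REC)) {
      hits <- .matchStarts0(rec, seqStr)
      for (p in setdiff(hits, plantedStarts))
        dirty <- mutateIn(p, nchar(rec)) || dirty
    }
    ## (b) spurious motif occurrences within 100 bp of the unit boundaries
    for (i in seq_len(nrow(mhPlan))) {
      m <- mhPlan$motif[i]
      hits <- .matchStarts0(m, seqStr)
      near <- hits[(hits > u5 - 100L - nchar(m) & hits < u5 + 100L) |
                   (hits > u3 - 100L - nchar(m) & hits < u3 + 100L)]
      for (p in setdiff(near, c(mhPlan$startA[i], mhPlan$startB[i])))
        dirty <- mutateIn(p, nchar(m)) || dirty
    }
    ## (c) primer-site and probe subsequences must be unique
    for (df in list(primerSites, probes)) {
      for (i in seq_len(nrow(df))) {
        sub <- as.character(Biostrings::subseq(seqStr, df$start[i] + 1L,
                                               df$end[i]))
        hits <- .matchStarts0(sub, seqStr)
        for (p in setdiff(hits, df$start[i]))
          dirty <- mutateIn(p, nchar(sub)) || dirty
      }
    }
    ## (d) breakpoint windows share no off-plan >= 5 bp substring (keeps the
    ## microhomology report to exactly the planted hits)
    rad <- 40L
    wa <- c(u5 - rad, u5 + rad); wb <- c(u3 - rad, u3 + rad)
    A <- as.character(Biostrings::subseq(seqStr, wa[1] + 1L, wa[2]))
    B <- as.character(Biostrings::subseq(seqStr, wb[1] + 1L, wb[2]))
    hits <- .commonSubstrings(A, B, minLen = 5L)
    if (nrow(hits)) {
      okA <- mhPlan$startA - wa[1]; okB <- mhPlan$startB - wb[1]
      for (i in seq_len(nrow(hits))) {
        contained <- any(hits$startA[i] >= okA &
                         hits$startA[i] + hits$len[i] <=
                           okA + nchar(mhPlan$motif) &
                         hits$startB[i] >= okB &
                         hits$startB[i] + hits$len[i] <=
                           okB + nchar(mhPlan$motif))
        if (!contained) {
          done <- mutateIn(wb[1] + hits$startB[i], hits$len[i]) ||
            mutateIn(wa[1] + hits$startA[i], hits$len[i])
          dirty <- done || dirty
        }
      }
    }
    ## (e) no homology straddling the breakpoints: junction coordinate unique
    if (x[u5] == x[u3]) dirty <- mutateIn(u5 - 1L, 1L) || dirty    # ref[u5-1]
    if (x[u5 + 1L] == x[u3 + 1L]) dirty <- mutateIn(u3, 1L) || dirty # ref[u3]

    if (!dirty) return(x)
  }
  stop("background patching did not converge; geometry too constrained")
}
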