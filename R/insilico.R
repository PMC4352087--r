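#' @include AllGenerics.R
NULL

#' Extension-time product-size caps
#'
#' Thermocycler extension time bounds the amplifiable product size. The
#' mapping used throughout the package is a declared, configurable proxy:
#' \code{"short"} (a 2 min extension) caps products at 3,000 bp and
#' \code{"long"} (8 min) at 12,000 bp, bracketing the diagnostic 1.7 kb
#' junction product and 9.4 kb whole-locus product on the correct sides.
#'
#' @param time \code{"short"} or \code{"long"}.
#' @return cap in bp.
#' @examples
#' extensionCap("short")
#' @export
extensionCap <- function(time = c("short", "long")) {
  switch(match.arg(time), short = 3000, long = 12000)
}

#' In-silico PCR on a linear or circular template
#'
#' Enumerates all convergent placements of an exact-matching primer pair
#' whose product size does not exceed the extension cap. On circular
#' templates a product may wrap the origin exactly once, which is what lets
#' an outward-pointing primer pair (P1) amplify across the junction of a
#' circle or tandem repeat while producing nothing on the single-copy
#' linear locus. Product sizes are inclusive of both primers. A primer
#' absent from the template yields an empty, flagged prediction rather
#' than an error.
#'
#' @param template template sequence (\link[Biostrings]{DNAString},
#'   character, or a named molecule of a \linkS4class{GenomeBuild}).
#' @param fwdPrimer,revPrimer primer oligos 5'->3' (the reverse primer
#'   anneals to the plus strand as its reverse complement).
#' @param cap maximum product size in bp (see [extensionCap()]).
#' @param circular is the template circular?
#' @param primerSet,templateId labels carried into the prediction.
#' @return a \linkS4class{PcrPrediction}.
#' @export
insilicoPcr <- function(template, fwdPrimer, revPrimer, cap,
                        circular = FALSE, primerSet = "", templateId = "") {
  stopifnot(cap > 0)
  if (is.character(template)) template <- Biostrings::DNAString(template)
  L <- length(template)
  revSite <- .revcomp(revPrimer)
  scanSeq <- if (circular) Biostrings::xscat(template, template) else template
  fw <- .matchStarts0(fwdPrimer, scanSeq)
  rv <- .matchStarts0(revSite, scanSeq)
  fw <- unique(fw[fw < L]); rv <- unique(rv[rv < L])
  found <- length(fw) > 0L && length(rv) > 0L
  prods <- data.frame(start = integer(), end = integer(), size = integer(),
                      wrapped = logical())
  if (found) {
    minSize <- nchar(fwdPrimer) + nchar(revPrimer)
    for (f in fw) for (r in rv) {
      e <- r + nchar(revPrimer)          # product end (exclusive)
      if (e > f) {
        size <- e - f
        if (size >= minSize && size <= cap)
          prods <- rbind(prods, data.frame(start = f, end = e, size = size,
                                           wrapped = FALSE))
      } else if (circular) {
        size <- L - f + e                # wraps the origin once
        if (size >= minSize && size <= cap)
          prods <- rbind(prods, data.frame(start = f, end = e, size = size,
                                           wrapped = TRUE))
      }
    }
    prods <- prods[order(prods$size), , drop = FALSE]
    rownames(prods) <- NULL
  }
  new("PcrPrediction", primerSet = primerSet, template = templateId,
      topology = if (circular) "circular" else "linear",
      products = prods, extensionCap = as.numeric(cap),
      primersFound = found)
}

#' In-silico restriction digest with Southern-band prediction
#'
#' Computes fragments by cut-coordinate differencing (wraparound
#' differencing on circles: one cut linearizes a circle into a single
#' full-length fragment; zero cuts leave an uncut circular species that is
#' flagged as not band-forming). Fragment sizes always sum to the template
#' length. Each probe's exact occurrences are assigned to fragments by
#' overlap; band intensity is the copy-weighted count of probe-bearing
#' fragments, grouped by display size (0.1 kb, truncated as read off a
#' gel).
#'
#' @param template template sequence.
#' @param enzyme list with \code{recognition} and \code{cutOffset} (as in a
#'   \linkS4class{LocusModel}'s \code{enzymeSites}), or an enzyme name
#'   combined with \code{model}.
#' @param probes named character vector of probe sequences.
#' @param circular is the template circular?
#' @param copyWeight weight of this template in the band table (molecule
#'   copy number).
#' @param model optional \linkS4class{LocusModel} to resolve an enzyme
#'   name and default probes.
#' @param templateId label carried into the prediction.
#' @return a \linkS4class{DigestPrediction}.
#' @export
insilicoDigest <- function(template, enzyme, probes = NULL,
                           circular = FALSE, copyWeight = 1,
                           model = NULL, templateId = "") {
  if (is.character(enzyme)) {
    stopifnot(!is.null(model))
    name <- enzyme
    enzyme <- model@enzymeSites[[enzyme]]
    if (is.null(enzyme)) stop("unknown enzyme: ", name)
    enzyme$name <- name
  }
  if (is.null(enzyme$name)) enzyme$name <- enzyme$recognition
  if (is.null(probes)) {
    stopifnot(!is.null(model))
    chrA <- model@parentSeqs[[model@unitChrom]]
    probes <- setNames(
      vapply(seq_len(nrow(model@probes)), function(i)
        .as_chr0(chrA, model@probes$start[i], model@probes$end[i]), ""),
      model@probes$name)
  }
  if (is.character(template)) template <- Biostrings::DNAString(template)
  L <- length(template)
  scanSeq <- if (circular) Biostrings::xscat(template, template) else template
  sites <- .matchStarts0(enzyme$recognition, scanSeq)
  if (circular) {
    cuts <- sort(unique((sites[sites < L] + enzyme$cutOffset) %% L))
  } else {
    cuts <- sort(unique(sites + enzyme$cutOffset))
    cuts <- cuts[cuts > 0L & cuts < L]
  }

  uncut <- circular && length(cuts) == 0L
  if (uncut) {
    frags <- data.frame(start = 0L, end = L, size = L)
  } else if (circular) {
    cuts <- sort(cuts)
    nxt <- c(cuts[-1], cuts[1] + L)
    frags <- data.frame(start = cuts, end = nxt, size = nxt - cuts)
  } else {
    bnd <- unique(c(0L, cuts, L))
    frags <- data.frame(start = bnd[-length(bnd)], end = bnd[-1],
                        size = diff(bnd))
  }

  ## probe occurrences (positions may exceed L on circles: fragment
  ## intervals beyond L wrap, and so may a probe site)
  for (pn in names(probes)) {
    occ <- .matchStarts0(probes[[pn]], scanSeq)
    if (circular) occ <- unique(occ %% L)
    w <- nchar(probes[[pn]])
    hit <- integer(nrow(frags))
    for (o in occ) {
      ends <- o + w
      ov <- (o < frags$end & ends > frags$start) |
        (circular & (o + L < frags$end & ends + L > frags$start))
      hit <- hit + as.integer(ov)
    }
    frags[[paste0("probe_", pn)]] <- hit
  }
  probeCols <- grep("^probe_", names(frags), value = TRUE)
  bearing <- rowSums(frags[, probeCols, drop = FALSE]) > 0
  if (uncut || !any(bearing)) {
    bands <- data.frame(sizeKb = numeric(), intensity = numeric(),
                        probes = character())
  } else {
    bf <- frags[bearing, , drop = FALSE]
    bf$sizeKb <- .displayKb(bf$size)
    bands <- do.call(rbind, lapply(split(bf, bf$sizeKb), function(g) {
      hitProbes <- probeCols[vapply(probeCols,
                                    function(pc) any(g[[pc]] > 0), TRUE)]
      data.frame(sizeKb = g$sizeKb[1],
                 intensity = copyWeight * nrow(g),
                 probes = paste(sub("^probe_", "", hitProbes),
                                collapse = ","))
    }))
    bands <- bands[order(-bands$intensity, -bands$sizeKb), , drop = FALSE]
    rownames(bands) <- NULL
  }
  new("DigestPrediction", enzyme = enzyme$name, template = templateId,
      topology = if (circular) "circular" else "linear",
      fragments = frags, bands = bands, copyWeight = as.numeric(copyWeight),
      uncutCircle = uncut)
}

#' Combine band tables from several digested templates
#'
#' Aggregates copy-weighted band intensities across the molecules of a
#' sample (e.g. both homologs plus an episome), as a Southern blot of total
#' genomic DNA would.
#'
#' @param preds list of \linkS4class{DigestPrediction}s for one enzyme.
#' @return data.frame (sizeKb, intensity) sorted by decreasing intensity.
#' @export
combineBands <- function(preds) {
  tabs <- lapply(preds, function(p) p@bands[, c("sizeKb", "intensity")])
  tab <- do.call(rbind, tabs)
  if (is.null(tab) || !nrow(tab))
    return(data.frame(sizeKb = numeric(), intensity = numeric()))
  agg <- stats::aggregate(intensity ~ sizeKb, tab, sum)
  agg[order(-agg$intensity, -agg$sizeKb), , drop = FALSE]
}

#' Intensity ratio of the two dominant probe-bearing bands
#'
#' For a single-cutter digest of an n-copy tandem array amplified in both
#' alleles this ratio (unit-length band over boundary band) equals n - 1:
#' each allele yields n - 1 internal unit-length fragments carrying the
#' probe and one probe-bearing boundary fragment. The ratio is reported as
#' intensity of the larger-sized band over the smaller-sized of the two
#' most intense probe-bearing bands.
#'
#' @param x a \linkS4class{DigestPrediction} or a combined band table from
#'   [combineBands()].
#' @return numeric ratio, or NA (with a warning) when fewer than two
#'   probe-bearing bands exist.
#' @export
intensityRatio <- function(x) {
  bands <- if (is(x, "DigestPrediction")) x@bands else x
  if (nrow(bands) < 2L) {
    warning("fewer than two probe-bearing bands: intensity ratio undefined")
    return(NA_real_)
  }
  top <- bands[order(-bands$intensity), ][1:2, ]
  top <- top[order(-top$sizeKb), ]
  top$intensity[1] / top$intensity[2]
}
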