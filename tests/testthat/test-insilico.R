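test_that("P1 amplifies only across a circular or tandem junction", {
  m <- defaultLocusModel()
  p1 <- primerPair(m, "P1")
  parent <- applyScenario(m, scenarioPreset("parent"))
  circle <- applyScenario(m, ScenarioSpec(episomeCount = 1))
  tandem <- applyScenario(m, ScenarioSpec(c(9L, 9L)))
  cap <- extensionCap("short")

  none <- insilicoPcr(parent@seqs[["chrA_allele1"]], p1[["fwd"]], p1[["rev"]],
                      cap)
  expect_true(none@primersFound)
  expect_identical(nrow(none@products), 0L)

  onCircle <- insilicoPcr(circle@seqs[["episome"]], p1[["fwd"]], p1[["rev"]],
                          cap, circular = TRUE)
  expect_identical(onCircle@products$size, 1700L)
  expect_true(onCircle@products$wrapped)

  onTandem <- insilicoPcr(tandem@seqs[["chrA_allele1"]], p1[["fwd"]],
                          p1[["rev"]], cap)
  expect_identical(unique(onTandem@products$size), 1700L)
  expect_identical(nrow(onTandem@products), 8L)   # one per junction
})

test_that("P2 anchors the locus and P3 spans it only in single copy", {
  m <- defaultLocusModel()
  p2 <- primerPair(m, "P2"); p3 <- primerPair(m, "P3")
  parent <- applyScenario(m, scenarioPreset("parent"))@seqs[["chrA_allele1"]]
  tandem <- applyScenario(m, ScenarioSpec(c(9L, 9L)))@seqs[["chrA_allele1"]]
  deleted <- applyScenario(m,
                           ScenarioSpec(c(0L, 1L)))@seqs[["chrA_allele1"]]

  expect_identical(
    insilicoPcr(parent, p2[["fwd"]], p2[["rev"]],
                extensionCap("short"))@products$size, 1100L)
  ## P3 long extension: 9.4 kb on single copy, nothing on the tandem
  expect_identical(
    insilicoPcr(parent, p3[["fwd"]], p3[["rev"]],
                extensionCap("long"))@products$size, 9400L)
  expect_identical(nrow(
    insilicoPcr(tandem, p3[["fwd"]], p3[["rev"]],
                extensionCap("long"))@products), 0L)
  ## P3 short extension reports a deleted allele (flanks joined)
  expect_identical(
    insilicoPcr(deleted, p3[["fwd"]], p3[["rev"]],
                extensionCap("short"))@products$size,
    9400L - unitLength(m))
  ## absent primer: empty and flagged
  off <- insilicoPcr(strrep("ACGT", 100), p3[["fwd"]], p3[["rev"]], 3000)
  expect_false(off@primersFound)
  expect_identical(nrow(off@products), 0L)
})

test_that("digest fragment algebra is exact and conserves template length", {
  m <- defaultLocusModel()
  builds <- lapply(c("parent", "episome", "tandem_one", "tandem_both"),
                   function(p) applyScenario(m, scenarioPreset(p)))
  for (b in builds) for (i in seq_along(b@seqs)) {
    if (!any(b@coordMap$molecule == names(b@seqs)[i] &
             b@coordMap$chrom == m@unitChrom)) next
    for (enz in c("hindIII-like", "sacII-like")) {
      d <- insilicoDigest(b@seqs[[i]], enz, model = m,
                          circular = b@circular[i])
      expect_identical(sum(d@fragments$size),
                       Biostrings::width(b@seqs)[i])
    }
  }
  ## linear template: fragment count = cut count + 1; circular: = cut count
  parent <- builds[[1]]
  dLin <- insilicoDigest(parent@seqs[["chrA_allele1"]], "hindIII-like",
                         model = m)
  expect_identical(nrow(dLin@fragments),
                   length(cutSites(m, "hindIII-like")) + 1L)
  circle <- applyScenario(m, ScenarioSpec(episomeCount = 1))
  dCirc <- insilicoDigest(circle@seqs[["episome"]], "hindIII-like",
                          model = m, circular = TRUE)
  expect_identical(nrow(dCirc@fragments), 1L)
})

test_that("the single-cutter produces the diagnostic band pattern", {
  m <- defaultLocusModel()
  ## one cut linearizes the episome into a single unit-length fragment
  circle <- applyScenario(m, ScenarioSpec(episomeCount = 1))
  d <- insilicoDigest(circle@seqs[["episome"]], "hindIII-like", model = m,
                      circular = TRUE)
  expect_identical(nrow(d@fragments), 1L)
  expect_identical(d@fragments$size, unitLength(m))
  expect_identical(d@bands$sizeKb, 7.4)

  ## tandem in both alleles: 7.4 kb internal band 8x the 4.3 kb boundary
  ev <- gatherAssayEvidence(applyScenario(m, scenarioPreset("tandem_both")))
  expect_setequal(ev$singleCutter$sizeKb, c(7.4, 4.3))
  expect_identical(ev$singleCutter$intensity[ev$singleCutter$sizeKb == 7.4],
                   16)
  expect_identical(ev$intensityRatio, 8)

  ## parent: single 4.3 kb band only
  evP <- gatherAssayEvidence(applyScenario(m, scenarioPreset("parent")))
  expect_identical(evP$singleCutter$sizeKb, 4.3)
})

test_that("the outside cutter separates single copy from tandem growth", {
  m <- defaultLocusModel()
  parent <- applyScenario(m, scenarioPreset("parent"))
  d <- insilicoDigest(parent@seqs[["chrA_allele1"]], "sacII-like", model = m)
  probeBands <- d@bands
  expect_true(11.0 %in% probeBands$sizeKb)
  ## an n-copy tandem allele grows the probe fragment by (n-1) units
  for (n in c(2L, 9L)) {
    bn <- applyScenario(m, ScenarioSpec(c(n, 0L)))
    dn <- insilicoDigest(bn@seqs[["chrA_allele1"]], "sacII-like", model = m)
    sizes <- dn@fragments$size[rowSums(
      dn@fragments[, grep("^probe_", names(dn@fragments)), drop = FALSE]) > 0]
    expect_true((11000L + (n - 1L) * unitLength(m)) %in% sizes)
  }
  ## zero cuts on a circle: uncut species, not band-forming
  circle <- applyScenario(m, ScenarioSpec(episomeCount = 1))
  dc <- insilicoDigest(circle@seqs[["episome"]], "sacII-like", model = m,
                       circular = TRUE)
  expect_true(dc@uncutCircle)
  expect_identical(nrow(dc@bands), 0L)
})

test_that("intensity ratios follow the fragment-counting oracle", {
  m <- defaultLocusModel()
  ## n = 9 both alleles: 16 internal vs 2 boundary probe fragments
  ev9 <- gatherAssayEvidence(applyScenario(m, ScenarioSpec(c(9L, 9L))))
  expect_identical(ev9$intensityRatio, 8)
  ## n = 2 one allele, single copy in the other: 1 internal vs 2 boundary
  ev2 <- gatherAssayEvidence(applyScenario(m, ScenarioSpec(c(2L, 1L))))
  expect_identical(ev2$intensityRatio, 0.5)
  ## single copy probed inside the unit: one band, ratio undefined
  chrA <- parentSeqs(m)[["chrA"]]
  insideProbe <- as.character(Biostrings::subseq(
    chrA, m@probes$start[m@probes$name == "inside"] + 1L,
    m@probes$end[m@probes$name == "inside"]))
  d <- insilicoDigest(
    applyScenario(m, scenarioPreset("parent"))@seqs[["chrA_allele1"]],
    "hindIII-like", probes = c(inside = insideProbe), model = m)
  expect_warning(r <- intensityRatio(d), "undefined")
  expect_true(is.na(r))
})

test_that("predictions match string-level brute force on random geometries", {
  set.seed(77)
  for (case in 1:50) {
    unitLen <- sample(2000:3500, 1)
    hindToEnd <- sample(500:(unitLen - 500), 1)
    geom <- list(unitLength = unitLen, chromLength = 20000,
                 hindToEnd = hindToEnd,
                 boundaryFragment = hindToEnd + sample(300:1200, 1),
                 hindLeftGap = sample(500:1500, 1),
                 sacLeftGap = sample(300:900, 1),
                 p1Product = sample(900:1800, 1),
                 r1Inset = sample(300:700, 1),
                 p2Product = 1100, r2Inset = 760,
                 p3LeftGap = 1000,
                 auxChromLength = 0, rdnaChromLength = 0,
                 seed = 7000 + case)
    geom$outsideFragment <- unitLen + geom$sacLeftGap + sample(500:1500, 1)
    geom$p3Product <- unitLen + geom$p3LeftGap + sample(100:800, 1)
    if (geom$p1Product - geom$r1Inset < 20) next
    mod <- do.call(buildLocusModel, geom)
    nCopies <- sample(1:3, 1)
    tmpl <- as.character(
      applyScenario(mod,
                    ScenarioSpec(c(nCopies, 0L)))@seqs[["chrA_allele1"]])

    ## oracle PCR by raw string scanning
    pr <- primerPair(mod, "P1")
    fw <- gregexpr(pr[["fwd"]], tmpl, fixed = TRUE)[[1]]
    rvSite <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(pr[["rev"]])))
    rv <- gregexpr(rvSite, tmpl, fixed = TRUE)[[1]]
    want <- integer()
    if (fw[1] != -1 && rv[1] != -1)
      for (f in fw) for (r in rv) {
        size <- r + nchar(rvSite) - f
        if (r + nchar(rvSite) > f && size <= 3000 &&
            size >= nchar(pr[["fwd"]]) + nchar(pr[["rev"]]))
          want <- c(want, size)
      }
    got <- insilicoPcr(tmpl, pr[["fwd"]], pr[["rev"]], 3000)@products$size
    expect_identical(sort(got), sort(want))

    ## oracle digest by raw string scanning
    e <- mod@enzymeSites[["hindIII-like"]]
    occ <- gregexpr(e$recognition, tmpl, fixed = TRUE)[[1]]
    cutsOracle <- sort(occ - 1L + e$cutOffset)
    wantSizes <- diff(c(0L, cutsOracle, nchar(tmpl)))
    gotSizes <- insilicoDigest(tmpl, "hindIII-like",
                               model = mod)@fragments$size
    expect_identical(sort(gotSizes), sort(as.integer(wantSizes)))
    expect_identical(sum(gotSizes), nchar(tmpl))
  }
})
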