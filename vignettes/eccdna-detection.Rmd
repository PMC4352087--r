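---
title: "Detecting eccDNA and tandem amplification from read evidence"
author: "eccFinder"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting eccDNA and tandem amplification from read evidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eccFinder)
```

## The inference problem

When a gene under strong selection is amplified, the amplification can take
several structural forms that leave identical local signals: a
self-replicating extrachromosomal circle (eccDNA) carrying the gene and an
origin of replication (ARS), a tandem head-to-tail array integrated at the
chromosomal locus of origin, or combinations of the two. Short-read
sequencing of an evolved strain against its parent shows the copy-number
gain and the novel junction, but the junction itself cannot distinguish a
circle from a tandem array: reading through the 3' end of the amplified
unit into its 5' end is exactly what both structures look like. The
discriminating evidence is combinatorial -- an outward-facing PCR across
the junction, a locus-spanning PCR whose product grows with copy number
past what a polymerase can extend, and Southern blots with an enzyme that
cuts once inside the unit versus one that cuts only outside it.

eccFinder implements that whole inference chain as testable code:

1. **synthetic data** -- a parameterized diploid genome carrying an
   annotated amplifiable locus, rearranged according to a scenario, and a
   paired-end read simulator with exact truth alignments;
2. **coverage CNV** -- two-sample windowed depth, normalized log2 ratio,
   moving-average smoothing, segment calling and fold estimation;
3. **junction detection** -- soft-clip collection, breakpoint clustering,
   cross-matching of clipped tails, unit-length inference;
4. **microhomology** -- exact common-substring scan around the breakpoints;
5. **in-silico validation** -- PCR and restriction-digest/Southern
   predictions per topology, and a classifier that combines all assays.

## The locus model and its geometry

`buildLocusModel()` constructs the parent reference. The amplifiable unit
is 7,483 bp by default and carries placeholders for the genes the real
amplicon contains (a REV1-like ORF, a tRNA-like gene, a 236 bp ARS-like
origin, and a XylA-like xylose-isomerase gene whose dosage is the selected
trait). All diagnostic distances are parameters, with defaults chosen so
that the classic assay read-outs fall out of the geometry:

| parameter | default | meaning |
|---|---|---|
| `unitLength` | 7,483 bp | amplifiable unit (circle size / repeat period) |
| `hindToEnd` | 3,000 bp | intra-unit single-cutter site to the 3' boundary |
| `boundaryFragment` | 4,300 bp | single-cutter boundary fragment (probe-bearing) |
| `outsideFragment` | 11,000 bp | outside-cutter fragment for a single-copy locus |
| `p1Product` | 1,700 bp | outward-facing junction PCR product |
| `p2Product` | 1,100 bp | locus-anchor PCR product |
| `p3Product` | 9,400 bp | locus-spanning PCR product (single copy) |
| window | 500 bp | depth averaging window |
| span | 10,000 bp | moving-average smoothing span |
| depth | 44x | simulated coverage |
| read length | 90 bp | paired-end reads, 500 bp fragments |

Two microhomology motifs are planted at the unit boundaries: an 8 bp motif
(`GGAAAGGG`) whose downstream copy ends exactly at the 3' boundary and
whose second copy sits 21 bp downstream of the 5' boundary, and a 7 bp
motif (`TATGATG`) flanking the unit at offsets -14 and +15. The junctional
8 bp motif is the plausible substrate of the MMBIR
(microhomology-mediated break-induced replication) event that excised the
unit as a circle; microhomologies of 5-25 bp are the hallmark of that
mechanism, which is why the scanner's defaults are a 30 bp search radius
and a 5 bp minimum.

The background sequence is i.i.d. uniform ACGT from a seeded generator and
is then deterministically patched so the model's guarantees hold *by
construction*: no spurious enzyme-recognition, primer or probe occurrence
on the locus chromosome, no off-plan motif copy within 100 bp of the unit
boundaries, no off-plan common substring of 5 bp or more between the two
breakpoint windows, and no homology straddling the breakpoints (so the
junction coordinate is unambiguous). The patcher mutates a random
unprotected base of each offending occurrence and re-scans to a fixpoint;
randomizing both position and replacement letter is what guarantees
convergence even when the constraints on one particular base are jointly
unsatisfiable. A uniform background is deliberately simpler than a real
genome: it has no repeats, no GC structure and no low-complexity tracts,
so passing tests demonstrate the correctness of the algorithms, not their
robustness to repeat-rich genomes (see *Limitations*).

## Scenarios and the read simulator

A `ScenarioSpec` declares the sample genome as a derivation from the
parent: tandem copies per homolog, mean episomes per cell, per-chromosome
copy counts, and a copy factor for a 20 kb tandem-repeat proxy region (the
rDNA stand-in). Six presets mirror the strain archetypes the classifier
must separate: `parent`, `deletion`, `episome`, `circle_plus_single`,
`tandem_one` and `tandem_both` (nine copies per allele in both homologs,
a trisomic 200 kb chromosome, rDNA factor 0.5).

Three generator choices deserve justification:

* **Tandem joins.** Because the junction-side motif ends exactly at the 3'
  boundary, a head-to-tail repeat of the unit automatically places one
  shared copy of the motif at every join; an n-copy allele is exactly
  `n * unitLength` longer than a deletion allele, with no inserted bases.
* **Episome weight.** Cultures are populations, so the episome count is a
  real-valued mean and enters the simulator as a fractional copy weight
  rather than an integer molecule count.
* **rDNA proxy.** The analysis consumes depth, not sequence, so the proxy
  region scales the read-sampling density (and the molecule's total read
  budget) instead of materializing 150-200 literal repeats.

`simulateReads()` draws per-molecule Poisson pair counts with mean
`depth * weight/2 * effectiveLength / (2 * readLen)` -- a locus at copy
number two is covered at `depth` -- and Gaussian fragment lengths
(mean 500 bp, sd 50 bp). Errors are uniform substitutions at 0.002 per
base; indels are excluded on purpose, since no downstream target depends
on them and they would complicate exact truth CIGARs. Each read's truth
alignment against the *parent* is derived through the build's coordinate
map; a read crossing a junction is anchored on its longest
parent-contiguous piece and the rest is soft-clipped at the junction
coordinate, which is precisely the evidence a real aligner leaves at an
amplicon breakpoint. Identical seeds give byte-identical FASTQ/SAM output.

## Coverage CNV: normalization and fold estimation

Depth is per-base counting into non-overlapping 500 bp tiles (partial
terminal windows are normalized by their true width), and the two plotted
series of a classical CNV figure come from one mechanism each: the raw
windows, and a centred moving average over `span/window` windows (masked
windows excluded, edges truncated).

The log2 ratio is computed after two normalizations:

1. the sample track is scaled to the reference library size (total aligned
   bases, robust to read-length differences) -- this makes the ratio
   exactly invariant under rescaling all sample depths by a constant;
2. the genome-wide log2 ratio is re-centred on its copy-neutral mode: the
   global median is refined twice as the median of windows within 0.3
   log2 units of the current centre.

The second step matters whenever the copy-changed fraction of the genome
is visible in the library total. On the synthetic genome the 9-fold
amplification, a whole-chromosome trisomy and the rDNA loss together shift
the library by tens of percent; plain equal-total-bases scaling would make
a planted 50% trisomy read as ~40% excess, and a plain median would land
on the flank of the neutral peak because the shifted windows are a large,
one-sided fraction. Mode re-centring (the same idea as the mode/median
normalizations of standard CNV-seq tools) recovers log2(1.5) for the
trisomy and -1 for the halved rDNA proxy regardless of genome composition.
Windows with reference depth below 5 are masked: log ratios explode at
near-zero denominators.

Segments are maximal runs of at least 5 consecutive unmasked windows with
smoothed |log2| >= 0.4 and consistent sign. The **fold estimate** is
`2^mean` over the *raw* windows inside the run after trimming
sub-threshold edge windows, not over the smoothed values: the default
10 kb smoother is wider than the 7.5 kb amplicon, so a smoothed mean
necessarily dilutes a short event by roughly the ratio of span to event
size (a 9-fold gain would report as ~5-fold). The smoothed series is the
right tool for *detecting* the run; the raw windows inside it carry the
undiluted ratio, which is also how one reads a fold off the zoomed locus
plot. Both means are reported in the segment table. A corollary used by
the test-suite's scaled-down geometry (a 3 kb unit): when an event is
shorter than half the span, a 2-fold change never crosses the 0.4
threshold after smoothing, so tests of small events smooth at a span
matched to the unit and say so.

## Junction detection conventions

Soft-clips of at least 10 bp are collected with their clip coordinate and
side, clustered by single linkage with a 5 bp gap on (chromosome, side),
and clusters with fewer than 3 supporting reads are dropped -- these
thresholds are declared defaults, not values inferred from data. The
consensus clipped tail (per-position majority vote, anchored at the
junction side) of the 3'-side cluster must read into the reference at the
5' breakpoint and vice versa, allowing one mismatch per 20 bases;
evaluating both directions makes the call independent of cluster order.
Junctions are reported continuous: any non-reference bases between the
breakpoints leave the pair unresolved rather than called, which matches
the read-through continuity the Sanger evidence for this class of event
shows and avoids a speculative inserted-bases field.

Where homology straddles the breakpoints the coordinate pair can slide;
the call uses the **leftmost** compatible pair and records the slide range
as the ambiguity span (the standard deterministic SV convention). The
implied unit length `rightBp - leftBp` equals the circle length for an
episome and the repeat period for an array -- the call deliberately
carries only the topology hint `"circular-or-tandem"`, because deciding
between them from the junction alone would be unsound; that decision
belongs to the assay classifier.

## Microhomology scan

`findMicrohomology()` enumerates all maximal exact common substrings of at
least 5 bp between +/-30 bp windows around the two breakpoints, classifies
a hit *junctional* when one occurrence abuts a breakpoint, suppresses hits
contained in a longer hit at both placements, and sorts
junctional-first-then-longest. Matching is exact: the reported motifs are
verbatim repeats, and mismatch-tolerant homology would require a scoring
scheme the underlying analysis never states. The 30 bp radius covers both
reported offsets with margin; it is configurable. A brute-force oracle
(every substring pair, by direct string comparison) verifies the scanner
over hundreds of random window pairs in the test suite.

## In-silico assays and the decision table

**PCR.** Products are all convergent exact-match primer placements within
the extension cap; circular templates allow exactly one wrap of the
origin, which is what lets the outward-facing P1 pair amplify 1.7 kb
across the junction of a circle or array while producing nothing on the
single-copy linear locus. Extension time is mapped to a size cap --
"short" (2 min) = 3,000 bp, "long" (8 min) = 12,000 bp. The mapping is an
invented but declared proxy; any monotone cap works, and these values
bracket the diagnostic 1.7 kb and 9.4 kb products on the correct sides.

**Digest.** Fragments come from cut-coordinate differencing (wraparound on
circles; a single cut linearizes a circle into one unit-length fragment;
zero cuts leave an uncut species flagged as not band-forming), and sizes
always sum to the template length. Band intensity is the copy-weighted
count of probe-bearing fragments -- no transfer-efficiency or
size-dependent signal modeling -- which is the minimal model that yields
the n-1 internal-to-boundary ratio for an n-copy array cut once per unit
in both alleles (16:2 = 8 at n = 9). The single-cutter blot is probed
inside the unit only; probing must not span the cut site, otherwise a
single-copy locus would show two bands where one is observed. Display
sizes truncate to 0.1 kb, as a band is read off a gel: a 7,483 bp
fragment runs as "7.4 kb".

**Classification.** The decision table composes the assays:

| P1 | outside-cutter | P3-short | verdict |
|---|---|---|---|
| - | 11 kb only | - | `single_copy` |
| - | 11 kb only | + | `deleted` |
| + | 11 kb only | - | `episomal_circle` |
| + | 11 kb only | + | `circle_plus_single_copy` |
| + | 11 kb + high-MW | | `tandem_one_allele` |
| + | high-MW only | | `tandem_both_alleles` |

"High-MW" is any probe-bearing outside-cutter fragment larger than the
single-copy fragment by at least half a unit. Contradictions (a high-MW
band without a P1 product; two single-cutter probe bands without P1) are
returned as `inconsistent` with the clash listed, never silently
classified. One taxonomy choice was genuinely open: a strain carrying a
circle with both chromosomal alleles still single copy shows P1+ and the
11 kb band only. This package calls that `episomal_circle` -- the circle
is the only amplified species, matching how such strains are described --
and reserves `circle_plus_single_copy` for a circle accompanying one
deleted and one intact single-copy allele (P1+, 11 kb, plus the
flank-joining P3-short product of the deleted allele).

Copies per amplified allele are estimated twice: from the coverage fold
(fold = n for both-allele arrays; (n+1)/2 when one allele is amplified)
and from the band-intensity ratio (n = ratio + 1, or 2 ratio + 1 for one
allele), with an agreement flag. One caveat the fragment-counting makes
explicit: for one 2-copy allele plus one single-copy allele, three unit
copies yield one internal and two boundary probe fragments, so the
unit-band to boundary-band ratio is 1/2 -- the counting identity
"internal = total copies - number of array ends" is what the tests pin
down.

## Problem sizes and numerical choices

The default study-scale configuration -- a 300 kb locus chromosome, a
200 kb aneuploidy-target chromosome and a 200 kb chromosome carrying the
20 kb rDNA proxy, simulated at 44x with 90 bp reads -- yields ~750,000
reads per two-sample comparison and runs the whole CNV chain in well under
a minute. The acceptance checks use this scale. Module tests that sweep
many seeds use a structurally identical scaled-down geometry (3 kb unit on
a 40 kb chromosome, 20 kb auxiliary chromosomes); the vignette's point
above about smoothing spans applies there. Other fixed choices: depth
pseudocount 0.1; masking floor 5; junction consensus flank 40 bp;
breakpoint cluster coordinate = member median; all coordinates 0-based
half-open internally, 1-based closed only in exported GRanges and printed
reports.

## Limitations

* The synthetic background is uniform random DNA: no repeats, GC bias,
  mappability structure or quality-score variation. Passing tests verify
  algorithmic correctness, not robustness to real-genome confounders, and
  real data would additionally need an actual read aligner (the pipeline
  consumes alignments, it does not produce them).
* The unit's sequence content is synthetic; only its geometry (lengths,
  site and motif placements) reproduces the modeled locus.
* No GC correction, mappability masking or HMM/CBS segmentation in the
  CNV module; thresholded runs on smoothed ratios are adequate for the
  large, clean events targeted here.
* PCR is modeled as exact primer matching under a size cap: no melting
  temperatures, dimers or mispriming. Band intensity ignores transfer
  efficiency and probe kinetics.
* Discordant read-pair evidence and general SV classes (inversions,
  translocations) are out of scope; the junction module handles the
  circular-or-tandem class only.
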