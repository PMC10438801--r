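---
title: "Resolving phage genome termini and curating assembly artifacts"
author: "phagecurate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resolving phage genome termini and curating assembly artifacts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phagecurate)
```

## The problem

T7-like phages (podoviruses such as the *Przondovirus* genus infecting
*Klebsiella*) have linear double-stranded DNA genomes of roughly 37–42 kb
that end in **direct terminal repeats (DTRs)**: an identical sequence of
about 180–230 bp present at both physical ends of the chromosome. The
repeats arise during packaging — replication produces head-to-tail
concatemers, terminases cut unit-length genomes out of them, and a second
repeat copy is synthesised at the other end so no genetic material is
lost.

Assemblers do not know about physical ends. Depending on the read set and
the assembler, a phage contig commonly emerges in one of several defective
states:

* **Collapsed DTR** — the two repeat copies are merged into one. Because
  every virion carries the repeat twice, read depth over the surviving
  copy is *doubled* relative to the rest of the genome, giving a
  characteristic terminal coverage peak.
* **Mid-genome opening** — the circular assembly-graph representation of
  the linear genome is opened at an arbitrary internal position, leaving
  the (collapsed) DTR somewhere in the middle of the contig. The
  diagnostic is a single coverage peak away from both ends.
* **Terminal flank artifacts** — untrimmed sequencing adapter/barcode
  sequence assembled *outside* the genome ends, typically as a pair of
  inverted repeats (observed as 64 bp flanks containing a 23 bp adapter
  core) sitting upstream of the left repeat and downstream of the right
  repeat.
* **Spurious tandem duplications** — short-read assemblers sometimes
  introduce an adjacent duplication of ~79 bp near (or within) the DTR
  region. The signature of a false duplication is that *no read spans the
  junction between the two copies* and the extra copy does not coincide
  with elevated depth.
* **Homopolymer indels** — the dominant nanopore error mode; residual
  single-base insertions/deletions inside homopolymer runs cause
  frameshifts in coding regions and are found by mapping the reads back
  and scanning for near-unanimous disagreement.

`phagecurate` implements the curation core of this workflow: it consumes
an assembled contig plus read alignments, resolves the DTR, repairs
collapse/mis-opening, trims flank artifacts, collapses unsupported
duplications, flags residual indel errors, and reorients the genome to a
canonical start. A built-in simulator generates all of these defect
states with ground truth, so every detector is testable without any
external data.

## The model and its components

### Coverage signal

`depthFromAlignments()` counts, per position, the primary alignments
whose reference-consuming CIGAR span (`M,=,X,D`; `N` excluded) covers it.
Deletion-spanned positions count as covered because the signal of
interest is copy-number support, not base agreement. Depth is normalized
by the **median** — the DTR peak itself and terminal ramps would bias a
mean. `segmentElevated()` extracts maximal runs with normalized depth
`>= theta` (default 1.6, splitting the expected 1x and 2x levels with
margin for Poisson noise), merging runs separated by at most `maxGap = 10`
positions and discarding regions shorter than `minLen = 50` bp (the
repeats of interest are ≥ 180 bp; short spikes are noise).
`classifyTerminusSignal()` turns the region list into a terminus verdict:
flat, left/right-terminal peak (collapsed DTR), internal peak
(mid-genome opening), or ambiguous (several regions; downstream proceeds
with the highest mean with a warning).

### Terminal self-repeat search

`findTerminalSelfRepeat()` looks for the maximal pair of near-identical
equal-length substrings with one copy in the first `window` bases and one
in the last `window` bases. Copies are compared position-wise
(substitution distance): within one contig, genuine DTR copies and
assembly-duplicated sequence are near-exact, so co-linear comparison is
the right model and keeps the search exact and fast (one pass per
diagonal). The reported pair is the maximal-*scoring* stretch (match +1,
mismatch −4) rather than the longest pair within an edit budget: a pure
length criterion would deterministically absorb a few random flanking
bases into the repeat (any budget `floor(0.02 L) > 0` pays for junk
extension), whereas with a strong mismatch penalty an extension must win
five chance matches per mismatch to survive, so planted exact repeats are
recovered with exact coordinates while genuinely divergent copies (sparse
mismatches between long exact runs) still align end to end. A final
filter enforces `length >= minLen` (30) and mismatch fraction
`<= maxDivergence` (0.02).

### DTR resolution and repair

`resolveDtr()` combines both evidence types. A terminal self-repeat
flanking the contig ends short-circuits to `FINISHED` — this also makes
re-resolution after an edit terminate instead of re-proposing the same
edit on the basis of the historical coverage peak. A repeat inset from
the ends (behind adapter flanks) is reported as `INSET`. Without a
repeat, the coverage signal proposes a repair: `relinearize()` either
rotates an internally-opened contig so the repeat leads and appends a
copy of it at the other end, or duplicates a terminal peak region to the
opposite end for a collapsed DTR. Proposed region edges are snapped to
the largest single step in raw depth within ±20 bp of the threshold
crossing: the underlying copy-number step is sharp at the true boundary
(the projected depth drops from 2x to 1x exactly at the repeat edge)
while threshold crossings wobble with sampling noise. Note that within a
single contig only *one* copy of a collapsed repeat exists, so no
within-contig sequence comparison can refine the boundary — any choice of
D yields a trivially self-consistent appended copy; coverage is the only
boundary evidence, and the post-edit re-resolution validates the result
by requiring a terminal self-repeat.

When both coverage and self-repeat evidence exist, the annotation records
evidence `BOTH` with the supporting depth ratio, and a conflict flag is
raised when they disagree on the repeat length by more than 5 bp — such
cases are surfaced for review (resolving them would take targeted
sequencing), not guessed at.

### Artifact repair

`findTerminalFlanks()` takes flank candidates from the resolved DTR
(`[0, leftStart)` and `[rightEnd, n)`) or — when the DTR is not yet
resolved because relinearization was deferred — from the terminal runs of
near-zero normalized depth, using the same logic the workflow applies to
spurious repeats: artifact bases are unsupported by reads. A call
requires an adapter hit (semi-global match, edit distance
`<= 0.15 × adapter length`, both orientations) *or* the inverted-partner
signature (`revComp(left) ≈ right`, identity ≥ 0.9); either alone
suffices and both are recorded. `trimTerminalFlanks()` removes the called
intervals and is idempotent.

`findTandemArtifacts()` scans for adjacent near-identical copy pairs
(unit 20–500 bp, mismatch fraction ≤ 0.05) starting within 2 kb of a
terminus or DTR boundary; shifted same-unit candidates collapse to the
best-matching one and sub-repeats of longer reported units are
suppressed. The artifact test is **junction support**
(`junctionSupport()`): the number of reads whose alignment covers
`junction ± 50 bp` contiguously — no clip inside, no deletion of half a
unit or more, at most 5 indel events. Depth inside a false duplication
depends on the mapper's multi-mapping policy; junction spanning is
mapper-robust. `callTandemVerdict()` calls `ARTIFACT` only when support
is below 2 *and* local depth is at least 5 (otherwise `UNDETERMINED` —
there is not enough data to judge); `collapseTandemArtifact()` removes
the second copy and refuses to edit anything not called `ARTIFACT`. An
artifact overlapping a DTR copy is flagged but not auto-collapsed by
default (`collapseInDtr = FALSE`).

### Residual-error scan

`pileupCounts()` tallies per-position alleles by CIGAR walk (insertions
keyed to the gap after a position, deletions to their first deleted
position) and `discordanceScan()` flags sites where a non-reference
allele reaches 70% of at least 10 covering reads, annotated with the
longest homopolymer run overlapping position ±2. The 0.7 default is
deliberately high: true assembly errors show near-unanimous read
disagreement, sequencing noise does not. The scan *flags* sites rather
than editing the consensus — polishing from a single read set inside the
curation step would duplicate (badly) what dedicated polishers do, and
the value here is verification.

### Pipeline order

`curate()` runs: (1) depth and terminus signal; (2) DTR resolution and
relinearization — but *deferred* when the terminal 200 bp contain adapter
hits, because rotating a flanked contig would move the artifacts into the
genome interior; (3) flank detection and trimming; (4) tandem-artifact
detection and collapse (right-to-left so stored coordinates stay valid);
(5) re-resolution, applying any deferred relinearization, with a warning
if the result is not self-repeat-finished; (6) discordance scan; (7)
reorientation to the canonical start anchor (semi-global search on both
strands; found only on the reverse strand means the assembly is flipped).
Real manual curations order these steps per genome; this fixed order is
one consistent choice and every edit is recorded in a replayable report
(`replayEdits()` reproduces the output byte-exactly from the original
contig).

## The simulator and what it does (and does not) emulate

`simConfig()` defaults describe the study conditions: a 41,642 bp genome
at GC 0.5264 with a 181 bp DTR, a canonical start motif planted at
position 0 (the conserved start of these phages lies at the DTR start),
64 bp flanks with a 23 bp adapter core, and a 79 bp tandem unit placed
300 bp from the left terminus. The shipped adapters and anchor are
synthetic placeholders — the artifact dimensions, not the vendor
sequences, are what matters to the detectors.

Long reads model sequencing of a linear molecule: the start is uniform
over `[-(len-1), G-1]` and the read is clipped at the physical ends, so
terminal bases receive full coverage — every molecule end yields an
end-anchored fragment. (A uniform-start-in-`[0, G)` model would leave a
coverage ramp of one read length at each terminus and could not produce
the 2x collapsed-DTR signal at all with reads much longer than the
repeat.) Read lengths are truncated Normal (defaults 5,000 ± 1,500 bp,
minimum 500); errors are applied per base — substitutions, then indels,
with the indel rate multiplied inside homopolymer runs of ≥ 3 — and
default to zero so that tests of the curation logic are exact; realistic
rates are a configuration away. Short reads are 150 bp pairs whose
fragments are rejected within `endExclusionZone = 10` bp of the ends,
emulating tagmentation end-loss (the physical ends are systematically
missed while most of the DTR interior is captured). The zone's real
magnitude is not documented anywhere we know of; 10 bp is a modelling
choice.

Truth placements are emitted directly as SAM rather than via an external
aligner, keeping tests hermetic. A read whose truth interval maps
discontinuously onto the defective contig (the collapsed-DTR fold, a
duplication jump, the rotation cut) is emitted as one *primary* record
per contiguously-mapped segment with soft clips for the rest — this is
how the doubled-depth signal arises while depth still excludes
secondary/supplementary records, and it automatically gives spurious
duplications zero junction support. Two aspects are deliberately
idealized and worth keeping in mind when extrapolating to real data:
signal-level nanopore error structure (quality strings are constant) and
mapper behaviour (a real aligner may place DTR-spanning reads
differently, e.g. as supplementary alignments). When the underlying
contig is DTR-finished, the flank base adjacent to the genome is
constrained not to extend the terminal repeat: without that constraint
the true flank extent would be ambiguous *in principle* (the repeat would
genuinely be one base longer), and no detector could be exact.

## Worked example

```{r example}
cfg <- simConfig(genomeLength = 12000L, dtrLength = 181L, seed = 42L,
                 longRead = list(meanLen = 2000, sdLen = 500,
                                 minLen = 300))
truth <- generateGenome(cfg)
inj <- injectDefects(truth, list(defectMidOpen(6000L), defectTandemDup(),
                                 defectTerminalFlank()))
reads <- sampleLongReads(truth, cfg, inj$contigId, nchar(inj$contigSeq),
                         inj$map, coverage = 200)
out <- curate(inj$contigSeq, reads$alignments,
              adapters = cfg@adapterSet,
              config = curationConfig(anchor = truth@anchor))
out$report
identical(out$seq, genomeSeq(truth))
```

## Numerical choices and degenerate inputs

* All internal coordinates are 0-based half-open; conversion happens only
  at the SAM (1-based POS) and report boundaries. Genomes are linear —
  no accessor wraps around; rotation logic lives in the termini stage.
* Input sequences are upper-cased, `U` becomes `T`, and IUPAC ambiguity
  codes other than `N` are rejected (these genomes are plain dsDNA).
* A flat profile with no self-repeat is a reportable "no DTR" state, not
  an error; an all-zero profile cannot be segmented and says so.
* Ambiguous multi-peak signals proceed with the highest-mean region under
  a logged warning; ties break by leftmost start, keeping output
  deterministic.
* An opening offset *inside* the DTR itself (offset < D) splits the
  repeat across both contig ends; the pipeline reports the ambiguous
  two-region signal rather than attempting the repair, and the
  relinearization identity is therefore guaranteed for offsets ≥ D.
* Problem sizes in the test suite: genome-scale scenarios run at the
  published dimensions (~41 kb, 200x) where the quantities under test are
  the published ones, and at 6–12 kb for property sweeps (exhaustive
  rotation offsets, multi-seed recovery), keeping the full suite in the
  low minutes.

## Limitations

Termini that are not direct terminal repeats — cos sites, pac headful
packaging, host-fragment ends — are out of scope; dedicated terminus
predictors cover those. The package consumes assemblies and alignments;
it does not run assemblers or polishers, and its discordance scan
deliberately stops short of editing the consensus. Read-level adapter
trimming is likewise out of scope: the flank detector operates on the
assembly, where untrimmed adapter ends up when reads were not cleaned.
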