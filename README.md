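# phagecurate

Curation of linear phage genome assemblies with direct terminal repeats
(DTRs), for anyone finishing T7-like (podovirus) genomes from long- or
hybrid-read assemblies: resolve the genome termini from read coverage and
terminal self-repeat evidence, repair collapsed or mid-opened contigs, trim
terminal adapter/barcode artifacts, remove spurious tandem duplications
unsupported by reads, flag residual homopolymer indel errors, and reorient
the genome to a canonical start.

## The science in brief

Linear dsDNA phage chromosomes of the T7 type end in a direct terminal
repeat: an identical sequence of D ≈ 180–230 bp at both physical ends,
regenerated from concatemeric replication intermediates during packaging.
Because each virion carries the repeat twice, the DTR sequence is present
at twice the molar concentration of the rest of the genome. Assemblies
therefore come out in characteristic defective states, each with a
diagnostic signal:

| assembly state | diagnostic | repair |
|---|---|---|
| collapsed DTR (one copy) | terminal coverage peak at ~2x the median | duplicate the peak region to the opposite end |
| opened mid-genome | single internal ~2x peak | rotate so the repeat leads, append its copy |
| adapter/barcode flanks | terminal bases with no read support, inverted-repeat pair containing an adapter core | trim outside the DTR |
| spurious tandem duplication | adjacent near-identical copies with **zero junction-spanning reads** | delete the extra copy |
| residual homopolymer indel | near-unanimous read disagreement at one pileup position | flag for polishing |

Formally: with per-position depth d(i) and median m, elevated regions are
maximal runs with d(i)/m ≥ θ (default θ = 1.6, merging gaps ≤ 10 bp,
discarding runs < 50 bp). The terminal self-repeat is the maximal-scoring
co-linear substring pair (match +1, mismatch −4) with one copy in each
terminal window, subject to length ≥ 30 and divergence ≤ 2%. A tandem
candidate with junction support < 2 at local depth ≥ 5 is an artifact.
Discordant sites require an alternative allele fraction ≥ 0.7 at depth
≥ 10. A built-in simulator generates T7-like genomes, injects every defect
class with ground truth, and emits reads with truth-coordinate SAM
alignments, so the whole pipeline is testable hermetically.

## Worked example

Simulate a 12 kb phage genome with a 181 bp DTR, break it three ways
(opened mid-genome, 79 bp spurious duplication, 64 bp adapter flanks), and
curate it back:

```r
library(phagecurate)

cfg   <- simConfig(genomeLength = 12000L, dtrLength = 181L, seed = 42L,
                   longRead = list(meanLen = 2000, sdLen = 500, minLen = 300))
truth <- generateGenome(cfg)
inj   <- injectDefects(truth, list(defectMidOpen(6000L), defectTandemDup(),
                                   defectTerminalFlank()))
reads <- sampleLongReads(truth, cfg, inj$contigId, nchar(inj$contigSeq),
                         inj$map, coverage = 200)
out   <- curate(inj$contigSeq, reads$alignments, adapters = cfg@adapterSet,
                config = curationConfig(anchor = truth@anchor))
out$report
#> CurationReport: 'contig' (12026 bp) -> 'contig_curated' (12000 bp), 3 edit(s), 0 discordant site(s)
#>   trim_flanks: 12026 -> 11898 bp
#>   collapse_tandem: 11898 -> 11819 bp
#>   relinearize: 11819 -> 12000 bp
#>   warning: relinearization deferred: terminal adapter hits present
identical(out$seq, genomeSeq(truth))
#> [1] TRUE
```

Reading the report: the 12,026 bp input carried two 64 bp flanks (trimmed:
−128 bp), one spurious 79 bp duplication (collapsed: −79 bp), and had been
opened mid-genome with its DTR collapsed, so relinearization rotated the
contig and restored the second 181 bp repeat copy (+181 bp), arriving at
the true 12,000 bp genome byte-exactly. Relinearization was initially
deferred because adapter sequence sat at the termini — rotating first
would have moved the artifacts into the genome. The report replays:
`replayEdits(inj$contigSeq, out$report)` reproduces `out$seq` exactly.

A command-line interface wraps the same functions
(`system.file("exec", "phagecurate", package = "phagecurate")`) with
subcommands `simulate`, `curate`, `dtr` and `report`.

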