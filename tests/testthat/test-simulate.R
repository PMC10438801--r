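# Simulator: genome construction, defect injection, read sampling.

smallCfg <- function(seed = 7L, ...) {
  simConfig(genomeLength = 6000L, dtrLength = 120L, gcTarget = 0.52,
            seed = seed,
            longRead = list(meanLen = 1200, sdLen = 300, minLen = 200), ...)
}

test_that("generated genomes carry an exact DTR and hit the GC target", {
  cfg <- simConfig(genomeLength = 1000L, dtrLength = 50L, seed = 1L,
                   anchorMotif = "")
  tr <- generateGenome(cfg)
  s <- genomeSeq(tr)
  expect_equal(nchar(s), 1000L)
  expect_identical(substr(s, 1, 50), substr(s, 951, 1000))

  tr2 <- generateGenome(cfg)
  expect_identical(genomeSeq(tr2), s)   # byte-identical under a fixed seed

  cfg0 <- simConfig(genomeLength = 1000L, dtrLength = 0L, seed = 2L,
                    anchorMotif = "")
  tr0 <- generateGenome(cfg0)
  expect_null(findTerminalSelfRepeat(genomeSeq(tr0), window = 400L))

  big <- generateGenome(simConfig(seed = 3L))   # study defaults
  expect_equal(gcContent(genomeSeq(big)), 0.5264, tolerance = 0.01 / 0.5264)
  expect_true(startsWith(genomeSeq(big), big@anchor))
})

test_that("configuration invariants are enforced", {
  expect_error(simConfig(genomeLength = 100L, dtrLength = 50L,
                         anchorMotif = ""), "dtrLength")
  expect_error(simConfig(gcTarget = 1.2), "gcTarget")
  expect_error(simConfig(longRead = list(subRate = 2)), "rates")
  expect_error(generateGenome(simConfig(genomeLength = 100L,
                                        dtrLength = 20L,
                                        anchorMotif = strrep("A", 80))),
               "anchorMotif")
})

test_that("defect injection matches hand-built constructions", {
  tr <- truthSet("GGACATGG", dtrLength = 2L)
  col <- injectDefects(tr, list(defectCollapsedDtr()))
  expect_equal(col$contigSeq, "GGACAT")
  expect_equal(col$map, c(0:5, 0:1))

  mo <- injectDefects(tr, list(defectMidOpen(3L)))
  expect_equal(mo$contigSeq, "CATGGA")
  # rotating back by the recorded offset recovers the circle
  expect_equal(relinearize(mo$contigSeq, 3L, 5L, "INTERNAL"), "GGACATGG")

  expect_error(injectDefects(tr, list(defectCollapsedDtr(),
                                      defectMidOpen(2L))),
               "mutually exclusive")
  expect_error(injectDefects(tr, list()), "no defects")
})

test_that("terminal flank injection adds inverted-repeat flanks with an adapter core", {
  cfg <- smallCfg()
  tr <- generateGenome(cfg)
  inj <- injectDefects(tr, list(defectTerminalFlank()))
  G <- nchar(genomeSeq(tr))
  expect_equal(nchar(inj$contigSeq), G + 128L)
  d <- inj$defects[[1]]
  expect_equal(d$flankLen, 64L)
  expect_equal(d$coreLen, 23L)
  left <- substr(inj$contigSeq, 1, 64)
  right <- substr(inj$contigSeq, G + 65, G + 128)
  expect_identical(revComp(left), right)
  core <- substr(cfg@adapterSet[[d$adapterId]], 1, d$coreLen)
  expect_true(grepl(core, left, fixed = TRUE))
  expect_identical(substr(inj$contigSeq, 65, G + 64), genomeSeq(tr))
})

test_that("homopolymer indel injection edits one base inside a run", {
  cfg <- smallCfg(seed = 9L)
  tr <- generateGenome(cfg)
  inj <- injectDefects(tr, list(defectHomopolymerIndel("ins")))
  d <- inj$defects[[1]]
  expect_equal(nchar(inj$contigSeq), nchar(genomeSeq(tr)) + 1L)
  expect_gte(d$runLength, 4L)
  expect_equal(substr(inj$contigSeq, d$position + 1L, d$position + 1L),
               d$base)
  del <- injectDefects(tr, list(defectHomopolymerIndel("del")))
  expect_equal(nchar(del$contigSeq), nchar(genomeSeq(tr)) - 1L)
})

test_that("error-free long reads are exact substrings with full-span placements", {
  cfg <- smallCfg()
  tr <- generateGenome(cfg)
  lr <- sampleLongReads(tr, cfg, coverage = 20)
  pl <- lr$placements
  expect_true(all(pl$start >= 0 & pl$end <= nchar(genomeSeq(tr))))
  for (i in sample(nrow(pl), 25)) {
    frag <- substr(genomeSeq(tr), pl$start[i] + 1L, pl$end[i])
    got <- lr$reads$seq[lr$reads$id == pl$id[i]]
    expect_identical(got, if (pl$strand[i] == "-") revComp(frag) else frag)
  }
  d <- alignmentData(lr$alignments)
  expect_true(all(grepl("^[0-9]+M$", d$cigar)))   # identity placements
  expect_error(sampleLongReads(tr, simConfig(genomeLength = 6000L,
                                             dtrLength = 120L,
                                             longRead = list(count = 0L))),
               "at least one read")
})

test_that("collapsed-DTR projection doubles depth over the surviving copy", {
  ratios <- vapply(1:5, function(seed) {
    cfg <- simConfig(genomeLength = 20000L, dtrLength = 181L, seed = seed,
                     longRead = list(meanLen = 2000, sdLen = 500,
                                     minLen = 300))
    tr <- generateGenome(cfg)
    inj <- injectDefects(tr, list(defectCollapsedDtr()))
    lr <- sampleLongReads(tr, cfg, inj$contigId, nchar(inj$contigSeq),
                          inj$map, coverage = 200)
    prof <- depthFromAlignments(nchar(inj$contigSeq), lr$alignments)
    mean(normalizedDepth(prof)[1:181])
  }, numeric(1))
  expect_true(all(ratios >= 1.75 & ratios <= 2.25))
})

test_that("short reads respect the end exclusion zone yet cover the DTR interior", {
  cfg <- smallCfg()
  tr <- generateGenome(cfg)
  G <- nchar(genomeSeq(tr))
  srs <- sampleShortReads(tr, cfg, coverage = 50)
  pl <- srs$placements
  expect_true(all(pl$start >= 10L))
  expect_true(all(pl$end <= G - 10L))
  prof <- depthFromAlignments(G, srs$alignments)
  # tagmentation end-loss: the physical ends are missed but the majority
  # of the DTR interior is captured (deep beyond the edge ramp)
  interior <- depthValues(prof)[11:120]
  expect_gt(mean(interior > 0L), 0.5)
  expect_true(all(depthValues(prof)[61:120] > 0L))
  expect_error(
    sampleShortReads(tr, simConfig(genomeLength = 6000L, dtrLength = 120L,
                                   shortRead = list(endExclusionZone = 3000L,
                                                    pairs = 10L))),
    "no room")
})

test_that("simulateToFiles writes a coherent, reloadable bundle", {
  dir <- withr::local_tempdir()
  cfg <- smallCfg()
  paths <- simulateToFiles(cfg, list(defectCollapsedDtr()), dir,
                           longCoverage = 10, shortCoverage = 5)
  truth <- readFasta(paths$truth_fasta)
  contig <- readFasta(paths$contig_fasta)
  expect_equal(unname(BiocGenerics::width(truth)), 6000L)
  expect_equal(unname(BiocGenerics::width(contig)), 6000L - 120L)
  aln <- readSam(paths$long_sam)
  expect_gt(length(aln), 0L)
  man <- jsonlite::read_json(paths$manifest)
  expect_equal(man$defects[[1]]$kind, "COLLAPSED_DTR")
  bed <- read.table(paths$dtr_bed, sep = "\t")
  expect_equal(bed$V2, c(0L, 6000L - 120L))
})
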