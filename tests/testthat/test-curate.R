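# The full pipeline: stage ordering, audit trail, determinism, report
# serialization.

curateFixture <- function(seed, defects, coverage = 200,
                          G = 9000L, D = 150L) {
  cfg <- simConfig(genomeLength = G, dtrLength = D, seed = seed,
                   longRead = list(meanLen = 1500, sdLen = 400,
                                   minLen = 250))
  tr <- generateGenome(cfg)
  if (length(defects)) {
    inj <- injectDefects(tr, defects)
  } else {
    inj <- list(contigId = "fin", contigSeq = genomeSeq(tr), map = NULL)
  }
  lr <- sampleLongReads(tr, cfg, inj$contigId, nchar(inj$contigSeq),
                        inj$map, coverage = coverage)
  list(cfg = cfg, tr = tr, inj = inj, aln = lr$alignments)
}

test_that("a finished artifact-free genome passes through with zero edits", {
  fx <- curateFixture(51L, list())
  out <- curate(fx$inj$contigSeq, fx$aln,
                config = curationConfig(anchor = fx$tr@anchor))
  expect_equal(length(curationActions(out$report)), 0L)
  expect_identical(out$seq, genomeSeq(fx$tr))
  expect_equal(out$report@discordantCount, 0L)
  expect_equal(dtrLength(out$report@dtr), 150L)
})

test_that("the full defect cocktail is repaired byte-exactly at error rate 0", {
  fx <- curateFixture(52L, list(defectMidOpen(4500L), defectTandemDup(),
                                defectTerminalFlank()))
  out <- curate(fx$inj$contigSeq, fx$aln, adapters = fx$cfg@adapterSet,
                config = curationConfig(anchor = fx$tr@anchor))
  expect_identical(out$seq, genomeSeq(fx$tr))
  types <- vapply(curationActions(out$report), `[[`, character(1), "type")
  expect_equal(types, c("trim_flanks", "collapse_tandem", "relinearize"))
  # audit trail: replaying the recorded edits reproduces the output
  expect_identical(replayEdits(fx$inj$contigSeq, out$report), out$seq)
})

test_that("a collapsed contig behind adapter flanks is fully restored", {
  fx <- curateFixture(53L, list(defectCollapsedDtr(),
                                defectTerminalFlank()))
  out <- curate(fx$inj$contigSeq, fx$aln, adapters = fx$cfg@adapterSet,
                config = curationConfig(anchor = fx$tr@anchor))
  expect_identical(out$seq, genomeSeq(fx$tr))
  expect_equal(out$report@finalLength, 9000L)
  expect_true(any(grepl("deferred", out$report@warnings)))
})

test_that("a reverse-orientation assembly is flipped back to the anchor", {
  fx <- curateFixture(54L, list())
  rcSeq <- revComp(fx$inj$contigSeq)
  d <- alignmentData(fx$aln)
  n <- nchar(rcSeq)
  span <- cigarRefSpan(d$cigar)
  d$ref_start <- n - (d$ref_start + span)
  d$strand <- ifelse(d$strand == "+", "-", "+")
  d$cigar <- vapply(d$cigar, function(cg) {
    p <- phagecurate:::.parseCigar(cg)
    paste0(rev(paste0(p$len, p$op)), collapse = "")
  }, character(1), USE.NAMES = FALSE)
  d$seq <- vapply(d$seq, revComp, character(1), USE.NAMES = FALSE)
  rcAln <- phageAlignments(d, stats::setNames(n, names(referenceLengths(fx$aln))))
  out <- curate(rcSeq, rcAln, config = curationConfig(anchor = fx$tr@anchor))
  expect_identical(out$seq, genomeSeq(fx$tr))
  types <- vapply(curationActions(out$report), `[[`, character(1), "type")
  expect_equal(types, "revcomp")
})

test_that("two runs with identical inputs produce identical outputs", {
  fx <- curateFixture(55L, list(defectCollapsedDtr()))
  out1 <- curate(fx$inj$contigSeq, fx$aln,
                 config = curationConfig(anchor = fx$tr@anchor))
  out2 <- curate(fx$inj$contigSeq, fx$aln,
                 config = curationConfig(anchor = fx$tr@anchor))
  expect_identical(out1$seq, out2$seq)
  expect_identical(out1$report@actions, out2$report@actions)
})

test_that("curation reports serialize to JSON and reload losslessly", {
  fx <- curateFixture(56L, list(defectCollapsedDtr(),
                                defectTerminalFlank()))
  out <- curate(fx$inj$contigSeq, fx$aln, adapters = fx$cfg@adapterSet,
                config = curationConfig(anchor = fx$tr@anchor),
                contigId = "phi1")
  f <- withr::local_tempfile(fileext = ".json")
  writeCurationReport(out$report, f)
  back <- readCurationReport(f)
  expect_equal(back@inputId, "phi1")
  expect_equal(back@inputLength, out$report@inputLength)
  expect_equal(back@finalLength, out$report@finalLength)
  expect_equal(dtrLength(back@dtr), dtrLength(out$report@dtr))
  expect_equal(length(back@actions), length(out$report@actions))
  # the reloaded report still replays to the same output
  expect_identical(replayEdits(fx$inj$contigSeq, back), out$seq)
})

test_that("final length reconciles with the recorded edits", {
  fx <- curateFixture(57L, list(defectMidOpen(3000L),
                                defectTerminalFlank()))
  out <- curate(fx$inj$contigSeq, fx$aln, adapters = fx$cfg@adapterSet,
                config = curationConfig(anchor = fx$tr@anchor))
  len <- out$report@inputLength
  for (a in curationActions(out$report)) {
    expect_equal(a$before_length, len)
    len <- a$after_length
  }
  expect_equal(len, out$report@finalLength)
})
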