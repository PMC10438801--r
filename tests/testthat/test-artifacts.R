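# Terminal flank artifacts and spurious tandem duplications.

test_that("flank detection is empty on a finished genome and exact on a flanked one", {
  cfg <- simConfig(genomeLength = 6000L, dtrLength = 120L, seed = 7L,
                   longRead = list(meanLen = 1200, sdLen = 300,
                                   minLen = 200))
  tr <- generateGenome(cfg)
  fin <- resolveDtr(genomeSeq(tr), NULL)
  expect_equal(nrow(findTerminalFlanks(genomeSeq(tr), fin@annotation,
                                       cfg@adapterSet)), 0L)

  inj <- injectDefects(tr, list(defectTerminalFlank()))
  res <- resolveDtr(inj$contigSeq, NULL)
  expect_equal(res@status, "INSET")
  fl <- findTerminalFlanks(inj$contigSeq, res@annotation, cfg@adapterSet)
  expect_equal(nrow(fl), 2L)
  expect_equal(fl$end - fl$start, c(64L, 64L))
  expect_equal(fl$core_end - fl$core_start, c(23L, 23L))
  expect_true(all(fl$inverted_partner))
  expect_true(all(fl$revcomp_identity >= 0.9))

  tr2 <- trimTerminalFlanks(inj$contigSeq, fl)
  expect_identical(tr2$seq, genomeSeq(tr))
  # idempotent: nothing left to detect after the trim
  res2 <- resolveDtr(tr2$seq, NULL)
  expect_equal(nrow(findTerminalFlanks(tr2$seq, res2@annotation,
                                       cfg@adapterSet)), 0L)
})

test_that("an adapter hit with edits within the budget is retained", {
  cfg <- simConfig(genomeLength = 6000L, dtrLength = 120L, seed = 8L)
  tr <- generateGenome(cfg)
  inj <- injectDefects(tr, list(defectTerminalFlank()))
  s <- inj$contigSeq
  co <- inj$defects[[1]]$coreOffset
  # introduce 2 substitutions inside the 23 bp left adapter core
  for (p in co + c(3L, 9L)) {
    old <- substr(s, p + 1, p + 1)
    substr(s, p + 1, p + 1) <- setdiff(c("A", "C", "G", "T"), old)[1]
  }
  res <- resolveDtr(s, NULL)
  fl <- findTerminalFlanks(s, res@annotation, cfg@adapterSet,
                           maxEditFrac = 0.15)   # budget floor(3.45) = 3
  left <- fl[fl$side == "LEFT", ]
  expect_equal(nrow(left), 1L)
  expect_false(is.na(left$adapter_id))
})

test_that("flank trimming validates its calls and preserves interior bases", {
  calls <- data.frame(side = c("LEFT", "RIGHT"), start = c(0L, 10L),
                      end = c(2L, 12L))
  out <- trimTerminalFlanks("XXGGACATGGYY", calls)
  expect_equal(out$seq, "GGACATGG")
  none <- trimTerminalFlanks("XXGGACATGGYY",
                             data.frame(side = character(0),
                                        start = integer(0),
                                        end = integer(0)))
  expect_equal(none$seq, "XXGGACATGGYY")
  expect_error(trimTerminalFlanks("ACGTACGT",
                                  data.frame(side = "LEFT", start = 1L,
                                             end = 3L)), "position 0")
  expect_error(trimTerminalFlanks("ACGT",
                                  data.frame(side = c("LEFT", "RIGHT"),
                                             start = c(0L, 1L),
                                             end = c(3L, 4L))), "overlap")
})

test_that("tandem scan finds planted adjacent duplications", {
  set.seed(3)
  s <- paste0(randSeq(30), "ACGTACGT", randSeq(30))
  cand <- findTandemArtifacts(s, unitRange = c(3L, 10L), wholeSeq = TRUE)
  # short units can also occur by chance in the random context; the
  # planted duplication must be among the calls
  expect_true(any(cand$start1 == 30L & cand$unit_length == 4L))

  expect_equal(nrow(findTandemArtifacts(randSeq(200),
                                        unitRange = c(10L, 40L),
                                        wholeSeq = TRUE)), 0L)
})

test_that("tandem scan agrees with the brute-force all-pairs oracle", {
  set.seed(19)
  for (k in 1:60) {
    n <- sample(60:120, 1)
    s <- randSeq(n)
    if (k %% 3 != 0) {
      u <- sample(8:20, 1)
      i <- sample(0:(n - 2 * u), 1)
      unit <- randSeq(u)
      substr(s, i + 1, i + u) <- unit
      substr(s, i + u + 1, i + 2 * u) <- unit
    }
    got <- findTandemArtifacts(s, unitRange = c(8L, 25L),
                               maxDivergence = 0.05, wholeSeq = TRUE)
    want <- oracleTandem(s, c(8L, 25L), 0.05)
    expect_equal(got$start1, want$start1)
    expect_equal(got$unit_length, want$unit)
    expect_equal(round(got$divergence * got$unit_length), want$ham)
  }
})

test_that("junction support counts contiguously spanning reads only", {
  cand <- data.frame(start1 = 100L, end1 = 179L, start2 = 179L,
                     end2 = 258L, unit_length = 79L, divergence = 0)
  mk <- function(...) toyAlignments("c", 400L, ...)
  spanning <- lapply(1:5, function(i) list(start = 100L, cigar = "160M"))
  expect_equal(junctionSupport(cand, do.call(mk, spanning)), 5L)

  short <- lapply(1:5, function(i) list(start = 60L, cigar = "110M"))
  expect_equal(junctionSupport(cand, do.call(mk, short)), 0L)

  # 10 spanning reads of which 4 carry a deletion >= unit/2 in the window
  mixed <- c(lapply(1:6, function(i) list(start = 100L, cigar = "160M")),
             lapply(1:4, function(i)
               list(start = 100L, cigar = "70M45D90M")))
  expect_equal(junctionSupport(cand, do.call(mk, mixed)), 6L)

  # soft-clipped at the junction: the clip breaks contiguity
  clipped <- lapply(1:3, function(i) list(start = 100L, cigar = "79M81S"))
  expect_equal(junctionSupport(cand, do.call(mk, clipped)), 0L)

  expect_error(junctionSupport(data.frame(start1 = 0L, end1 = 20L,
                                          start2 = 20L, end2 = 40L,
                                          unit_length = 20L,
                                          divergence = 0),
                               do.call(mk, spanning)), "bounds")
})

test_that("tandem verdicts follow the support/depth decision table", {
  cand <- data.frame(start1 = 10L, end1 = 14L, start2 = 14L, end2 = 18L,
                     unit_length = 4L, divergence = 0)
  expect_equal(callTandemVerdict(cand, 0L, 50)$verdict, "ARTIFACT")
  expect_equal(callTandemVerdict(cand, 10L, 50)$verdict, "SUPPORTED")
  expect_equal(callTandemVerdict(cand, 0L, 2)$verdict, "UNDETERMINED")
})

test_that("collapsing removes one copy and refuses supported duplications", {
  s <- "AAACGTACGTTT"
  cand <- findTandemArtifacts(s, unitRange = c(3L, 6L), wholeSeq = TRUE)
  call <- callTandemVerdict(cand[1, ], 0L, 50)
  out <- collapseTandemArtifact(s, call)
  expect_equal(out, "AAACGTTT")
  # untouched bases outside the removed copy
  expect_equal(substr(out, 1, call$end1), substr(s, 1, call$end1))
  # idempotent: the duplication is gone
  expect_equal(nrow(findTandemArtifacts(out, unitRange = c(3L, 6L),
                                        wholeSeq = TRUE)), 0L)
  sup <- callTandemVerdict(cand[1, ], 10L, 50)
  expect_error(collapseTandemArtifact(s, sup), "refusing")
})

test_that("an injected 79 bp duplication without junction reads is collapsed", {
  cfg <- simConfig(genomeLength = 9000L, dtrLength = 150L, seed = 15L,
                   longRead = list(meanLen = 1500, sdLen = 400,
                                   minLen = 250))
  tr <- generateGenome(cfg)
  inj <- injectDefects(tr, list(defectTandemDup()))
  lr <- sampleLongReads(tr, cfg, inj$contigId, nchar(inj$contigSeq),
                        inj$map, coverage = 60)
  cand <- findTandemArtifacts(inj$contigSeq)
  expect_equal(cand$unit_length, 79L)
  sup <- junctionSupport(cand[1, ], lr$alignments)
  expect_equal(sup, 0L)
  prof <- depthFromAlignments(nchar(inj$contigSeq), lr$alignments)
  dep <- mean(depthValues(prof)[(cand$start1[1] + 1):cand$end2[1]])
  call <- callTandemVerdict(cand[1, ], sup, dep)
  expect_equal(call$verdict, "ARTIFACT")
  expect_identical(collapseTandemArtifact(inj$contigSeq, call),
                   genomeSeq(tr))
})
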