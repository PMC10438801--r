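# Terminal self-repeat search, DTR resolution, relinearization,
# reorientation.

test_that("terminal self-repeat search matches hand-checked examples", {
  hit <- findTerminalSelfRepeat("ACGTTTTTACGT", window = 4L, minLen = 4L)
  expect_equal(hit$left, c(0L, 4L))
  expect_equal(hit$right, c(8L, 12L))
  expect_equal(hit$identity, 1.0)

  expect_null(findTerminalSelfRepeat("AAAATTTT", window = 4L, minLen = 3L))
  expect_error(findTerminalSelfRepeat("ACGTACGT", window = 6L), "window")
})

test_that("self-repeat search agrees with the brute-force all-pairs oracle", {
  set.seed(31)
  for (k in 1:40) {
    n <- sample(80:160, 1)
    w <- sample(20:35, 1)
    s <- randSeq(n)
    if (k %% 2 == 0) {
      # plant a repeat of length ~ [10, w] at random offsets in each window
      L <- sample(10:w, 1)
      i <- sample(0:(w - L), 1)
      j <- sample((n - w):(n - L), 1)
      rep <- randSeq(L)
      substr(s, i + 1, i + L) <- rep
      substr(s, j + 1, j + L) <- rep
    }
    got <- findTerminalSelfRepeat(s, window = w, minLen = 10L,
                                  maxDivergence = 0.05)
    want <- oracleSelfRepeat(s, w, 10L, 0.05)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_false(is.null(got))
      sc <- (got$length - got$mismatches) - 4 * got$mismatches
      expect_equal(sc, want$score[1])
      if (nrow(want) == 1L) {
        expect_equal(got$left[1], want$i)
        expect_equal(got$right[1], want$j)
        expect_equal(got$length, want$L)
      }
    }
  }
})

test_that("self-repeat search tolerates low divergence between copies", {
  set.seed(77)
  core <- randSeq(5000)
  rep <- randSeq(180)
  mut <- rep
  pos <- sample(20:160, 2)
  for (p in pos) substr(mut, p, p) <- setdiff(c("A", "C", "G", "T"),
                                              substr(mut, p, p))[1]
  s <- paste0(rep, core, mut)
  hit <- findTerminalSelfRepeat(s, window = 500L)
  expect_equal(hit$length, 180L)
  expect_equal(hit$mismatches, 2L)
  expect_equal(hit$left, c(0L, 180L))
})

test_that("relinearization reconstructs the two-copy form", {
  expect_equal(relinearize("CATGGA", 3L, 5L, "INTERNAL"), "GGACATGG")
  expect_equal(relinearize("GGACAT", 0L, 2L, "LEFT"), "GGACATGG")
  expect_equal(relinearize("GGACAT", 4L, 6L, "RIGHT"), "ATGGACAT")
  expect_error(relinearize("GGACAT", 0L, 6L, "INTERNAL"), "whole contig")
  expect_error(relinearize("GGACAT", 2L, 9L, "INTERNAL"), "bounds")
})

test_that("relinearize inverts MID_OPEN injection for every valid offset", {
  set.seed(13)
  for (rep in 1:3) {
    D <- sample(3:8, 1)
    L <- sample((2 * D + 2):40, 1)
    core <- randSeq(L)
    g <- paste0(core, substr(core, 1, D))
    tr <- truthSet(g, D)
    for (p in D:(L - 1)) {
      inj <- injectDefects(tr, list(defectMidOpen(p)))
      rs <- (0 - p) %% L          # contig position of the DTR start
      out <- if (rs + D < L)
        relinearize(inj$contigSeq, rs, rs + D, "INTERNAL")
      else
        relinearize(inj$contigSeq, rs, L, "RIGHT")
      expect_identical(out, g)
    }
  }
})

test_that("DTR resolution distinguishes finished, collapsed and mid-open contigs", {
  cfg <- simConfig(genomeLength = 9000L, dtrLength = 150L, seed = 21L,
                   longRead = list(meanLen = 1500, sdLen = 400,
                                   minLen = 250))
  tr <- generateGenome(cfg)
  G <- nchar(genomeSeq(tr))

  lr0 <- sampleLongReads(tr, cfg, coverage = 100)
  prof0 <- depthFromAlignments(G, lr0$alignments)
  fin <- resolveDtr(genomeSeq(tr), prof0)
  expect_equal(fin@status, "FINISHED")
  expect_equal(dtrLength(fin@annotation), 150L)
  expect_equal(fin@annotation@evidence, "SELF_REPEAT")

  injC <- injectDefects(tr, list(defectCollapsedDtr()))
  lrC <- sampleLongReads(tr, cfg, injC$contigId, nchar(injC$contigSeq),
                         injC$map, coverage = 200)
  profC <- depthFromAlignments(nchar(injC$contigSeq), lrC$alignments)
  col <- resolveDtr(injC$contigSeq, profC)
  expect_equal(col@status, "RELINEARIZE_LEFT")
  expect_equal(col@regionStart, 0L)
  expect_equal(col@regionEnd, 150L)

  injM <- injectDefects(tr, list(defectMidOpen(4000L)))
  lrM <- sampleLongReads(tr, cfg, injM$contigId, nchar(injM$contigSeq),
                         injM$map, coverage = 200)
  profM <- depthFromAlignments(nchar(injM$contigSeq), lrM$alignments)
  mid <- resolveDtr(injM$contigSeq, profM)
  expect_equal(mid@status, "RELINEARIZE_INTERNAL")
  L <- G - 150L
  expect_equal(mid@regionStart, (0L - 4000L) %% L)
  expect_equal(mid@regionEnd, (0L - 4000L) %% L + 150L)

  none <- resolveDtr(genomeSeq(tr), NULL, window = 800L)
  expect_equal(none@status, "FINISHED")   # sequence-only still finds it
  noDtr <- resolveDtr(randSeq(4000), NULL)
  expect_equal(noDtr@status, "NO_DTR")
})

test_that("reorientation restores the canonical strand byte-exactly", {
  set.seed(41)
  anchor <- "ATTCGTGGCATCCTTAGGACC"
  g <- paste0(anchor, randSeq(800))
  expect_equal(reorient(g, anchor)$action, "NONE")
  ro <- reorient(revComp(g), anchor)
  expect_equal(ro$action, "REVCOMP")
  expect_identical(ro$seq, g)

  miss <- reorient(randSeq(500), anchor)
  expect_equal(miss$action, "NONE")
  expect_match(miss$warnings, "not found")

  both <- paste0(anchor, randSeq(300), revComp(anchor))
  expect_error(reorient(both, anchor), "both strands")
  expect_error(reorient(g, "ACGTACGT"), "at least 15")
})
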