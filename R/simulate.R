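# Simulator of T7-like phage genomes with direct terminal repeats (DTRs),
# assembly-defect injection, and long/short read sampling with
# truth-coordinate SAM placements. Every detector in the package is
# validated against this ground truth.

.BASES <- c("A", "C", "G", "T")

# Run code under a fixed seed without disturbing the caller's RNG stream.
.withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Synthetic adapter sequences (placeholders, not vendor adapters): the study
# conditions fix the adapter core length at 23 bp but not its sequence.
.DEFAULT_ADAPTERS <- c(
  synthetic_adapter_A = "CAGCACCTTGGTAGGTTCAACAC",
  synthetic_adapter_B = "GGTGCTGAACCTTCAACGGTTACA")

# Canonical start motif planted inside the left DTR (synthetic stand-in for
# the conserved przondovirus start).
.DEFAULT_ANCHOR <- "ATTCGTGGCATCCTTAGGACC"

#' Build a simulation configuration
#'
#' Defaults describe the study conditions: a 41,642 bp genome at GC 0.5264
#' with a 181 bp DTR; 64 bp terminal flanks carrying a 23 bp adapter core;
#' a 79 bp spurious tandem unit placed 300 bp from the left terminus.
#'
#' @param genomeLength Genome length G in bp.
#' @param dtrLength DTR length D in bp (0 disables the terminal repeat).
#' @param gcTarget GC fraction of the i.i.d. unique region.
#' @param anchorMotif Canonical start motif planted at position 0; "" for
#'   none.
#' @param seed Integer seed.
#' @param longRead List overriding any of \code{meanLen} (bp), \code{sdLen},
#'   \code{minLen}, \code{count}, \code{subRate}, \code{indelRate},
#'   \code{homopolymerIndelBoost}.
#' @param shortRead List overriding any of \code{readLen}, \code{insertMean},
#'   \code{insertSd}, \code{pairs}, \code{endExclusionZone} (bp suppressed at
#'   each physical end, emulating tagmentation end-loss).
#' @param adapterSet Named character vector of adapter sequences.
#' @param artifact List overriding any of \code{flankLen},
#'   \code{adapterCoreLen}, \code{tandemUnitLen}, \code{tandemPosOffset}.
#' @return A \linkS4class{SimulationConfig}.
#' @examples
#' cfg <- simConfig(genomeLength = 2000L, dtrLength = 100L, seed = 7L)
#' @export
simConfig <- function(genomeLength = 41642L, dtrLength = 181L,
                      gcTarget = 0.5264, anchorMotif = .DEFAULT_ANCHOR,
                      seed = 1L, longRead = list(), shortRead = list(),
                      adapterSet = .DEFAULT_ADAPTERS, artifact = list()) {
  lr <- utils::modifyList(list(meanLen = 5000, sdLen = 1500, minLen = 500,
                               count = NA_integer_, subRate = 0,
                               indelRate = 0, homopolymerIndelBoost = 3),
                          longRead)
  sr <- utils::modifyList(list(readLen = 150L, insertMean = 400,
                               insertSd = 50, pairs = NA_integer_,
                               endExclusionZone = 10L),
                          shortRead)
  ar <- utils::modifyList(list(flankLen = 64L, adapterCoreLen = 23L,
                               tandemUnitLen = 79L, tandemPosOffset = 300L),
                          artifact)
  new("SimulationConfig", genomeLength = as.integer(genomeLength),
      dtrLength = as.integer(dtrLength), gcTarget = gcTarget,
      anchorMotif = anchorMotif, seed = as.integer(seed), longRead = lr,
      shortRead = sr, adapterSet = adapterSet, artifact = ar)
}

#' Generate a truth genome with a direct terminal repeat
#'
#' The unique region is i.i.d. with \code{P(G)+P(C) = gcTarget}; the last D
#' bases are an exact copy of the first D bases (the DTR); the anchor motif,
#' if any, is planted at position 0 (the canonical start lies at the DTR
#' start). Deterministic and byte-identical given the seed.
#'
#' @param config A \linkS4class{SimulationConfig}.
#' @return A \linkS4class{TruthSet}.
#' @export
generateGenome <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  G <- config@genomeLength; D <- config@dtrLength
  .withSeed(config@seed, {
    U <- G - D
    gc <- config@gcTarget
    core <- sample(.BASES, U, replace = TRUE,
                   prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
    if (nzchar(config@anchorMotif)) {
      a <- strsplit(.normalizeSeq(config@anchorMotif, "anchor"), "")[[1L]]
      core[seq_along(a)] <- a
    }
    seqc <- if (D > 0L) c(core, core[seq_len(D)]) else core
    new("TruthSet", id = "sim_truth", seq = paste(seqc, collapse = ""),
        dtrLength = D, anchor = config@anchorMotif, config = config)
  })
}

#' Construct a truth set from an explicit sequence
#'
#' Useful for toy examples and tests; [generateGenome()] is the usual
#' source. The last \code{dtrLength} bases must equal the first
#' \code{dtrLength} bases exactly.
#'
#' @param seq Genome sequence (character scalar).
#' @param dtrLength DTR length D in bp.
#' @param id Genome identifier.
#' @param anchor Canonical start motif ("" for none).
#' @param config Optional \linkS4class{SimulationConfig}; defaults to a
#'   minimal configuration consistent with \code{seq}.
#' @return A \linkS4class{TruthSet}.
#' @export
truthSet <- function(seq, dtrLength, id = "truth", anchor = "",
                     config = NULL) {
  seq <- .normalizeSeq(seq, id)
  if (is.null(config))
    config <- simConfig(genomeLength = nchar(seq),
                        dtrLength = dtrLength, gcTarget = 0.5,
                        anchorMotif = anchor)
  new("TruthSet", id = id, seq = seq, dtrLength = as.integer(dtrLength),
      anchor = anchor, config = config)
}

## ---- defect constructors ---------------------------------------------------

.defect <- function(kind, ...) {
  structure(list(kind = kind, ...), class = "phagecurate_defect")
}

#' Assembly defect constructors
#'
#' Each constructor describes one defect class to be injected into an
#' "assembly" contig by [injectDefects()]:
#' \describe{
#'   \item{defectCollapsedDtr()}{the two DTR copies merged into one: the
#'     contig is the genome with the right copy removed, doubling read depth
#'     over the surviving copy.}
#'   \item{defectMidOpen(offset)}{the circularized unique+single-DTR form
#'     opened at internal offset \code{offset}, placing the DTR mid-contig.}
#'   \item{defectTerminalFlank()}{adapter/barcode flanks prepended and
#'     appended outside the genome; the right flank is the reverse
#'     complement of the left (an inverted-repeat pair), each containing an
#'     adapter core as a substring.}
#'   \item{defectTandemDup()}{a spurious adjacent duplication of a window
#'     near a terminus, unsupported by any read.}
#'   \item{defectHomopolymerIndel(mode)}{one base inserted into or deleted
#'     from a homopolymer run of length >= 4.}
#' }
#'
#' Parameters left \code{NULL} default to the configuration's
#' \code{artifact} block at injection time.
#'
#' @param offset 0-based opening offset into the circularized form
#'   (MID_OPEN).
#' @param unitLength,posOffset Tandem unit length and 0-based distance of
#'   the first copy from the left terminus.
#' @param flankLen,coreLen,coreOffset Flank length, adapter core length, and
#'   0-based core offset within the flank.
#' @param adapterId Name of the adapter in the configuration's
#'   \code{adapterSet} to embed.
#' @param mode \code{"ins"} or \code{"del"}.
#' @return A defect descriptor (opaque list) for [injectDefects()].
#' @name defects
NULL

#' @rdname defects
#' @export
defectCollapsedDtr <- function() .defect("COLLAPSED_DTR")

#' @rdname defects
#' @export
defectMidOpen <- function(offset) {
  .defect("MID_OPEN", offset = as.integer(offset))
}

#' @rdname defects
#' @export
defectTandemDup <- function(unitLength = NULL, posOffset = NULL) {
  .defect("TANDEM_DUP", unitLength = unitLength, posOffset = posOffset)
}

#' @rdname defects
#' @export
defectTerminalFlank <- function(flankLen = NULL, coreLen = NULL,
                                coreOffset = NULL, adapterId = NULL) {
  .defect("TERMINAL_FLANK", flankLen = flankLen, coreLen = coreLen,
          coreOffset = coreOffset, adapterId = adapterId)
}

#' @rdname defects
#' @export
defectHomopolymerIndel <- function(mode = c("ins", "del")) {
  .defect("HOMOPOLYMER_INDEL", mode = match.arg(mode))
}

## ---- defect injection ------------------------------------------------------

#' Inject assembly defects into a contig
#'
#' Starting from the truth genome, applies the requested defects in the
#' canonical order (mid-open/collapse, then tandem duplication, then
#' homopolymer indel, then terminal flanks) and maintains a truth-to-contig
#' coordinate map so that read samplers can place reads on the defective
#' contig. At most one of \code{COLLAPSED_DTR} and \code{MID_OPEN} is
#' allowed.
#'
#' @param truth A \linkS4class{TruthSet}.
#' @param defects List of defect descriptors (see [defects]).
#' @param seed Seed for the stochastic defect components (flank barcode
#'   bases); defaults to the truth configuration seed + 1.
#' @return List with elements \code{contigId}, \code{contigSeq},
#'   \code{defects} (completed records, each sufficient to reconstruct the
#'   edit), \code{map} (integer vector: 0-based truth position ->
#'   0-based contig position, \code{NA} where deleted), and \code{truth}.
#' @export
injectDefects <- function(truth, defects, seed = NULL) {
  stopifnot(is(truth, "TruthSet"))
  if (!length(defects)) stop("no defects supplied")
  kinds <- vapply(defects, `[[`, character(1), "kind")
  known <- c("COLLAPSED_DTR", "MID_OPEN", "TERMINAL_FLANK", "TANDEM_DUP",
             "HOMOPOLYMER_INDEL")
  if (!all(kinds %in% known))
    stop("unknown defect kind: ", setdiff(kinds, known)[1L])
  if (sum(kinds %in% c("COLLAPSED_DTR", "MID_OPEN")) > 1L)
    stop("COLLAPSED_DTR and MID_OPEN are mutually exclusive")
  cfg <- truth@config
  if (is.null(seed)) seed <- cfg@seed + 1L
  G <- nchar(truth@seq); D <- truth@dtrLength
  ord <- order(match(kinds, known))
  defects <- defects[ord]

  x <- strsplit(truth@seq, "")[[1L]]
  map <- 0:(G - 1L)
  done <- list()

  .withSeed(seed, {
    for (d in defects) {
      n <- length(x)
      if (d$kind == "COLLAPSED_DTR") {
        if (D <= 0L) stop("COLLAPSED_DTR requires a genome with a DTR")
        L <- G - D
        x <- x[seq_len(L)]
        map <- ifelse(map < L, map, map - L)
        done <- c(done, list(list(kind = "COLLAPSED_DTR", dtrLength = D)))
      } else if (d$kind == "MID_OPEN") {
        L <- G - D
        p <- d$offset
        if (p <= 0L || p >= L) stop("MID_OPEN offset out of range (0, ", L, ")")
        circ <- x[seq_len(L)]
        x <- c(circ[(p + 1L):L], circ[seq_len(p)])
        map <- ((map %% L) - p) %% L
        done <- c(done, list(list(kind = "MID_OPEN", offset = p,
                                  dtrLength = D)))
      } else if (d$kind == "TANDEM_DUP") {
        u <- as.integer(d$unitLength %||% cfg@artifact$tandemUnitLen)
        q <- as.integer(d$posOffset %||% cfg@artifact$tandemPosOffset)
        if (q < 0L || q + u > n) stop("TANDEM_DUP window out of range")
        x <- c(x[seq_len(q + u)], x[(q + 1L):n])
        map <- ifelse(map < q + u, map, map + u)
        done <- c(done, list(list(kind = "TANDEM_DUP", unitLength = u,
                                  copy1 = c(q, q + u),
                                  copy2 = c(q + u, q + 2L * u))))
      } else if (d$kind == "HOMOPOLYMER_INDEL") {
        r <- rle(x)
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1L
        margin <- min(1000L, floor(n / 4L))
        elig <- which(r$lengths >= 4L & starts > margin & ends < n - margin)
        if (!length(elig)) stop("no eligible homopolymer run (length >= 4)")
        mid <- (starts[elig] + ends[elig]) / 2
        run <- elig[which.min(abs(mid - n / 2))]
        rs <- starts[run]          # 1-based run start
        p0 <- rs - 1L              # 0-based position of the edit
        if (d$mode == "ins") {
          x <- append(x, x[rs], after = rs)
          map <- ifelse(map <= p0, map, map + 1L)
        } else {
          x <- x[-rs]
          map <- ifelse(map < p0, map, ifelse(map == p0, NA_integer_,
                                              map - 1L))
        }
        done <- c(done, list(list(kind = "HOMOPOLYMER_INDEL", mode = d$mode,
                                  position = p0, base = r$values[run],
                                  runLength = r$lengths[run])))
      } else if (d$kind == "TERMINAL_FLANK") {
        fl <- as.integer(d$flankLen %||% cfg@artifact$flankLen)
        cl <- as.integer(d$coreLen %||% cfg@artifact$adapterCoreLen)
        co <- as.integer(d$coreOffset %||% floor((fl - cl) / 2))
        aid <- d$adapterId %||% names(cfg@adapterSet)[1L]
        adapter <- cfg@adapterSet[[aid]]
        if (cl > nchar(adapter)) stop("adapter core longer than adapter")
        if (co < 0L || co + cl > fl) stop("adapter core outside flank")
        core <- strsplit(substr(adapter, 1L, cl), "")[[1L]]
        flank <- sample(.BASES, fl, replace = TRUE)
        flank[(co + 1L):(co + cl)] <- core
        # Keep the artifact boundary identifiable: when the underlying
        # contig is DTR-finished, a flank whose genome-adjacent base
        # happens to extend the terminal repeat (or its inverted partner)
        # would make the true flank extent ambiguous even in principle.
        if (D > 0L && n >= 2L * D &&
            identical(x[seq_len(D)], x[(n - D + 1L):n])) {
          comp <- c(A = "T", C = "G", G = "C", T = "A")
          forbid <- c(x[n - D], comp[[x[D + 1L]]])
          if (flank[fl] %in% forbid)
            flank[fl] <- sample(setdiff(.BASES, forbid), 1L)
        }
        flankL <- paste(flank, collapse = "")
        flankR <- revComp(flankL)
        x <- c(flank, x[seq_len(n)])
        x <- c(x, strsplit(flankR, "")[[1L]])
        map <- map + fl
        done <- c(done, list(list(kind = "TERMINAL_FLANK", flankLen = fl,
                                  coreLen = cl, coreOffset = co,
                                  adapterId = aid, flankSeqLeft = flankL)))
      }
    }
  })
  list(contigId = paste0(truth@id, "_contig"),
       contigSeq = paste(x, collapse = ""),
       defects = done, map = map, truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- read placement machinery ---------------------------------------------

# Apply the per-base error model to one read. `bases` is the error-free
# fragment; returns mutated bases plus, per output base, the 1-based index
# into the original fragment (NA for inserted bases). Substitutions first,
# then indels, left to right, one pass; the indel rate is multiplied by
# `boost` inside homopolymer runs of length >= 3.
.mutateRead <- function(bases, subRate, indelRate, boost = 1) {
  n <- length(bases)
  if (subRate > 0) {
    hit <- which(runif(n) < subRate)
    if (length(hit)) {
      alt <- sample(.BASES, length(hit), replace = TRUE)
      clash <- alt == bases[hit]
      while (any(clash)) {
        alt[clash] <- sample(.BASES, sum(clash), replace = TRUE)
        clash <- alt == bases[hit]
      }
      bases[hit] <- alt
    }
  }
  emit <- rep(1L, n)
  if (indelRate > 0) {
    r <- rle(bases)
    runlen <- rep(r$lengths, r$lengths)
    rate <- ifelse(runlen >= 3L, pmin(1, indelRate * boost), indelRate)
    hit <- which(runif(n) < rate)
    if (length(hit)) {
      isDel <- runif(length(hit)) < 0.5
      emit[hit[isDel]] <- 0L
      emit[hit[!isDel]] <- 2L
    }
  }
  idx <- rep(seq_len(n), emit)
  out <- bases[idx]
  truthIdx <- idx
  dup <- which(c(FALSE, diff(idx) == 0L))
  if (length(dup)) {
    out[dup] <- sample(.BASES, length(dup), replace = TRUE)
    truthIdx[dup] <- NA_integer_
  }
  list(bases = out, truthIdx = truthIdx)
}

# CIGAR for one contiguously-mapped segment. mi: 1-based read positions of
# mapped bases; ri: their 0-based reference positions; L: read length.
.segCigar <- function(mi, ri, L) {
  jj <- which(diff(mi) > 1L | diff(ri) > 1L)
  bs <- c(1L, jj + 1L); be <- c(jj, length(mi))
  parts <- character(0)
  if (mi[1L] > 1L) parts <- c(parts, paste0(mi[1L] - 1L, "S"))
  for (b in seq_along(bs)) {
    parts <- c(parts, paste0(be[b] - bs[b] + 1L, "M"))
    if (b < length(bs)) {
      ins <- mi[bs[b + 1L]] - mi[be[b]] - 1L
      del <- ri[bs[b + 1L]] - ri[be[b]] - 1L
      if (ins > 0L) parts <- c(parts, paste0(ins, "I"))
      if (del > 0L) parts <- c(parts, paste0(del, "D"))
    }
  }
  if (mi[length(mi)] < L) parts <- c(parts, paste0(L - mi[length(mi)], "S"))
  paste(parts, collapse = "")
}

# Project one read onto the contig. cpos: per-read-base 0-based contig
# position (NA = inserted base or deleted truth position target). A read
# whose mapping is discontinuous beyond maxGap (tandem-duplication jump,
# collapsed-DTR fold, rotation cut) is split into one alignment per
# contiguously-mapped segment; small gaps become I/D CIGAR ops. Segments
# with fewer than minSeg mapped bases are dropped.
.projectRead <- function(cpos, minSeg = 20L, maxGap = 20L) {
  L <- length(cpos)
  m <- which(!is.na(cpos))
  if (!length(m)) return(list())
  ref <- cpos[m]
  k <- length(m)
  brk <- if (k > 1L) {
    dref <- diff(ref); dread <- diff(m)
    which(dref < 1L | (dref - 1L) > maxGap | (dread - 1L) > maxGap)
  } else integer(0)
  segStart <- c(1L, brk + 1L)
  segEnd <- c(brk, k)
  segs <- list()
  for (s in seq_along(segStart)) {
    idx <- segStart[s]:segEnd[s]
    if (length(idx) < minSeg) next
    mi <- m[idx]; ri <- ref[idx]
    segs[[length(segs) + 1L]] <-
      list(refStart = ri[1L], cigar = .segCigar(mi, ri, L))
  }
  segs
}

# Assemble alignment records for a batch of reads.
# fragsTruthPos: list of 0-based truth positions per read base (NA allowed);
# map: truth->contig map or NULL for identity.
.placementsToAlignments <- function(ids, seqs, strands, fragsTruthPos,
                                    map, refId, refLen) {
  rows <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    tp <- fragsTruthPos[[i]]
    cpos <- if (is.null(map)) tp else map[tp + 1L]
    segs <- .projectRead(cpos)
    if (!length(segs)) next
    idsSeg <- if (length(segs) == 1L) ids[i]
              else paste0(ids[i], "/p", seq_along(segs))
    rows[[i]] <- data.frame(
      read_id = idsSeg, ref_id = refId,
      ref_start = vapply(segs, `[[`, integer(1), "refStart"),
      strand = strands[i],
      cigar = vapply(segs, `[[`, character(1), "cigar"),
      seq = seqs[i], qual = NA_character_,
      secondary = FALSE, supplementary = FALSE)
  }
  df <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(df))
    df <- data.frame(read_id = character(0), ref_id = character(0),
                     ref_start = integer(0), strand = character(0),
                     cigar = character(0), seq = character(0),
                     qual = character(0), secondary = logical(0),
                     supplementary = logical(0))
  phageAlignments(df, stats::setNames(refLen, refId))
}

#' Number of long reads needed for a target mean coverage
#'
#' Under the linear-molecule sampling model (read starts uniform over
#' \code{[-(len-1), G-1]}, clipped at the physical ends) interior coverage
#' is \code{n * meanLen / (G + meanLen)}.
#'
#' @param genomeLength Genome length G in bp.
#' @param meanLen Mean read length in bp.
#' @param coverage Target mean depth.
#' @return Integer read count.
#' @export
readsForCoverage <- function(genomeLength, meanLen, coverage) {
  as.integer(ceiling(coverage * (genomeLength + meanLen) / meanLen))
}

#' Sample long reads from a truth genome
#'
#' Reads model sequencing of a linear molecule: the start is uniform over
#' \code{[-(len-1), G-1]} and the read is clipped at the physical ends, so
#' terminal bases receive full coverage (every molecule end yields an
#' end-anchored fragment). Lengths are Normal(meanLen, sdLen) truncated at
#' minLen; strand is Bernoulli(0.5). Errors are applied per base
#' (substitutions, then indels, with the indel rate boosted inside
#' homopolymer runs of length >= 3).
#'
#' When a defect \code{map} is supplied the truth placements are
#' re-projected onto the defective contig: reads from either DTR copy land
#' on a collapsed copy (producing the doubled-depth signal), and reads whose
#' mapping is discontinuous are emitted as one primary record per
#' contiguously-mapped segment (ids suffixed \code{/p1}, \code{/p2}) with
#' soft clips for the off-segment bases.
#'
#' @param truth A \linkS4class{TruthSet}.
#' @param config Optional \linkS4class{SimulationConfig} (defaults to the
#'   truth's).
#' @param contigId,contigLength,map Defective-contig identity, length and
#'   truth-to-contig map from [injectDefects()]; all NULL to place reads on
#'   the truth genome itself.
#' @param coverage Target mean depth; used when \code{longRead$count} is NA.
#' @param seedOffset Offset added to the configuration seed for this
#'   sampler's RNG stream.
#' @return List with \code{reads} (data.frame id/seq/qual; seq is the read
#'   as sequenced, reverse-complemented for minus-strand reads),
#'   \code{alignments} (\linkS4class{PhageAlignments}), and
#'   \code{placements} (data.frame of truth intervals and strands).
#' @export
sampleLongReads <- function(truth, config = NULL, contigId = NULL,
                            contigLength = NULL, map = NULL, coverage = NULL,
                            seedOffset = 2L) {
  stopifnot(is(truth, "TruthSet"))
  cfg <- config %||% truth@config
  lr <- cfg@longRead
  G <- nchar(truth@seq)
  if (lr$meanLen > G) stop("mean read length exceeds genome length")
  n <- if (!is.na(lr$count)) as.integer(lr$count)
       else if (!is.null(coverage)) readsForCoverage(G, lr$meanLen, coverage)
       else stop("either longRead$count or coverage must be given")
  if (n < 1L) stop("at least one read must be requested")
  refId <- contigId %||% truth@id
  refLen <- contigLength %||% G
  .withSeed(cfg@seed + seedOffset, {
    lens <- pmax(lr$minLen, round(rnorm(n, lr$meanLen, lr$sdLen)))
    lens <- pmin(lens, G)
    s0 <- floor(runif(n, min = -(lens - 1L), max = G))
    a <- pmax(0, s0); b <- pmin(G, s0 + lens)
    keep <- (b - a) >= 30L
    a <- as.integer(a[keep]); b <- as.integer(b[keep])
    nk <- length(a)
    strands <- sample(c("+", "-"), nk, replace = TRUE)
    ids <- sprintf("lr_%06d", seq_len(nk))
    frags <- substring(truth@seq, a + 1L, b)
    withErr <- lr$subRate > 0 || lr$indelRate > 0
    tpos <- vector("list", nk)
    if (withErr) {
      for (i in seq_len(nk)) {
        mut <- .mutateRead(strsplit(frags[i], "")[[1L]], lr$subRate,
                           lr$indelRate, lr$homopolymerIndelBoost)
        frags[i] <- paste(mut$bases, collapse = "")
        tpos[[i]] <- a[i] + mut$truthIdx - 1L
      }
    } else {
      for (i in seq_len(nk)) tpos[[i]] <- a[i]:(b[i] - 1L)
    }
    aln <- .placementsToAlignments(ids, frags, strands, tpos, map, refId,
                                   refLen)
    fq <- ifelse(strands == "-",
                 vapply(frags, revComp, character(1), USE.NAMES = FALSE),
                 frags)
    list(reads = data.frame(id = ids, seq = fq,
                            qual = strrep("I", nchar(fq))),
         alignments = aln,
         placements = data.frame(id = ids, start = a, end = b,
                                 strand = strands))
  })
}

#' Sample paired short reads from a truth genome
#'
#' Fragment placements are uniform, but any fragment whose boundary lies
#' within \code{endExclusionZone} bases of either physical end is excluded
#' (tagmentation-based libraries cannot capture the physical ends of a
#' linear genome, though they do capture most of the DTR interior). Both
#' mates have length \code{readLen}; the error model matches
#' [sampleLongReads()] without the homopolymer boost.
#'
#' @inheritParams sampleLongReads
#' @param coverage Target mean depth; used when \code{shortRead$pairs} is
#'   NA.
#' @return As [sampleLongReads()]; mate ids carry \code{/1} and \code{/2}
#'   suffixes.
#' @export
sampleShortReads <- function(truth, config = NULL, contigId = NULL,
                             contigLength = NULL, map = NULL,
                             coverage = NULL, seedOffset = 3L) {
  stopifnot(is(truth, "TruthSet"))
  cfg <- config %||% truth@config
  sr <- cfg@shortRead
  lr <- cfg@longRead   # shares sub/indel rates
  G <- nchar(truth@seq)
  rl <- as.integer(sr$readLen)
  dz <- as.integer(sr$endExclusionZone)
  if (G - 2L * dz < rl)
    stop("end exclusion zone leaves no room for any fragment")
  np <- if (!is.na(sr$pairs)) as.integer(sr$pairs)
        else if (!is.null(coverage))
          as.integer(ceiling(coverage * G / (2 * rl)))
        else stop("either shortRead$pairs or coverage must be given")
  if (np < 1L) stop("at least one pair must be requested")
  refId <- contigId %||% truth@id
  refLen <- contigLength %||% G
  .withSeed(cfg@seed + seedOffset, {
    flen <- pmax(rl, round(rnorm(np, sr$insertMean, sr$insertSd)))
    flen <- pmin(flen, G - 2L * dz)
    s <- dz + floor(runif(np, 0, G - 2L * dz - flen + 1))
    s <- as.integer(s); flen <- as.integer(flen)
    a1 <- s; b1 <- s + rl
    a2 <- s + flen - rl; b2 <- s + flen
    ids <- sprintf("sr_%06d", seq_len(np))
    mkMate <- function(a, b, strand, suffix) {
      frags <- substring(truth@seq, a + 1L, b)
      tpos <- vector("list", np)
      withErr <- lr$subRate > 0 || lr$indelRate > 0
      if (withErr) {
        for (i in seq_len(np)) {
          mut <- .mutateRead(strsplit(frags[i], "")[[1L]], lr$subRate,
                             lr$indelRate, 1)
          frags[i] <- paste(mut$bases, collapse = "")
          tpos[[i]] <- a[i] + mut$truthIdx - 1L
        }
      } else {
        for (i in seq_len(np)) tpos[[i]] <- a[i]:(b[i] - 1L)
      }
      mateIds <- paste0(ids, suffix)
      aln <- .placementsToAlignments(mateIds, frags, rep(strand, np), tpos,
                                     map, refId, refLen)
      fq <- if (strand == "-")
        vapply(frags, revComp, character(1), USE.NAMES = FALSE) else frags
      list(reads = data.frame(id = mateIds, seq = fq,
                              qual = strrep("I", nchar(fq))),
           alignments = aln,
           placements = data.frame(id = mateIds, start = a, end = b,
                                   strand = strand))
    }
    m1 <- mkMate(a1, b1, "+", "/1")
    m2 <- mkMate(a2, b2, "-", "/2")
    alnData <- rbind(alignmentData(m1$alignments),
                     alignmentData(m2$alignments))
    list(reads1 = m1$reads, reads2 = m2$reads,
         alignments = phageAlignments(alnData,
                                      stats::setNames(refLen, refId)),
         placements = rbind(m1$placements, m2$placements))
  })
}

#' Run a full simulation and write its outputs to disk
#'
#' Writes the truth genome and defective contig FASTA, long reads FASTQ,
#' short read pair FASTQs, truth-coordinate SAM files, a truth DTR BED, and
#' a machine-readable defect manifest (JSON).
#'
#' @param config A \linkS4class{SimulationConfig}.
#' @param defects List of defect descriptors (see [defects]); may be empty
#'   for a finished, artifact-free contig.
#' @param outdir Output directory (created if needed).
#' @param longCoverage,shortCoverage Target depths used when the
#'   configuration does not fix read counts.
#' @return Invisibly, a list of the written paths.
#' @export
simulateToFiles <- function(config, defects = list(), outdir,
                            longCoverage = 50, shortCoverage = 50) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  truth <- generateGenome(config)
  G <- nchar(truth@seq); D <- truth@dtrLength
  if (length(defects)) {
    inj <- injectDefects(truth, defects)
    contigId <- inj$contigId; contigSeq <- inj$contigSeq
    map <- inj$map; manifest <- inj$defects
  } else {
    contigId <- paste0(truth@id, "_contig"); contigSeq <- truth@seq
    map <- NULL; manifest <- list()
  }
  lrs <- sampleLongReads(truth, config, contigId, nchar(contigSeq), map,
                         coverage = longCoverage)
  srs <- sampleShortReads(truth, config, contigId, nchar(contigSeq), map,
                          coverage = shortCoverage)
  p <- list(
    truth_fasta = file.path(outdir, "truth.fasta"),
    contig_fasta = file.path(outdir, "contig.fasta"),
    long_fastq = file.path(outdir, "reads_long.fastq"),
    short_r1 = file.path(outdir, "reads_short_R1.fastq"),
    short_r2 = file.path(outdir, "reads_short_R2.fastq"),
    long_sam = file.path(outdir, "alignments_long.sam"),
    short_sam = file.path(outdir, "alignments_short.sam"),
    dtr_bed = file.path(outdir, "truth_dtr.bed"),
    manifest = file.path(outdir, "manifest.json"))
  writeFasta(stats::setNames(c(truth@seq), truth@id), p$truth_fasta)
  writeFasta(stats::setNames(c(contigSeq), contigId), p$contig_fasta)
  writeFastq(lrs$reads, p$long_fastq)
  writeFastq(srs$reads1, p$short_r1)
  writeFastq(srs$reads2, p$short_r2)
  writeSam(lrs$alignments, p$long_sam)
  writeSam(srs$alignments, p$short_sam)
  bed <- if (D > 0L)
    data.frame(start = c(0L, G - D), end = c(D, G),
               name = c("DTR_left", "DTR_right"))
  else data.frame(start = integer(0), end = integer(0), name = character(0))
  writeBed(bed, truth@id, p$dtr_bed, G)
  jsonlite::write_json(
    list(genome_length = G, dtr_length = D, seed = config@seed,
         defects = manifest),
    p$manifest, auto_unbox = TRUE, digits = NA, null = "null",
    na = "null")
  invisible(p)
}
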