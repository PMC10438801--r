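# Terminal adapter/barcode flank artifacts and spurious tandem
# duplications. Flank evidence is an adapter hit OR an inverted-repeat
# partner (either alone suffices; both are recorded). The spurious-repeat
# test is junction support -- depth inside a false duplication depends on
# the mapper's multi-mapping policy, while junction spanning is
# mapper-robust.

# Best approximate adapter hit in a window: scans edit distances 0..maxk
# and returns the leftmost hit at the smallest distance, over both adapter
# orientations. Returns NULL or list(start, end (0-based within window),
# edits, orientation).
.bestAdapterHit <- function(windowSeq, adapter, maxk) {
  subject <- Biostrings::DNAString(windowSeq)
  for (k in 0:maxk) {
    for (orient in c("fwd", "rc")) {
      pat <- if (orient == "fwd") adapter else revComp(adapter)
      hits <- Biostrings::matchPattern(pat, subject, max.mismatch = k,
                                       with.indels = TRUE)
      if (length(hits) > 0L) {
        return(list(start = BiocGenerics::start(hits)[1L] - 1L,
                    end = BiocGenerics::end(hits)[1L],
                    edits = k, orientation = orient))
      }
    }
  }
  NULL
}

#' Detect terminal adapter/barcode flank artifacts
#'
#' Flank candidates are the stretches outside the resolved DTR copies
#' (\code{[0, leftStart)} and \code{[rightEnd, n)}) when the DTR is inset
#' from the contig ends; when the DTR is not resolved, the terminal runs of
#' near-zero normalized depth serve as candidates (adapter/barcode bases
#' are not supported by reads). Each candidate is scanned for adapter hits
#' (semi-global, edit distance <= \code{maxEditFrac} times the adapter
#' length, both orientations) and the two candidates are tested for the
#' inverted-repeat partner signature
#' (\code{revComp(left) ~ right, identity >= 0.9}). A call is emitted only
#' when at least one evidence type exists.
#'
#' @param seq Contig sequence (character scalar).
#' @param dtr Optional \linkS4class{DTRAnnotation} from [resolveDtr()].
#' @param adapters Named character vector of adapter sequences (may be
#'   NULL for inverted-repeat-only detection).
#' @param maxFlank Maximum flank length considered, bp.
#' @param maxEditFrac Maximum edit fraction for an adapter hit.
#' @param profile Optional \linkS4class{DepthProfile} used when \code{dtr}
#'   does not localize the flanks.
#' @param zeroNorm Normalized depth below which a terminal position counts
#'   as unsupported.
#' @param minInvertedIdentity Identity threshold for the inverted-partner
#'   signature.
#' @return data.frame with one row per call: \code{side}, \code{start},
#'   \code{end}, \code{adapter_id}, \code{core_start}, \code{core_end},
#'   \code{inverted_partner}, \code{revcomp_identity}. Zero rows when the
#'   DTR already flanks the contig ends.
#' @export
findTerminalFlanks <- function(seq, dtr = NULL, adapters = NULL,
                               maxFlank = 200L, maxEditFrac = 0.15,
                               profile = NULL, zeroNorm = 0.1,
                               minInvertedIdentity = 0.9) {
  n <- nchar(seq)
  empty <- data.frame(side = character(0), start = integer(0),
                      end = integer(0), adapter_id = character(0),
                      core_start = integer(0), core_end = integer(0),
                      inverted_partner = logical(0),
                      revcomp_identity = numeric(0))
  leftEnd <- NA_integer_; rightStart <- NA_integer_
  if (!is.null(dtr)) {
    if (dtr@leftStart == 0L && dtr@rightEnd == n) return(empty)
    if (dtr@leftStart > 0L && dtr@leftStart <= maxFlank)
      leftEnd <- dtr@leftStart
    if (dtr@rightEnd < n && n - dtr@rightEnd <= maxFlank)
      rightStart <- dtr@rightEnd
  } else if (!is.null(profile) && profile@medianDepth > 0) {
    norm <- normalizedDepth(profile)
    k <- which(norm >= zeroNorm)
    if (length(k)) {
      if (k[1L] > 1L && k[1L] - 1L <= maxFlank) leftEnd <- k[1L] - 1L
      if (k[length(k)] < n && n - k[length(k)] <= maxFlank)
        rightStart <- k[length(k)]
    }
  }
  if (is.na(leftEnd) && is.na(rightStart)) return(empty)

  flankSeq <- function(a, b) substr(seq, a + 1L, b)
  lSeq <- if (!is.na(leftEnd)) flankSeq(0L, leftEnd) else NULL
  rSeq <- if (!is.na(rightStart)) flankSeq(rightStart, n) else NULL

  inverted <- FALSE; rcIdent <- NA_real_
  if (!is.null(lSeq) && !is.null(rSeq)) {
    a <- revComp(lSeq); b <- rSeq
    if (nchar(a) == nchar(b)) {
      av <- strsplit(a, "")[[1L]]; bv <- strsplit(b, "")[[1L]]
      rcIdent <- mean(av == bv)
    } else {
      rcIdent <- 1 - utils::adist(a, b)[1L, 1L] / max(nchar(a), nchar(b))
    }
    inverted <- rcIdent >= minInvertedIdentity
  }

  mkCall <- function(side, a, b, fseq) {
    hit <- NULL
    if (!is.null(adapters)) {
      for (aid in names(adapters)) {
        maxk <- floor(maxEditFrac * nchar(adapters[[aid]]))
        h <- .bestAdapterHit(fseq, adapters[[aid]], maxk)
        if (!is.null(h) && (is.null(hit) || h$edits < hit$edits)) {
          hit <- h; hit$id <- aid
        }
      }
    }
    if (is.null(hit) && !inverted) return(NULL)
    data.frame(side = side, start = a, end = b,
               adapter_id = if (!is.null(hit)) hit$id else NA_character_,
               core_start = if (!is.null(hit)) a + hit$start else NA_integer_,
               core_end = if (!is.null(hit)) a + hit$end else NA_integer_,
               inverted_partner = inverted, revcomp_identity = rcIdent)
  }
  calls <- list()
  if (!is.null(lSeq)) calls <- c(calls, list(mkCall("LEFT", 0L, leftEnd, lSeq)))
  if (!is.null(rSeq)) calls <- c(calls, list(mkCall("RIGHT", rightStart, n, rSeq)))
  calls <- calls[!vapply(calls, is.null, logical(1))]
  if (!length(calls)) return(empty)
  do.call(rbind, calls)
}

#' Trim detected terminal flank artifacts
#'
#' Removes the called flank intervals from the contig ends; the output
#' length decreases by exactly the summed flank lengths, bases outside the
#' removed intervals are untouched, and the operation is idempotent
#' (re-running detection on the output finds nothing).
#'
#' @param seq Contig sequence (character scalar).
#' @param calls data.frame from [findTerminalFlanks()].
#' @return List with \code{seq} (trimmed) and \code{removed} (data.frame of
#'   removed intervals with side and length).
#' @export
trimTerminalFlanks <- function(seq, calls) {
  n <- nchar(seq)
  if (nrow(calls) == 0L)
    return(list(seq = seq, removed = data.frame(side = character(0),
                                                start = integer(0),
                                                end = integer(0))))
  if (any(duplicated(calls$side))) stop("duplicate flank side")
  a <- 0L; b <- n
  for (i in seq_len(nrow(calls))) {
    if (calls$start[i] < 0L || calls$end[i] > n ||
        calls$end[i] <= calls$start[i])
      stop("flank call out of bounds")
    if (calls$side[i] == "LEFT") {
      if (calls$start[i] != 0L) stop("LEFT flank must start at position 0")
      a <- calls$end[i]
    } else {
      if (calls$end[i] != n) stop("RIGHT flank must end at the contig end")
      b <- calls$start[i]
    }
  }
  if (a >= b) stop("flank calls overlap")
  list(seq = substr(seq, a + 1L, b),
       removed = data.frame(side = calls$side, start = calls$start,
                            end = calls$end))
}

#' Find adjacent near-identical tandem duplication candidates
#'
#' All adjacent equal-length copy pairs with unit length in
#' \code{unitRange} and position-wise mismatch fraction at most
#' \code{maxDivergence}, whose first copy starts within
#' \code{searchWindow} of either terminus or of a supplied DTR boundary.
#' Shifted same-unit duplicates of one array are collapsed to the leftmost,
#' and candidates whose span is contained in the span of a longer-unit
#' candidate are suppressed (maximal units only).
#'
#' @param seq Contig sequence (character scalar).
#' @param searchWindow Distance from a terminus/DTR boundary within which
#'   the first copy must start; ignored when \code{wholeSeq}.
#' @param unitRange Integer length-2 vector: smallest and largest unit.
#' @param maxDivergence Maximum mismatch fraction between the two copies.
#' @param dtrBoundaries Optional integer vector of additional 0-based
#'   anchor coordinates (DTR copy boundaries).
#' @param wholeSeq Scan every position (used for small sequences and
#'   oracle checks).
#' @return data.frame with columns \code{start1}, \code{end1},
#'   \code{start2}, \code{end2} (0-based half-open; \code{end1 == start2}),
#'   \code{unit_length}, \code{divergence}, ordered by \code{start1}.
#' @export
findTandemArtifacts <- function(seq, searchWindow = 2000L,
                                unitRange = c(20L, 500L),
                                maxDivergence = 0.05, dtrBoundaries = NULL,
                                wholeSeq = FALSE) {
  n <- nchar(seq)
  umin <- as.integer(unitRange[1L]); umax <- as.integer(unitRange[2L])
  if (n <= 2L * umin) stop("contig shorter than twice the minimum unit")
  umax <- min(umax, floor(n / 2))
  x <- strsplit(toupper(seq), "")[[1L]]
  allowed <- if (wholeSeq) rep(TRUE, n) else {
    anchors <- unique(c(0L, n, as.integer(dtrBoundaries)))
    a <- rep(FALSE, n)
    for (p in anchors) {
      lo <- max(0L, p - searchWindow); hi <- min(n - 1L, p + searchWindow)
      a[(lo + 1L):(hi + 1L)] <- TRUE
    }
    a
  }
  cand <- list()
  for (u in umin:umax) {
    if (2L * u > n) break
    e <- x[seq_len(n - u)] == x[(u + 1L):n]
    S <- c(0L, cumsum(e))
    i <- 0:(n - 2L * u)                       # 0-based copy1 starts
    matches <- S[i + u + 1L] - S[i + 1L]
    ham <- u - matches
    ok <- ham <= floor(maxDivergence * u) & allowed[i + 1L]
    if (any(ok))
      cand[[length(cand) + 1L]] <-
        data.frame(start1 = i[ok], unit = u, ham = ham[ok])
  }
  empty <- data.frame(start1 = integer(0), end1 = integer(0),
                      start2 = integer(0), end2 = integer(0),
                      unit_length = integer(0), divergence = numeric(0))
  if (!length(cand)) return(empty)
  cd <- do.call(rbind, cand)
  # collapse shifted duplicates of one array (same unit, consecutive
  # starts) to the best-matching candidate, then the leftmost
  cd <- cd[order(cd$unit, cd$start1), ]
  newRun <- c(TRUE, diff(cd$start1) != 1L | diff(cd$unit) != 0L)
  grp <- cumsum(newRun)
  pick <- vapply(split(seq_len(nrow(cd)), grp), function(ix)
    ix[order(cd$ham[ix], cd$start1[ix])[1L]], integer(1))
  cd <- cd[sort(pick), , drop = FALSE]
  # maximal units: drop candidates contained in a longer-unit candidate
  cd <- cd[order(-cd$unit, cd$start1), ]
  spanS <- cd$start1; spanE <- cd$start1 + 2L * cd$unit
  keep <- rep(TRUE, nrow(cd))
  for (k in seq_len(nrow(cd))) {
    if (!keep[k]) next
    if (k > 1L) {
      prior <- which(keep[seq_len(k - 1L)] &
                       cd$unit[seq_len(k - 1L)] > cd$unit[k])
      if (any(spanS[prior] <= spanS[k] & spanE[prior] >= spanE[k]))
        keep[k] <- FALSE
    }
  }
  cd <- cd[keep, , drop = FALSE]
  out <- data.frame(start1 = cd$start1, end1 = cd$start1 + cd$unit,
                    start2 = cd$start1 + cd$unit,
                    end2 = cd$start1 + 2L * cd$unit,
                    unit_length = cd$unit,
                    divergence = cd$ham / cd$unit)
  out[order(out$start1), , drop = FALSE]
}

#' Count reads spanning a tandem-duplication junction
#'
#' A spanning read must cover the window
#' \code{[junction - minFlank, junction + minFlank)} contiguously: no clip
#' inside the window, no deletion of at least half the unit length inside
#' it, and at most \code{maxEdits} indel events within it. Near-zero
#' support indicates an assembly-introduced duplication.
#'
#' @param candidate One row of [findTandemArtifacts()] output.
#' @param alignments A \linkS4class{PhageAlignments}.
#' @param minFlank Required anchor length on each side of the junction, bp.
#' @param maxEdits Maximum indel events tolerated inside the window.
#' @return Integer count of junction-spanning alignments.
#' @export
junctionSupport <- function(candidate, alignments, minFlank = 50L,
                            maxEdits = 5L) {
  stopifnot(is(alignments, "PhageAlignments"))
  j <- candidate$end1[1L]
  u <- candidate$unit_length[1L]
  contigLen <- alignments@seqinfo[[1L]]
  w0 <- j - minFlank; w1 <- j + minFlank
  if (w0 < 0L || w1 > contigLen)
    stop("minFlank window exceeds contig bounds at the candidate")
  d <- alignments@data
  d <- d[!d$secondary & !d$supplementary, , drop = FALSE]
  if (nrow(d) == 0L) return(0L)
  span <- cigarRefSpan(d$cigar)
  covers <- d$ref_start <= w0 & d$ref_start + span >= w1
  d <- d[covers, , drop = FALSE]
  if (nrow(d) == 0L) return(0L)
  okEach <- vapply(seq_len(nrow(d)), function(i) {
    p <- .parseCigar(d$cigar[i])
    pos <- d$ref_start[i]
    edits <- 0L
    for (k in seq_along(p$op)) {
      op <- p$op[k]; len <- p$len[k]
      if (op %in% c("M", "=", "X")) {
        pos <- pos + len
      } else if (op %in% c("D", "N")) {
        if (pos < w1 && pos + len > w0) {
          if (len >= u / 2) return(FALSE)
          edits <- edits + 1L
        }
        pos <- pos + len
      } else if (op == "I") {
        if (pos > w0 && pos < w1) edits <- edits + 1L
      }
      # S/H only at read ends; they consume no reference
    }
    edits <= maxEdits
  }, logical(1))
  sum(okEach)
}

#' Verdict for a tandem-duplication candidate
#'
#' \code{SUPPORTED} when junction support reaches \code{minSupport};
#' otherwise \code{UNDETERMINED} when local depth is below \code{minDepth}
#' (not enough data to judge), else \code{ARTIFACT}.
#'
#' @param candidate One row of [findTandemArtifacts()] output.
#' @param support Junction support from [junctionSupport()].
#' @param localDepth Mean raw depth over the candidate span.
#' @param minSupport Spanning reads required to accept the duplication.
#' @param minDepth Depth below which the verdict is withheld.
#' @return The candidate row with added columns \code{junction_support},
#'   \code{local_depth} and \code{verdict}.
#' @export
callTandemVerdict <- function(candidate, support, localDepth,
                              minSupport = 2L, minDepth = 5L) {
  verdict <- if (support >= minSupport) "SUPPORTED"
             else if (localDepth < minDepth) "UNDETERMINED"
             else "ARTIFACT"
  out <- candidate
  out$junction_support <- as.integer(support)
  out$local_depth <- localDepth
  out$verdict <- verdict
  out
}

#' Collapse a tandem-duplication artifact
#'
#' Deletes the second copy; the length decreases by the unit length and all
#' downstream coordinates shift by -unit_length. Refuses to edit unless the
#' verdict is \code{ARTIFACT}.
#'
#' @param seq Contig sequence (character scalar).
#' @param call Verdict row from [callTandemVerdict()].
#' @return Collapsed sequence (character scalar).
#' @export
collapseTandemArtifact <- function(seq, call) {
  if (!identical(call$verdict[1L], "ARTIFACT"))
    stop("refusing to collapse a candidate with verdict ",
         call$verdict[1L])
  n <- nchar(seq)
  if (call$end2[1L] > n) stop("call out of bounds")
  paste0(substr(seq, 1L, call$end1[1L]), substr(seq, call$end2[1L] + 1L, n))
}
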