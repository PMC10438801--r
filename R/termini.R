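# DTR resolution: terminal self-repeat search, coverage-guided
# relinearization of collapsed or mid-opened contigs, and reorientation to
# a canonical start.

# Max-score subarray (match = +1, mismatch = -penalty) over a logical
# match vector. Returns c(score, start, end, mism) (1-based inclusive) or
# NULL. The mismatch penalty (> 1) makes reported pairs
# boundary-parsimonious: they always begin and end on a match, and a
# boundary excursion into random sequence must win `penalty` chance
# matches per mismatch to pay for itself. Ties: first maximal end, then
# the longest window for that end.
.maxScoreRun <- function(m, penalty = 4) {
  v <- ifelse(m, 1, -penalty)
  p <- cumsum(v)
  base <- cummin(c(0, p[-length(p)]))
  gain <- p - base
  sc <- max(gain)
  if (sc <= 0) return(NULL)
  e <- which.max(gain)
  # start = first index after the first occurrence of the minimal prefix
  pre <- c(0, p)[seq_len(e)]          # prefix sums p[0..e-1]
  s <- which(pre == base[e])[1L]
  mism <- sum(!m[s:e])
  c(score = sc, start = s, end = e, mism = mism)
}

#' Find the longest near-identical terminal self-repeat
#'
#' Searches for the maximal pair of near-identical equal-length substrings
#' with one copy entirely inside the first \code{window} bases and the
#' other inside the last \code{window} bases. Copies are compared
#' position-wise (substitution divergence); the reported pair is the
#' maximal-scoring co-linear local match (match +1, mismatch -4), subject
#' to length >= \code{minLen} and divergence <= \code{maxDivergence}. The
#' strong mismatch penalty makes reported pairs boundary-parsimonious:
#' extending an exact repeat into random flanking sequence would need a
#' five-for-one excursion of chance matches, so planted repeats are
#' recovered with exact coordinates, while genuine low-divergence copies
#' (sparse mismatches between long exact runs) still align end to end.
#'
#' @param seq Contig sequence (character scalar).
#' @param window Terminal window size in bp; must not exceed half the
#'   sequence length.
#' @param minLen Minimum repeat length in bp.
#' @param maxDivergence Maximum mismatch fraction between the two copies.
#' @return NULL when no qualifying pair exists, else a list with
#'   \code{left} and \code{right} (integer 0-based half-open
#'   \code{c(start, end)}), \code{length}, \code{identity} and
#'   \code{mismatches}.
#' @examples
#' findTerminalSelfRepeat("ACGTTTTTACGT", window = 4, minLen = 4)
#' @export
findTerminalSelfRepeat <- function(seq, window = 1000L, minLen = 30L,
                                   maxDivergence = 0.02) {
  n <- nchar(seq)
  window <- as.integer(window)
  if (window > floor(n / 2))
    stop("window (", window, ") exceeds half the sequence length (", n, ")")
  if (window < minLen) return(NULL)
  x <- strsplit(toupper(seq), "")[[1L]]
  A <- x[seq_len(window)]
  B <- x[(n - window + 1L):n]
  best <- NULL   # c(score, len, iStart, jStart, mism) with 0-based starts
  for (d in (-(window - 1L)):(window - 1L)) {
    i0 <- max(1L, 1L - d); i1 <- min(window, window - d)
    if (i1 - i0 + 1L < minLen) next
    idx <- i0:i1
    m <- A[idx] == B[idx + d]
    r <- .maxScoreRun(m)
    if (is.null(r)) next
    len <- r[["end"]] - r[["start"]] + 1L
    if (len < minLen) next
    if (r[["mism"]] > maxDivergence * len) next
    iStart <- idx[r[["start"]]] - 1L          # 0-based within A
    jStart <- idx[r[["start"]]] + d - 1L      # 0-based within B
    cand <- c(r[["score"]], len, iStart, jStart, r[["mism"]])
    if (is.null(best) || cand[1L] > best[1L] ||
        (cand[1L] == best[1L] && cand[2L] > best[2L]) ||
        (cand[1L] == best[1L] && cand[2L] == best[2L] &&
         cand[3L] < best[3L]))
      best <- cand
  }
  if (is.null(best)) return(NULL)
  len <- as.integer(best[2L])
  list(left = c(as.integer(best[3L]), as.integer(best[3L]) + len),
       right = c(n - window + as.integer(best[4L]),
                 n - window + as.integer(best[4L]) + len),
       length = len, identity = 1 - best[5L] / len,
       mismatches = as.integer(best[5L]))
}

# Snap an elevated-region edge to the depth step. The collapsed-DTR depth
# drops from ~2x to ~1x precisely at the repeat boundary; the
# threshold-crossing estimate is refined (shift <= maxShift) to the
# position of the largest single-step change in raw depth.
.refineRegionEdges <- function(profile, start, end, maxShift = 20L) {
  depth <- profile@depth
  n <- length(depth)
  step <- diff(depth)   # step[i] = depth[i+1] - depth[i] (1-based)
  if (start > 0L) {
    lo <- max(1L, start - maxShift); hi <- min(n - 1L, start + maxShift)
    w <- lo:hi
    start <- w[which.max(step[w])]  # rise into the region; 0-based start
  }
  if (end < n) {
    lo <- max(1L, end - maxShift); hi <- min(n - 1L, end + maxShift)
    w <- lo:hi
    end <- w[which.min(step[w])]    # drop out of the region
  }
  c(start, end)
}

#' Resolve the direct terminal repeat of a contig
#'
#' Combines terminal self-repeat search with the coverage terminus signal:
#' \itemize{
#'   \item a terminal self-repeat flanking the contig ends yields a
#'     \code{FINISHED} annotation (evidence \code{SELF_REPEAT}, or
#'     \code{BOTH} when a coverage region overlaps a copy);
#'   \item a self-repeat inset from the ends (e.g. behind adapter flanks)
#'     yields \code{INSET};
#'   \item with no self-repeat, an \code{INTERNAL_PEAK} proposes
#'     relinearization at the region, and a \code{LEFT_PEAK}/
#'     \code{RIGHT_PEAK} proposes duplicating the terminal region to the
#'     opposite end (a collapsed DTR);
#'   \item a flat profile without a self-repeat reports \code{NO_DTR};
#'   \item an \code{AMBIGUOUS} signal proposes the highest-mean region with
#'     a warning.
#' }
#' Proposed region edges are refined to the raw depth step (shift <= 20 bp)
#' because sampling noise blurs the threshold crossing while the underlying
#' copy-number step is sharp.
#'
#' @param seq Contig sequence (character scalar).
#' @param profile Optional \linkS4class{DepthProfile} on this contig; NULL
#'   for sequence-only resolution.
#' @param window,minLen,maxDivergence Passed to [findTerminalSelfRepeat()]
#'   (window is clamped to half the contig length).
#' @param theta,segMinLen,maxGap Passed to [segmentElevated()].
#' @param endMargin Passed to [classifyTerminusSignal()].
#' @return A \linkS4class{DtrResolution}.
#' @export
resolveDtr <- function(seq, profile = NULL, window = 1000L, minLen = 30L,
                       maxDivergence = 0.02, theta = 1.6, segMinLen = 50L,
                       maxGap = 10L, endMargin = 100L) {
  n <- nchar(seq)
  window <- min(as.integer(window), floor(n / 2))
  rep <- findTerminalSelfRepeat(seq, window, minLen, maxDivergence)
  regions <- if (!is.null(profile) && profile@medianDepth > 0)
    segmentElevated(profile, theta, segMinLen, maxGap)
  else data.frame(start = integer(0), end = integer(0),
                  mean_norm = numeric(0))
  signal <- classifyTerminusSignal(regions, n, endMargin)
  warnings <- character(0)

  if (!is.null(rep)) {
    evidence <- "SELF_REPEAT"
    depthRatio <- NA_real_
    conflict <- FALSE
    if (nrow(regions) > 0L) {
      ov <- regions$start < rep$left[2L] & regions$end > rep$left[1L] |
        regions$start < rep$right[2L] & regions$end > rep$right[1L]
      if (any(ov)) {
        top <- which(ov)[which.max(regions$mean_norm[ov])]
        evidence <- "BOTH"
        depthRatio <- regions$mean_norm[top]
        covLen <- regions$end[top] - regions$start[top]
        if (abs(covLen - rep$length) > 5L) {
          conflict <- TRUE
          warnings <- c(warnings, sprintf(
            "coverage region length (%d) and self-repeat length (%d) disagree by > 5 bp",
            covLen, rep$length))
        }
      }
    }
    ann <- new("DTRAnnotation", dtrLength = rep$length,
               leftStart = rep$left[1L], leftEnd = rep$left[2L],
               rightStart = rep$right[1L], rightEnd = rep$right[2L],
               evidence = evidence, identity = rep$identity,
               depthRatio = depthRatio, conflict = conflict)
    status <- if (rep$left[1L] == 0L && rep$right[2L] == n) "FINISHED"
              else "INSET"
    return(new("DtrResolution", status = status, annotation = ann,
               regionStart = NA_integer_, regionEnd = NA_integer_,
               signal = signal, warnings = warnings))
  }

  if (signal@case == "FLAT")
    return(new("DtrResolution", status = "NO_DTR", annotation = NULL,
               regionStart = NA_integer_, regionEnd = NA_integer_,
               signal = signal, warnings = "no DTR detected"))

  reg <- regions
  if (signal@case == "AMBIGUOUS") {
    ordSel <- order(-reg$mean_norm, reg$start)
    reg <- reg[ordSel[1L], , drop = FALSE]
    warnings <- c(warnings, sprintf(
      "%d elevated regions; proceeding with the highest (mean %.2fx at [%d,%d))",
      nrow(regions), reg$mean_norm, reg$start, reg$end))
    case <- classifyTerminusSignal(reg, n, endMargin)@case
  } else {
    case <- signal@case
  }
  edges <- if (!is.null(profile))
    .refineRegionEdges(profile, reg$start[1L], reg$end[1L])
  else c(reg$start[1L], reg$end[1L])
  status <- switch(case,
                   INTERNAL_PEAK = "RELINEARIZE_INTERNAL",
                   LEFT_PEAK = "RELINEARIZE_LEFT",
                   RIGHT_PEAK = "RELINEARIZE_RIGHT")
  new("DtrResolution", status = status, annotation = NULL,
      regionStart = as.integer(edges[1L]), regionEnd = as.integer(edges[2L]),
      signal = signal, warnings = warnings)
}

#' Relinearize a contig at a proposed DTR region
#'
#' \code{INTERNAL}: rotates the contig so the region leads, then appends a
#' copy of it at the end (the mis-opened circular form is reopened at the
#' DTR and the second repeat copy regenerated). \code{LEFT}/\code{RIGHT}:
#' duplicates the terminal region to the opposite end (a collapsed DTR is
#' expanded back to two copies). Output length is input length + D, and the
#' first D bases equal the last D bases exactly.
#'
#' @param seq Contig sequence (character scalar).
#' @param regionStart,regionEnd Region (0-based half-open).
#' @param case \code{"INTERNAL"}, \code{"LEFT"} or \code{"RIGHT"}.
#' @return Relinearized sequence (character scalar).
#' @export
relinearize <- function(seq, regionStart, regionEnd,
                        case = c("INTERNAL", "LEFT", "RIGHT")) {
  case <- match.arg(case)
  n <- nchar(seq)
  rs <- as.integer(regionStart); re <- as.integer(regionEnd)
  if (rs < 0L || re > n || re <= rs) stop("region out of bounds")
  if (re - rs >= n) stop("region spans the whole contig")
  out <- switch(case,
    INTERNAL = {
      if (rs == 0L || re == n)
        stop("INTERNAL relinearization requires a region strictly inside the contig")
      paste0(substr(seq, rs + 1L, n), substr(seq, 1L, rs),
             substr(seq, rs + 1L, re))
    },
    LEFT = {
      # region touches the left terminus; duplicate [0, regionEnd) to the end
      paste0(seq, substr(seq, 1L, re))
    },
    RIGHT = {
      # region touches the right terminus; duplicate it to the front
      paste0(substr(seq, rs + 1L, n), seq)
    })
  D <- switch(case, INTERNAL = re - rs, LEFT = re, RIGHT = n - rs)
  stopifnot(substr(out, 1L, D) ==
              substr(out, nchar(out) - D + 1L, nchar(out)))
  out
}

#' Reorient a genome to its canonical start anchor
#'
#' Searches for the anchor (semi-global, edit distance <= \code{maxEdit})
#' on both strands. Found on the forward strand: unchanged (action
#' \code{NONE}); only on the reverse strand: the genome is
#' reverse-complemented (action \code{REVCOMP}); on neither: unchanged with
#' a warning; on both strands (palindromic/ambiguous anchor): an error.
#'
#' @param seq Genome sequence (character scalar).
#' @param anchorSeq Anchor sequence, length >= 15.
#' @param maxEdit Maximum edit distance for an anchor hit.
#' @return List with \code{seq}, \code{action} (\code{NONE} or
#'   \code{REVCOMP}) and \code{warnings}.
#' @export
reorient <- function(seq, anchorSeq, maxEdit = 2L) {
  anchorSeq <- .normalizeSeq(anchorSeq, "anchor")
  if (nchar(anchorSeq) < 15L)
    stop("anchor must be at least 15 bp (got ", nchar(anchorSeq), ")")
  fwd <- Biostrings::matchPattern(anchorSeq, Biostrings::DNAString(seq),
                                  max.mismatch = maxEdit,
                                  with.indels = TRUE)
  rev <- Biostrings::matchPattern(anchorSeq,
                                  Biostrings::DNAString(revComp(seq)),
                                  max.mismatch = maxEdit,
                                  with.indels = TRUE)
  nf <- length(fwd); nr <- length(rev)
  if (nf > 0L && nr > 0L)
    stop("anchor found on both strands; choose a non-palindromic anchor")
  if (nf > 0L)
    return(list(seq = seq, action = "NONE", warnings = character(0)))
  if (nr > 0L)
    return(list(seq = revComp(seq), action = "REVCOMP",
                warnings = character(0)))
  list(seq = seq, action = "NONE",
       warnings = "anchor not found on either strand; orientation unchanged")
}
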