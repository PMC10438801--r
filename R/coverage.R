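# Per-base depth and segmentation/classification of the elevated-coverage
# signal that localizes a collapsed DTR.

#' Construct a depth profile from an explicit depth vector
#'
#' Useful for toy examples and tests; [depthFromAlignments()] is the usual
#' source.
#'
#' @param depth Integer vector of per-position depth.
#' @param refId Contig identifier.
#' @return A \linkS4class{DepthProfile}.
#' @export
depthProfile <- function(depth, refId = "contig") {
  new("DepthProfile", refId = refId, depth = as.integer(depth),
      medianDepth = stats::median(as.integer(depth)))
}

#' Compute a per-base depth profile from alignments
#'
#' A position is counted once per alignment whose reference-consuming span
#' covers it; deletions (\code{D}) count as covered (the signal of interest
#' is copy-number support, not base agreement), \code{N} gaps do not, and
#' soft/hard clips consume nothing. Secondary and supplementary records are
#' excluded.
#'
#' @param contigLength Contig length in bp.
#' @param alignments A \linkS4class{PhageAlignments}.
#' @param refId Reference to profile; defaults to the only reference in
#'   \code{alignments}.
#' @return A \linkS4class{DepthProfile}.
#' @export
depthFromAlignments <- function(contigLength, alignments, refId = NULL) {
  stopifnot(is(alignments, "PhageAlignments"))
  si <- alignments@seqinfo
  if (is.null(refId)) {
    if (length(si) != 1L)
      stop("refId must be given when alignments span several references")
    refId <- names(si)
  }
  contigLength <- as.integer(contigLength)
  d <- alignments@data
  d <- d[d$ref_id == refId & !d$secondary & !d$supplementary, , drop = FALSE]
  if (nrow(d) == 0L) {
    return(new("DepthProfile", refId = refId,
               depth = integer(contigLength), medianDepth = 0))
  }
  blocks <- lapply(seq_len(nrow(d)), function(i)
    .cigarRefBlocks(d$cigar[i], d$ref_start[i]))
  bm <- do.call(rbind, blocks)
  if (any(bm[, "end"] > contigLength) || any(bm[, "start"] < 0L))
    stop("alignment span exceeds contig bounds")
  cov <- IRanges::coverage(IRanges::IRanges(start = bm[, "start"] + 1L,
                                            end = bm[, "end"]),
                           width = contigLength)
  depth <- as.integer(cov)
  new("DepthProfile", refId = refId, depth = depth,
      medianDepth = stats::median(depth))
}

#' Segment elevated-coverage regions of a depth profile
#'
#' Maximal runs of positions whose median-normalized depth is at least
#' \code{theta}; runs separated by at most \code{maxGap} positions are
#' merged, and merged runs shorter than \code{minLen} are discarded. The
#' default \code{theta = 1.6} splits the expected 1x vs 2x levels with
#' margin for sampling noise; \code{minLen = 50} rejects spike noise (the
#' repeats of interest are >= 180 bp).
#'
#' @param profile A \linkS4class{DepthProfile} with positive median depth.
#' @param theta Normalized-depth threshold.
#' @param minLen Minimum region length in bp after merging.
#' @param maxGap Maximum below-threshold gap bridged when merging.
#' @return data.frame with columns \code{start}, \code{end} (0-based
#'   half-open) and \code{mean_norm}, sorted by start.
#' @export
segmentElevated <- function(profile, theta = 1.6, minLen = 50L,
                            maxGap = 10L) {
  stopifnot(is(profile, "DepthProfile"))
  if (profile@medianDepth <= 0)
    stop("profile median depth is zero; cannot segment")
  norm <- normalizedDepth(profile)
  r <- rle(norm >= theta)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  hi <- which(r$values)
  if (!length(hi))
    return(data.frame(start = integer(0), end = integer(0),
                      mean_norm = numeric(0)))
  rs <- starts[hi]; re <- ends[hi]
  # merge runs separated by <= maxGap
  ms <- rs[1L]; me <- re[1L]
  outS <- integer(0); outE <- integer(0)
  if (length(hi) > 1L) {
    for (k in 2L:length(hi)) {
      if (rs[k] - me - 1L <= maxGap) {
        me <- re[k]
      } else {
        outS <- c(outS, ms); outE <- c(outE, me)
        ms <- rs[k]; me <- re[k]
      }
    }
  }
  outS <- c(outS, ms); outE <- c(outE, me)
  keep <- (outE - outS + 1L) >= minLen
  outS <- outS[keep]; outE <- outE[keep]
  data.frame(start = outS - 1L, end = outE,
             mean_norm = vapply(seq_along(outS), function(k)
               mean(norm[outS[k]:outE[k]]), numeric(1)))
}

#' Classify the terminus signal of a contig
#'
#' One region starting within \code{endMargin} of position 0 is a
#' \code{LEFT_PEAK}; one region ending within \code{endMargin} of the
#' contig end is a \code{RIGHT_PEAK}; one region touching neither margin is
#' an \code{INTERNAL_PEAK} (the assembly was opened in the middle of the
#' genome); no region is \code{FLAT}; more than one region is
#' \code{AMBIGUOUS} (the payload retains all; downstream picks the highest
#' mean_norm with a warning).
#'
#' @param regions data.frame from [segmentElevated()].
#' @param contigLength Contig length in bp.
#' @param endMargin Distance in bp within which a region is considered to
#'   touch a terminus.
#' @return A \linkS4class{TerminusSignal}.
#' @export
classifyTerminusSignal <- function(regions, contigLength, endMargin = 100L) {
  if (nrow(regions) == 0L)
    return(new("TerminusSignal", case = "FLAT", regions = regions))
  if (nrow(regions) > 1L)
    return(new("TerminusSignal", case = "AMBIGUOUS", regions = regions))
  touchesLeft <- regions$start[1L] <= endMargin
  touchesRight <- (contigLength - regions$end[1L]) <= endMargin
  case <- if (touchesLeft) "LEFT_PEAK"
          else if (touchesRight) "RIGHT_PEAK"
          else "INTERNAL_PEAK"
  new("TerminusSignal", case = case, regions = regions)
}
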