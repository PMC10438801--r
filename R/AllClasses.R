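# S4 classes for the curation workflow. All coordinates are 0-based
# half-open; conversion to 1-based happens only at the SAM/BED/VCF-like
# boundaries.

.CIGAR_RE <- "^([0-9]+[MIDNSHP=X])+$"

.validAlignmentData <- function(df) {
  need <- c("read_id", "ref_id", "ref_start", "strand", "cigar",
            "seq", "secondary", "supplementary")
  if (!all(need %in% names(df)))
    return(paste("alignment data lacks columns:",
                 paste(setdiff(need, names(df)), collapse = ", ")))
  if (nrow(df) == 0L) return(TRUE)
  if (any(df$ref_start < 0L)) return("negative ref_start")
  if (!all(df$strand %in% c("+", "-"))) return("strand must be '+' or '-'")
  bad <- !grepl(.CIGAR_RE, df$cigar)
  if (any(bad)) return(paste("malformed CIGAR:", df$cigar[which(bad)[1L]]))
  TRUE
}

#' Alignments against one or more contigs
#'
#' A thin S4 container for read alignments in SAM coordinates converted to
#' 0-based half-open reference positions. Secondary (flag 0x100) and
#' supplementary (0x800) records are kept but flagged so that depth and
#' pileup computations can exclude them.
#'
#' @slot seqinfo Named integer vector of reference lengths (from \code{@SQ}).
#' @slot data data.frame with columns \code{read_id}, \code{ref_id},
#'   \code{ref_start} (0-based), \code{strand}, \code{cigar}, \code{seq}
#'   (possibly \code{NA}), \code{qual}, \code{secondary}, \code{supplementary}.
#' @exportClass PhageAlignments
setClass("PhageAlignments",
  representation(seqinfo = "integer", data = "data.frame"),
  validity = function(object) {
    if (is.null(names(object@seqinfo)) && length(object@seqinfo) > 0L)
      return("seqinfo must be named")
    ok <- .validAlignmentData(object@data)
    if (!isTRUE(ok)) return(ok)
    if (nrow(object@data) > 0L &&
        !all(object@data$ref_id %in% names(object@seqinfo)))
      return("alignment ref_id absent from seqinfo")
    TRUE
  })

#' Per-position read depth on one contig
#'
#' @slot refId Contig identifier.
#' @slot depth Integer vector, one entry per contig position.
#' @slot medianDepth Median of \code{depth}; the robust normalizer used by
#'   peak segmentation (the DTR peak itself would bias a mean).
#' @exportClass DepthProfile
setClass("DepthProfile",
  representation(refId = "character", depth = "integer",
                 medianDepth = "numeric"),
  validity = function(object) {
    if (any(object@depth < 0L)) return("negative depth")
    TRUE
  })

#' Classified elevated-coverage signal for terminus inference
#'
#' @slot case One of \code{FLAT}, \code{INTERNAL_PEAK}, \code{LEFT_PEAK},
#'   \code{RIGHT_PEAK}, \code{AMBIGUOUS}.
#' @slot regions data.frame of elevated regions (\code{start}, \code{end},
#'   \code{mean_norm}), 0-based half-open, sorted by start.
#' @exportClass TerminusSignal
setClass("TerminusSignal",
  representation(case = "character", regions = "data.frame"),
  validity = function(object) {
    cases <- c("FLAT", "INTERNAL_PEAK", "LEFT_PEAK", "RIGHT_PEAK", "AMBIGUOUS")
    if (!object@case %in% cases)
      return(paste("case must be one of", paste(cases, collapse = ", ")))
    if (object@case == "FLAT" && nrow(object@regions) != 0L)
      return("FLAT signal cannot carry regions")
    TRUE
  })

#' Resolved direct terminal repeat annotation
#'
#' @slot dtrLength Repeat length D in bp.
#' @slot leftStart,leftEnd,rightStart,rightEnd 0-based half-open coordinates
#'   of the two copies. In a finished genome \code{leftStart == 0} and
#'   \code{rightEnd} equals the contig length.
#' @slot evidence \code{SELF_REPEAT}, \code{COVERAGE} or \code{BOTH}.
#' @slot identity Fraction of positions matching between the two copies.
#' @slot depthRatio Mean normalized depth of the supporting coverage region
#'   (NA when evidence is sequence-only).
#' @slot conflict TRUE when coverage and self-repeat evidence disagree on D
#'   by more than 5 bp.
#' @exportClass DTRAnnotation
setClass("DTRAnnotation",
  representation(dtrLength = "integer",
                 leftStart = "integer", leftEnd = "integer",
                 rightStart = "integer", rightEnd = "integer",
                 evidence = "character", identity = "numeric",
                 depthRatio = "numeric", conflict = "logical"),
  validity = function(object) {
    if (object@leftEnd - object@leftStart != object@dtrLength ||
        object@rightEnd - object@rightStart != object@dtrLength)
      return("copy interval lengths must equal dtrLength")
    if (!object@evidence %in% c("SELF_REPEAT", "COVERAGE", "BOTH"))
      return("evidence must be SELF_REPEAT, COVERAGE or BOTH")
    if (object@identity < 0 || object@identity > 1)
      return("identity must be in [0, 1]")
    TRUE
  })

#' Outcome of DTR resolution on one contig
#'
#' @slot status One of \code{FINISHED} (terminal self-repeat at both ends),
#'   \code{INSET} (self-repeat found but not flanking, e.g. behind adapter
#'   flanks), \code{NO_DTR}, \code{RELINEARIZE_INTERNAL},
#'   \code{RELINEARIZE_LEFT}, \code{RELINEARIZE_RIGHT}.
#' @slot annotation \linkS4class{DTRAnnotation} or NULL.
#' @slot regionStart,regionEnd Proposed edit region (0-based half-open) for
#'   the RELINEARIZE_* statuses, NA otherwise.
#' @slot signal \linkS4class{TerminusSignal} backing the decision.
#' @slot warnings Character vector of reportable caveats.
#' @exportClass DtrResolution
setClass("DtrResolution",
  representation(status = "character", annotation = "ANY",
                 regionStart = "integer", regionEnd = "integer",
                 signal = "ANY", warnings = "character"),
  validity = function(object) {
    sts <- c("FINISHED", "INSET", "NO_DTR", "RELINEARIZE_INTERNAL",
             "RELINEARIZE_LEFT", "RELINEARIZE_RIGHT")
    if (!object@status %in% sts)
      return(paste("status must be one of", paste(sts, collapse = ", ")))
    TRUE
  })

#' Simulation parameters for a T7-like phage genome and its reads
#'
#' Defaults are parameterized on the przondovirus study conditions: a
#' 41,642 bp genome at GC 0.5264 with a 181 bp DTR, 64 bp terminal
#' adapter/barcode flanks carrying a 23 bp adapter core, and a 79 bp
#' spurious tandem unit.
#'
#' @slot genomeLength Genome length G in bp.
#' @slot dtrLength DTR length D in bp (0 for no terminal repeat).
#' @slot gcTarget Target GC fraction of the unique region.
#' @slot anchorMotif Canonical start motif planted at position 0 (inside the
#'   left DTR); "" for none.
#' @slot seed Integer seed; every sampler derives its stream from it.
#' @slot longRead List: meanLen, sdLen, minLen, count, subRate, indelRate,
#'   homopolymerIndelBoost.
#' @slot shortRead List: readLen, insertMean, insertSd, pairs,
#'   endExclusionZone.
#' @slot adapterSet Named character vector of adapter sequences.
#' @slot artifact List: flankLen, adapterCoreLen, tandemUnitLen,
#'   tandemPosOffset.
#' @exportClass SimulationConfig
setClass("SimulationConfig",
  representation(genomeLength = "integer", dtrLength = "integer",
                 gcTarget = "numeric", anchorMotif = "character",
                 seed = "integer", longRead = "list", shortRead = "list",
                 adapterSet = "character", artifact = "list"),
  validity = function(object) {
    G <- object@genomeLength; D <- object@dtrLength
    if (G <= 0L) return("genomeLength must be positive")
    if (D < 0L || 2L * D >= G) return("need 0 <= 2*dtrLength < genomeLength")
    if (object@gcTarget <= 0 || object@gcTarget >= 1)
      return("gcTarget must lie strictly in (0, 1)")
    lr <- object@longRead
    rates <- c(lr$subRate, lr$indelRate)
    if (any(rates < 0 | rates > 1)) return("error rates must lie in [0, 1]")
    if (lr$homopolymerIndelBoost < 1)
      return("homopolymerIndelBoost must be >= 1")
    if (object@shortRead$endExclusionZone < 0)
      return("endExclusionZone must be >= 0")
    if (nchar(object@anchorMotif) > 0L &&
        nchar(object@anchorMotif) > G - 2L * D)
      return("anchorMotif longer than the unique region")
    TRUE
  })

#' Ground truth for a simulated phage genome
#'
#' @slot id Genome identifier.
#' @slot seq Genome sequence (character, A/C/G/T).
#' @slot dtrLength DTR length D; \code{seq[0:D] == seq[G-D:G]} exactly.
#' @slot anchor The planted canonical start motif ("" if none).
#' @slot config The \linkS4class{SimulationConfig} that produced it.
#' @exportClass TruthSet
setClass("TruthSet",
  representation(id = "character", seq = "character", dtrLength = "integer",
                 anchor = "character", config = "ANY"),
  validity = function(object) {
    G <- nchar(object@seq); D <- object@dtrLength
    if (D > 0L &&
        substr(object@seq, 1L, D) != substr(object@seq, G - D + 1L, G))
      return("terminal repeat copies are not identical")
    TRUE
  })

#' Audit record of one curation run
#'
#' @slot inputId,inputLength Identity and length of the input contig.
#' @slot actions Ordered list of applied edits; each entry carries the edit
#'   type, its coordinates, and before/after lengths, and suffices to replay
#'   the edit on the original sequence.
#' @slot dtr Final \linkS4class{DTRAnnotation} or NULL.
#' @slot discordantCount Number of discordant pileup sites on the output.
#' @slot warnings Character vector.
#' @slot config Configuration echo (flat list).
#' @slot finalId,finalLength Identity and length of the output genome.
#' @slot version Package version string.
#' @exportClass CurationReport
setClass("CurationReport",
  representation(inputId = "character", inputLength = "integer",
                 actions = "list", dtr = "ANY",
                 discordantCount = "integer", warnings = "character",
                 config = "list", finalId = "character",
                 finalLength = "integer", version = "character"))

setMethod("show", "PhageAlignments", function(object) {
  d <- object@data
  cat("PhageAlignments:", nrow(d), "records on",
      length(object@seqinfo), "reference(s)\n")
  if (nrow(d) > 0L)
    cat("  secondary:", sum(d$secondary),
        " supplementary:", sum(d$supplementary), "\n")
})

setMethod("show", "DepthProfile", function(object) {
  cat("DepthProfile for", object@refId, "-", length(object@depth),
      "positions, median depth", object@medianDepth, "\n")
})

setMethod("show", "TerminusSignal", function(object) {
  cat("TerminusSignal:", object@case, "with", nrow(object@regions),
      "elevated region(s)\n")
})

setMethod("show", "DTRAnnotation", function(object) {
  cat(sprintf(
    "DTRAnnotation: D=%d bp, left [%d,%d), right [%d,%d), %s, identity %.3f%s\n",
    object@dtrLength, object@leftStart, object@leftEnd, object@rightStart,
    object@rightEnd, object@evidence, object@identity,
    if (isTRUE(object@conflict)) " [CONFLICT]" else ""))
})

setMethod("show", "DtrResolution", function(object) {
  cat("DtrResolution:", object@status, "\n")
  if (!is.null(object@annotation)) show(object@annotation)
  if (!is.na(object@regionStart))
    cat(sprintf("  proposed region [%d,%d)\n",
                object@regionStart, object@regionEnd))
  for (w in object@warnings) cat("  warning:", w, "\n")
})

setMethod("show", "TruthSet", function(object) {
  cat(sprintf("TruthSet '%s': %d bp, DTR %d bp, anchor '%s'\n", object@id,
              nchar(object@seq), object@dtrLength, object@anchor))
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf("SimulationConfig: G=%d bp, D=%d bp, GC %.4f, seed %d\n",
              object@genomeLength, object@dtrLength, object@gcTarget,
              object@seed))
})

setMethod("show", "CurationReport", function(object) {
  cat(sprintf("CurationReport: '%s' (%d bp) -> '%s' (%d bp), %d edit(s), %d discordant site(s)\n",
              object@inputId, object@inputLength, object@finalId,
              object@finalLength, length(object@actions),
              object@discordantCount))
  for (a in object@actions)
    cat(sprintf("  %s: %d -> %d bp\n", a$type, a$before_length,
                a$after_length))
  for (w in object@warnings) cat("  warning:", w, "\n")
})
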