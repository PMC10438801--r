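# The curation pipeline: sequences coverage analysis, DTR resolution and
# relinearization, flank trimming, tandem-artifact collapse, a final
# discordance scan and reorientation into one deterministic run with a
# replayable audit trail.

#' Curation pipeline configuration
#'
#' Flat key-value list of every tunable; all defaults match the individual
#' stage functions. Echoed into the \linkS4class{CurationReport}.
#'
#' @param theta,segMinLen,maxGap,endMargin Coverage segmentation and
#'   classification (see [segmentElevated()], [classifyTerminusSignal()]).
#' @param window,repeatMinLen,maxDivergence Terminal self-repeat search
#'   (see [findTerminalSelfRepeat()]).
#' @param maxFlank,maxEditFrac Flank detection (see [findTerminalFlanks()]).
#' @param tandemWindow,unitRange,tandemMaxDivergence Tandem-artifact scan
#'   (see [findTandemArtifacts()]).
#' @param minSupport,minJunctionFlank,minLocalDepth Junction-support verdict
#'   (see [junctionSupport()], [callTandemVerdict()]).
#' @param qcMinDepth,qcMinAltFraction Discordance scan (see
#'   [discordanceScan()]).
#' @param anchor Canonical start anchor for reorientation ("" disables).
#' @param anchorMaxEdit Edit tolerance of the anchor search.
#' @param collapseInDtr Collapse tandem artifacts overlapping a DTR copy
#'   (default FALSE: flag for review instead of auto-editing).
#' @return Named list.
#' @export
curationConfig <- function(theta = 1.6, segMinLen = 50L, maxGap = 10L,
                           endMargin = 100L, window = 1000L,
                           repeatMinLen = 30L, maxDivergence = 0.02,
                           maxFlank = 200L, maxEditFrac = 0.15,
                           tandemWindow = 2000L, unitRange = c(20L, 500L),
                           tandemMaxDivergence = 0.05, minSupport = 2L,
                           minJunctionFlank = 50L, minLocalDepth = 5L,
                           qcMinDepth = 10L, qcMinAltFraction = 0.7,
                           anchor = "", anchorMaxEdit = 2L,
                           collapseInDtr = FALSE) {
  as.list(environment())
}

## ---- alignment coordinate maintenance -------------------------------------

# Shift all alignments by delta; drop records that would leave
# [0, newLen) and return the kept set.
.shiftAlignments <- function(aln, delta, newLen, refId) {
  d <- aln@data
  if (nrow(d)) {
    d$ref_start <- d$ref_start + as.integer(delta)
    span <- cigarRefSpan(d$cigar)
    keep <- d$ref_start >= 0L & d$ref_start + span <= newLen
    d <- d[keep, , drop = FALSE]
    d$ref_id <- refId
  }
  phageAlignments(d, stats::setNames(as.integer(newLen), refId))
}

# Remap alignments through the rotation contig[rs:] + contig[:rs] (old
# length L). Records crossing the rotation cut are dropped (they would
# need to be split; the local depth loss is negligible and no decision
# downstream of the rotation depends on depth).
.rotateAlignments <- function(aln, rs, L, newLen, refId) {
  d <- aln@data
  if (nrow(d)) {
    span <- cigarRefSpan(d$cigar)
    crosses <- d$ref_start < rs & d$ref_start + span > rs
    d <- d[!crosses, , drop = FALSE]
    span <- span[!crosses]
    d$ref_start <- ifelse(d$ref_start >= rs, d$ref_start - rs,
                          d$ref_start + L - rs)
    keep <- d$ref_start + span <= newLen
    d <- d[keep, , drop = FALSE]
    d$ref_id <- refId
  }
  phageAlignments(d, stats::setNames(as.integer(newLen), refId))
}

## ---- the pipeline ----------------------------------------------------------

.action <- function(type, before, after, ...) {
  c(list(type = type, before_length = as.integer(before),
         after_length = as.integer(after)), list(...))
}

# Does any adapter hit the terminal `margin` bases of the contig?
.terminalAdapterHits <- function(seq, adapters, margin = 200L,
                                 maxEditFrac = 0.15) {
  if (is.null(adapters)) return(FALSE)
  n <- nchar(seq)
  m <- min(margin, n)
  for (aid in names(adapters)) {
    maxk <- floor(maxEditFrac * nchar(adapters[[aid]]))
    for (w in c(substr(seq, 1L, m), substr(seq, n - m + 1L, n))) {
      if (!is.null(.bestAdapterHit(w, adapters[[aid]], maxk))) return(TRUE)
    }
  }
  FALSE
}

#' Run the full curation pipeline on one contig
#'
#' Stage order: (1) depth profile and terminus signal; (2) DTR resolution,
#' applying a proposed relinearization unless the terminal 200 bp contain
#' adapter hits (in which case the edit is deferred until after flank
#' trimming, since relinearizing a flanked contig would rotate the
#' artifacts into the genome); (3) terminal flank detection and trimming;
#' (4) tandem-artifact detection, junction-support testing, and collapse of
#' ARTIFACT verdicts (right-to-left so stored coordinates stay valid);
#' (5) DTR re-resolution on the edited sequence, applying a deferred
#' relinearization, and a warning if the result is not
#' self-repeat-finished; (6) pileup discordance scan; (7) reorientation to
#' the configured anchor. Every edit is appended to the report; the
#' pipeline is deterministic given its inputs.
#'
#' @param contigSeq Contig sequence (character scalar).
#' @param alignments A \linkS4class{PhageAlignments} of reads mapped to the
#'   contig.
#' @param adapters Named character vector of adapter sequences, or NULL.
#' @param config List from [curationConfig()].
#' @param contigId Contig identifier for the report.
#' @return List with \code{seq} (curated genome), \code{report}
#'   (\linkS4class{CurationReport}) and \code{sites} (discordant-site
#'   data.frame).
#' @export
curate <- function(contigSeq, alignments, adapters = NULL,
                   config = curationConfig(), contigId = "contig") {
  stopifnot(is(alignments, "PhageAlignments"))
  cfg <- utils::modifyList(curationConfig(), config)
  seq <- .normalizeSeq(contigSeq, contigId)
  inputLength <- nchar(seq)
  if (length(alignments@seqinfo) != 1L)
    stop("curate expects alignments against exactly one reference")
  refId <- names(alignments@seqinfo)
  if (alignments@seqinfo[[1L]] != inputLength)
    stop("alignment reference length does not match the contig")
  aln <- alignments
  actions <- list()
  warnings <- character(0)

  resolveNow <- function(s, prof) {
    resolveDtr(s, prof, window = cfg$window, minLen = cfg$repeatMinLen,
               maxDivergence = cfg$maxDivergence, theta = cfg$theta,
               segMinLen = cfg$segMinLen, maxGap = cfg$maxGap,
               endMargin = cfg$endMargin)
  }
  profileNow <- function(s) depthFromAlignments(nchar(s), aln, refId)

  applyRelin <- function(s, res) {
    case <- sub("RELINEARIZE_", "", res@status)
    before <- nchar(s)
    out <- relinearize(s, res@regionStart, res@regionEnd, case)
    D <- nchar(out) - before
    if (case == "INTERNAL") {
      L <- before
      aln <<- .rotateAlignments(aln, res@regionStart, L, nchar(out), refId)
    } else if (case == "RIGHT") {
      aln <<- .shiftAlignments(aln, D, nchar(out), refId)
    } else {
      aln <<- .shiftAlignments(aln, 0L, nchar(out), refId)
    }
    actions[[length(actions) + 1L]] <<-
      .action("relinearize", before, nchar(out), case = case,
              region_start = res@regionStart, region_end = res@regionEnd)
    out
  }

  # (1) + (2)
  prof <- profileNow(seq)
  if (prof@medianDepth == 0)
    warnings <- c(warnings, "no usable coverage; proceeding sequence-only")
  res <- resolveNow(seq, prof)
  warnings <- c(warnings, res@warnings)
  deferred <- FALSE
  if (startsWith(res@status, "RELINEARIZE")) {
    if (.terminalAdapterHits(seq, adapters, 200L, cfg$maxEditFrac)) {
      deferred <- TRUE
      warnings <- c(warnings,
                    "relinearization deferred: terminal adapter hits present")
    } else {
      seq <- applyRelin(seq, res)
      prof <- profileNow(seq)
      res <- resolveNow(seq, prof)
    }
  }

  # (3) terminal flanks
  fl <- findTerminalFlanks(seq, dtr = res@annotation, adapters = adapters,
                           maxFlank = cfg$maxFlank,
                           maxEditFrac = cfg$maxEditFrac, profile = prof)
  if (nrow(fl) > 0L) {
    before <- nchar(seq)
    tr <- trimTerminalFlanks(seq, fl)
    seq <- tr$seq
    leftCut <- if (any(fl$side == "LEFT")) fl$end[fl$side == "LEFT"] else 0L
    aln <- .shiftAlignments(aln, -leftCut, nchar(seq), refId)
    actions[[length(actions) + 1L]] <-
      .action("trim_flanks", before, nchar(seq),
              flanks = lapply(seq_len(nrow(fl)), function(i)
                list(side = fl$side[i], start = fl$start[i],
                     end = fl$end[i],
                     adapter_id = fl$adapter_id[i],
                     inverted_partner = fl$inverted_partner[i])))
    prof <- profileNow(seq)
    res <- resolveNow(seq, prof)
    warnings <- c(warnings, res@warnings)
  }

  # (4) tandem artifacts
  dtrB <- if (!is.null(res@annotation))
    c(res@annotation@leftStart, res@annotation@leftEnd,
      res@annotation@rightStart, res@annotation@rightEnd)
  else if (!is.na(res@regionStart)) c(res@regionStart, res@regionEnd)
  else NULL
  cands <- findTandemArtifacts(seq, searchWindow = cfg$tandemWindow,
                               unitRange = cfg$unitRange,
                               maxDivergence = cfg$tandemMaxDivergence,
                               dtrBoundaries = dtrB)
  if (nrow(cands) > 0L) {
    cands <- cands[order(-cands$start1), , drop = FALSE]   # right-to-left
    for (i in seq_len(nrow(cands))) {
      cand <- cands[i, , drop = FALSE]
      sup <- junctionSupport(cand, aln, minFlank = cfg$minJunctionFlank)
      dep <- mean(prof@depth[(cand$start1 + 1L):cand$end2])
      call <- callTandemVerdict(cand, sup, dep,
                                minSupport = cfg$minSupport,
                                minDepth = cfg$minLocalDepth)
      overlapsDtr <- FALSE
      if (!is.null(res@annotation)) {
        a <- res@annotation
        overlapsDtr <-
          (cand$start1 < a@leftEnd & cand$end2 > a@leftStart) ||
          (cand$start1 < a@rightEnd & cand$end2 > a@rightStart)
      }
      if (call$verdict == "ARTIFACT" && overlapsDtr && !cfg$collapseInDtr) {
        warnings <- c(warnings, sprintf(
          "tandem artifact at [%d,%d) overlaps a DTR copy; flagged, not collapsed",
          cand$start1, cand$end2))
        next
      }
      if (call$verdict == "ARTIFACT") {
        before <- nchar(seq)
        seq <- collapseTandemArtifact(seq, call)
        u <- cand$unit_length
        d <- aln@data
        if (nrow(d)) {
          d$ref_start <- ifelse(d$ref_start >= cand$end2, d$ref_start - u,
                                d$ref_start)
          aln <- phageAlignments(d, stats::setNames(nchar(seq), refId))
          aln <- .shiftAlignments(aln, 0L, nchar(seq), refId)
        } else {
          aln <- phageAlignments(d, stats::setNames(nchar(seq), refId))
        }
        actions[[length(actions) + 1L]] <-
          .action("collapse_tandem", before, nchar(seq),
                  unit_length = u, copy1_start = cand$start1,
                  copy2_start = cand$start2, copy2_end = cand$end2,
                  junction_support = call$junction_support)
      } else if (call$verdict != "SUPPORTED") {
        warnings <- c(warnings, sprintf(
          "tandem candidate at [%d,%d) left %s (support %d, depth %.1f)",
          cand$start1, cand$end2, call$verdict, call$junction_support, dep))
      }
    }
    if (length(actions) > 0L) prof <- profileNow(seq)
  }

  # (5) re-resolution on the edited sequence
  res <- resolveNow(seq, prof)
  if (startsWith(res@status, "RELINEARIZE")) {
    seq <- applyRelin(seq, res)
    res <- resolveNow(seq, NULL)
  }
  if (res@status != "FINISHED")
    warnings <- c(warnings, paste0(
      "termini not self-repeat-finished after curation (status ",
      res@status, ")"))
  dtrFinal <- res@annotation

  # (6) discordance scan
  sites <- NULL
  d <- aln@data
  if (nrow(d) > 0L && !any(is.na(d$seq))) {
    pu <- pileupCounts(nchar(seq), aln)
    sites <- discordanceScan(pu, seq, minDepth = cfg$qcMinDepth,
                             minAltFraction = cfg$qcMinAltFraction)
  } else {
    warnings <- c(warnings, "alignments carry no sequences; discordance scan skipped")
    sites <- discordanceScan(list(depth = integer(nchar(seq)),
                                  baseCounts = matrix(0L, 5L, nchar(seq)),
                                  delStart = integer(nchar(seq)),
                                  delCover = integer(nchar(seq)),
                                  insCount = integer(nchar(seq)),
                                  insAllele = vector("list", nchar(seq))),
                             seq)
  }

  # (7) reorientation
  if (nzchar(cfg$anchor)) {
    ro <- reorient(seq, cfg$anchor, cfg$anchorMaxEdit)
    warnings <- c(warnings, ro$warnings)
    if (ro$action == "REVCOMP") {
      before <- nchar(seq)
      seq <- ro$seq
      actions[[length(actions) + 1L]] <-
        .action("revcomp", before, nchar(seq))
      if (!is.null(dtrFinal)) {
        n <- nchar(seq)
        dtrFinal <- new("DTRAnnotation", dtrLength = dtrFinal@dtrLength,
                        leftStart = n - dtrFinal@rightEnd,
                        leftEnd = n - dtrFinal@rightStart,
                        rightStart = n - dtrFinal@leftEnd,
                        rightEnd = n - dtrFinal@leftStart,
                        evidence = dtrFinal@evidence,
                        identity = dtrFinal@identity,
                        depthRatio = dtrFinal@depthRatio,
                        conflict = dtrFinal@conflict)
      }
    }
  }

  report <- new("CurationReport", inputId = contigId,
                inputLength = inputLength, actions = actions,
                dtr = dtrFinal, discordantCount = nrow(sites),
                warnings = unique(warnings), config = cfg,
                finalId = paste0(contigId, "_curated"),
                finalLength = nchar(seq),
                version = as.character(utils::packageVersion("phagecurate")))
  list(seq = seq, report = report, sites = sites)
}

## ---- report serialization and replay --------------------------------------

.dtrToList <- function(a) {
  if (is.null(a)) return(NULL)
  list(dtr_length = a@dtrLength, left = c(a@leftStart, a@leftEnd),
       right = c(a@rightStart, a@rightEnd), evidence = a@evidence,
       identity = a@identity, depth_ratio = a@depthRatio,
       conflict = a@conflict)
}

#' Write a curation report as JSON
#'
#' @param report A \linkS4class{CurationReport}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeCurationReport <- function(report, path) {
  obj <- list(schema = "phagecurate_report/1",
              version = report@version,
              input = list(id = report@inputId,
                           length = report@inputLength),
              output = list(id = report@finalId,
                            length = report@finalLength),
              actions = report@actions,
              dtr = .dtrToList(report@dtr),
              discordant_sites = report@discordantCount,
              warnings = as.list(report@warnings),
              config = report@config)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

#' Read a curation report from JSON
#'
#' @param path Path written by [writeCurationReport()].
#' @return A \linkS4class{CurationReport}.
#' @export
readCurationReport <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  dtr <- NULL
  if (!is.null(obj$dtr)) {
    d <- obj$dtr
    dtr <- new("DTRAnnotation", dtrLength = as.integer(d$dtr_length),
               leftStart = as.integer(d$left[[1L]]),
               leftEnd = as.integer(d$left[[2L]]),
               rightStart = as.integer(d$right[[1L]]),
               rightEnd = as.integer(d$right[[2L]]),
               evidence = d$evidence, identity = as.numeric(d$identity),
               depthRatio = if (is.null(d$depth_ratio) ||
                                is.na(suppressWarnings(as.numeric(d$depth_ratio))))
                 NA_real_ else as.numeric(d$depth_ratio),
               conflict = isTRUE(d$conflict))
  }
  cfgList <- lapply(obj$config, function(v)
    if (is.list(v)) unlist(v) else v)
  new("CurationReport", inputId = obj$input$id,
      inputLength = as.integer(obj$input$length),
      actions = lapply(obj$actions, function(a) {
        a$before_length <- as.integer(a$before_length)
        a$after_length <- as.integer(a$after_length)
        a
      }),
      dtr = dtr, discordantCount = as.integer(obj$discordant_sites),
      warnings = as.character(unlist(obj$warnings)),
      config = cfgList, finalId = obj$output$id,
      finalLength = as.integer(obj$output$length),
      version = obj$version)
}

#' Replay a report's recorded edits on the original contig
#'
#' Applies the ordered sequence edits recorded in a
#' \linkS4class{CurationReport} to the original contig sequence; the result
#' must reproduce the curated output byte-exactly (the audit-trail
#' property).
#'
#' @param contigSeq The original contig sequence.
#' @param report A \linkS4class{CurationReport}.
#' @return Character scalar: the replayed curated sequence.
#' @export
replayEdits <- function(contigSeq, report) {
  seq <- .normalizeSeq(contigSeq, report@inputId)
  for (a in report@actions) {
    stopifnot(nchar(seq) == a$before_length)
    seq <- switch(a$type,
      relinearize = relinearize(seq, a$region_start, a$region_end, a$case),
      trim_flanks = {
        fl <- do.call(rbind, lapply(a$flanks, function(f)
          data.frame(side = f$side, start = as.integer(f$start),
                     end = as.integer(f$end))))
        trimTerminalFlanks(seq, fl)$seq
      },
      collapse_tandem = {
        call <- data.frame(start1 = as.integer(a$copy1_start),
                           end1 = as.integer(a$copy2_start),
                           start2 = as.integer(a$copy2_start),
                           end2 = as.integer(a$copy2_end),
                           unit_length = as.integer(a$unit_length),
                           divergence = 0, junction_support = 0L,
                           local_depth = 0, verdict = "ARTIFACT")
        collapseTandemArtifact(seq, call)
      },
      revcomp = revComp(seq),
      stop("unknown action type: ", a$type))
    stopifnot(nchar(seq) == a$after_length)
  }
  seq
}
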