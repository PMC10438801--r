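# Pileup-based discordance scan: flags residual SNP/indel errors between
# the assembly and its reads, with homopolymer-context annotation. The scan
# flags sites, it does not auto-correct the consensus -- it is the
# verification instrument, not a polisher.

.BASE_CODE <- c(A = 1L, C = 2L, G = 3L, T = 4L, N = 5L)

#' Per-position allele counts from alignments
#'
#' Counts are derived by a CIGAR walk: matched bases (\code{M,=,X})
#' contribute a base allele, deletions contribute a DEL allele keyed to the
#' first deleted position (and deletion coverage over their span),
#' insertions are keyed to the gap after the preceding reference position,
#' and soft-clipped bases are ignored. Secondary and supplementary records
#' are excluded, so each read contributes at most one allele per position.
#'
#' @param contigLength Contig length in bp.
#' @param alignments A \linkS4class{PhageAlignments} whose records carry
#'   sequences.
#' @return List with \code{baseCounts} (5 x n integer matrix, rows
#'   A,C,G,T,N), \code{delStart} (deletion events keyed to first deleted
#'   position), \code{delCover} (positions spanned by deletions),
#'   \code{insCount} (insertion events after each position),
#'   \code{insAllele} (example inserted sequence per position) and
#'   \code{depth} (base alleles + deletion spans).
#' @export
pileupCounts <- function(contigLength, alignments) {
  stopifnot(is(alignments, "PhageAlignments"))
  n <- as.integer(contigLength)
  d <- alignments@data
  d <- d[!d$secondary & !d$supplementary, , drop = FALSE]
  if (nrow(d) > 0L && any(is.na(d$seq)))
    stop("pileup requires alignment records with sequences")
  posAll <- vector("list", nrow(d)); codeAll <- vector("list", nrow(d))
  delStart <- integer(n); delCover <- integer(n)
  insCount <- integer(n); insAllele <- vector("list", n)
  for (i in seq_len(nrow(d))) {
    p <- .parseCigar(d$cigar[i])
    bases <- strsplit(d$seq[i], "")[[1L]]
    rpos <- d$ref_start[i]   # 0-based
    qpos <- 1L               # 1-based into read
    mp <- integer(0); mc <- integer(0)
    for (k in seq_along(p$op)) {
      op <- p$op[k]; len <- p$len[k]
      if (op %in% c("M", "=", "X")) {
        mp <- c(mp, rpos:(rpos + len - 1L))
        mc <- c(mc, .BASE_CODE[bases[qpos:(qpos + len - 1L)]])
        rpos <- rpos + len; qpos <- qpos + len
      } else if (op == "D") {
        delStart[rpos + 1L] <- delStart[rpos + 1L] + 1L
        delCover[(rpos + 1L):(rpos + len)] <-
          delCover[(rpos + 1L):(rpos + len)] + 1L
        rpos <- rpos + len
      } else if (op == "I") {
        if (rpos > 0L) {
          insCount[rpos] <- insCount[rpos] + 1L   # gap after position rpos-1
          if (is.null(insAllele[[rpos]]))
            insAllele[[rpos]] <- paste(bases[qpos:(qpos + len - 1L)],
                                       collapse = "")
        }
        qpos <- qpos + len
      } else if (op == "S") {
        qpos <- qpos + len
      } else if (op == "N") {
        rpos <- rpos + len
      }
      # H, P: nothing consumed from SEQ
    }
    posAll[[i]] <- mp; codeAll[[i]] <- mc
  }
  pos <- unlist(posAll); code <- unlist(codeAll)
  baseCounts <- matrix(0L, nrow = 5L, ncol = n,
                       dimnames = list(names(.BASE_CODE), NULL))
  if (length(pos)) {
    tab <- tabulate((pos) * 5L + code, nbins = 5L * n)
    baseCounts[] <- tab
  }
  depth <- colSums(baseCounts) + delCover
  list(baseCounts = baseCounts, delStart = delStart, delCover = delCover,
       insCount = insCount, insAllele = insAllele,
       depth = as.integer(depth))
}

# Length of the longest homopolymer run overlapping [pos-2, pos+2]
# (0-based pos) -- frameshift errors concentrate in such runs.
.homopolymerLen <- function(runLen, pos, n) {
  lo <- max(1L, pos - 1L); hi <- min(n, pos + 3L)   # 1-based window
  max(runLen[lo:hi])
}

#' Scan a pileup for discordant sites
#'
#' Emits a site wherever depth reaches \code{minDepth} and a non-reference
#' allele (substitution, deletion, or insertion after the position) reaches
#' \code{minAltFraction} of the covering reads. The default fraction 0.7 is
#' chosen so that true assembly errors (near-unanimous read disagreement)
#' pass while sequencing noise does not. Each site is annotated with the
#' length of the longest homopolymer run overlapping position +/- 2.
#'
#' @param pu Pileup from [pileupCounts()].
#' @param seq The contig sequence the pileup was computed against.
#' @param minDepth Minimum covering reads at a site.
#' @param minAltFraction Minimum fraction of covering reads supporting the
#'   alternative allele.
#' @return data.frame sorted by position: \code{position} (0-based),
#'   \code{ref_base}, \code{kind} (\code{SNP}, \code{INS}, \code{DEL}),
#'   \code{alt}, \code{alt_fraction}, \code{depth},
#'   \code{homopolymer_len}.
#' @export
discordanceScan <- function(pu, seq, minDepth = 10L, minAltFraction = 0.7) {
  n <- length(pu$depth)
  x <- strsplit(toupper(seq), "")[[1L]]
  stopifnot(length(x) == n)
  r <- rle(x)
  runLen <- rep(r$lengths, r$lengths)
  refCode <- .BASE_CODE[x]
  rows <- list()
  eligible <- which(pu$depth >= minDepth)
  for (p1 in eligible) {
    dp <- pu$depth[p1]
    counts <- c(pu$baseCounts[1:4, p1], DEL = pu$delStart[p1])
    counts[refCode[p1]] <- 0L   # mask the reference allele
    top <- which.max(counts)
    if (counts[top] / dp >= minAltFraction) {
      kind <- if (names(counts)[top] == "DEL") "DEL" else "SNP"
      alt <- if (kind == "DEL") "-" else names(counts)[top]
      rows[[length(rows) + 1L]] <- data.frame(
        position = p1 - 1L, ref_base = x[p1], kind = kind, alt = alt,
        alt_fraction = counts[[top]] / dp, depth = dp,
        homopolymer_len = .homopolymerLen(runLen, p1 - 1L, n))
    }
    if (pu$insCount[p1] > 0L && pu$insCount[p1] / dp >= minAltFraction) {
      rows[[length(rows) + 1L]] <- data.frame(
        position = p1 - 1L, ref_base = x[p1], kind = "INS",
        alt = pu$insAllele[[p1]] %||% "+",
        alt_fraction = pu$insCount[p1] / dp, depth = dp,
        homopolymer_len = .homopolymerLen(runLen, p1 - 1L, n))
    }
  }
  if (!length(rows))
    return(data.frame(position = integer(0), ref_base = character(0),
                      kind = character(0), alt = character(0),
                      alt_fraction = numeric(0), depth = integer(0),
                      homopolymer_len = integer(0)))
  out <- do.call(rbind, rows)
  out[order(out$position), , drop = FALSE]
}

#' Write discordant sites as a minimal VCF-like tab file
#'
#' Columns: CHROM, POS (1-based), REF, ALT, DP, AF, HP_LEN.
#'
#' @param sites data.frame from [discordanceScan()].
#' @param refId Contig name.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeDiscordantSites <- function(sites, refId, path) {
  hdr <- "#CHROM\tPOS\tREF\tALT\tDP\tAF\tHP_LEN"
  body <- if (nrow(sites))
    paste(refId, sites$position + 1L, sites$ref_base,
          ifelse(sites$kind == "INS", paste0("+", sites$alt), sites$alt),
          sites$depth, sprintf("%.4f", sites$alt_fraction),
          sites$homopolymer_len, sep = "\t")
  else character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}
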