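# Sequence utilities and FASTA/FASTQ/SAM/BED readers and writers.
# Sequences travel internally as plain upper-case character scalars over
# {A,C,G,T,N}; Biostrings does the heavy lifting at the file boundary.

.ALPHABET <- c("A", "C", "G", "T", "N")

# Normalize raw sequence text: upper-case, RNA U -> T. Returns the string or
# stops naming the record and the 0-based offset of the first illegal char.
.normalizeSeq <- function(s, id = "<seq>") {
  s <- chartr("u", "T", toupper(s))
  s <- chartr("U", "T", s)
  bad <- regexpr("[^ACGTN]", s)
  if (bad != -1L)
    stop(sprintf("illegal character '%s' in record '%s' at offset %d",
                 substr(s, bad, bad), id, bad - 1L))
  s
}

#' Reverse complement of a nucleotide string
#'
#' @param seq Character scalar over \code{A,C,G,T,N} (case-insensitive,
#'   \code{U} accepted and converted).
#' @return Character scalar; an involution (\code{revComp(revComp(s)) == s}),
#'   with \code{N} mapping to \code{N}.
#' @examples
#' revComp("ANC")  # "GNT"
#' @export
revComp <- function(seq) {
  seq <- .normalizeSeq(seq)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' GC content of a nucleotide string
#'
#' \code{N} bases are excluded from both numerator and denominator.
#'
#' @param seq Character scalar over \code{A,C,G,T,N}.
#' @return Fraction in \code{[0, 1]}.
#' @examples
#' gcContent("ACGTN")  # 0.5
#' @export
gcContent <- function(seq) {
  seq <- .normalizeSeq(seq)
  if (nchar(seq) == 0L) stop("empty sequence")
  counts <- Biostrings::letterFrequency(Biostrings::DNAString(seq),
                                        c("A", "C", "G", "T"))
  denom <- sum(counts)
  if (denom == 0L) stop("sequence contains no unambiguous bases")
  unname((counts[["C"]] + counts[["G"]]) / denom)
}

#' Read a FASTA file
#'
#' Sequences are upper-cased, \code{U} is converted to \code{T}, and any
#' character outside \code{A,C,G,T,N,U} is rejected with the record id and
#' 0-based offset.
#'
#' @param path Path to an existing FASTA file.
#' @return A named \code{DNAStringSet} in file order; names hold the full
#'   header line (id and description).
#' @export
readFasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(raw))
  seqs <- vapply(seq_along(raw), function(i)
    .normalizeSeq(as.character(raw[[i]]), ids[i]), character(1))
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- names(raw)
  out
}

#' Write sequences to a FASTA file
#'
#' Round-trips with [readFasta()] modulo case and line-width normalization.
#'
#' @param x Named \code{DNAStringSet}, or a named character vector of
#'   sequences.
#' @param path Output path.
#' @param lineWidth Wrap width in characters.
#' @return \code{path}, invisibly.
#' @export
writeFasta <- function(x, path, lineWidth = 70L) {
  if (is.character(x)) {
    if (is.null(names(x))) stop("sequences must be named")
    nm <- names(x)
    x <- Biostrings::DNAStringSet(vapply(seq_along(x), function(i)
      .normalizeSeq(x[[i]], nm[i]), character(1)))
    names(x) <- nm
  }
  if (length(x) == 0L) stop("refusing to write an empty record list")
  Biostrings::writeXStringSet(x, filepath = path, width = lineWidth)
  invisible(path)
}

#' Read a FASTQ file (Phred+33)
#'
#' @param path Path to a FASTQ file.
#' @return data.frame with columns \code{id}, \code{seq}, \code{qual}.
#' @export
readFastq <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L) stop("truncated FASTQ: ", path)
  if (length(lines) == 0L) stop("empty FASTQ file: ", path)
  ids <- sub("^@", "", sub("\\s.*$", "", lines[seq(1L, length(lines), 4L)]))
  seqs <- toupper(lines[seq(2L, length(lines), 4L)])
  quals <- lines[seq(4L, length(lines), 4L)]
  if (any(nchar(seqs) != nchar(quals)))
    stop("FASTQ quality length mismatch in ", path)
  data.frame(id = ids, seq = seqs, qual = quals)
}

#' Write reads to a FASTQ file (Phred+33)
#'
#' @param reads data.frame with columns \code{id}, \code{seq} and optionally
#'   \code{qual} (defaults to Q40 for every base).
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeFastq <- function(reads, path) {
  qual <- if ("qual" %in% names(reads) && !all(is.na(reads$qual)))
    reads$qual
  else
    vapply(nchar(reads$seq), function(n) strrep("I", n), character(1))
  writeLines(paste0("@", reads$id, "\n", reads$seq, "\n+\n", qual), path)
  invisible(path)
}

## ---- CIGAR utilities -------------------------------------------------------

# Parse one CIGAR string into a list(op = character, len = integer).
.parseCigar <- function(cigar) {
  if (!grepl(.CIGAR_RE, cigar)) stop("malformed CIGAR: ", cigar)
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1L]])
  ops <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))[[1L]]
  list(op = ops, len = lens)
}

#' Reference span of a CIGAR string
#'
#' Sum of the lengths of reference-consuming operations
#' (\code{M,=,X,D,N}).
#'
#' @param cigar Character vector of CIGAR strings.
#' @return Integer vector of reference spans.
#' @export
cigarRefSpan <- function(cigar) {
  vapply(cigar, function(cg) {
    p <- .parseCigar(cg)
    sum(p$len[p$op %in% c("M", "=", "X", "D", "N")])
  }, integer(1), USE.NAMES = FALSE)
}

# Read-consuming length (M,I,S,=,X) -- must equal nchar(SEQ) when present.
.cigarReadLen <- function(cigar) {
  vapply(cigar, function(cg) {
    p <- .parseCigar(cg)
    sum(p$len[p$op %in% c("M", "I", "S", "=", "X")])
  }, integer(1), USE.NAMES = FALSE)
}

# Covered reference blocks (0-based half-open) of one alignment: M,=,X and D
# count as covered (copy-number support, not base agreement); N splits.
.cigarRefBlocks <- function(cigar, refStart) {
  p <- .parseCigar(cigar)
  pos <- refStart
  starts <- integer(0); ends <- integer(0)
  open <- NA_integer_
  for (k in seq_along(p$op)) {
    op <- p$op[k]; len <- p$len[k]
    if (op %in% c("M", "=", "X", "D")) {
      if (is.na(open)) open <- pos
      pos <- pos + len
    } else if (op == "N") {
      if (!is.na(open)) { starts <- c(starts, open); ends <- c(ends, pos) }
      open <- NA_integer_
      pos <- pos + len
    }
    # I, S, H, P consume no reference
  }
  if (!is.na(open)) { starts <- c(starts, open); ends <- c(ends, pos) }
  cbind(start = starts, end = ends)
}

## ---- SAM -------------------------------------------------------------------

#' Construct a PhageAlignments object
#'
#' @param data data.frame of alignment records (see
#'   \linkS4class{PhageAlignments}); \code{qual} is optional.
#' @param seqinfo Named integer vector of reference lengths.
#' @return A \linkS4class{PhageAlignments}.
#' @export
phageAlignments <- function(data, seqinfo) {
  if (is.null(data$qual)) data$qual <- NA_character_
  if (is.null(data$secondary)) data$secondary <- FALSE
  if (is.null(data$supplementary)) data$supplementary <- FALSE
  seqinfo <- stats::setNames(as.integer(seqinfo), names(seqinfo))
  data$ref_start <- as.integer(data$ref_start)
  new("PhageAlignments", seqinfo = seqinfo, data = data)
}

#' Read a text SAM file
#'
#' SAM \code{POS} is converted from 1-based to the package's 0-based
#' convention. Unmapped records (flag 0x4) are skipped with a logged count;
#' secondary (0x100) and supplementary (0x800) records are kept but flagged.
#'
#' @param path Path to a SAM file with \code{@SQ} header lines for every
#'   reference that is aligned to.
#' @return A \linkS4class{PhageAlignments}; the number of skipped unmapped
#'   records is available as \code{attr(x, "nUnmapped")}.
#' @export
readSam <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "@")]
  rec <- lines[!startsWith(lines, "@") & nzchar(lines)]
  sq <- hdr[startsWith(hdr, "@SQ")]
  sn <- sub(".*\tSN:([^\t]+).*", "\\1", sq)
  ln <- as.integer(sub(".*\tLN:([0-9]+).*", "\\1", sq))
  seqinfo <- stats::setNames(ln, sn)
  nUnmapped <- 0L
  if (length(rec) == 0L) {
    out <- phageAlignments(
      data.frame(read_id = character(0), ref_id = character(0),
                 ref_start = integer(0), strand = character(0),
                 cigar = character(0), seq = character(0),
                 qual = character(0), secondary = logical(0),
                 supplementary = logical(0)), seqinfo)
    attr(out, "nUnmapped") <- nUnmapped
    return(out)
  }
  f <- strsplit(rec, "\t", fixed = TRUE)
  nf <- lengths(f)
  if (any(nf < 11L)) stop("SAM record with fewer than 11 fields")
  m <- matrix(unlist(lapply(f, `[`, 1:11)), ncol = 11L, byrow = TRUE)
  flag <- as.integer(m[, 2L])
  unmapped <- bitwAnd(flag, 4L) != 0L
  nUnmapped <- sum(unmapped)
  if (nUnmapped > 0L)
    message(nUnmapped, " unmapped record(s) skipped")
  m <- m[!unmapped, , drop = FALSE]
  flag <- flag[!unmapped]
  if (!all(m[, 3L] %in% names(seqinfo)))
    stop("alignment reference absent from @SQ header: ",
         setdiff(m[, 3L], names(seqinfo))[1L])
  seqs <- ifelse(m[, 10L] == "*", NA_character_, m[, 10L])
  df <- data.frame(
    read_id = m[, 1L], ref_id = m[, 3L],
    ref_start = as.integer(m[, 4L]) - 1L,
    strand = ifelse(bitwAnd(flag, 16L) != 0L, "-", "+"),
    cigar = m[, 6L], seq = seqs,
    qual = ifelse(m[, 11L] == "*", NA_character_, m[, 11L]),
    secondary = bitwAnd(flag, 256L) != 0L,
    supplementary = bitwAnd(flag, 2048L) != 0L)
  has <- !is.na(df$seq)
  if (any(has)) {
    want <- .cigarReadLen(df$cigar[has])
    gotten <- nchar(df$seq[has])
    if (any(want != gotten))
      stop("CIGAR/sequence length mismatch for read ",
           df$read_id[has][which(want != gotten)[1L]])
  }
  out <- phageAlignments(df, seqinfo)
  attr(out, "nUnmapped") <- nUnmapped
  out
}

#' Write alignments as a text SAM file
#'
#' The 0-based \code{ref_start} is converted back to SAM's 1-based
#' \code{POS}; \code{@SQ} lines are emitted for every reference.
#'
#' @param alignments A \linkS4class{PhageAlignments}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeSam <- function(alignments, path) {
  stopifnot(is(alignments, "PhageAlignments"))
  si <- alignments@seqinfo
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", names(si), si),
           "@PG\tID:phagecurate\tPN:phagecurate")
  d <- alignments@data
  span <- if (nrow(d)) cigarRefSpan(d$cigar) else integer(0)
  if (nrow(d) && any(d$ref_start + span > si[d$ref_id]))
    stop("alignment span exceeds reference bounds")
  flag <- ifelse(d$strand == "-", 16L, 0L) +
    ifelse(d$secondary, 256L, 0L) + ifelse(d$supplementary, 2048L, 0L)
  body <- if (nrow(d)) paste(d$read_id, flag, d$ref_id, d$ref_start + 1L,
                             60L, d$cigar, "*", 0L, 0L,
                             ifelse(is.na(d$seq), "*", d$seq),
                             ifelse(is.na(d$qual), "*", d$qual),
                             sep = "\t") else character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}

## ---- BED -------------------------------------------------------------------

#' Write intervals as BED3+name
#'
#' BED is natively 0-based half-open, matching the package's internal
#' convention, so coordinates pass through unchanged.
#'
#' @param intervals data.frame with columns \code{start}, \code{end},
#'   \code{name}.
#' @param refId Contig name for column 1.
#' @param path Output path.
#' @param contigLength Optional contig length for bounds checking.
#' @return \code{path}, invisibly.
#' @export
writeBed <- function(intervals, refId, path, contigLength = NULL) {
  if (nrow(intervals) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  if (any(intervals$end <= intervals$start))
    stop("interval with end <= start")
  if (any(intervals$start < 0L))
    stop("interval with negative start")
  if (!is.null(contigLength) && any(intervals$end > contigLength))
    stop("interval out of contig bounds")
  writeLines(paste(refId, intervals$start, intervals$end, intervals$name,
                   sep = "\t"), path)
  invisible(path)
}
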