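#' Construct a sequence record
#'
#' A `SequenceRecord` is a named nucleotide sequence over the alphabet
#' {A, C, G, T, N}, together with the genomic (or promoter-frame) offset of
#' its first residue. All analysis functions in the package accept either a
#' `SequenceRecord` or a plain character string.
#'
#' @param id character scalar, sequence name.
#' @param residues character scalar, nucleotide sequence; lowercase input is
#'   uppercased on construction.
#' @param origin_offset integer, 0-based internal coordinate of the first
#'   residue in whatever frame the caller is working in. Default 0.
#' @return An object of class `SequenceRecord`.
#' @export
#' @examples
#' seq_record("s1", "acGTN")
seq_record <- function(id, residues, origin_offset = 0L) {
  stopifnot(is.character(id), length(id) == 1L,
            is.character(residues), length(residues) == 1L)
  residues <- toupper(residues)
  bad <- gsub("[ACGTN]", "", residues)
  if (nzchar(bad)) {
    stop("sequence '", id, "' contains non-ACGTN characters: ",
         paste(unique(strsplit(bad, "")[[1]]), collapse = ""))
  }
  structure(
    list(id = id, residues = residues,
         origin_offset = as.integer(origin_offset)),
    class = "SequenceRecord"
  )
}

#' @export
print.SequenceRecord <- function(x, ...) {
  n <- nchar(x$residues)
  prev <- if (n > 60L) paste0(substr(x$residues, 1L, 57L), "...") else x$residues
  cat(sprintf("SequenceRecord '%s': %d bp (offset %d)\n  %s\n",
              x$id, n, x$origin_offset, prev))
  invisible(x)
}

#' @export
length.SequenceRecord <- function(x) nchar(x$residues)

# Accept a SequenceRecord or a bare string; returns the uppercase residues.
as_residues <- function(x) {
  if (inherits(x, "SequenceRecord")) return(x$residues)
  if (is.character(x) && length(x) == 1L) {
    r <- toupper(x)
    bad <- gsub("[ACGTN]", "", r)
    if (nzchar(bad)) stop("sequence contains non-ACGTN characters")
    return(r)
  }
  stop("expected a SequenceRecord or a single character string")
}

#' Reverse complement of a nucleotide sequence
#'
#' @param x `SequenceRecord` or character scalar.
#' @return Character scalar, the reverse complement (N maps to N).
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(as_residues(x))))
}

#' Read a FASTA file
#'
#' Light structural validation (line-numbered errors for records with empty
#' sequences or sequence data before the first header) is performed before
#' parsing with \code{Biostrings::readBStringSet}. Residues are uppercased;
#' N is permitted.
#'
#' @param path path to a FASTA file.
#' @return List of [seq_record()] objects, one per entry.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) stop("empty FASTA file: ", path)
  if (!startsWith(trimws(lines[nonblank[1]]), ">")) {
    stop("FASTA parse error at line ", nonblank[1],
         ": sequence data before first header")
  }
  hdr <- which(startsWith(trimws(lines), ">"))
  for (i in seq_along(hdr)) {
    from <- hdr[i] + 1L
    to <- if (i < length(hdr)) hdr[i + 1L] - 1L else length(lines)
    body <- if (from > to) character(0) else lines[from:to]
    if (sum(nchar(trimws(body))) == 0L) {
      stop("FASTA parse error at line ", hdr[i], ": empty sequence for header '",
           trimws(lines[hdr[i]]), "'")
    }
  }
  set <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  lapply(seq_along(set), function(i) {
    seq_record(ids[i], as.character(set[[i]]))
  })
}

#' Write sequence records to FASTA
#'
#' @param records list of `SequenceRecord` (or a single record).
#' @param path output path.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  if (inherits(records, "SequenceRecord")) records <- list(records)
  set <- Biostrings::BStringSet(vapply(records, function(r) r$residues,
                                       character(1)))
  names(set) <- vapply(records, function(r) r$id, character(1))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read peak intervals (BED3 / BED6 / narrowPeak)
#'
#' Coordinates are kept 0-based half-open, exactly as stored in the file.
#' narrowPeak extra columns (signalValue, pValue, qValue, summit offset) are
#' retained.
#'
#' @param path tab-separated interval file.
#' @param dialect one of `"bed3"`, `"bed6"`, `"narrowPeak"`.
#' @return A `data.frame` with columns `seq_id, start, end, name, score,
#'   strand` (plus narrowPeak metadata columns), sorted by (seq_id, start).
#' @export
read_peaks <- function(path, dialect = c("bed3", "bed6", "narrowPeak")) {
  dialect <- match.arg(dialect)
  need <- switch(dialect, bed3 = 3L, bed6 = 6L, narrowPeak = 10L)
  df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (ncol(df) < need) {
    stop(dialect, " requires ", need, " columns, found ", ncol(df))
  }
  out <- data.frame(
    seq_id = as.character(df[[1]]),
    start  = as.integer(df[[2]]),
    end    = as.integer(df[[3]]),
    name   = if (ncol(df) >= 4L) as.character(df[[4]])
             else paste0("peak_", seq_len(nrow(df))),
    score  = if (ncol(df) >= 5L) as.numeric(df[[5]]) else NA_real_,
    strand = if (ncol(df) >= 6L) as.character(df[[6]]) else ".",
    stringsAsFactors = FALSE
  )
  if (dialect == "narrowPeak") {
    out$signal_value <- as.numeric(df[[7]])
    out$p_value <- as.numeric(df[[8]])
    out$q_value <- as.numeric(df[[9]])
    out$summit <- as.integer(df[[10]])
  }
  bad <- which(out$start >= out$end | out$start < 0L)
  if (length(bad)) {
    stop("invalid interval (start >= end or negative) at record ",
         paste(bad, collapse = ", "))
  }
  out[order(out$seq_id, out$start), , drop = FALSE]
}

#' Map a promoter-frame coordinate to an internal 0-based offset
#'
#' The promoter frame labels positions ... -2, -1, +1, +2 ... relative to a
#' designated +1 residue (the first base of the annotated first exon); there
#' is no position 0.
#'
#' @param coord nonzero integer promoter coordinate (vectorized).
#' @param plus_one_offset internal 0-based offset of the +1 position.
#' @return Integer internal offset(s).
#' @seealso [offset_to_promoter()], [interval_length_promoter()]
#' @export
#' @examples
#' promoter_to_offset(1, 117)    # 117
#' promoter_to_offset(-117, 117) # 0
promoter_to_offset <- function(coord, plus_one_offset) {
  coord <- as.integer(coord)
  plus_one_offset <- as.integer(plus_one_offset)
  if (any(coord == 0L)) stop("promoter frame has no position 0")
  ifelse(coord > 0L, plus_one_offset + coord - 1L, plus_one_offset + coord)
}

#' Inverse of [promoter_to_offset()]
#'
#' @param offset internal 0-based offset (vectorized).
#' @param plus_one_offset internal offset of the +1 position.
#' @return Nonzero promoter-frame coordinate(s).
#' @export
offset_to_promoter <- function(offset, plus_one_offset) {
  offset <- as.integer(offset)
  plus_one_offset <- as.integer(plus_one_offset)
  ifelse(offset >= plus_one_offset, offset - plus_one_offset + 1L,
         offset - plus_one_offset)
}

#' Length of a promoter-frame interval, inclusive of both endpoints
#'
#' Counts valid positions between two promoter-frame coordinates, skipping
#' the nonexistent position 0. The span -117..+103 therefore has length 220.
#'
#' @param frm,to nonzero promoter coordinates, `frm` not after `to` in the
#'   promoter ordering (... -2, -1, +1, +2 ...).
#' @return Integer count of positions.
#' @export
#' @examples
#' interval_length_promoter(-117, 103) # 220
interval_length_promoter <- function(frm, to) {
  frm <- as.integer(frm); to <- as.integer(to)
  if (frm == 0L || to == 0L) stop("promoter frame has no position 0")
  if (frm > to) stop("'frm' must not be after 'to' in promoter ordering")
  n <- to - frm + 1L
  if (frm < 0L && to > 0L) n <- n - 1L  # position 0 does not exist
  n
}
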