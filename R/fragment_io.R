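#' Read mapped nucleosome-sized fragments
#'
#' Reads nucleosome fragments from BED6, BAM or FASTA into the plain
#' data.frame representation used throughout the package. Coordinates are
#' 0-based half-open internally; sequences are stored uppercased in
#' reference-forward orientation.
#'
#' @param path Input file path.
#' @param format One of `"BED"`, `"BAM"`, `"FASTA"`. Defaults to a guess from
#'   the file extension.
#' @param reference Optional path to an (indexable) reference FASTA. Required
#'   for BED input; for BAM input it replaces the read sequences with the
#'   reference-forward slice of the aligned span.
#' @return A data.frame with columns `contig`, `start`, `end`, `strand`,
#'   `sequence`, `length`. Records whose sequence cannot be resolved are
#'   dropped with a message.
#' @details FASTA input yields coordinate-less fragments: `contig` is the
#'   record id, `start` is 0 and `strand` is `"+"`. BAM records that are
#'   unmapped or secondary (samtools flag 260 semantics) are skipped.
#' @export
read_fragments <- function(path, format = c("BED", "BAM", "FASTA"),
                           reference = NULL) {
  if (!file.exists(path)) stop("cannot read fragment file: ", path)
  if (missing(format)) {
    ext <- toupper(tools::file_ext(path))
    format <- switch(ext,
      BED = "BED", BAM = "BAM",
      FA = "FASTA", FASTA = "FASTA", FNA = "FASTA",
      stop("cannot guess format from extension '", ext, "'; pass format=")
    )
  }
  format <- match.arg(format)
  frags <- switch(format,
    BED = read_fragments_bed(path, reference),
    BAM = read_fragments_bam(path, reference),
    FASTA = read_fragments_fasta(path)
  )
  bad <- is.na(frags$sequence) | nchar(frags$sequence) != frags$length
  if (any(bad)) {
    message(sum(bad), " fragment(s) dropped (unresolvable sequence)")
    frags <- frags[!bad, , drop = FALSE]
  }
  frags$sequence <- toupper(frags$sequence)
  rownames(frags) <- NULL
  validate_fragments(frags)
  frags
}

read_fragments_bed <- function(path, reference) {
  if (is.null(reference)) {
    stop("BED input requires a reference FASTA to resolve sequences")
  }
  gr <- rtracklayer::import(path, format = "BED")
  fa <- open_reference(reference)
  seqs <- as.character(Biostrings::getSeq(fa, granges_unstranded(gr)))
  strand <- as.character(GenomicRanges::strand(gr))
  strand[strand == "*"] <- "+"
  data.frame(
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = strand,
    sequence = seqs,
    length = GenomicRanges::width(gr),
    stringsAsFactors = FALSE
  )
}

read_fragments_bam <- function(path, reference) {
  flags <- Rsamtools::scanBamFlag(
    isUnmappedQuery = FALSE,
    isSecondaryAlignment = FALSE
  )
  param <- Rsamtools::ScanBamParam(flag = flags, what = "seq")
  aln <- GenomicAlignments::readGAlignments(path, param = param)
  gr <- GenomicRanges::granges(aln)
  if (!is.null(reference)) {
    fa <- open_reference(reference)
    seqs <- as.character(Biostrings::getSeq(fa, granges_unstranded(gr)))
  } else {
    # query sequence is reference-forward in BAM; only usable when the
    # alignment span equals the read length (no indels/clipping)
    seqs <- as.character(S4Vectors::mcols(aln)$seq)
    seqs[nchar(seqs) != GenomicRanges::width(gr)] <- NA_character_
  }
  strand <- as.character(GenomicRanges::strand(gr))
  strand[strand == "*"] <- "+"
  data.frame(
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = strand,
    sequence = seqs,
    length = GenomicRanges::width(gr),
    stringsAsFactors = FALSE
  )
}

read_fragments_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  data.frame(
    contig = ids,
    start = 0L,
    end = Biostrings::width(ss),
    strand = "+",
    sequence = as.character(ss),
    length = Biostrings::width(ss),
    stringsAsFactors = FALSE
  )
}

open_reference <- function(reference) {
  if (!file.exists(paste0(reference, ".fai"))) {
    Rsamtools::indexFa(reference)
  }
  Rsamtools::FaFile(reference)
}

# getSeq() reverse-complements minus-strand ranges; we always want the
# reference-forward slice
granges_unstranded <- function(gr) {
  GenomicRanges::strand(gr) <- "*"
  gr
}

validate_fragments <- function(fragments) {
  need <- c("contig", "start", "end", "strand", "sequence", "length")
  miss <- setdiff(need, names(fragments))
  if (length(miss)) stop("fragment table lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (any(fragments$start < 0)) stop("fragment with negative start")
  if (any(fragments$end <= fragments$start)) stop("fragment with end <= start")
  if (any(fragments$length != fragments$end - fragments$start)) {
    stop("fragment length != end - start")
  }
  has_seq <- !is.na(fragments$sequence)
  if (any(nchar(fragments$sequence[has_seq]) !=
          fragments$length[has_seq])) {
    stop("fragment sequence length != coordinate length")
  }
  invisible(fragments)
}

#' Filter fragments by length
#'
#' Keeps fragments with `min_len <= length <= max_len`, preserving order.
#' Mononucleosomal libraries are typically restricted to a narrow band around
#' 147 bp (e.g. 147--149 bp, or 146--148 bp for more trimmed preparations)
#' before profile computation.
#'
#' @param fragments Fragment data.frame (see [read_fragments()]).
#' @param min_len,max_len Inclusive length bounds in bp.
#' @param quiet Suppress the in/out count message.
#' @return The filtered fragment data.frame.
#' @export
filter_by_length <- function(fragments, min_len, max_len, quiet = FALSE) {
  stopifnot(min_len >= 1, max_len >= min_len)
  keep <- fragments$length >= min_len & fragments$length <= max_len
  if (!quiet) {
    message("length filter [", min_len, ", ", max_len, "]: ",
            sum(keep), "/", length(keep), " fragments kept")
  }
  out <- fragments[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Dyad position of fragments
#'
#' The dyad is the central base pair of the wrapped DNA. For a fragment of
#' length L starting at `start` (0-based), the dyad coordinate is
#' `start + floor((L - 1) / 2)`: the exact centre for odd L, the base 5' of
#' centre (reference-forward) for even L.
#'
#' @param fragments Fragment data.frame with coordinates.
#' @return Integer vector of 0-based reference dyad coordinates.
#' @export
dyad_position <- function(fragments) {
  as.integer(fragments$start + (fragments$length - 1L) %/% 2L)
}

#' Build a dyad occurrence table
#'
#' Tallies fragments per dyad position per contig. Duplicate fragments are
#' counted multiply: a position occupied by k fragments has occurrence k, and
#' those occurrences are used as multiplicative weights downstream (see
#' [compute_dcc()]).
#'
#' @param fragments Fragment data.frame with coordinates.
#' @return A `dyad_table`: data.frame with columns `contig`, `pos`
#'   (0-based dyad coordinate), `occurrence`, plus attribute
#'   `total_occurrence`.
#' @export
build_dyad_table <- function(fragments) {
  dy <- dyad_position(fragments)
  key <- paste(fragments$contig, dy, sep = "\r")
  tab <- table(key)
  parts <- strsplit(names(tab), "\r", fixed = TRUE)
  out <- data.frame(
    contig = vapply(parts, `[`, "", 1L),
    pos = as.integer(vapply(parts, `[`, "", 2L)),
    occurrence = as.integer(tab),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$contig, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "total_occurrence") <- nrow(fragments)
  class(out) <- c("dyad_table", "data.frame")
  out
}

#' Construct a dyad table from positions and occurrence counts
#'
#' @param pos Integer vector of 0-based dyad coordinates.
#' @param occurrence Non-negative integer occurrence counts.
#' @param contig Contig name(s), recycled.
#' @return A `dyad_table` (see [build_dyad_table()]).
#' @export
dyad_table <- function(pos, occurrence, contig = "chr") {
  stopifnot(length(pos) == length(occurrence), all(occurrence >= 0))
  out <- data.frame(
    contig = rep_len(as.character(contig), length(pos)),
    pos = as.integer(pos),
    occurrence = as.integer(occurrence),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(paste(out$contig, out$pos))) {
    stop("duplicate dyad positions within a contig")
  }
  out <- out[order(out$contig, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "total_occurrence") <- sum(out$occurrence)
  class(out) <- c("dyad_table", "data.frame")
  out
}

#' Write / read a dyad table as BED-like TSV
#'
#' Columns: contig, pos, pos + 1, occurrence (0-based, half-open, like BED).
#'
#' @param x A `dyad_table`.
#' @param path Output path.
#' @export
write_dyad_table <- function(x, path) {
  df <- data.frame(x$contig, x$pos, x$pos + 1L, x$occurrence)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_dyad_table
#' @export
read_dyad_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("contig", "pos", "end", "occurrence"),
                          stringsAsFactors = FALSE)
  dyad_table(df$pos, df$occurrence, df$contig)
}
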