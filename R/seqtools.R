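## Spliced sequence extraction and translation.

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Extract a spliced transcript or CDS sequence from a genome
#'
#' Concatenates the given exon/CDS segments in transcript (5' to 3')
#' orientation. On the minus strand the segments are taken in descending
#' genomic order and each contributes its reverse complement. The returned
#' object keeps an invertible segment map: every position of the spliced
#' sequence maps to exactly one genomic coordinate.
#'
#' @param genome named character vector (seqid -> sequence)
#' @param segments data.frame with columns `seqid`, `start`, `end`
#'   (1-based inclusive, non-overlapping, one seqid)
#' @param strand "+" or "-"
#' @param transcript_id id stored on the result
#' @return Object of class `spliced_seq`: list with `transcript_id`, `dna`,
#'   `seqid`, `strand` and `segments` (5'->3' order, with 0-based `offset`
#'   of each segment within `dna`).
#' @export
extract_spliced <- function(genome, segments, strand, transcript_id = NA_character_) {
  stopifnot(nrow(segments) >= 1, strand %in% c("+", "-"))
  sq <- unique(segments$seqid)
  if (length(sq) != 1) stop("segments span multiple seqids")
  if (!sq %in% names(genome)) stop("unknown seqid: ", sq)
  chrom <- genome[[sq]]
  if (any(segments$start < 1) || any(segments$end > nchar(chrom)))
    stop("segment outside genome bounds on ", sq)
  segments <- segments[order(segments$start), , drop = FALSE]
  if (nrow(segments) > 1 &&
      any(segments$start[-1] <= segments$end[-nrow(segments)]))
    stop("overlapping segments")
  if (strand == "-") segments <- segments[rev(seq_len(nrow(segments))), , drop = FALSE]

  lens <- segments$end - segments$start + 1L
  segments$offset <- cumsum(c(0L, lens[-length(lens)]))
  pieces <- substring(chrom, segments$start, segments$end)
  if (strand == "-") pieces <- vapply(pieces, .revcomp, character(1), USE.NAMES = FALSE)
  structure(list(transcript_id = transcript_id, dna = paste(pieces, collapse = ""),
                 seqid = sq, strand = strand,
                 segments = segments[, c("start", "end", "offset")]),
            class = "spliced_seq")
}

#' Translate a DNA string with the standard genetic code
#'
#' Codons are read from position 1; a trailing incomplete codon is ignored.
#' Stop codons render `*`; any codon containing a non-ACGT character renders
#' `X`. With `to_first_stop = TRUE` the translation is truncated after the
#' first `*`.
#'
#' @param dna DNA string
#' @param to_first_stop truncate after the first stop codon
#' @return Protein string.
#' @export
translate_dna <- function(dna, to_first_stop = FALSE) {
  n <- nchar(dna)
  if (n < 3) return("")
  starts <- seq(1L, n - 2L, by = 3L)
  codons <- substring(dna, starts, starts + 2L)
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X"
  if (to_first_stop) {
    s <- which(aa == "*")
    if (length(s)) aa <- aa[seq_len(s[1])]
  }
  paste(aa, collapse = "")
}

## 0-based offset of a genomic position within the spliced sequence
.tx_offset <- function(s, genomic_pos) {
  seg <- s$segments
  hit <- which(genomic_pos >= seg$start & genomic_pos <= seg$end)
  if (!length(hit)) stop("position ", genomic_pos, " not in any segment")
  i <- hit[1]
  if (s$strand == "+") seg$offset[i] + (genomic_pos - seg$start[i])
  else seg$offset[i] + (seg$end[i] - genomic_pos)
}

#' Map a genomic position to protein coordinates
#'
#' Inverse of the segment map composed with integer division by 3.
#'
#' @param s a `spliced_seq` built from a CDS chain
#' @param genomic_pos genomic coordinate inside one of the segments
#' @return Named integer vector `c(aa, codon)`, both 0-based.
#' @export
genomic_to_protein_coord <- function(s, genomic_pos) {
  off <- .tx_offset(s, genomic_pos)
  c(aa = off %/% 3L, codon = off %% 3L)
}

#' Genomic segments covering a spliced-coordinate interval
#'
#' Maps an interval in transcript coordinates (1-based inclusive positions in
#' `s$dna`) back to genomic intervals, clipped at segment boundaries. Used to
#' rewrite CDS features after ORF repair.
#'
#' @param s a `spliced_seq`
#' @param tx_start,tx_end 1-based inclusive positions in `s$dna`
#' @return data.frame `start`, `end` in ascending genomic order.
#' @export
segments_for_range <- function(s, tx_start, tx_end) {
  stopifnot(tx_start >= 1, tx_end <= nchar(s$dna), tx_start <= tx_end)
  seg <- s$segments
  out <- list()
  for (i in seq_len(nrow(seg))) {
    len <- seg$end[i] - seg$start[i] + 1L
    a <- seg$offset[i] + 1L        # tx coords covered by this segment
    b <- seg$offset[i] + len
    lo <- max(a, tx_start); hi <- min(b, tx_end)
    if (lo > hi) next
    if (s$strand == "+") {
      out[[length(out) + 1L]] <- c(seg$start[i] + (lo - a), seg$start[i] + (hi - a))
    } else {
      out[[length(out) + 1L]] <- c(seg$end[i] - (hi - a), seg$end[i] - (lo - a))
    }
  }
  m <- do.call(rbind, out)
  df <- data.frame(start = m[, 1], end = m[, 2])
  df[order(df$start), , drop = FALSE]
}

## CDS phase column recomputed from scratch: cumulative length mod 3 in
## transcript order.
.recompute_phase <- function(cds, strand) {
  cds <- cds[order(cds$start), , drop = FALSE]
  ord <- if (strand == "-") rev(seq_len(nrow(cds))) else seq_len(nrow(cds))
  lens <- (cds$end - cds$start + 1L)[ord]
  phase <- (3L - (cumsum(c(0L, lens[-length(lens)])) %% 3L)) %% 3L
  cds$phase <- NA_integer_
  cds$phase[ord] <- phase
  cds
}
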