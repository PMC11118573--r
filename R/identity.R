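## Pairwise global alignment and the three identity metrics: BLAST-style DNA
## identity, gap-compressed protein identity, and partial (windowed) identity.

.AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
                  "M", "F", "P", "S", "T", "W", "Y", "V", "X", "*")

## BLOSUM62 over the 20 amino acids (from Biostrings), with the package's
## conventions for the extended letters: X scores 0 against everything;
## "*" scores +1 against "*" and -4 against anything else.
.blosum62_ext <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    b <- e$BLOSUM62
    m <- matrix(0, 22, 22, dimnames = list(.AA_ALPHABET, .AA_ALPHABET))
    aa20 <- .AA_ALPHABET[1:20]
    m[aa20, aa20] <- b[aa20, aa20]
    m["*", ] <- -4; m[, "*"] <- -4; m["*", "*"] <- 1
    m["X", ] <- 0; m[, "X"] <- 0
    cache <<- m
    m
  }
})

.dna_score_matrix <- function(match = 1, mismatch = -3) {
  ab <- c("A", "C", "G", "T", "N")
  m <- matrix(mismatch, 5, 5, dimnames = list(ab, ab))
  diag(m) <- match
  m["N", ] <- 0; m[, "N"] <- 0
  m
}

.align_core <- function(ref, qry, smat, gap_open, gap_extend) {
  ab <- rownames(smat)
  r <- match(strsplit(ref, "")[[1]], ab) - 1L
  q <- match(strsplit(qry, "")[[1]], ab) - 1L
  if (anyNA(r) || anyNA(q)) stop("sequence contains characters outside the alphabet")
  res <- .align_affine_cpp(r, q, smat, gap_open, gap_extend)
  ops <- res$ops       # 1 = M, 2 = D (ref vs -), 3 = I (- vs qry)
  rc <- strsplit(ref, "")[[1]]
  qc <- strsplit(qry, "")[[1]]
  ar <- character(length(ops)); aq <- character(length(ops))
  i <- 0L; j <- 0L
  for (k in seq_along(ops)) {
    if (ops[k] == 1L) { i <- i + 1L; j <- j + 1L; ar[k] <- rc[i]; aq[k] <- qc[j] }
    else if (ops[k] == 2L) { i <- i + 1L; ar[k] <- rc[i]; aq[k] <- "-" }
    else { j <- j + 1L; ar[k] <- "-"; aq[k] <- qc[j] }
  }
  opc <- c("M", "D", "I")[ops]
  rl <- rle(opc)
  structure(list(aligned_ref = paste(ar, collapse = ""),
                 aligned_qry = paste(aq, collapse = ""),
                 cigar = data.frame(op = rl$values, len = rl$lengths),
                 score = res$score),
            class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("<pairwise_alignment> score %g, %d columns\n  ref: %s\n  qry: %s\n",
              x$score, nchar(x$aligned_ref), x$aligned_ref, x$aligned_qry))
  invisible(x)
}

#' Global DNA alignment
#'
#' Needleman-Wunsch with affine gaps, match score 1, mismatch penalty -3, gap
#' opening penalty 2 (charged on the first gap base) and gap extension
#' penalty 2. Traceback ties are broken diagonal > up > left, so the result
#' is deterministic.
#'
#' @param ref,qry DNA strings (non-empty)
#' @return A `pairwise_alignment`: `aligned_ref`/`aligned_qry` with `-` gaps,
#'   a run-length `cigar` (ops M/I/D) and the alignment `score`.
#' @export
align_dna <- function(ref, qry) {
  if (!nzchar(ref) || !nzchar(qry)) stop("empty sequence")
  .align_core(ref, qry, .dna_score_matrix(), gap_open = 2, gap_extend = 2)
}

#' Global protein alignment
#'
#' BLOSUM62, gap opening penalty 11 (first gap residue), gap extension 2.
#' Alphabet: the 20 amino acids plus `X` (scores 0 vs everything) and `*`
#' (+1 vs `*`, -4 otherwise).
#'
#' @inheritParams align_dna
#' @return A `pairwise_alignment`.
#' @export
align_protein <- function(ref, qry) {
  if (!nzchar(ref) || !nzchar(qry)) stop("empty sequence")
  .align_core(ref, qry, .blosum62_ext(), gap_open = 11, gap_extend = 2)
}

#' BLAST-style DNA identity
#'
#' Number of matching bases over the number of alignment columns; gap columns
#' count in the denominator.
#'
#' @param aln a `pairwise_alignment`
#' @return Fraction in `[0, 1]`.
#' @export
dna_identity <- function(aln) {
  r <- strsplit(aln$aligned_ref, "")[[1]]
  q <- strsplit(aln$aligned_qry, "")[[1]]
  sum(r == q & r != "-") / length(r)
}

## shared worker: identity over a column window with stop truncation and
## reference-gap-run compression
.gc_identity <- function(r, q, cols) {
  if (!length(cols)) return(0)
  r <- r[cols]; q <- q[cols]
  ## truncate after the column containing the query's first stop (the stop
  ## column itself is kept); a stop matching a reference stop ends the
  ## protein and is a match, so it does not truncate anything that matters
  first_stop <- which(q == "*")
  if (length(first_stop)) {
    keep <- seq_len(first_stop[1])
    r <- r[keep]; q <- q[keep]
  }
  matches <- sum(r == q & r != "-")
  refgap <- r == "-"
  ## each maximal run of reference-row gaps counts once
  runs <- rle(refgap)
  denom <- sum(ifelse(runs$values, 1L, runs$lengths))
  if (denom == 0) return(0)
  matches / denom
}

#' Gap-compressed protein identity
#'
#' Alignment columns after the column containing the query's first stop
#' codon (`*`) are discarded; each maximal run of columns gapped in the
#' reference row counts as a single column in the denominator (so a long
#' query-side extension is penalized once, not per residue); the numerator
#' is the number of exact residue matches.
#'
#' @param aln a `pairwise_alignment` of query protein vs reference protein
#' @return Fraction in `[0, 1]`.
#' @export
protein_identity <- function(aln) {
  r <- strsplit(aln$aligned_ref, "")[[1]]
  q <- strsplit(aln$aligned_qry, "")[[1]]
  .gc_identity(r, q, seq_along(r))
}

#' Partial (windowed) protein identity
#'
#' Same formula as [protein_identity()], restricted to the alignment columns
#' covering the given residue spans. The window is the envelope of the
#' columns holding reference residues `ref_span[1]..ref_span[2]` and query
#' residues `qry_span[1]..qry_span[2]` (1-based, inclusive); either span may
#' be `NULL` when that side contributes nothing. Stop truncation considers
#' only stops inside the window, so a premature stop in one block does not
#' zero out downstream blocks.
#'
#' @param aln a `pairwise_alignment`
#' @param ref_span,qry_span integer length-2 vectors of amino-acid positions,
#'   or `NULL`
#' @return Fraction in `[0, 1]`; 0 when both spans are empty.
#' @export
partial_identity <- function(aln, ref_span = NULL, qry_span = NULL) {
  r <- strsplit(aln$aligned_ref, "")[[1]]
  q <- strsplit(aln$aligned_qry, "")[[1]]
  ridx <- cumsum(r != "-")
  qidx <- cumsum(q != "-")
  cols <- integer()
  span_cols <- function(idx, gap, span) {
    if (is.null(span) || span[2] < span[1]) return(integer())
    if (span[1] < 1 || span[2] > max(idx)) stop("span outside alignment")
    which(!gap & idx >= span[1] & idx <= span[2])
  }
  cols <- c(span_cols(ridx, r == "-", ref_span), span_cols(qidx, q == "-", qry_span))
  if (!length(cols)) return(0)
  .gc_identity(r, q, seq(min(cols), max(cols)))
}
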