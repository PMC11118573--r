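## Pair protein-based (miniprot-style) candidate transcripts with DNA-based
## (Liftoff-style) candidate transcripts, with read-through removal and
## multi-copy disambiguation.

## reference transcript id of a protein-based candidate: Target attribute
## when present (the aligner records the source protein), otherwise the id
## stripped of a copy suffix
.prot_base_id <- function(db, id, copy_regex = "_copy\\d+$") {
  tgt <- db_attr(db, id, "Target")
  if (!is.na(tgt)) sub("\\s.*$", "", tgt) else sub(copy_regex, "", id)
}

## gene loci of dna_db overlapped by a span, strand-aware
.span_loci <- function(dna_db, seqid, start, end, strand) {
  locus_overlaps(dna_db, seqid, start, end, strand = strand)
}

#' Match protein-based candidate transcripts to DNA-based candidates
#'
#' A protein-based transcript matches a DNA-based transcript of the same
#' reference transcript when (1) the two loci overlap (same seqid and
#' strand), and (2) the protein-based locus does not overlap any *other*
#' DNA-based gene locus, except loci that the matched gene locus itself also
#' overlaps. Candidates failing either condition are dropped from the pair.
#' DNA-based extra gene copies (genes carrying an `extra_copy_number`
#' attribute) take no part in pairing; they are handled by the copy
#' resolver.
#'
#' @param dna_db,prot_db candidate annotation databases
#' @param copy_regex suffix regex stripped from protein candidate ids to
#'   recover the reference transcript id (when no `Target` attribute exists)
#' @return Named list of `transcript_pair` objects keyed by reference
#'   transcript id, each with `ref_transcript_id`, `dna_transcript_id`,
#'   `prot_candidates`, `chosen_prot` (NA until [resolve_multicopy()]), and
#'   `status` in both/dna_only/prot_only/unmapped.
#' @export
match_transcripts <- function(dna_db, prot_db, copy_regex = "_copy\\d+$") {
  dtx <- db_transcripts(dna_db)
  ## exclude transcripts under extra-copy genes from pairing
  is_copy <- vapply(seq_len(nrow(dtx)), function(i) {
    p <- dtx$parent_id[i]
    !is.na(p) && !is.na(db_attr(dna_db, p, "extra_copy_number"))
  }, logical(1))
  dtx <- dtx[!is_copy, , drop = FALSE]
  ptx <- db_transcripts(prot_db)
  pbase <- vapply(ptx$feature_id, function(id) .prot_base_id(prot_db, id, copy_regex),
                  character(1))

  ids <- unique(c(dtx$feature_id, pbase))
  pairs <- list()
  for (rid in ids) {
    di <- match(rid, dtx$feature_id)
    dna_id <- if (is.na(di)) NA_character_ else rid
    cand <- ptx$feature_id[pbase == rid]
    extra <- character()
    if (!is.na(di)) {
      gene_id <- dtx$parent_id[di]
      gene <- if (!is.na(gene_id)) db_feature(dna_db, gene_id) else dtx[di, , drop = FALSE]
      allowed <- .span_loci(dna_db, gene$seqid, gene$start, gene$end, gene$strand)
      verdict <- vapply(cand, function(cid) {
        ct <- db_feature(prot_db, cid)
        if (ct$seqid != gene$seqid || ct$strand != gene$strand ||
            ct$end < gene$start || ct$start > gene$end)      # fails (1):
          return("extra")                                    # candidate extra locus
        others <- setdiff(.span_loci(dna_db, ct$seqid, ct$start, ct$end, ct$strand),
                          allowed)                           # (2)
        if (length(others)) "drop" else "match"
      }, character(1))
      extra <- cand[verdict == "extra"]
      cand <- cand[verdict == "match"]
    } else {
      extra <- cand
      cand <- character()
    }
    status <- if (!is.na(dna_id) && length(cand)) "both"
      else if (!is.na(dna_id)) "dna_only"
      else if (length(extra)) "prot_only"
      else "unmapped"
    pairs[[rid]] <- structure(
      list(ref_transcript_id = rid, dna_transcript_id = dna_id,
           prot_candidates = cand, extra_candidates = extra,
           chosen_prot = NA_integer_, chosen_identity = NA_real_,
           status = status),
      class = "transcript_pair")
  }
  pairs
}

#' Disambiguate multiple protein-based mappings of one transcript
#'
#' Removes read-through candidates -- mappings whose span intersects more
#' than one DNA-based gene locus (beyond loci the matched locus itself
#' overlaps) and would otherwise fuse neighboring genes -- then selects the
#' remaining candidate with the highest gap-compressed protein identity to
#' the reference protein. Ties are broken by leftmost genomic start.
#'
#' @param pair a `transcript_pair` from [match_transcripts()]
#' @param dna_db,prot_db candidate databases
#' @param ref_protein reference protein string
#' @param genome target genome (named character vector)
#' @return The pair with `prot_candidates` pruned, `chosen_prot` set to an
#'   index into them (or NA when all candidates were removed), and
#'   `chosen_identity`.
#' @export
resolve_multicopy <- function(pair, dna_db, prot_db, ref_protein, genome) {
  cand <- pair$prot_candidates
  if (!length(cand)) return(pair)

  allowed <- character()
  if (!is.na(pair$dna_transcript_id)) {
    tx <- db_feature(dna_db, pair$dna_transcript_id)
    gid <- tx$parent_id
    gene <- if (!is.na(gid)) db_feature(dna_db, gid) else tx
    allowed <- .span_loci(dna_db, gene$seqid, gene$start, gene$end, gene$strand)
  }
  read_through <- vapply(cand, function(cid) {
    ct <- db_feature(prot_db, cid)
    loci <- .span_loci(dna_db, ct$seqid, ct$start, ct$end, ct$strand)
    if (length(allowed)) length(setdiff(loci, allowed)) >= 1L
    else length(loci) >= 2L
  }, logical(1))
  cand <- cand[!read_through]
  pair$prot_candidates <- cand
  if (!length(cand)) {
    pair$chosen_prot <- NA_integer_
    pair$status <- if (!is.na(pair$dna_transcript_id)) "dna_only"
      else if (length(pair$extra_candidates)) "prot_only" else "unmapped"
    return(pair)
  }
  ids <- vapply(cand, function(cid) {
    prot <- .tx_protein(prot_db, cid, genome)
    protein_identity(align_protein(ref_protein, prot))
  }, numeric(1))
  starts <- vapply(cand, function(cid) db_feature(prot_db, cid)$start, numeric(1))
  best <- max(ids)
  pair$chosen_prot <- order(-ids, starts)[1]
  pair$chosen_identity <- best
  pair
}

## translation of a transcript's CDS chain, honoring the first CDS's phase
.tx_protein <- function(db, tx_id, genome) {
  tx <- db_feature(db, tx_id)
  cds <- db_children(db, tx_id, "CDS")
  sp <- extract_spliced(genome, cds[, c("seqid", "start", "end")], tx$strand, tx_id)
  skip <- .phase_skip(cds, tx$strand)
  translate_dna(substring(sp$dna, 1L + skip))
}

.phase_skip <- function(cds, strand) {
  cds <- .tx_order(cds, strand)
  p <- cds$phase[1]
  if (is.na(p)) 0L else as.integer(p)
}
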