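## Resolve overlapping gene loci and accept/reject extra gene copies, with
## the stricter pseudogene filters for protein-only candidates.

#' Create a locus registry
#'
#' Tracks accepted gene loci per seqid and the pairs of reference genes that
#' already overlap in the reference annotation (such overlaps are
#' whitelisted: they may be reproduced in the target regardless of the 10%
#' rule). Strand is ignored for overlap tests: an accepted locus blocks both
#' strands.
#'
#' @param ref_db reference `annotation_db` (used to build the whitelist)
#' @return Object of class `locus_registry`.
#' @export
locus_registry <- function(ref_db = NULL) {
  wl <- character()
  if (!is.null(ref_db)) {
    g <- db_genes(ref_db)
    if (nrow(g) > 1) {
      gr <- GenomicRanges::GRanges(g$seqid, IRanges::IRanges(g$start, g$end))
      hits <- GenomicRanges::findOverlaps(gr, gr, ignore.strand = TRUE)
      qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
      keep <- qi < si
      wl <- unique(paste(pmin(g$feature_id[qi[keep]], g$feature_id[si[keep]]),
                         pmax(g$feature_id[qi[keep]], g$feature_id[si[keep]]),
                         sep = "|"))
    }
  }
  structure(list(
    loci = data.frame(locus_id = character(), ref_gene = character(),
                      seqid = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE),
    whitelist = wl), class = "locus_registry")
}

#' Register an accepted locus
#' @param registry a `locus_registry`
#' @param locus_id unique id of the locus in the target annotation
#' @param ref_gene reference gene the locus derives from
#' @param seqid,start,end target-genome span
#' @return Updated registry.
#' @export
register_locus <- function(registry, locus_id, ref_gene, seqid, start, end) {
  registry$loci <- rbind(registry$loci,
                         data.frame(locus_id = locus_id, ref_gene = ref_gene,
                                    seqid = seqid, start = start, end = end,
                                    stringsAsFactors = FALSE))
  registry
}

.overlap_frac <- function(s1, e1, s2, e2) {
  shared <- min(e1, e2) - max(s1, s2) + 1L
  if (shared <= 0) return(0)
  shared / min(e1 - s1 + 1L, e2 - s2 + 1L)
}

## overlap violation against all registered loci: fraction > max_overlap and
## the reference gene pair is not whitelisted
.overlap_violation <- function(registry, ref_gene, seqid, start, end,
                               max_overlap = 0.10) {
  l <- registry$loci[registry$loci$seqid == seqid, , drop = FALSE]
  for (i in seq_len(nrow(l))) {
    f <- .overlap_frac(start, end, l$start[i], l$end[i])
    if (f <= max_overlap) next
    key <- paste(min(ref_gene, l$ref_gene[i]), max(ref_gene, l$ref_gene[i]), sep = "|")
    if (!(key %in% registry$whitelist)) return(TRUE)
  }
  FALSE
}

#' Admit extra gene copies found by the DNA-based aligner
#'
#' Candidates are processed in descending DNA identity (then genomic
#' position) and accepted when their identity meets the `-sc` threshold and
#' their overlap with every already-accepted locus is at most `max_overlap`
#' (shared bases over the shorter span) or the overlap also exists between
#' the corresponding reference genes.
#'
#' @param candidates data.frame with `locus_id`, `ref_gene`, `seqid`,
#'   `start`, `end`, `dna_identity`
#' @param registry a `locus_registry` (primary loci already registered)
#' @param sc_threshold minimum DNA identity (default 0.95, the `-sc` value)
#' @param max_overlap maximum tolerated overlap fraction (default 0.10)
#' @return list `decisions` (data.frame `locus_id`, `source`, `accepted`,
#'   `reasons`) and the updated `registry`.
#' @export
admit_dna_copies <- function(candidates, registry, sc_threshold = 0.95,
                             max_overlap = 0.10) {
  ord <- order(-candidates$dna_identity, candidates$seqid, candidates$start)
  candidates <- candidates[ord, , drop = FALSE]
  dec <- list()
  for (i in seq_len(nrow(candidates))) {
    cc <- candidates[i, ]
    reasons <- character()
    if (cc$dna_identity < sc_threshold) reasons <- c(reasons, "below_sc_threshold")
    if (.overlap_violation(registry, cc$ref_gene, cc$seqid, cc$start, cc$end, max_overlap))
      reasons <- c(reasons, "overlap_excess")
    accepted <- !length(reasons)
    if (accepted)
      registry <- register_locus(registry, cc$locus_id, cc$ref_gene,
                                 cc$seqid, cc$start, cc$end)
    dec[[i]] <- data.frame(locus_id = cc$locus_id, source = "dna",
                           accepted = accepted,
                           reasons = paste(reasons, collapse = ";"),
                           stringsAsFactors = FALSE)
  }
  list(decisions = if (length(dec)) do.call(rbind, dec) else
         data.frame(locus_id = character(), source = character(),
                    accepted = logical(), reasons = character()),
       registry = registry)
}

## summed CDS length of the longest-coding isoform of a reference gene,
## and the minimum CDS count over its isoforms
.ref_coding_stats <- function(ref_db, gene_id) {
  txs <- db_children(ref_db, gene_id, "transcript")
  best <- 0L; min_n <- Inf
  for (t in txs$feature_id) {
    cds <- db_children(ref_db, t, "CDS")
    if (!nrow(cds)) next
    len <- sum(cds$end - cds$start + 1L)
    if (len > best) best <- len
    min_n <- min(min_n, nrow(cds))
  }
  list(coding_len = best, min_cds_n = if (is.finite(min_n)) as.integer(min_n) else NA_integer_)
}

#' Admit extra gene copies found only by the protein-based aligner
#'
#' Protein-only candidates pass three filters designed to reject processed
#' pseudogenes and partial mappings: (1) overlap with accepted loci at most
#' `max_overlap`; (2) an intronless candidate (single CDS) is accepted only
#' if the reference gene also has a single-CDS isoform (a multi-exon gene
#' collapsing to one CDS is the signature of a retrocopy); (3) the ratio of
#' the candidate's summed CDS length to the coding length of the reference
#' gene's longest isoform must lie in `ratio_bounds`. Accepted copies get a
#' synthesized gene parent copied from the reference gene and carry no UTRs.
#'
#' @param candidates data.frame with `locus_id` (the candidate transcript
#'   id), `ref_gene`, `seqid`, `start`, `end`, `coding_len`, `n_cds`
#' @param registry a `locus_registry`
#' @param ref_db reference `annotation_db`
#' @param ratio_bounds numeric length-2, default `c(0.9, 1.5)`
#' @param max_overlap maximum overlap fraction, default 0.10
#' @return list `decisions` and updated `registry`, as [admit_dna_copies()].
#' @export
admit_prot_copies <- function(candidates, registry, ref_db,
                              ratio_bounds = c(0.9, 1.5), max_overlap = 0.10) {
  ord <- order(candidates$seqid, candidates$start)
  candidates <- candidates[ord, , drop = FALSE]
  dec <- list()
  for (i in seq_len(nrow(candidates))) {
    cc <- candidates[i, ]
    reasons <- character()
    stats <- .ref_coding_stats(ref_db, cc$ref_gene)
    if (.overlap_violation(registry, cc$ref_gene, cc$seqid, cc$start, cc$end, max_overlap))
      reasons <- c(reasons, "overlap_excess")
    if (cc$n_cds == 1L && (is.na(stats$min_cds_n) || stats$min_cds_n > 1L))
      reasons <- c(reasons, "single_cds_mismatch")
    ratio <- if (stats$coding_len > 0) cc$coding_len / stats$coding_len else Inf
    if (ratio < ratio_bounds[1] || ratio > ratio_bounds[2])
      reasons <- c(reasons, "length_ratio_out_of_range")
    accepted <- !length(reasons)
    if (accepted)
      registry <- register_locus(registry, cc$locus_id, cc$ref_gene,
                                 cc$seqid, cc$start, cc$end)
    dec[[i]] <- data.frame(locus_id = cc$locus_id, source = "prot",
                           accepted = accepted,
                           reasons = paste(reasons, collapse = ";"),
                           stringsAsFactors = FALSE)
  }
  list(decisions = if (length(dec)) do.call(rbind, dec) else
         data.frame(locus_id = character(), source = character(),
                    accepted = logical(), reasons = character()),
       registry = registry)
}

#' Assign stable ids to extra gene copies
#'
#' The first-mapped copy of a gene keeps the reference id; extra copies get
#' suffixes `_1`, `_2`, ... and an `extra_copy_number` attribute, numbered
#' deterministically by (seqid, start).
#'
#' @param accepted data.frame with `locus_id`, `ref_gene`, `seqid`, `start`,
#'   and logical `is_primary`
#' @return The input with columns `new_id` and `extra_copy_number` added.
#' @export
assign_copy_ids <- function(accepted) {
  accepted$new_id <- accepted$ref_gene
  accepted$extra_copy_number <- 0L
  for (g in unique(accepted$ref_gene)) {
    sel <- which(accepted$ref_gene == g & !accepted$is_primary)
    sel <- sel[order(accepted$seqid[sel], accepted$start[sel])]
    if (length(sel)) {
      accepted$new_id[sel] <- paste0(g, "_", seq_along(sel))
      accepted$extra_copy_number[sel] <- seq_along(sel)
    }
  }
  accepted
}
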