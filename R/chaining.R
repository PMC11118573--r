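## Step 1 of the protein-maximization algorithm: map CDS boundaries onto the
## protein alignments, group CDSs into comparison blocks with equal aligned
## reference amino-acid counts, select the higher-identity group per block,
## and concatenate the winners into the merged CDS chain.

## order a CDS table into transcript (5'->3') orientation
.tx_order <- function(cds, strand) {
  cds <- cds[order(cds$start), , drop = FALSE]
  if (strand == "-") cds <- cds[rev(seq_len(nrow(cds))), , drop = FALSE]
  cds
}

#' Map CDS boundaries onto a protein alignment
#'
#' Expresses each CDS of a candidate transcript as an interval of
#' *reference-protein* positions. The CDS endpoint in query amino acids is
#' the number of complete codons accumulated up to that CDS; the endpoint is
#' then carried through the pairwise alignment by a column walk (which is
#' where query-side gap runs shift the boundary), and the reference
#' amino-acid count at that column is recorded.
#'
#' @param aln `pairwise_alignment` of the candidate protein (query) vs the
#'   reference protein
#' @param cds data.frame with `start`, `end` (genomic, 1-based)
#' @param strand "+" or "-"
#' @param phase_skip bases skipped before translation when the first CDS is
#'   partial (GFF3 phase of the first CDS)
#' @return data.frame in transcript order with per-CDS `start`, `end`,
#'   `nt_len`, `cum_nt`, `qry_aa_start`, `qry_aa_end`, `ref_aa_end` and
#'   `zero_width` (CDS mapping entirely into a reference gap).
#' @export
map_cds_boundaries <- function(aln, cds, strand, phase_skip = 0L) {
  cds <- .tx_order(cds, strand)
  q <- strsplit(aln$aligned_qry, "")[[1]]
  r <- strsplit(aln$aligned_ref, "")[[1]]
  colq <- which(q != "-")          # column of each query residue
  refcnt <- cumsum(r != "-")
  nq <- length(colq)

  nt_len <- cds$end - cds$start + 1L
  cum_nt <- cumsum(nt_len) - phase_skip
  qry_aa_end <- pmin(pmax(cum_nt %/% 3L, 0L), nq)
  ref_aa_end <- vapply(qry_aa_end, function(k) {
    if (k == 0L) 0L else as.integer(refcnt[colq[k]])
  }, integer(1))
  qry_aa_start <- c(0L, qry_aa_end[-length(qry_aa_end)]) + 1L
  ref_aa_start <- c(0L, ref_aa_end[-length(ref_aa_end)])
  data.frame(start = cds$start, end = cds$end, nt_len = nt_len, cum_nt = cum_nt,
             qry_aa_start = qry_aa_start, qry_aa_end = qry_aa_end,
             ref_aa_end = ref_aa_end,
             zero_width = ref_aa_end == ref_aa_start)
}

#' Group CDSs of the two candidates into comparison blocks
#'
#' Starting from the first CDS of each candidate, CDSs are accumulated until
#' both candidates reach an endpoint with the same number of aligned
#' reference amino acids; that closes one block (a `GL_i`/`GM_i` pair). The
#' final block is forced closed at the last CDS of both candidates even if
#' no shared endpoint exists, and blocks may be one-sided when one candidate
#' runs out of CDSs first.
#'
#' @param dna_map,prot_map boundary maps from [map_cds_boundaries()]
#' @return List of blocks, each `list(dna_idx, prot_idx, ref_end)` with
#'   1-based CDS indices into the respective map (transcript order).
#' @export
form_groups <- function(dna_map, prot_map) {
  nl <- nrow(dna_map); nm <- nrow(prot_map)
  stopifnot(nl >= 1, nm >= 1)
  groups <- list()
  i <- 0L; j <- 0L
  while (i < nl || j < nm) {
    gi <- integer(); gj <- integer()
    if (i < nl) { i <- i + 1L; gi <- i }
    if (j < nm) { j <- j + 1L; gj <- j }
    repeat {
      eL <- if (length(gi)) dna_map$ref_aa_end[gi[length(gi)]] else -Inf
      eM <- if (length(gj)) prot_map$ref_aa_end[gj[length(gj)]] else -Inf
      if (length(gi) && length(gj) && eL == eM) break
      if (i >= nl && j >= nm) break
      if (i < nl && (j >= nm || eL < eM || !length(gi))) {
        i <- i + 1L; gi <- c(gi, i)
      } else {
        j <- j + 1L; gj <- c(gj, j)
      }
    }
    ref_end <- max(if (length(gi)) dna_map$ref_aa_end[gi[length(gi)]] else -Inf,
                   if (length(gj)) prot_map$ref_aa_end[gj[length(gj)]] else -Inf)
    groups[[length(groups) + 1L]] <- list(dna_idx = gi, prot_idx = gj,
                                          ref_end = ref_end)
  }
  groups
}

## partial identity of one side of a block; 0 when that side has no CDS
.block_partial <- function(aln, map, idx, ref_prev, ref_end) {
  if (!length(idx)) return(0)
  qs <- map$qry_aa_start[idx[1]]
  qe <- map$qry_aa_end[idx[length(idx)]]
  ref_span <- if (ref_end > ref_prev) c(ref_prev + 1L, ref_end) else NULL
  qry_span <- if (qe >= qs) c(qs, qe) else NULL
  partial_identity(aln, ref_span = ref_span, qry_span = qry_span)
}

#' Select the winning CDS group per block and build the merged chain
#'
#' For each block the partial protein identity of the DNA-based and the
#' protein-based group is compared; the higher-identity group wins, with
#' ties going to the DNA-based candidate (so UTRs survive downstream).
#' Winners are concatenated; when a source switch lands mid-codon the first
#' CDS of the incoming group is trimmed by up to 2 nt so the reading frame
#' continues. The merged protein identity is recomputed from the merged
#' chain's translation; if it falls below the better single-source
#' candidate, the chain falls back to that candidate wholesale (dominance
#' guard).
#'
#' @param groups blocks from [form_groups()]
#' @param dna_map,prot_map boundary maps from [map_cds_boundaries()]
#' @param dna_aln,prot_aln the candidates' protein alignments to the reference
#' @param ref_protein reference protein string
#' @param genome target genome (named character vector)
#' @param seqid,strand location of the locus in the target genome
#' @param phase_skip_prot phase of the protein candidate's first CDS
#' @return Object of class `chain_selection`: `selected` ("dna"/"prot" per
#'   block), `partial_dna`/`partial_prot`, `merged_cds` (data.frame with
#'   `start`, `end`, `source`, `src_index`, `phase`), `merged_protein_id`,
#'   `fallback`.
#' @export
select_chain <- function(groups, dna_map, prot_map, dna_aln, prot_aln,
                         ref_protein, genome, seqid, strand,
                         phase_skip_prot = 0L) {
  nb <- length(groups)
  sel <- character(nb); pid_d <- numeric(nb); pid_p <- numeric(nb)
  ref_prev <- 0L
  for (b in seq_len(nb)) {
    g <- groups[[b]]
    ref_end_d <- if (length(g$dna_idx)) dna_map$ref_aa_end[g$dna_idx[length(g$dna_idx)]] else ref_prev
    ref_end_p <- if (length(g$prot_idx)) prot_map$ref_aa_end[g$prot_idx[length(g$prot_idx)]] else ref_prev
    pid_d[b] <- .block_partial(dna_aln, dna_map, g$dna_idx, ref_prev, ref_end_d)
    pid_p[b] <- .block_partial(prot_aln, prot_map, g$prot_idx, ref_prev, ref_end_p)
    sel[b] <- if (pid_d[b] >= pid_p[b]) "dna" else "prot"
    ref_prev <- as.integer(max(ref_end_d, ref_end_p))
  }

  build_chain <- function(winners) {
    rows <- list(); cum <- 0L
    for (b in seq_len(nb)) {
      g <- groups[[b]]
      src <- winners[b]
      idx <- if (src == "dna") g$dna_idx else g$prot_idx
      map <- if (src == "dna") dna_map else prot_map
      if (!length(idx)) { # winner side empty: take the other side
        src <- if (src == "dna") "prot" else "dna"
        idx <- if (src == "dna") g$dna_idx else g$prot_idx
        map <- if (src == "dna") dna_map else prot_map
        if (!length(idx)) next
      }
      ## source-local offset of the group start; cum_nt is already expressed
      ## relative to that source's translation start (phase included)
      o_src <- map$cum_nt[idx[1]] - map$nt_len[idx[1]]
      delta <- (cum - o_src) %% 3L
      for (k in seq_along(idx)) {
        st <- map$start[idx[k]]; en <- map$end[idx[k]]
        if (k == 1L && delta > 0L) {
          if (strand == "+") st <- st + delta else en <- en - delta
          if (st > en) next
        }
        rows[[length(rows) + 1L]] <- data.frame(start = st, end = en,
                                                source = src,
                                                src_index = idx[k])
        cum <- cum + (en - st + 1L)
      }
    }
    do.call(rbind, rows)
  }

  merged <- build_chain(sel)
  chain_identity <- function(cds) {
    sp <- extract_spliced(genome, data.frame(seqid = seqid, start = cds$start,
                                             end = cds$end), strand)
    protein_identity(align_protein(ref_protein, translate_dna(sp$dna)))
  }
  merged_id <- chain_identity(merged)

  id_dna <- protein_identity(dna_aln)
  id_prot <- protein_identity(prot_aln)
  fallback <- FALSE
  if (merged_id < max(id_dna, id_prot) - 1e-12) {
    fallback <- TRUE
    if (id_dna >= id_prot) {
      merged <- data.frame(start = dna_map$start, end = dna_map$end,
                           source = "dna", src_index = seq_len(nrow(dna_map)))
      merged_id <- id_dna
    } else {
      merged <- data.frame(start = prot_map$start, end = prot_map$end,
                           source = "prot", src_index = seq_len(nrow(prot_map)))
      merged_id <- id_prot
    }
  }
  merged <- merged[order(merged$start), , drop = FALSE]
  merged <- .recompute_phase(merged, strand)
  rownames(merged) <- NULL
  structure(list(selected = sel, partial_dna = pid_d, partial_prot = pid_p,
                 merged_cds = merged, merged_protein_id = merged_id,
                 fallback = fallback),
            class = "chain_selection")
}

#' @export
print.chain_selection <- function(x, ...) {
  cat(sprintf("<chain_selection> %d blocks [%s], merged protein identity %.4f%s\n",
              length(x$selected), paste(x$selected, collapse = ","),
              x$merged_protein_id, if (x$fallback) " (fallback)" else ""))
  invisible(x)
}
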