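## Step 2 of the protein-maximization algorithm: mutation classification,
## three-frame ORF search, and CDS boundary repair for transcripts carrying
## deleterious mutations.

.DELETERIOUS <- c("frameshift", "stop_gain", "stop_loss", "start_loss")

#' A minimal transcript model
#'
#' Container used by the ORF-repair stage: a transcript on the target genome
#' with its exon set (UTRs included when known) and its CDS chain.
#'
#' @param transcript_id id
#' @param seqid,strand location
#' @param exons data.frame `start`,`end` or NULL (CDS-only transcript)
#' @param cds data.frame `start`,`end`
#' @return Object of class `tx_model`.
#' @export
tx_model <- function(transcript_id, seqid, strand, exons, cds) {
  cds <- cds[order(cds$start), , drop = FALSE]
  if (!is.null(exons)) exons <- exons[order(exons$start), , drop = FALSE]
  structure(list(transcript_id = transcript_id, seqid = seqid, strand = strand,
                 exons = exons, cds = cds),
            class = "tx_model")
}

#' Classify the differences between a reference transcript and its mapping
#'
#' Categories follow the usual lift-over mutation report: `identical` (CDS
#' DNA strings equal; exclusive of all others), `synonymous` (DNA differs,
#' proteins equal), `nonsynonymous` (substitutions changing residues),
#' `inframe_insertion` / `inframe_deletion` (CDS indel with length divisible
#' by 3), `frameshift` (indel length not divisible by 3), `stop_gain` (stop
#' in the target protein aligned before the reference stop), `stop_loss`
#' (reference-terminal stop absent from the target frame) and `start_loss`
#' (target CDS does not begin with ATG while the reference does). Every
#' input pair receives at least one category.
#'
#' @param ref_cds_dna,tgt_cds_dna spliced CDS DNA of the reference and target
#'   transcript
#' @param ref_protein,tgt_protein their translations (not pre-truncated)
#' @return Object of class `mutation_report`: list with `categories`.
#' @export
classify_mutations <- function(ref_cds_dna, tgt_cds_dna, ref_protein = NULL,
                               tgt_protein = NULL) {
  if (is.null(ref_protein)) ref_protein <- translate_dna(ref_cds_dna)
  if (is.null(tgt_protein)) tgt_protein <- translate_dna(tgt_cds_dna)
  if (identical(ref_cds_dna, tgt_cds_dna))
    return(structure(list(categories = "identical"), class = "mutation_report"))
  if (identical(ref_protein, tgt_protein))
    return(structure(list(categories = "synonymous"), class = "mutation_report"))

  cats <- character()
  ## indel detection uses a contiguity-preferring gap cost (open > extend):
  ## under the identity scoring (open == extend) a 3-nt gap can split into
  ## co-optimal 1+2 runs and masquerade as a frameshift
  daln <- .align_core(ref_cds_dna, tgt_cds_dna, .dna_score_matrix(),
                      gap_open = 6, gap_extend = 2)
  indels <- daln$cigar[daln$cigar$op %in% c("I", "D"), , drop = FALSE]
  if (nrow(indels)) {
    inframe <- indels$len %% 3L == 0L
    if (any(indels$op == "I" & inframe)) cats <- c(cats, "inframe_insertion")
    if (any(indels$op == "D" & inframe)) cats <- c(cats, "inframe_deletion")
    if (any(!inframe)) cats <- c(cats, "frameshift")
  }
  if ((nchar(tgt_cds_dna) - nchar(ref_cds_dna)) %% 3L != 0L)
    cats <- union(cats, "frameshift")

  paln <- align_protein(ref_protein, tgt_protein)
  r <- strsplit(paln$aligned_ref, "")[[1]]
  q <- strsplit(paln$aligned_qry, "")[[1]]
  sub_cols <- r != "-" & q != "-" & r != q & r != "*" & q != "*"
  if (any(sub_cols)) cats <- c(cats, "nonsynonymous")
  ## stop gained: a target stop aligned to a non-stop reference column
  if (any(q == "*" & r != "*")) cats <- c(cats, "stop_gain")
  ## stop lost: reference ends in a stop that the target frame lacks
  if (endsWith(ref_protein, "*") && !grepl("*", tgt_protein, fixed = TRUE))
    cats <- c(cats, "stop_loss")
  if (startsWith(ref_cds_dna, "ATG") && !startsWith(tgt_cds_dna, "ATG"))
    cats <- c(cats, "start_loss")
  if (!length(cats)) cats <- "nonsynonymous"
  structure(list(categories = unique(cats)), class = "mutation_report")
}

#' @export
print.mutation_report <- function(x, ...) {
  cat("<mutation_report>", paste(x$categories, collapse = ";"), "\n")
  invisible(x)
}

#' Has a report any deleterious category?
#' @param report a `mutation_report`
#' @return logical
#' @export
is_deleterious <- function(report) any(report$categories %in% .DELETERIOUS)

#' Three-frame ORF search
#'
#' For each reading frame (0, 1, 2) of the spliced transcript sequence, finds
#' ATG-initiated open reading frames ending at the next in-frame stop codon
#' (TAA/TAG/TGA) or, when no stop follows, at the end of the sequence, and
#' retains the longest one per frame (ties: leftmost start).
#'
#' @param spliced_dna transcript sequence (exons including UTRs when present)
#' @return List of up to 3 ORF candidates: `list(frame, start_offset,
#'   end_offset, protein)` with 1-based nt offsets into `spliced_dna`
#'   (`end_offset` is the last base of the stop codon, or of the last
#'   complete codon when no stop was found).
#' @export
find_orfs <- function(spliced_dna) {
  n <- nchar(spliced_dna)
  out <- list()
  for (frame in 0:2) {
    if (n - frame < 3) next
    starts <- seq(1L + frame, n - 2L, by = 3L)
    codons <- substring(spliced_dna, starts, starts + 2L)
    is_atg <- codons == "ATG"
    is_stop <- codons %in% c("TAA", "TAG", "TGA")
    best <- NULL; open_at <- NA_integer_
    close_orf <- function(from, to_codon, has_stop) {
      list(frame = frame, start_offset = starts[from],
           end_offset = starts[to_codon] + 2L,
           n_codons = to_codon - from + 1L, has_stop = has_stop)
    }
    for (k in seq_along(codons)) {
      if (is.na(open_at) && is_atg[k]) open_at <- k
      if (is_stop[k] && !is.na(open_at)) {
        cand <- close_orf(open_at, k, TRUE)
        if (is.null(best) || cand$n_codons > best$n_codons) best <- cand
        open_at <- NA_integer_
      }
    }
    if (!is.na(open_at)) {
      cand <- close_orf(open_at, length(codons), FALSE)
      if (is.null(best) || cand$n_codons > best$n_codons) best <- cand
    }
    if (!is.null(best)) {
      best$protein <- translate_dna(substring(spliced_dna, best$start_offset,
                                              best$end_offset))
      best$n_codons <- NULL
      out[[length(out) + 1L]] <- best
    }
  }
  out
}

#' Repair the ORF of a transcript carrying a deleterious mutation
#'
#' Runs [find_orfs()] on the spliced transcript (exons including UTRs when
#' the transcript has them, otherwise the CDS chain), scores each frame-best
#' candidate by gap-compressed protein identity against the reference
#' protein, and rewrites the CDS boundaries to the best candidate -- but only
#' if its identity strictly exceeds the identity of the current annotation.
#' Identity ties prefer the frame of the unrepaired annotation, then frame
#' 0 < 1 < 2. Exons are extended where needed so that CDS stays contained.
#'
#' @param tx a [tx_model()]
#' @param genome target genome (named character vector)
#' @param ref_protein reference protein string
#' @param trigger optional `mutation_report`; when given and not deleterious
#'   the transcript is returned unchanged
#' @return list `tx` (possibly updated), `repaired` (logical),
#'   `identity_before`, `identity_after`.
#' @export
orf_repair <- function(tx, genome, ref_protein, trigger = NULL) {
  if (!is.null(trigger) && !is_deleterious(trigger))
    return(list(tx = tx, repaired = FALSE,
                identity_before = NA_real_, identity_after = NA_real_))
  domain <- if (!is.null(tx$exons) && nrow(tx$exons)) tx$exons else tx$cds
  sp <- extract_spliced(genome, data.frame(seqid = tx$seqid, domain),
                        tx$strand, tx$transcript_id)
  cds_sp <- extract_spliced(genome, data.frame(seqid = tx$seqid, tx$cds), tx$strand)
  pre_id <- protein_identity(align_protein(ref_protein, translate_dna(cds_sp$dna)))

  ## transcript-coordinate offset (and hence frame) of the current CDS start
  cds_tx <- .tx_order(tx$cds, tx$strand)
  cur_start <- if (tx$strand == "+") cds_tx$start[1] else cds_tx$end[1]
  cur_frame <- tryCatch(.tx_offset(sp, cur_start) %% 3L, error = function(e) NA_integer_)

  orfs <- find_orfs(sp$dna)
  if (!length(orfs))
    return(list(tx = tx, repaired = FALSE, identity_before = pre_id,
                identity_after = pre_id))
  ids <- vapply(orfs, function(o)
    protein_identity(align_protein(ref_protein, o$protein)), numeric(1))
  frames <- vapply(orfs, `[[`, integer(1), "frame")
  best_id <- max(ids)
  tied <- which(ids >= best_id - 1e-12)
  pick <- if (!is.na(cur_frame) && any(frames[tied] == cur_frame))
    tied[which(frames[tied] == cur_frame)[1]] else tied[which.min(frames[tied])]

  if (best_id <= pre_id + 1e-12)
    return(list(tx = tx, repaired = FALSE, identity_before = pre_id,
                identity_after = pre_id))

  o <- orfs[[pick]]
  new_cds <- segments_for_range(sp, o$start_offset, o$end_offset)
  new_cds <- .recompute_phase(new_cds, tx$strand)
  exons <- tx$exons
  if (!is.null(exons)) exons <- .merge_intervals(rbind(exons[, c("start", "end")],
                                                       new_cds[, c("start", "end")]))
  out <- tx_model(tx$transcript_id, tx$seqid, tx$strand, exons, new_cds)
  list(tx = out, repaired = TRUE, identity_before = pre_id,
       identity_after = best_id)
}

## union of possibly-overlapping intervals
.merge_intervals <- function(df) {
  df <- df[order(df$start), , drop = FALSE]
  out <- df[1, , drop = FALSE]
  for (i in seq_len(nrow(df))[-1]) {
    last <- nrow(out)
    if (df$start[i] <= out$end[last] + 1L) {
      out$end[last] <- max(out$end[last], df$end[i])
    } else out <- rbind(out, df[i, , drop = FALSE])
  }
  rownames(out) <- NULL
  out
}
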