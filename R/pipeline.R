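## Orchestration: read -> pair -> chain -> repair -> resolve copies ->
## write GFF3 + reports.

#' Run configuration
#'
#' @param sc_threshold minimum DNA identity for extra DNA-based gene copies
#'   (the `-sc` parameter; default 0.95)
#' @param max_overlap maximum tolerated overlap fraction between distinct
#'   gene loci (default 0.10)
#' @param ratio_bounds allowed ratio of candidate coding length to the
#'   reference gene's longest-isoform coding length for protein-only copies
#' @param copies search for extra gene copies (the `-copies` flag)
#' @param drop_scaffold_suffixes,drop_biotypes reference preprocessing
#'   filters, see [filter_reference()]
#' @param feature_types top-level feature types lifted over
#' @return A `protlift_config` list.
#' @export
protlift_config <- function(sc_threshold = 0.95, max_overlap = 0.10,
                            ratio_bounds = c(0.9, 1.5), copies = TRUE,
                            drop_scaffold_suffixes = character(),
                            drop_biotypes = character(),
                            feature_types = c("gene", "pseudogene")) {
  stopifnot(sc_threshold > 0, sc_threshold <= 1,
            max_overlap >= 0, max_overlap <= 1,
            length(ratio_bounds) == 2, ratio_bounds[1] < ratio_bounds[2])
  structure(list(sc_threshold = sc_threshold, max_overlap = max_overlap,
                 ratio_bounds = ratio_bounds, copies = copies,
                 drop_scaffold_suffixes = drop_scaffold_suffixes,
                 drop_biotypes = drop_biotypes, feature_types = feature_types),
            class = "protlift_config")
}

## a bare unnamed string is a path; genome maps from read_fasta() are named
.read_if_path <- function(x, reader)
  if (is.character(x) && length(x) == 1 && is.null(names(x))) reader(x) else x

.exons_or_cds <- function(db, tx_id) {
  ex <- db_children(db, tx_id, "exon")
  if (nrow(ex)) ex else db_children(db, tx_id, "CDS")
}

## spliced DNA (exon-level) and CDS chain of a transcript
.tx_seqs <- function(db, tx_id, genome) {
  tx <- db_feature(db, tx_id)
  cds <- db_children(db, tx_id, "CDS")
  ex <- .exons_or_cds(db, tx_id)
  list(tx = tx,
       exon_sp = extract_spliced(genome, ex[, c("seqid", "start", "end")], tx$strand, tx_id),
       cds = cds,
       cds_sp = if (nrow(cds))
         extract_spliced(genome, cds[, c("seqid", "start", "end")], tx$strand, tx_id)
       else NULL)
}

#' Reconcile two candidate annotations of a target genome
#'
#' The full flow: read inputs, filter the reference, pair protein-based with
#' DNA-based candidate transcripts, merge each pair's CDS chains by the
#' chaining algorithm, repair ORFs of transcripts with deleterious
#' mutations, resolve extra gene copies and overlapping loci, and write the
#' merged GFF3 plus mutation/identity reports and a feature census.
#'
#' @param ref_fasta,ref_gff reference genome and annotation (paths or the
#'   objects returned by [read_fasta()] / [read_annotation()])
#' @param target_fasta target genome (path or object)
#' @param dna_gff DNA-based candidate annotation (Liftoff-style)
#' @param prot_gff protein-based candidate annotation (miniprot-style)
#' @param out_prefix output path prefix; `NULL` suppresses file output
#' @param config a [protlift_config()]
#' @param verbose log progress to stderr
#' @return Invisibly, a list: `out_db` (merged annotation), `report`
#'   (per-transcript data.frame with identities and mutation categories),
#'   `unmapped` (data.frame), `copy_decisions`, `census`, `pairs`.
#' @export
protlift_run <- function(ref_fasta, ref_gff, target_fasta, dna_gff, prot_gff,
                         out_prefix = NULL, config = protlift_config(),
                         verbose = FALSE) {
  say <- function(...) if (verbose) message(...)
  ref_genome <- .read_if_path(ref_fasta, read_fasta)
  tgt_genome <- .read_if_path(target_fasta, read_fasta)
  ref_db <- .read_if_path(ref_gff, read_annotation)
  dna_db <- .read_if_path(dna_gff, read_annotation)
  prot_db <- .read_if_path(prot_gff, read_annotation)
  ref_db <- filter_reference(ref_db, config$drop_scaffold_suffixes, config$drop_biotypes)
  ref_db <- .keep_feature_types(ref_db, config$feature_types)

  for (dbx in list(list(ref_db, ref_genome, "reference"),
                   list(dna_db, tgt_genome, "dna candidate"),
                   list(prot_db, tgt_genome, "protein candidate"))) {
    bad <- setdiff(unique(dbx[[1]]$features$seqid), names(dbx[[2]]))
    if (length(bad))
      stop("seqid(s) in ", dbx[[3]], " annotation absent from genome: ",
           paste(bad, collapse = ", "))
  }

  ## reference protein-coding transcripts
  rtx <- db_transcripts(ref_db)
  has_cds <- vapply(rtx$feature_id, function(id) nrow(db_children(ref_db, id, "CDS")) > 0,
                    logical(1))
  coding_ids <- rtx$feature_id[has_cds]
  ref_info <- lapply(coding_ids, function(id) {
    s <- .tx_seqs(ref_db, id, ref_genome)
    list(tx = s$tx, exon_dna = s$exon_sp$dna, cds_dna = s$cds_sp$dna,
         protein = translate_dna(s$cds_sp$dna))
  })
  names(ref_info) <- coding_ids

  say("pairing ", length(coding_ids), " reference protein-coding transcripts")
  pairs <- match_transcripts(dna_db, prot_db)
  for (rid in names(pairs)) {
    if (length(pairs[[rid]]$prot_candidates) && rid %in% coding_ids)
      pairs[[rid]] <- resolve_multicopy(pairs[[rid]], dna_db, prot_db,
                                        ref_info[[rid]]$protein, tgt_genome)
  }

  report <- list(); unmapped <- list(); out_tx <- list()
  for (rid in coding_ids) {
    pr <- pairs[[rid]]
    if (is.null(pr) || pr$status %in% c("unmapped", "prot_only")) {
      if (is.null(pr) || pr$status == "unmapped")
        unmapped[[length(unmapped) + 1L]] <-
          data.frame(feature_id = rid, reason = "no_candidate_mapping")
      next
    }
    ri <- ref_info[[rid]]
    res <- .process_pair(pr, ri, dna_db, prot_db, tgt_genome, say)
    out_tx[[rid]] <- res
    report[[length(report) + 1L]] <- data.frame(
      transcript_id = rid, status = pr$status,
      categories = paste(res$categories, collapse = ";"),
      dna_identity = res$dna_identity, protein_identity = res$protein_identity,
      repaired = res$repaired, fallback = res$fallback,
      stringsAsFactors = FALSE)
  }
  report <- if (length(report)) do.call(rbind, report) else
    data.frame(transcript_id = character(), status = character(),
               categories = character(), dna_identity = numeric(),
               protein_identity = numeric(), repaired = logical(),
               fallback = logical())

  ## ---- copy resolution ----
  registry <- locus_registry(ref_db)
  for (rid in names(out_tx)) {
    tx <- out_tx[[rid]]$tx
    gid <- out_tx[[rid]]$gene_id
    dom <- if (!is.null(tx$exons)) tx$exons else tx$cds
    registry <- register_locus(registry, gid, gid, tx$seqid, min(dom$start), max(dom$end))
  }
  copy_dec <- list(accepted = list())
  if (config$copies) {
    cd <- .resolve_copies(pairs, ref_db, dna_db, prot_db, ref_info,
                          ref_genome, tgt_genome, registry, config)
    copy_dec <- cd
  }

  out_db <- .assemble_output(out_tx, report, dna_db, ref_db, copy_dec, prot_db)
  cen <- census(out_db)

  unmapped <- if (length(unmapped)) do.call(rbind, unmapped) else
    data.frame(feature_id = character(), reason = character())

  if (!is.null(out_prefix)) {
    dir.create(dirname(out_prefix), showWarnings = FALSE, recursive = TRUE)
    write_gff3(out_db, paste0(out_prefix, ".gff3"))
    write.table(report[, c("transcript_id", "categories", "dna_identity",
                           "protein_identity")],
                paste0(out_prefix, ".mutations.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(unmapped, paste0(out_prefix, ".unmapped.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(cen, paste0(out_prefix, ".census.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(list(out_db = out_db, report = report, unmapped = unmapped,
                 copy_decisions = copy_dec$decisions, census = cen,
                 pairs = pairs))
}

.keep_feature_types <- function(db, feature_types) {
  g <- db_genes(db)
  drop <- !(g$orig_type %in% feature_types)
  if (!any(drop)) return(db)
  dead <- g$feature_id[drop]
  repeat {
    more <- db$features$feature_id[!is.na(db$features$parent_id) &
                                     db$features$parent_id %in% dead &
                                     !(db$features$feature_id %in% dead)]
    if (!length(more)) break
    dead <- c(dead, more)
  }
  annotation_db(db$features[!(db$features$feature_id %in% dead), , drop = FALSE])
}

## chain + classify + repair for one paired transcript
.process_pair <- function(pr, ri, dna_db, prot_db, tgt_genome, say) {
  rid <- pr$ref_transcript_id
  d <- .tx_seqs(dna_db, pr$dna_transcript_id, tgt_genome)
  gene_id <- d$tx$parent_id
  strand <- d$tx$strand
  exons <- .exons_or_cds(dna_db, rid)[, c("start", "end")]
  cds <- d$cds[, c("start", "end")]
  fallback <- FALSE; sel <- NULL

  use_chain <- pr$status == "both" && !is.na(pr$chosen_prot)
  if (use_chain) {
    pid <- pr$prot_candidates[pr$chosen_prot]
    p <- db_feature(prot_db, pid)
    if (p$seqid != d$tx$seqid || p$strand != strand) {
      say("  ", rid, ": candidates on different seqid/strand; DNA candidate kept")
      use_chain <- FALSE
    } else {
      pcds <- db_children(prot_db, pid, "CDS")
      skip <- .phase_skip(pcds, strand)
      psp <- extract_spliced(tgt_genome, pcds[, c("seqid", "start", "end")], strand)
      dna_aln <- align_protein(ri$protein, translate_dna(d$cds_sp$dna))
      prot_aln <- align_protein(ri$protein, translate_dna(substring(psp$dna, 1L + skip)))
      dna_map <- map_cds_boundaries(dna_aln, d$cds, strand)
      prot_map <- map_cds_boundaries(prot_aln, pcds, strand, phase_skip = skip)
      groups <- form_groups(dna_map, prot_map)
      sel <- select_chain(groups, dna_map, prot_map, dna_aln, prot_aln,
                          ri$protein, tgt_genome, d$tx$seqid, strand,
                          phase_skip_prot = skip)
      cds <- sel$merged_cds[, c("start", "end")]
      fallback <- sel$fallback
    }
  }

  exons <- .merge_intervals(rbind(exons, cds))
  tx <- tx_model(rid, d$tx$seqid, strand, exons, cds)

  cds_sp <- extract_spliced(tgt_genome, data.frame(seqid = tx$seqid, tx$cds), strand)
  mut <- classify_mutations(ri$cds_dna, cds_sp$dna, ri$protein,
                            translate_dna(cds_sp$dna))
  repaired <- FALSE
  pre_id <- protein_identity(align_protein(ri$protein, translate_dna(cds_sp$dna)))
  prot_id <- pre_id
  if (is_deleterious(mut)) {
    rep <- orf_repair(tx, tgt_genome, ri$protein, trigger = mut)
    stopifnot(rep$identity_after >= rep$identity_before - 1e-12)
    tx <- rep$tx
    repaired <- rep$repaired
    prot_id <- rep$identity_after
  }

  ex_sp <- extract_spliced(tgt_genome, data.frame(seqid = tx$seqid, tx$exons), strand)
  dna_id <- dna_identity(align_dna(ri$exon_dna, ex_sp$dna))
  list(tx = tx, gene_id = gene_id, categories = mut$categories,
       dna_identity = dna_id, protein_identity = prot_id,
       repaired = repaired, fallback = fallback, chain = sel)
}

## extra-copy admission for both sources
.resolve_copies <- function(pairs, ref_db, dna_db, prot_db, ref_info,
                            ref_genome, tgt_genome, registry, config) {
  ## DNA-based extra copies: genes carrying an extra_copy_number attribute
  g <- db_genes(dna_db)
  is_extra <- vapply(g$feature_id, function(id)
    !is.na(db_attr(dna_db, id, "extra_copy_number")), logical(1))
  dna_cand <- list()
  for (gid in g$feature_id[is_extra]) {
    txs <- db_children(dna_db, gid, "transcript")
    if (!nrow(txs)) next
    tid <- txs$feature_id[1]
    base_tid <- sub("_\\d+$", "", tid)
    base_gid <- sub("_\\d+$", "", gid)
    if (!base_tid %in% names(ref_info)) next
    s <- .tx_seqs(dna_db, tid, tgt_genome)
    ident <- dna_identity(align_dna(ref_info[[base_tid]]$exon_dna, s$exon_sp$dna))
    gg <- db_feature(dna_db, gid)
    dna_cand[[length(dna_cand) + 1L]] <- data.frame(
      locus_id = gid, ref_gene = base_gid, seqid = gg$seqid,
      start = gg$start, end = gg$end, dna_identity = ident,
      stringsAsFactors = FALSE)
  }
  dec_d <- list(decisions = NULL, registry = registry)
  if (length(dna_cand))
    dec_d <- admit_dna_copies(do.call(rbind, dna_cand), registry,
                              config$sc_threshold, config$max_overlap)
  registry <- dec_d$registry

  ## protein-only extra copies
  prot_cand <- list()
  for (pr in pairs) {
    for (cid in pr$extra_candidates) {
      rid <- pr$ref_transcript_id
      if (!rid %in% names(ref_info)) next
      ref_gene <- ref_info[[rid]]$tx$parent_id
      ct <- db_feature(prot_db, cid)
      cds <- db_children(prot_db, cid, "CDS")
      prot_cand[[length(prot_cand) + 1L]] <- data.frame(
        locus_id = cid, ref_gene = ref_gene, ref_tx = rid, seqid = ct$seqid,
        start = ct$start, end = ct$end,
        coding_len = sum(cds$end - cds$start + 1L), n_cds = nrow(cds),
        stringsAsFactors = FALSE)
    }
  }
  dec_p <- list(decisions = NULL, registry = registry)
  if (length(prot_cand))
    dec_p <- admit_prot_copies(do.call(rbind, prot_cand), registry, ref_db,
                               config$ratio_bounds, config$max_overlap)

  decisions <- rbind(dec_d$decisions, dec_p$decisions)
  list(decisions = decisions, registry = dec_p$registry,
       prot_cand = if (length(prot_cand)) do.call(rbind, prot_cand) else NULL)
}

## assemble the merged output database
.assemble_output <- function(out_tx, report, dna_db, ref_db, copy_dec, prot_db) {
  rows <- list()
  genes_done <- character()
  for (rid in names(out_tx)) {
    r <- out_tx[[rid]]
    tx <- r$tx
    gid <- r$gene_id
    rep_row <- report[report$transcript_id == rid, ]
    gene_feat <- if (!is.na(gid) && gid %in% dna_db$features$feature_id)
      db_feature(dna_db, gid) else NULL
    span <- c(min(tx$exons$start), max(tx$exons$end))
    if (!is.na(gid) && !(gid %in% genes_done)) {
      ga <- if (!is.null(gene_feat)) gene_feat$attributes[[1]] else character()
      rows[[length(rows) + 1L]] <- .feat(gid, "gene", "gene", tx$seqid,
                                         span[1], span[2], tx$strand,
                                         attrs = ga)
      genes_done <- c(genes_done, gid)
    }
    attrs <- c(mutation = rep_row$categories,
               dna_identity = sprintf("%.6f", rep_row$dna_identity),
               protein_identity = sprintf("%.6f", rep_row$protein_identity))
    rows[[length(rows) + 1L]] <- .feat(rid, "transcript", "mRNA", tx$seqid,
                                       span[1], span[2], tx$strand,
                                       parent = gid, attrs = attrs)
    for (i in seq_len(nrow(tx$exons)))
      rows[[length(rows) + 1L]] <- .feat(paste0(rid, ".exon", i), "exon", "exon",
                                         tx$seqid, tx$exons$start[i], tx$exons$end[i],
                                         tx$strand, parent = rid)
    cdsp <- .recompute_phase(tx$cds, tx$strand)
    for (i in seq_len(nrow(cdsp)))
      rows[[length(rows) + 1L]] <- .feat(paste0(rid, ".cds", i), "CDS", "CDS",
                                         tx$seqid, cdsp$start[i], cdsp$end[i],
                                         tx$strand, phase = cdsp$phase[i], parent = rid)
  }

  dec <- copy_dec$decisions
  if (!is.null(dec) && nrow(dec)) {
    for (i in which(dec$accepted)) {
      lid <- dec$locus_id[i]
      if (dec$source[i] == "dna") {
        ## emit the accepted extra-copy subtree from the dna candidate db
        sub <- .subtree_rows(dna_db, lid)
        rows[[length(rows) + 1L]] <- sub
      } else {
        ## synthesize gene parent from the reference gene; no UTRs
        pc <- copy_dec$prot_cand
        info <- pc[pc$locus_id == lid, ]
        refg <- db_feature(ref_db, info$ref_gene)
        ct <- db_feature(prot_db, lid)
        cds <- db_children(prot_db, lid, "CDS")
        n_existing <- sum(grepl(paste0("^", info$ref_gene, "(_\\d+)?$"),
                                vapply(rows, function(r) r$feature_id[1], character(1))))
        gid2 <- paste0(info$ref_gene, "_", n_existing)
        tid2 <- paste0(lid, ".copy")
        rows[[length(rows) + 1L]] <- .feat(gid2, "gene", "gene", ct$seqid, ct$start,
                                           ct$end, ct$strand,
                                           attrs = c(refg$attributes[[1]],
                                                     extra_copy_number = as.character(n_existing)))
        rows[[length(rows) + 1L]] <- .feat(tid2, "transcript", "mRNA", ct$seqid,
                                           ct$start, ct$end, ct$strand, parent = gid2)
        cdsp <- .recompute_phase(cds[, c("start", "end")], ct$strand)
        for (k in seq_len(nrow(cdsp))) {
          rows[[length(rows) + 1L]] <- .feat(paste0(tid2, ".exon", k), "exon", "exon",
                                             ct$seqid, cdsp$start[k], cdsp$end[k],
                                             ct$strand, parent = tid2)
          rows[[length(rows) + 1L]] <- .feat(paste0(tid2, ".cds", k), "CDS", "CDS",
                                             ct$seqid, cdsp$start[k], cdsp$end[k],
                                             ct$strand, phase = cdsp$phase[k], parent = tid2)
        }
      }
    }
  }

  ## pass through non-coding genes of the DNA candidate (no CDS anywhere)
  for (gid in setdiff(db_genes(dna_db)$feature_id, genes_done)) {
    if (!is.na(db_attr(dna_db, gid, "extra_copy_number"))) next
    txs <- db_children(dna_db, gid, "transcript")
    coding <- any(vapply(txs$feature_id, function(t)
      nrow(db_children(dna_db, t, "CDS")) > 0, logical(1)))
    if (!coding) rows[[length(rows) + 1L]] <- .subtree_rows(dna_db, gid)
  }
  annotation_db(do.call(rbind, rows))
}

.subtree_rows <- function(db, id) {
  ids <- id
  repeat {
    more <- db$features$feature_id[!is.na(db$features$parent_id) &
                                     db$features$parent_id %in% ids &
                                     !(db$features$feature_id %in% ids)]
    if (!length(more)) break
    ids <- c(ids, more)
  }
  db$features[db$features$feature_id %in% ids, , drop = FALSE]
}

#' Count genes and transcripts by class and copy status
#'
#' Genes are classed as protein-coding (`gene_biotype`/`gene_type` equal to
#' `protein_coding`), non-coding (`lncRNA` or `ncRNA`) or others (everything
#' else, including pseudogenes and missing biotypes). Transcripts are
#' protein-coding when their type is `mRNA` under a protein-coding gene,
#' non-coding when their type is `lncRNA`/`ncRNA` under a non-coding gene,
#' and others otherwise. Counts are split single copy / multi copy (a base
#' gene with extra copies present) / extra copy (features carrying
#' `extra_copy_number`).
#'
#' @param db an [annotation_db()]
#' @return Nested list suitable for JSON serialization.
#' @export
census <- function(db) {
  g <- db_genes(db)
  gene_class <- vapply(seq_len(nrow(g)), function(i) {
    b <- .biotype(g[i, , drop = FALSE])
    if (is.na(b)) "others"
    else if (b == "protein_coding") "protein_coding"
    else if (b %in% c("lncRNA", "ncRNA")) "non_coding"
    else "others"
  }, character(1))
  ecn <- vapply(g$feature_id, function(id) db_attr(db, id, "extra_copy_number"),
                character(1))
  is_extra <- !is.na(ecn) & ecn != "0"
  base_of <- ifelse(is_extra, sub("_\\d+$", "", g$feature_id), g$feature_id)
  has_extra <- g$feature_id %in% base_of[is_extra]
  copy_status <- ifelse(is_extra, "extra_copy",
                        ifelse(has_extra, "multi_copy", "single_copy"))

  t <- db_transcripts(db)
  tx_class <- vapply(seq_len(nrow(t)), function(i) {
    pty <- t$orig_type[i]
    pg <- t$parent_id[i]
    gclass <- if (!is.na(pg) && pg %in% g$feature_id)
      gene_class[match(pg, g$feature_id)] else "others"
    if (pty == "mRNA" && gclass == "protein_coding") "protein_coding"
    else if (pty %in% c("lncRNA", "lnc_RNA", "ncRNA") && gclass == "non_coding") "non_coding"
    else "others"
  }, character(1))
  tx_copy <- copy_status[match(t$parent_id, g$feature_id)]
  tx_copy[is.na(tx_copy)] <- "single_copy"

  tab <- function(cls, cp) {
    out <- list()
    for (cl in c("protein_coding", "non_coding", "others")) {
      sel <- cls == cl
      out[[cl]] <- list(single_copy = sum(sel & cp == "single_copy"),
                        multi_copy = sum(sel & cp == "multi_copy"),
                        extra_copy = sum(sel & cp == "extra_copy"),
                        total = sum(sel))
    }
    out$total <- length(cls)
    out
  }
  list(gene = tab(gene_class, copy_status), transcript = tab(tx_class, tx_copy))
}
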