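## Synthetic test worlds: a toy reference genome + annotation, a mutated
## target genome, and the two candidate annotations (DNA-style with UTRs and
## planted aligner errors; protein-style CDS-only), with a truth table.
##
## Sequence design rule used throughout: intergenic spacers, UTR filler and
## intron filler are A-free (alphabet C/G/T). A-free triplets can encode
## neither ATG nor a stop codon in any reading frame, so planted start/stop
## codons are the only ORF determinants and every scenario's repair target is
## unambiguous.

.SCENARIOS <- c("clean", "inframe_indel", "frameshift_early_stop",
                "downstream_start", "stop_loss", "start_loss_downstream",
                "start_loss_upstream", "missed_splice_dna",
                "missed_splice_prot", "skipped_exon_prot",
                "tandem_duplicate", "processed_pseudogene")

.codon_sets <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    gc <- Biostrings::GENETIC_CODE
    all <- names(gc)
    internal <- all[gc != "*" & all != "ATG"]
    afree <- internal[!grepl("A", internal)]
    cache <<- list(internal = internal, afree = afree, code = gc)
    cache
  }
})

.afree <- function(n) {
  if (n == 0) return("")
  paste(sample(c("C", "G", "T"), n, replace = TRUE), collapse = "")
}
.rand_codons <- function(n) sample(.codon_sets()$internal, n, replace = TRUE)
.afree_codons <- function(n) sample(.codon_sets()$afree, n, replace = TRUE)

## swap third positions to synonymous codons at n_changes random internal
## positions (used to plant near-identical tandem duplicates)
.synonymize <- function(codons, n_changes) {
  gc <- .codon_sets()$code
  idx <- sample(2:(length(codons) - 1L), min(n_changes, length(codons) - 2L))
  for (i in idx) {
    c0 <- codons[i]
    alts <- names(gc)[gc == gc[[c0]] & names(gc) != c0 &
                        substr(names(gc), 1, 2) == substr(c0, 1, 2)]
    alts <- setdiff(alts, "ATG")
    if (length(alts)) codons[i] <- alts[1]
  }
  codons
}

#' Describe one synthetic scenario
#'
#' @param scenario one of `clean`, `inframe_indel`, `frameshift_early_stop`,
#'   `downstream_start`, `stop_loss`, `start_loss_downstream`,
#'   `start_loss_upstream`, `missed_splice_dna`, `missed_splice_prot`,
#'   `skipped_exon_prot`, `tandem_duplicate`, `processed_pseudogene`
#' @param seed integer; the same seed reproduces the scenario byte-for-byte
#' @return Object of class `scenario_spec`.
#' @export
scenario_spec <- function(scenario, seed = 1L) {
  scenario <- match.arg(scenario, .SCENARIOS)
  structure(list(scenario = scenario, seed = as.integer(seed)),
            class = "scenario_spec")
}

## ---- gene construction (local, + strand) -----------------------------------

## plan and build one gene; scenario-specific codon plants are passed in
.build_gene <- function(aa_per_exon, intron_lens, utr5, utr3,
                        codons = NULL, utr5_seq = NULL, utr3_seq = NULL,
                        stop_codon = "TAA") {
  k <- length(aa_per_exon)
  n_aa <- sum(aa_per_exon)
  if (is.null(codons)) codons <- c("ATG", .rand_codons(n_aa - 1L))
  stopifnot(length(codons) == n_aa, codons[1] == "ATG")
  if (is.null(utr5_seq)) utr5_seq <- .afree(utr5)
  if (is.null(utr3_seq)) utr3_seq <- .afree(utr3)
  utr5 <- nchar(utr5_seq); utr3 <- nchar(utr3_seq)

  chunks <- split(codons, rep(seq_len(k), aa_per_exon))
  pieces <- character(); exons <- list(); cds <- list()
  cur <- 0L
  add <- function(s) { pieces[[length(pieces) + 1L]] <<- s; cur <<- cur + nchar(s) }
  add(utr5_seq)
  for (e in seq_len(k)) {
    cds_seq <- paste(chunks[[e]], collapse = "")
    if (e == k) cds_seq <- paste0(cds_seq, stop_codon)
    cds_start <- cur + 1L
    add(cds_seq)
    cds[[e]] <- c(cds_start, cur)
    ex_start <- if (e == 1L) cds_start - utr5 else cds_start
    if (e == k) add(utr3_seq)
    exons[[e]] <- c(ex_start, if (e == k) cur else cds[[e]][2])
    if (e < k) add(.afree(intron_lens[e]))
  }
  exons <- do.call(rbind, exons); cds <- do.call(rbind, cds)
  list(seq = paste(pieces, collapse = ""),
       exons = data.frame(start = exons[, 1], end = exons[, 2]),
       cds = data.frame(start = cds[, 1], end = cds[, 2]),
       aa_per_exon = aa_per_exon, utr5 = utr5, utr3 = utr3,
       codons = codons,
       protein = paste(c(unname(.codon_sets()$code[codons]), "*"), collapse = ""))
}

## genomic (local, + strand) position of the first base of coding codon c
## (c may be n_aa + 1 for the stop codon)
.codon_pos <- function(g, c) {
  cum <- cumsum(g$aa_per_exon)
  e <- which(cum >= c)[1]
  if (is.na(e)) e <- length(g$aa_per_exon)     # stop codon, last exon
  prior <- if (e > 1L) cum[e - 1L] else 0L
  g$cds$start[e] + 3L * (c - 1L - prior)
}

.subst <- function(seq, pos, repl) {
  paste0(substr(seq, 1L, pos - 1L), repl, substr(seq, pos + nchar(repl), nchar(seq)))
}
.delete <- function(seq, pos, len) {
  paste0(substr(seq, 1L, pos - 1L), substr(seq, pos + len, nchar(seq)))
}
.shift_df <- function(df, pos, len) {
  df$start <- ifelse(df$start > pos, df$start - len, df$start)
  df$end <- ifelse(df$end > pos, df$end - len, df$end)
  df
}

## ---- scenario application ---------------------------------------------------

## Applies one scenario to a built gene. Returns target-local sequence,
## truth/candidate features and expectations. All coordinates local, + strand.
.apply_scenario <- function(scenario, g) {
  out <- list(tgt_seq = g$seq,
              truth = list(exons = g$exons, cds = g$cds),
              dna = list(exons = g$exons, cds = g$cds),
              prot = list(list(suffix = "", cds = g$cds)),
              cats = "identical", repairable = TRUE,
              winner = NA_character_, winner_block = NA_integer_,
              extra = list())
  n_aa <- sum(g$aa_per_exon)
  cum <- cumsum(g$aa_per_exon)

  if (scenario == "clean") {
    return(out)

  } else if (scenario == "inframe_indel") {
    j <- cum[1] + ceiling(g$aa_per_exon[2] / 2)      # mid exon 2
    p <- .codon_pos(g, j)
    out$tgt_seq <- .delete(g$seq, p, 3L)
    out$truth$exons <- .shift_df(g$exons, p, 3L)
    out$truth$cds <- .shift_df(g$cds, p, 3L)
    out$dna <- out$truth
    out$prot <- list(list(suffix = "", cds = out$truth$cds))
    out$cats <- "inframe_deletion"

  } else if (scenario == "frameshift_early_stop") {
    j <- cum[length(cum) - 1L] + 3L                  # early in the last exon
    p <- .codon_pos(g, j)
    s <- .delete(g$seq, p, 1L)
    ex <- .shift_df(g$exons, p, 1L)
    cd <- .shift_df(g$cds, p, 1L)
    ## plant an in-frame (post-shift) stop two codons later
    s <- .subst(s, p + 3L, "TAA")
    out$tgt_seq <- s
    out$truth <- list(exons = ex, cds = cd)
    out$dna <- out$truth
    out$prot <- list(list(suffix = "", cds = cd))
    out$cats <- c("frameshift", "stop_gain")

  } else if (scenario == "downstream_start") {
    ## ref carries a natural internal Met at codon 6; target gains a stop at
    ## codon 4; repair switches to the downstream start
    out$tgt_seq <- .subst(g$seq, .codon_pos(g, 4L), "TAA")
    tc <- g$cds
    tc$start[1] <- .codon_pos(g, 6L)                 # truth: downstream ATG
    out$truth$cds <- tc
    out$cats <- "stop_gain"

  } else if (scenario == "stop_loss") {
    out$tgt_seq <- .subst(g$seq, .codon_pos(g, n_aa + 1L), "CAA")
    tc <- g$cds
    tc$end[nrow(tc)] <- tc$end[nrow(tc)] + 12L       # through the UTR stop
    out$truth$cds <- tc
    out$cats <- "stop_loss"

  } else if (scenario == "start_loss_downstream") {
    ## 2-nt deletion kills the start codon and shifts the frame; repair finds
    ## the planted ATG at codon 6 in the shifted frame
    p <- g$cds$start[1] + 1L                         # the "TG" of ATG
    s <- .delete(g$seq, p, 2L)
    ex <- .shift_df(g$exons, p, 2L)
    cd <- .shift_df(g$cds, p, 2L)
    out$tgt_seq <- s
    out$dna <- list(exons = ex, cds = cd)
    out$prot <- list(list(suffix = "", cds = cd))
    tc <- cd
    tc$start[1] <- .codon_pos(g, 6L) - 2L            # post-shift ATG position
    out$truth <- list(exons = ex, cds = tc)
    out$cats <- c("start_loss", "frameshift")

  } else if (scenario == "start_loss_upstream") {
    out$tgt_seq <- .subst(g$seq, g$cds$start[1], "G") # ATG -> GTG
    tc <- g$cds
    tc$start[1] <- tc$start[1] - 9L                  # planted UTR ATG
    out$truth$cds <- tc
    out$cats <- "start_loss"

  } else if (scenario == "missed_splice_dna") {
    ## DNA candidate picks an acceptor 6 nt inside intron 2; target is clean
    dc <- g$cds; de <- g$exons
    dc$start[3] <- dc$start[3] - 6L
    de$start[3] <- de$start[3] - 6L
    out$dna <- list(exons = de, cds = dc)
    out$winner <- "prot"; out$winner_block <- 3L

  } else if (scenario == "missed_splice_prot") {
    ## protein candidate retains intron 2 (length divisible by 3, A-free)
    pc <- g$cds[-3, , drop = FALSE]
    pc$end[2] <- g$cds$end[3]
    out$prot <- list(list(suffix = "", cds = pc))
    out$winner <- "dna"; out$winner_block <- 2L

  } else if (scenario == "skipped_exon_prot") {
    out$prot <- list(list(suffix = "", cds = g$cds[-1, , drop = FALSE]))
    out$winner <- "dna"; out$winner_block <- 1L

  } else if (scenario == "tandem_duplicate") {
    ## duplicate the whole gene region downstream, with a few synonymous
    ## third-position changes so the copy is near- but not fully identical
    dup_seq <- g$seq
    new_codons <- .synonymize(g$codons, 3L)
    for (i in which(new_codons != g$codons))
      dup_seq <- .subst(dup_seq, .codon_pos(g, i), new_codons[i])
    off <- nchar(g$seq) + 120L
    out$tgt_seq <- paste0(g$seq, .afree(120L), dup_seq)
    gdf <- function(df) { df$start <- df$start + off; df$end <- df$end + off; df }
    out$extra <- list(list(kind = "dna_copy", exons = gdf(g$exons),
                           cds = gdf(g$cds), expected_accepted = TRUE,
                           expected_reason = ""))

  } else if (scenario == "processed_pseudogene") {
    ## one intronless full retrocopy (rejected: single CDS vs multi-CDS
    ## reference) and one two-piece partial copy with coding-length ratio
    ## ~0.5 (rejected: outside the 0.9-1.5 band)
    cds_seq <- paste(substring(g$seq, g$cds$start, g$cds$end), collapse = "")
    retro_len <- nchar(cds_seq)
    q <- (retro_len %/% 12L) * 3L                    # quarter, in frame
    off1 <- nchar(g$seq) + 120L
    off2 <- off1 + retro_len + 120L
    out$tgt_seq <- paste0(g$seq, .afree(120L), cds_seq, .afree(120L),
                          substring(cds_seq, 1L, q), .afree(30L),
                          substring(cds_seq, q + 1L, 2L * q))
    out$extra <- list(
      list(kind = "prot_copy", suffix = "_copy2",
           cds = data.frame(start = off1 + 1L, end = off1 + retro_len),
           expected_accepted = FALSE, expected_reason = "single_cds_mismatch"),
      list(kind = "prot_copy", suffix = "_copy3",
           cds = data.frame(start = c(off2 + 1L, off2 + q + 31L),
                            end = c(off2 + q, off2 + 2L * q + 30L)),
           expected_accepted = FALSE, expected_reason = "length_ratio_out_of_range"))
  }
  out
}

## scenario-specific gene shapes and codon plants
.plan_gene <- function(scenario) {
  k <- sample(3:5, 1L)
  aa <- sample(10:16, k, replace = TRUE)
  introns <- sample(8:15, k - 1L, replace = TRUE) * 3L
  utr5 <- sample(6:12, 1L) * 3L
  utr3 <- sample(6:12, 1L) * 3L
  codons <- c("ATG", .rand_codons(sum(aa) - 1L))
  utr5_seq <- NULL; utr3_seq <- NULL

  if (scenario %in% c("downstream_start", "start_loss_downstream")) {
    codons[6] <- "ATG"                                # natural internal Met
    if (scenario == "start_loss_downstream") {
      codons[2:5] <- .afree_codons(4L)
      while (startsWith(codons[2], "TG")) codons[2] <- .afree_codons(1L)
    }
  }
  if (scenario == "stop_loss")
    utr3_seq <- paste0(.afree(9L), "TAACC", .afree(utr3 - 14L))
  if (scenario == "start_loss_upstream")
    utr5_seq <- paste0(.afree(utr5 - 9L), "ATG", paste(.afree_codons(2L), collapse = ""))
  .build_gene(aa, introns, utr5, utr3, codons = codons,
              utr5_seq = utr5_seq, utr3_seq = utr3_seq)
}

## ---- world assembly ---------------------------------------------------------

## flip a local block to the minus strand: reverse-complement the sequence
## and mirror all coordinates
.flip_df <- function(df, L) {
  if (is.null(df) || !nrow(df)) return(df)
  s <- L - df$end + 1L; e <- L - df$start + 1L
  df$start <- s; df$end <- e
  df[order(df$start), , drop = FALSE]
}

.feat <- function(id, ftype, orig_type, seqid, start, end, strand,
                  phase = NA_integer_, parent = NA_character_,
                  attrs = character()) {
  data.frame(feature_id = id, ftype = ftype, orig_type = orig_type,
             seqid = seqid, source = "protlift_sim", start = start, end = end,
             score = NA_character_, strand = strand, phase = phase,
             parent_id = parent, attributes = I(list(attrs)),
             stringsAsFactors = FALSE)
}

.tx_rows <- function(gid, tid, seqid, strand, exons, cds, gene_attrs = character(),
                     mrna_attrs = character(), with_gene = TRUE, with_exons = TRUE) {
  rows <- list()
  span <- c(min(if (with_exons) exons$start else cds$start),
            max(if (with_exons) exons$end else cds$end))
  if (with_gene)
    rows[[length(rows) + 1L]] <- .feat(gid, "gene", "gene", seqid, span[1], span[2],
                                       strand, parent = NA_character_,
                                       attrs = c(gene_biotype = "protein_coding", gene_attrs))
  rows[[length(rows) + 1L]] <- .feat(tid, "transcript", "mRNA", seqid, span[1], span[2],
                                     strand, parent = if (with_gene) gid else NA_character_,
                                     attrs = mrna_attrs)
  if (with_exons) {
    for (i in seq_len(nrow(exons)))
      rows[[length(rows) + 1L]] <- .feat(paste0(tid, ".exon", i), "exon", "exon",
                                         seqid, exons$start[i], exons$end[i],
                                         strand, parent = tid)
  }
  cdsp <- .recompute_phase(cds, strand)
  for (i in seq_len(nrow(cdsp)))
    rows[[length(rows) + 1L]] <- .feat(paste0(tid, ".cds", i), "CDS", "CDS",
                                       seqid, cdsp$start[i], cdsp$end[i],
                                       strand, phase = cdsp$phase[i], parent = tid)
  do.call(rbind, rows)
}

#' Generate a synthetic test world
#'
#' Builds a reference genome + annotation, a target genome carrying the
#' planted mutations of each scenario, a DNA-based candidate annotation
#' (gene/mRNA/exon/CDS, with UTRs, Liftoff-style) and a protein-based
#' candidate annotation (mRNA/CDS only, miniprot-style), plus a truth table
#' with the expected mutation categories, expected chaining winner, and the
#' truth protein of the correctly annotated target locus.
#'
#' @param specs list of [scenario_spec()] objects
#' @return list with `ref_genome`, `tgt_genome` (named character vectors),
#'   `ref_db`, `dna_db`, `prot_db` ([annotation_db()]), `truth`
#'   (data.frame) and `copy_truth` (data.frame of planted copy decisions).
#' @export
make_world <- function(specs) {
  stopifnot(length(specs) >= 1)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))

  ref_parts <- character(); tgt_parts <- character()
  ref_cur <- 0L; tgt_cur <- 0L
  rows_ref <- list(); rows_dna <- list(); rows_prot <- list()
  truth <- list(); copies <- list()

  for (i in seq_along(specs)) {
    spec <- specs[[i]]
    set.seed((spec$seed %% 100000L) * 131L + i)
    strand <- sample(c("+", "-"), 1L)
    g <- .plan_gene(spec$scenario)
    sc <- .apply_scenario(spec$scenario, g)

    gid <- sprintf("G%02d", i); tid <- sprintf("T%02d", i)
    spacer <- .afree(150L)

    ## truth protein, computed from the target-local sequence (+ strand space)
    tgt_local <- setNames(sc$tgt_seq, "loc")
    sp <- extract_spliced(tgt_local, data.frame(seqid = "loc", sc$truth$cds), "+")
    truth_protein <- translate_dna(sp$dna, to_first_stop = TRUE)

    ## flip to minus strand if drawn
    ref_seq <- g$seq; tgt_seq <- sc$tgt_seq
    ref_feats <- list(exons = g$exons, cds = g$cds)
    if (strand == "-") {
      Lr <- nchar(ref_seq); Lt <- nchar(tgt_seq)
      ref_seq <- .revcomp(ref_seq); tgt_seq <- .revcomp(tgt_seq)
      ref_feats <- lapply(ref_feats, .flip_df, L = Lr)
      sc$truth <- lapply(sc$truth, .flip_df, L = Lt)
      sc$dna <- lapply(sc$dna, .flip_df, L = Lt)
      sc$prot <- lapply(sc$prot, function(p) { p$cds <- .flip_df(p$cds, Lt); p })
      sc$extra <- lapply(sc$extra, function(x) {
        x$cds <- .flip_df(x$cds, Lt)
        if (!is.null(x$exons)) x$exons <- .flip_df(x$exons, Lt)
        x
      })
    }

    ref_off <- ref_cur + 150L; tgt_off <- tgt_cur + 150L
    ref_parts <- c(ref_parts, spacer, ref_seq)
    tgt_parts <- c(tgt_parts, spacer, tgt_seq)
    ref_cur <- ref_cur + 150L + nchar(ref_seq)
    tgt_cur <- tgt_cur + 150L + nchar(tgt_seq)

    off <- function(df, o) { df$start <- df$start + o; df$end <- df$end + o; df }

    rows_ref[[i]] <- .tx_rows(gid, tid, "chr1", strand,
                              off(ref_feats$exons, ref_off), off(ref_feats$cds, ref_off))
    dna_rows <- .tx_rows(gid, tid, "chrT", strand,
                         off(sc$dna$exons, tgt_off), off(sc$dna$cds, tgt_off))
    prot_rows <- do.call(rbind, lapply(sc$prot, function(p)
      .tx_rows(gid, paste0(tid, p$suffix), "chrT", strand, NULL,
               off(p$cds, tgt_off), with_gene = FALSE, with_exons = FALSE,
               mrna_attrs = c(Target = tid))))

    for (x in sc$extra) {
      if (x$kind == "dna_copy") {
        dna_rows <- rbind(dna_rows,
          .tx_rows(paste0(gid, "_1"), paste0(tid, "_1"), "chrT", strand,
                   off(x$exons, tgt_off), off(x$cds, tgt_off),
                   gene_attrs = c(extra_copy_number = "1")))
        copies[[length(copies) + 1L]] <- data.frame(
          scenario = spec$scenario, locus_id = paste0(gid, "_1"), source = "dna",
          ref_gene = gid, expected_accepted = x$expected_accepted,
          expected_reason = x$expected_reason, stringsAsFactors = FALSE)
      } else {
        prot_rows <- rbind(prot_rows,
          .tx_rows(gid, paste0(tid, x$suffix), "chrT", strand, NULL,
                   off(x$cds, tgt_off), with_gene = FALSE, with_exons = FALSE,
                   mrna_attrs = c(Target = tid)))
        copies[[length(copies) + 1L]] <- data.frame(
          scenario = spec$scenario, locus_id = paste0(tid, x$suffix), source = "prot",
          ref_gene = gid, expected_accepted = x$expected_accepted,
          expected_reason = x$expected_reason, stringsAsFactors = FALSE)
      }
    }
    rows_dna[[i]] <- dna_rows
    rows_prot[[i]] <- prot_rows

    truth[[i]] <- data.frame(
      scenario = spec$scenario, seed = spec$seed, gene_id = gid,
      transcript_id = tid, strand = strand,
      categories = paste(sc$cats, collapse = ";"),
      repairable = sc$repairable,
      expected_winner = sc$winner, winner_block = sc$winner_block,
      truth_protein = truth_protein, stringsAsFactors = FALSE)
  }

  list(ref_genome = setNames(paste(ref_parts, collapse = ""), "chr1"),
       tgt_genome = setNames(paste(tgt_parts, collapse = ""), "chrT"),
       ref_db = annotation_db(do.call(rbind, rows_ref)),
       dna_db = annotation_db(do.call(rbind, rows_dna)),
       prot_db = annotation_db(do.call(rbind, rows_prot)),
       truth = do.call(rbind, truth),
       copy_truth = if (length(copies)) do.call(rbind, copies) else
         data.frame(scenario = character(), locus_id = character(),
                    source = character(), ref_gene = character(),
                    expected_accepted = logical(), expected_reason = character()))
}

#' Write a synthetic world to disk
#'
#' Emits `ref.fa`, `ref.gff3`, `target.fa`, `dna.gff3`, `prot.gff3` and
#' `truth.tsv` under `dir`.
#'
#' @param world result of [make_world()]
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(world$ref_genome, file.path(dir, "ref.fa"))
  write_fasta(world$tgt_genome, file.path(dir, "target.fa"))
  write_gff3(world$ref_db, file.path(dir, "ref.gff3"))
  write_gff3(world$dna_db, file.path(dir, "dna.gff3"))
  write_gff3(world$prot_db, file.path(dir, "prot.gff3"))
  write.table(world$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' The worked chaining example: two flawed candidates, one merged chain
#'
#' Builds the canonical seven-vs-six CDS topology: the DNA-based candidate
#' (L1..L7) has an erroneous splice junction between L3 and L4 that inserts
#' two junk codons (one a premature stop) and drops the first two codons of
#' L4; the protein-based candidate (M1..M6) merges the last two exons into a
#' single CDS (M6), retaining an intron. The expected grouping is
#' GL1={L1} GM1={M1}; GL2={L2} GM2={M2}; GL3={L3,L4} GM3={M3,M4};
#' GL4={L5} GM4={M5}; GL5={L6,L7} GM5={M6}, and the expected merged chain is
#' L1,L2,M3,M4,L5,L6,L7.
#'
#' @param seed integer seed for the random filler sequence
#' @return list with `ref_genome`, `tgt_genome`, `ref_db`, `dna_db`,
#'   `prot_db`, `ref_protein`, plus `expected_groups_dna`,
#'   `expected_groups_prot`, `expected_chain` (source/index of each merged
#'   CDS) and ids of the planted features.
#' @export
make_fig1_fixture <- function(seed = 42L) {
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)

  aa <- c(10L, 10L, 8L, 8L, 10L, 10L, 10L)
  introns <- rep(21L, 6L)
  g <- .build_gene(aa, introns, utr5 = 0L, utr3 = 0L)
  ## intron 3 starts with two junk codons, the second a stop, that the DNA
  ## candidate's bad donor site pulls into L3
  s <- g$seq
  s <- .subst(s, g$cds$end[3] + 1L, "GGTTAA")
  off <- 150L
  tgt <- paste0(.afree(150L), s)
  ref <- tgt    # target locus is mutation-free; candidates are what differ

  o <- function(df) { df$start <- df$start + off; df$end <- df$end + off; df }
  truth_ex <- o(g$exons); truth_cds <- o(g$cds)

  dna_cds <- truth_cds
  dna_cds$end[3] <- dna_cds$end[3] + 6L      # bad donor: into intron 3
  dna_cds$start[4] <- dna_cds$start[4] + 6L  # bad acceptor: drops 2 codons
  prot_cds <- truth_cds[-7, , drop = FALSE]
  prot_cds$end[6] <- truth_cds$end[7]        # M6 retains intron 6

  ref_db <- annotation_db(.tx_rows("G1", "T1", "chr1", "+", truth_ex, truth_cds))
  dna_db <- annotation_db(.tx_rows("G1", "T1", "chrT", "+", dna_cds, dna_cds))
  prot_db <- annotation_db(.tx_rows("G1", "T1", "chrT", "+", NULL, prot_cds,
                                    with_gene = FALSE, with_exons = FALSE,
                                    mrna_attrs = c(Target = "T1")))
  list(ref_genome = setNames(ref, "chr1"),
       tgt_genome = setNames(tgt, "chrT"),
       ref_db = ref_db, dna_db = dna_db, prot_db = prot_db,
       ref_protein = g$protein,
       dna_cds = dna_cds, prot_cds = prot_cds, truth_cds = truth_cds,
       expected_groups_dna = list(1L, 2L, c(3L, 4L), 5L, c(6L, 7L)),
       expected_groups_prot = list(1L, 2L, c(3L, 4L), 5L, 6L),
       expected_selected = c("dna", "dna", "prot", "dna", "dna"),
       expected_chain = data.frame(
         source = c("dna", "dna", "prot", "prot", "dna", "dna", "dna"),
         src_index = c(1L, 2L, 3L, 4L, 5L, 6L, 7L)))
}
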