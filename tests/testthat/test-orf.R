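test_that("mutation classification covers all nine categories exactly", {
  # identical: equal DNA
  expect_identical(classify_mutations("ATGGCTAAATAA", "ATGGCTAAATAA")$categories,
                   "identical")
  # synonymous: GCT -> GCC (Ala -> Ala)
  expect_identical(classify_mutations("ATGGCTAAATAA", "ATGGCCAAATAA")$categories,
                   "synonymous")
  # nonsynonymous: AAA -> AGA (Lys -> Arg)
  expect_identical(classify_mutations("ATGGCTAAATAA", "ATGGCTAGATAA")$categories,
                   "nonsynonymous")
  # in-frame insertion of one codon
  expect_identical(classify_mutations("ATGGCTAAATAA", "ATGGCTCACAAATAA")$categories,
                   "inframe_insertion")
  # in-frame deletion of one codon
  expect_identical(classify_mutations("ATGGCTCACAAATAA", "ATGGCTAAATAA")$categories,
                   "inframe_deletion")
  # frameshift: 1-nt deletion mid-CDS introducing an early stop
  r <- "ATGCTGAAATAA"                  # M L K *
  t <- "ATGTGAAATAA"                   # C dropped -> ATG TGA ...
  cats <- classify_mutations(r, t)$categories
  expect_true(all(c("frameshift", "stop_gain") %in% cats))
  # stop gain by substitution
  expect_identical(classify_mutations("ATGGCTAAATGCTAA", "ATGGCTTAATGCTAA")$categories,
                   "stop_gain")
  # stop loss
  expect_identical(classify_mutations("ATGGCTAAATAA", "ATGGCTAAACAA")$categories,
                   "stop_loss")
  # start loss
  expect_identical(classify_mutations("ATGGCTAAATAA", "GTGGCTAAATAA")$categories,
                   c("nonsynonymous", "start_loss"))
})

test_that("classification is total: every pair gets at least one category", {
  set.seed(61)
  for (i in 1:40) {
    r <- paste0("ATG", rand_dna(3 * sample(2:6, 1)), "TAA")
    t <- paste0(sample(c("ATG", "GTG"), 1), rand_dna(3 * sample(2:6, 1)), "TAA")
    cats <- classify_mutations(r, t)$categories
    expect_gte(length(cats), 1)
    if ("identical" %in% cats) expect_length(cats, 1)
  }
})

test_that("find_orfs returns the longest ATG-initiated ORF per frame", {
  o1 <- find_orfs("ATGAAATAA")
  expect_length(o1, 1)
  expect_equal(o1[[1]]$frame, 0)
  expect_identical(o1[[1]]$protein, "MK*")

  o2 <- find_orfs("GATGAAATAA")
  expect_equal(o2[[1]]$frame, 1)
  expect_identical(o2[[1]]$protein, "MK*")

  ## two ORFs in frame 0 (6 and 12 nt): the longer retained
  s <- paste0("ATGTAA", "ATGAAAGAGTAA")
  o3 <- find_orfs(s)
  f0 <- Filter(function(o) o$frame == 0, o3)
  expect_equal(f0[[1]]$start_offset, 7)
  expect_identical(f0[[1]]$protein, "MKE*")

  ## ORF without a stop extends to the end of the sequence
  o4 <- find_orfs("CCATGAAAGGG")
  expect_identical(o4[[1]]$protein, "MKG")
  expect_length(find_orfs("CCCGGGTTT"), 0)  # no ATG anywhere
})

test_that("find_orfs agrees with a brute-force scan on random sequences", {
  brute <- function(s) {
    n <- nchar(s)
    best <- list()
    for (f in 0:2) {
      cand <- NULL
      starts <- seq(1 + f, n - 2, by = 3)
      if (length(starts) < 1) next
      for (a in starts) {
        if (substring(s, a, a + 2) != "ATG") next
        stop_at <- NA
        for (b in starts[starts >= a]) {
          if (substring(s, b, b + 2) %in% c("TAA", "TAG", "TGA")) { stop_at <- b; break }
        }
        len <- if (is.na(stop_at)) 3 * ((n - a + 1) %/% 3) else stop_at + 3 - a
        if (is.null(cand) || len > cand$len) cand <- list(start = a, len = len)
      }
      if (!is.null(cand)) best[[length(best) + 1]] <-
        c(frame = f, start = cand$start, end = cand$start + cand$len - 1)
    }
    best
  }
  set.seed(71)
  for (i in 1:40) {
    s <- rand_dna(sample(30:300, 1))
    mine <- find_orfs(s)
    ref <- brute(s)
    expect_equal(length(mine), length(ref))
    for (k in seq_along(mine)) {
      expect_equal(mine[[k]]$frame, unname(ref[[k]]["frame"]))
      expect_equal(mine[[k]]$start_offset, unname(ref[[k]]["start"]))
      expect_equal(mine[[k]]$end_offset, unname(ref[[k]]["end"]))
    }
  }
})

test_that("ORF repair extends a stop-loss CDS into the 3' UTR", {
  w <- one_world(6)
  row <- w$truth[w$truth$scenario == "stop_loss", ]
  tid <- row$transcript_id
  tx0 <- db_feature(w$dna_db, tid)
  exons <- db_children(w$dna_db, tid, "exon")[, c("start", "end")]
  cds <- db_children(w$dna_db, tid, "CDS")[, c("start", "end")]
  tx <- tx_model(tid, tx0$seqid, tx0$strand, exons, cds)
  ref_protein <- {
    rc <- db_children(w$ref_db, tid, "CDS")
    sp <- extract_spliced(w$ref_genome, rc[, c("seqid", "start", "end")], tx0$strand)
    translate_dna(sp$dna)
  }
  rep <- orf_repair(tx, w$tgt_genome, ref_protein)
  expect_true(rep$repaired)
  expect_gt(rep$identity_after, rep$identity_before)
  ## CDS end moved into the former 3' UTR but stayed inside the exons
  old_span <- sum(cds$end - cds$start + 1)
  new_span <- sum(rep$tx$cds$end - rep$tx$cds$start + 1)
  expect_equal(new_span, old_span + 12)
  sp <- extract_spliced(w$tgt_genome, data.frame(seqid = tx0$seqid, rep$tx$cds), tx0$strand)
  expect_identical(translate_dna(sp$dna, to_first_stop = TRUE), row$truth_protein)
})

test_that("repair leaves the transcript unchanged when no ORF improves it", {
  ## clean transcript: every ORF candidate ties the current annotation
  w <- one_world(7)
  tid <- w$truth$transcript_id[w$truth$scenario == "clean"]
  tx0 <- db_feature(w$dna_db, tid)
  tx <- tx_model(tid, tx0$seqid, tx0$strand,
                 db_children(w$dna_db, tid, "exon")[, c("start", "end")],
                 db_children(w$dna_db, tid, "CDS")[, c("start", "end")])
  rc <- db_children(w$ref_db, tid, "CDS")
  ref_protein <- translate_dna(extract_spliced(
    w$ref_genome, rc[, c("seqid", "start", "end")], tx0$strand)$dna)
  rep <- orf_repair(tx, w$tgt_genome, ref_protein)
  expect_false(rep$repaired)
  expect_equal(rep$tx$cds, tx$cds)
  ## a non-deleterious trigger short-circuits
  rep2 <- orf_repair(tx, w$tgt_genome, ref_protein,
                     trigger = structure(list(categories = "synonymous"),
                                         class = "mutation_report"))
  expect_false(rep2$repaired)
})
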