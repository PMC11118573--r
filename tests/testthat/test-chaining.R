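test_that("CDS boundaries map onto reference-protein coordinates", {
  ## two 9-nt CDSs, gapless alignment
  g <- c(c1 = paste0("ATGAAACCC", strrep("G", 20), "TTTGAAGCT"))
  cds <- data.frame(start = c(1, 30), end = c(9, 38))
  sp <- extract_spliced(g, data.frame(seqid = "c1", cds), "+")
  prot <- translate_dna(sp$dna)
  aln <- align_protein(prot, prot)
  m <- map_cds_boundaries(aln, cds, "+")
  expect_equal(m$qry_aa_end, c(3, 6))
  expect_equal(m$ref_aa_end, c(3, 6))
  expect_false(any(m$zero_width))
})

test_that("a query-side insertion narrows the reference interval", {
  ## query has one extra residue inside CDS 1 relative to the reference
  ref <- "MKLEQSWH"
  qry <- "MKLAEQSWH"     # A inserted after L
  aln <- align_protein(ref, qry)
  cds <- data.frame(start = c(1, 13), end = c(12, 27))  # 4 aa + 5 aa of query
  m <- map_cds_boundaries(aln, cds, "+")
  expect_equal(m$qry_aa_end, c(4, 9))
  ## CDS1 holds 4 query residues but only 3 reference residues
  expect_equal(m$ref_aa_end, c(3, 8))
})

test_that("boundaries landing mid-codon count complete residues only", {
  ref <- "MKLEQS"
  qry <- ref
  aln <- align_protein(ref, qry)
  ## 2-codon toy split 4 + 14 nt: first CDS ends mid-codon
  cds <- data.frame(start = c(1, 5), end = c(4, 18))
  m <- map_cds_boundaries(aln, cds, "+")
  expect_equal(m$qry_aa_end, c(1, 6))   # floor(4/3) = 1 complete codon
  expect_equal(m$ref_aa_end, c(1, 6))
})

test_that("grouping closes blocks at shared reference endpoints", {
  mk_map <- function(ends) data.frame(start = seq_along(ends), end = seq_along(ends),
                                      nt_len = 3, cum_nt = 3 * seq_along(ends),
                                      qry_aa_start = c(1, head(ends, -1) + 1),
                                      qry_aa_end = ends, ref_aa_end = ends,
                                      zero_width = FALSE)
  ## identical single-CDS annotations: one pair
  g1 <- form_groups(mk_map(5), mk_map(5))
  expect_length(g1, 1)
  ## 2 vs 3 CDSs with no interior shared endpoint: one pair spanning everything
  g2 <- form_groups(mk_map(c(4, 9)), mk_map(c(2, 6, 9)))
  expect_length(g2, 1)
  expect_equal(g2[[1]]$dna_idx, 1:2)
  expect_equal(g2[[1]]$prot_idx, 1:3)
  ## interior shared endpoint closes a block
  g3 <- form_groups(mk_map(c(4, 9)), mk_map(c(4, 7, 9)))
  expect_length(g3, 2)
  expect_equal(g3[[2]]$prot_idx, 2:3)
})

test_that("the worked seven-vs-six topology groups and chains as expected", {
  fx <- make_fig1_fixture()
  dsp <- extract_spliced(fx$tgt_genome, data.frame(seqid = "chrT", fx$dna_cds), "+")
  psp <- extract_spliced(fx$tgt_genome, data.frame(seqid = "chrT", fx$prot_cds), "+")
  da <- align_protein(fx$ref_protein, translate_dna(dsp$dna))
  pa <- align_protein(fx$ref_protein, translate_dna(psp$dna))
  dm <- map_cds_boundaries(da, fx$dna_cds, "+")
  pm <- map_cds_boundaries(pa, fx$prot_cds, "+")
  groups <- form_groups(dm, pm)
  expect_equal(lapply(groups, `[[`, "dna_idx"), fx$expected_groups_dna)
  expect_equal(lapply(groups, `[[`, "prot_idx"), fx$expected_groups_prot)
  sel <- select_chain(groups, dm, pm, da, pa, fx$ref_protein,
                      fx$tgt_genome, "chrT", "+")
  expect_identical(sel$selected, fx$expected_selected)
  expect_equal(sel$merged_cds[, c("source", "src_index")],
               fx$expected_chain, ignore_attr = TRUE)
  expect_equal(sel$merged_protein_id, 1.0)
})

test_that("all-tie blocks keep the DNA candidate exactly", {
  fx <- make_fig1_fixture()
  tsp <- extract_spliced(fx$tgt_genome, data.frame(seqid = "chrT", fx$truth_cds), "+")
  aln <- align_protein(fx$ref_protein, translate_dna(tsp$dna))
  m <- map_cds_boundaries(aln, fx$truth_cds, "+")
  groups <- form_groups(m, m)
  sel <- select_chain(groups, m, m, aln, aln, fx$ref_protein,
                      fx$tgt_genome, "chrT", "+")
  expect_true(all(sel$selected == "dna"))
  expect_equal(sel$merged_cds$start, fx$truth_cds$start)
  expect_equal(sel$merged_cds$end, fx$truth_cds$end)
})

test_that("fixture worlds pick the planted winner in the corrupted block", {
  for (seed in 1:3) {
    w <- one_world(seed)
    res <- world_result(seed)
    splice_rows <- w$truth[!is.na(w$truth$expected_winner), ]
    for (i in seq_len(nrow(splice_rows))) {
      tid <- splice_rows$transcript_id[i]
      rep_row <- res$report[res$report$transcript_id == tid, ]
      expect_equal(rep_row$protein_identity, 1.0, tolerance = 1e-12)
    }
  }
})

test_that("merged chains dominate both candidates on fixture worlds", {
  for (seed in 4:5) {
    w <- one_world(seed)
    res <- world_result(seed)
    for (tid in res$report$transcript_id) {
      id_dna <- candidate_identity(w, w$dna_db, tid, tid)
      id_prot <- candidate_identity(w, w$prot_db, tid, tid)
      rep_row <- res$report[res$report$transcript_id == tid, ]
      expect_gte(rep_row$protein_identity, max(id_dna, id_prot) - 1e-9)
    }
  }
})
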