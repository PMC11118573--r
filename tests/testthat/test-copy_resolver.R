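feat_row <- protlift:::.feat

## a reference with two genes: multi-exon gm (3 CDSs) and overlapping pair
ref_db_small <- function() {
  annotation_db(rbind(
    feat_row("gm", "gene", "gene", "c1", 100, 400, "+",
             attrs = c(gene_biotype = "protein_coding")),
    feat_row("tm", "transcript", "mRNA", "c1", 100, 400, "+", parent = "gm"),
    feat_row("tm.c1", "CDS", "CDS", "c1", 100, 150, "+", phase = 0L, parent = "tm"),
    feat_row("tm.c2", "CDS", "CDS", "c1", 200, 250, "+", phase = 0L, parent = "tm"),
    feat_row("tm.c3", "CDS", "CDS", "c1", 300, 400, "+", phase = 0L, parent = "tm"),
    feat_row("gs", "gene", "gene", "c1", 1000, 1200, "+",
             attrs = c(gene_biotype = "protein_coding")),
    feat_row("ts", "transcript", "mRNA", "c1", 1000, 1200, "+", parent = "gs"),
    feat_row("ts.c1", "CDS", "CDS", "c1", 1000, 1200, "+", phase = 0L, parent = "ts"),
    ## two genes that already overlap in the reference (whitelisted pair)
    feat_row("gx", "gene", "gene", "c2", 100, 300, "+"),
    feat_row("gy", "gene", "gene", "c2", 250, 500, "-")
  ))
}

test_that("DNA copy admission enforces identity threshold and overlap rule", {
  reg <- locus_registry(ref_db_small())
  reg <- register_locus(reg, "gm", "gm", "t1", 100, 400)
  cands <- data.frame(
    locus_id = c("gm_1", "gm_2", "gm_3"),
    ref_gene = "gm", seqid = "t1",
    start = c(2000, 3000, 150),           # third overlaps the primary by ~80%
    end = c(2300, 3300, 450),
    dna_identity = c(0.97, 0.90, 0.99), stringsAsFactors = FALSE)
  out <- admit_dna_copies(cands, reg, sc_threshold = 0.95)
  dec <- out$decisions
  expect_true(dec$accepted[dec$locus_id == "gm_1"])
  expect_identical(dec$reasons[dec$locus_id == "gm_2"], "below_sc_threshold")
  expect_identical(dec$reasons[dec$locus_id == "gm_3"], "overlap_excess")
})

test_that("reference-whitelisted overlaps are allowed in the target", {
  reg <- locus_registry(ref_db_small())
  reg <- register_locus(reg, "gx", "gx", "t1", 100, 300)
  cands <- data.frame(locus_id = "gy_t", ref_gene = "gy", seqid = "t1",
                      start = 250, end = 500, dna_identity = 0.99,
                      stringsAsFactors = FALSE)
  expect_true(admit_dna_copies(cands, reg)$decisions$accepted)
  ## same overlap, non-whitelisted pair: rejected
  cands2 <- data.frame(locus_id = "gs_t", ref_gene = "gs", seqid = "t1",
                       start = 250, end = 500, dna_identity = 0.99,
                       stringsAsFactors = FALSE)
  expect_false(admit_dna_copies(cands2, reg)$decisions$accepted)
})

test_that("protein-only copy filters reject pseudogene signatures", {
  rdb <- ref_db_small()
  reg <- locus_registry(rdb)
  ## intronless candidate of the multi-exon gene gm: processed-pseudogene guard
  c1 <- data.frame(locus_id = "p1", ref_gene = "gm", seqid = "t1",
                   start = 5000, end = 5203, coding_len = 204, n_cds = 1,
                   stringsAsFactors = FALSE)
  d1 <- admit_prot_copies(c1, reg, rdb)$decisions
  expect_false(d1$accepted)
  expect_identical(d1$reasons, "single_cds_mismatch")

  ## coding-length ratio 0.5: rejected
  c2 <- data.frame(locus_id = "p2", ref_gene = "gm", seqid = "t1",
                   start = 6000, end = 6101, coding_len = 102, n_cds = 2,
                   stringsAsFactors = FALSE)
  d2 <- admit_prot_copies(c2, reg, rdb)$decisions
  expect_identical(d2$reasons, "length_ratio_out_of_range")

  ## single-CDS candidate of a single-CDS gene, ratio 1.0, no overlap: accepted
  c3 <- data.frame(locus_id = "p3", ref_gene = "gs", seqid = "t1",
                   start = 7000, end = 7200, coding_len = 201, n_cds = 1,
                   stringsAsFactors = FALSE)
  expect_true(admit_prot_copies(c3, reg, rdb)$decisions$accepted)
})

test_that("copy ids are assigned in deterministic genomic order", {
  acc <- data.frame(
    locus_id = c("a", "b", "c", "d"),
    ref_gene = c("GENE", "GENE", "GENE", "GENE"),
    seqid = c("c2", "c1", "c1", "c1"),
    start = c(10, 500, 20, 1),
    is_primary = c(FALSE, FALSE, FALSE, TRUE), stringsAsFactors = FALSE)
  out <- assign_copy_ids(acc)
  expect_identical(out$new_id[out$locus_id == "d"], "GENE")
  expect_identical(out$new_id[out$locus_id == "c"], "GENE_1")  # c1:20
  expect_identical(out$new_id[out$locus_id == "b"], "GENE_2")  # c1:500
  expect_identical(out$new_id[out$locus_id == "a"], "GENE_3")  # c2:10
  expect_equal(out$extra_copy_number[out$locus_id == "a"], 3L)
  ## no extras: ids unchanged
  one <- data.frame(locus_id = "x", ref_gene = "G", seqid = "c1", start = 1,
                    is_primary = TRUE, stringsAsFactors = FALSE)
  expect_identical(assign_copy_ids(one)$new_id, "G")
})

test_that("planted copies resolve correctly and accepted loci respect overlap", {
  for (seed in 1:3) {
    w <- one_world(seed)
    res <- world_result(seed)
    dec <- res$copy_decisions
    for (i in seq_len(nrow(w$copy_truth))) {
      ct <- w$copy_truth[i, ]
      row <- dec[dec$locus_id == ct$locus_id, ]
      expect_equal(row$accepted, ct$expected_accepted, label = ct$locus_id)
      if (!ct$expected_accepted)
        expect_match(row$reasons, ct$expected_reason)
    }
    ## all-pairs sweep over output gene loci
    g <- db_genes(res$out_db)
    for (a in seq_len(nrow(g))) for (b in seq_len(nrow(g))) {
      if (a >= b || g$seqid[a] != g$seqid[b]) next
      shared <- min(g$end[a], g$end[b]) - max(g$start[a], g$start[b]) + 1
      if (shared <= 0) next
      frac <- shared / min(g$end[a] - g$start[a] + 1, g$end[b] - g$start[b] + 1)
      expect_lte(frac, 0.10)
    }
  }
})
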