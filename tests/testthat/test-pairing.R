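# small hand-built candidate databases for the pairing rules
feat_row <- protlift:::.feat

mk_db <- function(...) annotation_db(do.call(rbind, list(...)))

dna_world <- function() {
  mk_db(
    feat_row("gA", "gene", "gene", "c1", 100, 400, "+"),
    feat_row("tA", "transcript", "mRNA", "c1", 100, 400, "+", parent = "gA"),
    feat_row("tA.c1", "CDS", "CDS", "c1", 100, 400, "+", phase = 0L, parent = "tA"),
    feat_row("gB", "gene", "gene", "c1", 600, 900, "+"),
    feat_row("tB", "transcript", "mRNA", "c1", 600, 900, "+", parent = "gB"),
    feat_row("tB.c1", "CDS", "CDS", "c1", 600, 900, "+", phase = 0L, parent = "tB")
  )
}

prot_tx <- function(id, start, end, target, strand = "+") rbind(
  feat_row(id, "transcript", "mRNA", "c1", start, end, strand,
           attrs = c(Target = target)),
  feat_row(paste0(id, ".c1"), "CDS", "CDS", "c1", start, end, strand,
           phase = 0L, parent = id)
)

test_that("a protein transcript inside its matching gene span pairs as both", {
  pd <- mk_db(prot_tx("tA", 150, 350, "tA"))
  pairs <- match_transcripts(dna_world(), pd)
  expect_identical(pairs$tA$status, "both")
  expect_identical(pairs$tA$prot_candidates, "tA")
  expect_identical(pairs$tB$status, "dna_only")
})

test_that("a protein transcript also overlapping a different gene is rejected", {
  pd <- mk_db(prot_tx("tA", 150, 700, "tA")) # reaches into gB
  pairs <- match_transcripts(dna_world(), pd)
  expect_identical(pairs$tA$status, "dna_only")
  expect_length(pairs$tA$prot_candidates, 0)
})

test_that("overlap with a neighbor the matched locus also overlaps is allowed", {
  dd <- mk_db(
    feat_row("gA", "gene", "gene", "c1", 100, 650, "+"),   # gA overlaps gB
    feat_row("tA", "transcript", "mRNA", "c1", 100, 650, "+", parent = "gA"),
    feat_row("tA.c1", "CDS", "CDS", "c1", 100, 650, "+", phase = 0L, parent = "tA"),
    feat_row("gB", "gene", "gene", "c1", 600, 900, "+"),
    feat_row("tB", "transcript", "mRNA", "c1", 600, 900, "+", parent = "gB"),
    feat_row("tB.c1", "CDS", "CDS", "c1", 600, 900, "+", phase = 0L, parent = "tB")
  )
  pd <- mk_db(prot_tx("tA", 150, 640, "tA"))
  pairs <- match_transcripts(dd, pd)
  expect_identical(pairs$tA$status, "both")
})

test_that("strand-aware overlap: antisense neighbors never pair", {
  pd <- mk_db(prot_tx("tA", 150, 350, "tA", strand = "-"))
  pairs <- match_transcripts(dna_world(), pd)
  expect_identical(pairs$tA$status, "dna_only")
  expect_identical(pairs$tA$extra_candidates, "tA")  # flows to the copy resolver
})

test_that("multi-copy resolution removes read-throughs and keeps the best identity", {
  genome <- c(c1 = paste0(strrep("C", 99), "ATGAAAGGGTGCTGA",
                          strrep("G", 585), "T", strrep("GT", 100)))
  ## dna gene at 100-130; a second dna gene at 700-900 for the read-through case
  dd <- mk_db(
    feat_row("gA", "gene", "gene", "c1", 100, 130, "+"),
    feat_row("tA", "transcript", "mRNA", "c1", 100, 130, "+", parent = "gA"),
    feat_row("tA.c1", "CDS", "CDS", "c1", 100, 114, "+", phase = 0L, parent = "tA"),
    feat_row("gB", "gene", "gene", "c1", 700, 900, "+"),
    feat_row("tB", "transcript", "mRNA", "c1", 700, 900, "+", parent = "gB"),
    feat_row("tB.c1", "CDS", "CDS", "c1", 700, 900, "+", phase = 0L, parent = "tB")
  )
  ref_protein <- "MKGC*"
  ## candidate 1: perfect copy at the locus; candidate 2 starts 3 nt late and
  ## misses the initial Met
  pd <- mk_db(prot_tx("tA", 100, 114, "tA"),
              prot_tx("tA_copy2", 103, 117, "tA"))
  pairs <- match_transcripts(dd, pd)
  pr <- resolve_multicopy(pairs$tA, dd, pd, ref_protein, genome)
  expect_identical(pr$prot_candidates[pr$chosen_prot], "tA")
  expect_equal(pr$chosen_identity, 1.0)

  ## a read-through candidate spanning gA and gB is removed despite identity
  pd2 <- mk_db(prot_tx("tA", 100, 750, "tA"))
  pairs2 <- match_transcripts(dd, pd2)
  expect_length(pairs2$tA$prot_candidates, 0)

  ## single candidate is chosen
  pd3 <- mk_db(prot_tx("tA", 100, 114, "tA"))
  pr3 <- resolve_multicopy(match_transcripts(dd, pd3)$tA, dd, pd3, ref_protein, genome)
  expect_identical(pr3$chosen_prot, 1L)
})

test_that("pairing is a bijection on a clean fixture world", {
  w <- one_world(3)
  pairs <- match_transcripts(w$dna_db, w$prot_db)
  primary <- db_transcripts(w$ref_db)$feature_id
  for (tid in primary) {
    expect_false(is.null(pairs[[tid]]))
    expect_identical(pairs[[tid]]$status, "both")
  }
  ## no chosen protein candidate overlaps an unrelated gene locus
  for (tid in primary) {
    pr <- resolve_multicopy(pairs[[tid]], w$dna_db, w$prot_db,
                            "M", w$tgt_genome)
    if (is.na(pr$chosen_prot)) next
    ct <- db_feature(w$prot_db, pr$prot_candidates[pr$chosen_prot])
    gene <- db_feature(w$dna_db, db_feature(w$dna_db, tid)$parent_id)
    others <- setdiff(locus_overlaps(w$dna_db, ct$seqid, ct$start, ct$end, ct$strand),
                      gene$feature_id)
    expect_length(others, 0)
  }
})
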