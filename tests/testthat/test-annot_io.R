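write_tmp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

toy_gff <- function() write_tmp(c(
  "##gff-version 3",
  "chr1\ttoy\tgene\t100\t500\t.\t+\t.\tID=g1;gene_biotype=protein_coding",
  "chr1\ttoy\tmRNA\t100\t500\t.\t+\t.\tID=t1;Parent=g1",
  "chr1\ttoy\texon\t300\t500\t.\t+\t.\tID=t1.e2;Parent=t1",
  "chr1\ttoy\texon\t100\t200\t.\t+\t.\tID=t1.e1;Parent=t1",
  "chr1\ttoy\tCDS\t150\t200\t.\t+\t0\tID=t1.c1;Parent=t1;Note=has%3Bsemi",
  "chr1\ttoy\tCDS\t300\t400\t.\t+\t1\tID=t1.c2;Parent=t1"
), ".gff3")

test_that("read_fasta normalizes case, RNA and odd characters", {
  f <- write_tmp(c(">s1 some desc", "acgt"), ".fa")
  expect_identical(read_fasta(f), c(s1 = "ACGT"))
  f2 <- write_tmp(c(">s1", "ACGU"), ".fa")
  expect_identical(read_fasta(f2), c(s1 = "ACGT"))
  f3 <- write_tmp(c(">a", "AAA", ">b", "CCC"), ".fa")
  expect_identical(names(read_fasta(f3)), c("a", "b"))
  f4 <- write_tmp(c(">a", "ACRT"), ".fa")
  expect_warning(g <- read_fasta(f4), "non-ACGTN")
  expect_identical(unname(g), "ACNT")
  f5 <- write_tmp(c(">a", "AA", ">a", "CC"), ".fa")
  expect_error(read_fasta(f5), "duplicate")
})

test_that("GFF3 reading builds a sorted, indexed hierarchy", {
  db <- read_annotation(toy_gff(), "gff3")
  expect_equal(nrow(db$features), 6)
  expect_false(db$parentless)
  kids <- db_children(db, "t1", "exon")
  expect_equal(kids$start, c(100, 300))       # sorted by start
  cds <- db_children(db, "t1", "CDS")
  expect_equal(cds$phase, c(0L, 1L))
  expect_identical(db_attr(db, "t1.c1", "Note"), "has;semi")
  expect_identical(db_attr(db, "g1", "gene_biotype"), "protein_coding")
})

test_that("miniprot-style mRNA+CDS files are accepted and flagged parentless", {
  f <- write_tmp(c(
    "##gff-version 3",
    "chr1\tmp\tmRNA\t10\t100\t.\t+\t.\tID=m1;Target=t1",
    "chr1\tmp\tCDS\t10\t100\t.\t+\t0\tID=m1.c1;Parent=m1"
  ), ".gff3")
  db <- read_annotation(f, "gff3")
  expect_true(db$parentless)
  expect_identical(db_attr(db, "m1", "Target"), "t1")
})

test_that("dangling Parent references error with the offending id", {
  f <- write_tmp(c(
    "##gff-version 3",
    "chr1\ttoy\tmRNA\t1\t10\t.\t+\t.\tID=t1;Parent=ghost"
  ), ".gff3")
  expect_error(read_annotation(f, "gff3"), "ghost")
})

test_that("GTF input preserves gene_biotype and synthesizes parents", {
  f <- write_tmp(c(
    paste0("chr1\ttoy\texon\t100\t200\t.\t+\t.\t",
           'gene_id "g1"; transcript_id "t1"; gene_biotype "protein_coding";'),
    paste0("chr1\ttoy\tCDS\t120\t200\t.\t+\t0\t",
           'gene_id "g1"; transcript_id "t1";')
  ), ".gtf")
  db <- read_annotation(f, "gtf")
  expect_setequal(db$features$ftype, c("gene", "transcript", "exon", "CDS"))
  expect_identical(db_feature(db, "t1")$parent_id, "g1")
  g <- db_feature(db, "g1")
  expect_equal(c(g$start, g$end), c(100, 200))
})

test_that("GFF3 write/read round-trip is a fixed point on the feature set", {
  db <- read_annotation(toy_gff(), "gff3")
  out <- tempfile(fileext = ".gff3")
  write_gff3(db, out)
  expect_identical(readLines(out)[1], "##gff-version 3")
  db2 <- read_annotation(out, "gff3")
  cols <- c("feature_id", "ftype", "seqid", "start", "end", "strand", "phase", "parent_id")
  f1 <- db$features[order(db$features$feature_id), cols]
  f2 <- db2$features[order(db2$features$feature_id), cols]
  rownames(f1) <- rownames(f2) <- NULL
  expect_equal(f1, f2)
  expect_identical(db_attr(db2, "t1.c1", "Note"), "has;semi")  # escaping survives
  ## parent always precedes child
  lines <- readLines(out)[-1]
  ids <- sub(".*ID=([^;]+).*", "\\1", lines)
  parents <- ifelse(grepl("Parent=", lines), sub(".*Parent=([^;]+).*", "\\1", lines), NA)
  expect_true(all(is.na(parents) | match(parents, ids) < seq_along(parents)))
})

test_that("an empty database writes a header-only file", {
  empty <- annotation_db(read_annotation(toy_gff(), "gff3")$features[0, ])
  out <- tempfile(fileext = ".gff3")
  write_gff3(empty, out)
  expect_identical(readLines(out), "##gff-version 3")
})

test_that("filter_reference drops patch scaffolds and unwanted biotypes", {
  f <- write_tmp(c(
    "##gff-version 3",
    "chr1\tr\tgene\t1\t10\t.\t+\t.\tID=keep;gene_biotype=protein_coding",
    "chr1_alt\tr\tgene\t1\t10\t.\t+\t.\tID=onpatch;gene_biotype=protein_coding",
    "chr1_alt\tr\tmRNA\t1\t10\t.\t+\t.\tID=onpatch.t;Parent=onpatch",
    "chr1\tr\tgene\t50\t60\t.\t+\t.\tID=ribo;gene_biotype=rRNA"
  ), ".gff3")
  db <- read_annotation(f, "gff3")
  out <- filter_reference(db, drop_scaffold_suffixes = c("_fix", "_alt"),
                          drop_biotypes = "rRNA")
  expect_identical(db_genes(out)$feature_id, "keep")
  expect_false("onpatch.t" %in% out$features$feature_id)  # descendants removed
  expect_identical(filter_reference(db), db)              # empty filters: identity
})

test_that("locus index queries equal a brute-force interval scan", {
  set.seed(11)
  g <- data.frame(feature_id = sprintf("g%02d", 1:30), ftype = "gene",
                  orig_type = "gene", seqid = sample(c("c1", "c2"), 30, TRUE),
                  source = ".", start = sample(1:900, 30), score = NA_character_,
                  strand = sample(c("+", "-"), 30, TRUE), phase = NA_integer_,
                  parent_id = NA_character_, stringsAsFactors = FALSE)
  g$end <- g$start + sample(10:120, 30, TRUE)
  g$attributes <- I(replicate(30, character(), simplify = FALSE))
  db <- annotation_db(g)
  for (k in 1:25) {
    s <- sample(1:950, 1); e <- s + sample(5:100, 1)
    sq <- sample(c("c1", "c2"), 1)
    brute <- g$feature_id[g$seqid == sq & g$start <= e & g$end >= s]
    expect_setequal(locus_overlaps(db, sq, s, e), brute)
  }
})
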