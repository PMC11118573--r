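#' @useDynLib protlift, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats setNames
#' @importFrom utils write.table
NULL

## Feature types that are canonicalized to ftype = "transcript". Covers the
## coding and non-coding transcript vocabulary used in RefSeq/Ensembl dumps.
.TRANSCRIPT_TYPES <- c(
  "mRNA", "transcript", "lnc_RNA", "lncRNA", "ncRNA", "miRNA", "snoRNA",
  "tRNA", "snRNA", "rRNA", "misc_RNA", "antisense_RNA", "V_gene_segment",
  "J_gene_segment", "C_gene_segment", "primary_transcript"
)
.GENE_TYPES <- c("gene", "pseudogene")

.canon_ftype <- function(type) {
  ifelse(type %in% .GENE_TYPES, "gene",
    ifelse(type %in% .TRANSCRIPT_TYPES, "transcript",
      ifelse(type %in% c("exon", "CDS"), type, "other")))
}

#' Construct an annotation database from a feature table
#'
#' The database is the package's indexed store for a GFF3-style feature
#' hierarchy (gene -> transcript -> exon/CDS). Children are indexed per
#' parent and kept sorted by start coordinate. Coordinates are 1-based
#' inclusive throughout (GFF3 native).
#'
#' @param features data.frame with columns `feature_id`, `ftype`,
#'   `orig_type`, `seqid`, `source`, `start`, `end`, `score`, `strand`,
#'   `phase`, `parent_id` and a list-column `attributes` (named character
#'   vectors).
#' @return An object of class `annotation_db`.
#' @export
annotation_db <- function(features) {
  stopifnot(is.data.frame(features))
  need <- c("feature_id", "ftype", "orig_type", "seqid", "source", "start",
            "end", "score", "strand", "phase", "parent_id", "attributes")
  miss <- setdiff(need, names(features))
  if (length(miss)) stop("missing feature columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(features$feature_id))
    stop("duplicate feature ids: ",
         paste(unique(features$feature_id[duplicated(features$feature_id)]), collapse = ", "))
  bad <- features$start > features$end
  if (any(bad)) stop("start > end for: ", paste(features$feature_id[bad], collapse = ", "))
  dangling <- !is.na(features$parent_id) &
    !(features$parent_id %in% features$feature_id)
  if (any(dangling))
    stop("dangling Parent reference(s): ",
         paste(unique(features$parent_id[dangling]), collapse = ", "))
  rownames(features) <- NULL

  has_parent <- !is.na(features$parent_id)
  ord <- order(features$parent_id[has_parent], features$start[has_parent])
  kids <- split(features$feature_id[has_parent][ord],
                features$parent_id[has_parent][ord])
  parentless <- any(features$ftype == "transcript" & !has_parent)

  structure(list(features = features, children = kids, parentless = parentless),
            class = "annotation_db")
}

#' @export
print.annotation_db <- function(x, ...) {
  tab <- table(x$features$ftype)
  cat(sprintf("<annotation_db> %d features (%s)%s\n", nrow(x$features),
              paste(names(tab), tab, sep = ":", collapse = ", "),
              if (x$parentless) " [parentless transcripts]" else ""))
  invisible(x)
}

## ---- accessors -------------------------------------------------------------

#' Look up one feature record by id
#' @param db an `annotation_db`
#' @param id feature id
#' @return One-row data.frame.
#' @export
db_feature <- function(db, id) {
  i <- match(id, db$features$feature_id)
  if (anyNA(i)) stop("unknown feature id: ", paste(id[is.na(i)], collapse = ", "))
  db$features[i, , drop = FALSE]
}

#' Children of a feature, ordered by start
#' @inheritParams db_feature
#' @param ftype optional type filter (e.g. "CDS")
#' @return data.frame of child features (possibly empty).
#' @export
db_children <- function(db, id, ftype = NULL) {
  ids <- db$children[[id]]
  if (is.null(ids)) ids <- character()
  out <- db$features[match(ids, db$features$feature_id), , drop = FALSE]
  if (!is.null(ftype)) out <- out[out$ftype %in% ftype, , drop = FALSE]
  out[order(out$start), , drop = FALSE]
}

#' All gene features of a database
#' @inheritParams db_feature
#' @export
db_genes <- function(db) db$features[db$features$ftype == "gene", , drop = FALSE]

#' All transcript features of a database
#' @inheritParams db_feature
#' @export
db_transcripts <- function(db) db$features[db$features$ftype == "transcript", , drop = FALSE]

#' Gene loci intersecting an interval
#'
#' Interval query over gene spans, the package's locus index. Backed by
#' [IRanges::findOverlaps()].
#'
#' @inheritParams db_feature
#' @param seqid,start,end query interval (1-based inclusive)
#' @param strand optional strand restriction ("+" or "-")
#' @return Character vector of gene feature ids whose span intersects the query.
#' @export
locus_overlaps <- function(db, seqid, start, end, strand = NULL) {
  g <- db_genes(db)
  g <- g[g$seqid == seqid, , drop = FALSE]
  if (!is.null(strand)) g <- g[g$strand == strand, , drop = FALSE]
  if (!nrow(g)) return(character())
  hits <- IRanges::overlapsAny(IRanges::IRanges(g$start, g$end),
                               IRanges::IRanges(start, end))
  g$feature_id[hits]
}

#' Attribute value of a feature
#' @inheritParams db_feature
#' @param key attribute key
#' @return Character scalar or `NA_character_`.
#' @export
db_attr <- function(db, id, key) {
  a <- db$features$attributes[[match(id, db$features$feature_id)]]
  if (is.null(a) || !(key %in% names(a))) NA_character_ else unname(a[[key]])
}

## gene_biotype/gene_type lookup with fallback to the original feature type
.biotype <- function(row) {
  a <- row$attributes[[1]]
  for (k in c("gene_biotype", "gene_type", "biotype")) {
    if (!is.null(a) && k %in% names(a)) return(unname(a[[k]]))
  }
  NA_character_
}

## ---- FASTA -----------------------------------------------------------------

#' Read a FASTA file into a genome map
#'
#' Sequences are uppercased, RNA `U` is converted to `T`, and any character
#' outside `A,C,G,T,N` is replaced by `N` with a warning. Record order is
#' preserved.
#'
#' @param path FASTA file
#' @return Named character vector, seqid -> sequence.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids))
    stop("duplicate seqid in FASTA: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- toupper(as.character(ss))
  seqs <- chartr("U", "T", seqs)
  odd <- gsub("[ACGTN]", "", seqs)
  if (any(nchar(odd) > 0)) {
    warning("non-ACGTN characters replaced by N in: ",
            paste(ids[nchar(odd) > 0], collapse = ", "))
    seqs <- vapply(seqs, function(s) gsub("[^ACGTN]", "N", s), character(1))
  }
  setNames(unname(seqs), ids)
}

#' Write a genome map to FASTA
#' @param genome named character vector as returned by [read_fasta()]
#' @param path output file
#' @param width line width
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(genome)) {
    s <- genome[[id]]
    writeLines(paste0(">", id), con)
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

## ---- GFF3 / GTF reading ----------------------------------------------------

.attr_list_from_mcols <- function(mc, drop) {
  keep <- setdiff(names(mc), drop)
  n <- nrow(mc)
  out <- vector("list", n)
  vals <- lapply(keep, function(k) {
    v <- mc[[k]]
    if (methods::is(v, "List") || is.list(v))
      vapply(as.list(v), function(x) if (length(x)) paste(x, collapse = ",") else NA_character_, character(1))
    else as.character(v)
  })
  names(vals) <- keep
  for (i in seq_len(n)) {
    a <- vapply(vals, `[[`, character(1), i)
    out[[i]] <- a[!is.na(a)]
  }
  out
}

#' Read a GFF3 or GTF annotation into an [annotation_db()]
#'
#' Feature types are canonicalized: `gene`/`pseudogene` to ftype "gene",
#' `mRNA`/`transcript` and the non-coding transcript types to ftype
#' "transcript" (the original type is kept in `orig_type`), `exon`/`CDS`
#' unchanged, anything else to "other". Files containing transcripts with no
#' gene parent (miniprot-style mRNA -> CDS output) are accepted and flagged
#' via the database's `parentless` field. For GTF input, missing `gene` or
#' `transcript` rows are synthesized from the spans of their children.
#'
#' @param path annotation file
#' @param dialect "gff3" or "gtf"
#' @return An `annotation_db`.
#' @export
read_annotation <- function(path, dialect = c("gff3", "gtf")) {
  dialect <- match.arg(dialect)
  gr <- rtracklayer::import(path, format = if (dialect == "gff3") "gff3" else "gtf")
  df <- data.frame(
    seqid = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
  mc <- as.data.frame(S4Vectors::mcols(gr))
  df$source <- if ("source" %in% names(mc)) as.character(mc$source) else "."
  df$orig_type <- as.character(mc$type)
  df$ftype <- .canon_ftype(df$orig_type)
  df$score <- if ("score" %in% names(mc)) as.character(mc$score) else NA_character_
  df$phase <- if ("phase" %in% names(mc)) as.integer(mc$phase) else NA_integer_

  if (dialect == "gff3") {
    ids <- if ("ID" %in% names(mc)) as.character(mc$ID) else rep(NA_character_, nrow(df))
    par <- if ("Parent" %in% names(mc)) {
      vapply(as.list(mc$Parent), function(p) if (length(p)) p[[1]] else NA_character_, character(1))
    } else rep(NA_character_, nrow(df))
    df$feature_id <- ids
    df$parent_id <- par
    df$attributes <- .attr_list_from_mcols(mc, c("type", "score", "phase", "source", "ID", "Parent"))
  } else {
    gid <- as.character(mc$gene_id)
    tid <- if ("transcript_id" %in% names(mc)) as.character(mc$transcript_id) else rep(NA_character_, nrow(df))
    df$feature_id <- ifelse(df$ftype == "gene", gid,
                       ifelse(df$ftype == "transcript", tid, NA_character_))
    df$parent_id <- ifelse(df$ftype == "gene", NA_character_,
                      ifelse(df$ftype == "transcript", gid, tid))
    df$attributes <- .attr_list_from_mcols(mc, c("type", "score", "phase", "source",
                                                 "gene_id", "transcript_id"))
    ## synthesize absent gene/transcript rows from child spans
    df <- .gtf_synthesize(df, gid, tid)
  }

  ## synthesize ids for id-less rows (typically exon/CDS)
  noid <- is.na(df$feature_id)
  if (any(noid)) {
    base <- ifelse(is.na(df$parent_id[noid]), "feat", df$parent_id[noid])
    df$feature_id[noid] <- paste0(base, ".", tolower(df$orig_type[noid]), ".",
                                  stats::ave(seq_along(base), base, df$orig_type[noid],
                                             FUN = seq_along))
  }
  annotation_db(df[, c("feature_id", "ftype", "orig_type", "seqid", "source",
                       "start", "end", "score", "strand", "phase", "parent_id",
                       "attributes")])
}

.gtf_synthesize <- function(df, gid, tid) {
  add <- list()
  for (t in setdiff(unique(tid[!is.na(tid)]), df$feature_id[df$ftype == "transcript"])) {
    sel <- which(tid == t & df$ftype %in% c("exon", "CDS"))
    add[[length(add) + 1L]] <- data.frame(
      seqid = df$seqid[sel[1]], start = min(df$start[sel]), end = max(df$end[sel]),
      strand = df$strand[sel[1]], source = df$source[sel[1]], orig_type = "transcript",
      ftype = "transcript", score = NA_character_, phase = NA_integer_,
      feature_id = t, parent_id = gid[sel[1]],
      attributes = I(list(character())), stringsAsFactors = FALSE)
  }
  if (length(add)) df <- rbind(df, do.call(rbind, add))
  tx_par <- df$parent_id[df$ftype == "transcript"]
  for (g in setdiff(unique(tx_par[!is.na(tx_par)]), df$feature_id[df$ftype == "gene"])) {
    sel <- which(df$parent_id == g & df$ftype == "transcript")
    add2 <- data.frame(
      seqid = df$seqid[sel[1]], start = min(df$start[sel]), end = max(df$end[sel]),
      strand = df$strand[sel[1]], source = df$source[sel[1]], orig_type = "gene",
      ftype = "gene", score = NA_character_, phase = NA_integer_,
      feature_id = g, parent_id = NA_character_,
      attributes = I(list(character())), stringsAsFactors = FALSE)
    df <- rbind(df, add2)
  }
  df
}

## ---- GFF3 writing ----------------------------------------------------------

.gff_escape <- function(x) {
  x <- gsub("%", "%25", x, fixed = TRUE)
  x <- gsub(";", "%3B", x, fixed = TRUE)
  x <- gsub("=", "%3D", x, fixed = TRUE)
  x <- gsub("&", "%26", x, fixed = TRUE)
  x <- gsub(",", "%2C", x, fixed = TRUE)
  gsub("\t", "%09", x, fixed = TRUE)
}

.gff_line <- function(row) {
  a <- row$attributes[[1]]
  parts <- paste0("ID=", .gff_escape(row$feature_id))
  if (!is.na(row$parent_id))
    parts <- c(parts, paste0("Parent=", .gff_escape(row$parent_id)))
  a <- a[setdiff(names(a), c("ID", "Parent"))]
  if (length(a))
    parts <- c(parts, paste0(.gff_escape(names(a)), "=", .gff_escape(unname(a))))
  paste(row$seqid,
        ifelse(is.na(row$source), ".", row$source),
        row$orig_type, row$start, row$end,
        ifelse(is.na(row$score), ".", row$score),
        row$strand,
        ifelse(is.na(row$phase), ".", as.character(row$phase)),
        paste(parts, collapse = ";"),
        sep = "\t")
}

#' Write an annotation database as GFF3
#'
#' Features are emitted parent-before-child (depth-first from top-level
#' features ordered by seqid and start), so the output always satisfies the
#' GFF3 forward-reference convention and round-trips through
#' [read_annotation()].
#'
#' @param db an `annotation_db`
#' @param path output file
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(db, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  f <- db$features
  top <- f[is.na(f$parent_id), , drop = FALSE]
  top <- top[order(top$seqid, top$start, top$feature_id), , drop = FALSE]
  emit <- function(id) {
    row <- f[match(id, f$feature_id), , drop = FALSE]
    writeLines(.gff_line(row), con)
    for (cid in db$children[[id]]) emit(cid)
  }
  for (id in top$feature_id) emit(id)
  invisible(path)
}

## ---- reference preprocessing -----------------------------------------------

#' Drop alternative-scaffold genes and unwanted biotypes from a reference
#'
#' Removes genes located on seqids ending in any of `drop_scaffold_suffixes`
#' (e.g. the `_fix`/`_alt` patch scaffolds of GRCh38) and genes whose biotype
#' is listed in `drop_biotypes` (e.g. rRNA, which occurs in hundreds of
#' near-identical copies and confounds alignment), together with all their
#' descendants.
#'
#' @param db an `annotation_db`
#' @param drop_scaffold_suffixes character vector of seqid suffixes
#' @param drop_biotypes character vector of gene biotypes
#' @return Filtered `annotation_db`.
#' @export
filter_reference <- function(db, drop_scaffold_suffixes = character(),
                             drop_biotypes = character()) {
  g <- db_genes(db)
  drop <- rep(FALSE, nrow(g))
  for (suf in drop_scaffold_suffixes) drop <- drop | endsWith(g$seqid, suf)
  if (length(drop_biotypes)) {
    bt <- vapply(seq_len(nrow(g)), function(i) {
      b <- .biotype(g[i, , drop = FALSE])
      if (is.na(b)) "" else b
    }, character(1))
    drop <- drop | bt %in% drop_biotypes
  }
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
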