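# Shared fixture worlds, generated once per test run and cached.

.world_cache <- new.env(parent = emptyenv())

all_scenarios <- function() protlift:::.SCENARIOS

one_world <- function(seed = 1L) {
  key <- paste0("w", seed)
  if (!exists(key, .world_cache)) {
    sc <- all_scenarios()
    specs <- lapply(seq_along(sc), function(i) scenario_spec(sc[i], seed = seed * 37L + i))
    assign(key, make_world(specs), .world_cache)
  }
  get(key, .world_cache)
}

# run the pipeline on a world, cached
world_result <- function(seed = 1L) {
  key <- paste0("r", seed)
  if (!exists(key, .world_cache)) {
    w <- one_world(seed)
    assign(key, protlift_run(w$ref_genome, w$ref_db, w$tgt_genome,
                             w$dna_db, w$prot_db, out_prefix = NULL),
           .world_cache)
  }
  get(key, .world_cache)
}

# gap-compressed protein identity of a candidate transcript's CDS chain
# against the reference protein of the same world transcript
candidate_identity <- function(world, db, tx_id, ref_tx_id) {
  ref_cds <- db_children(world$ref_db, ref_tx_id, "CDS")
  ref_strand <- db_feature(world$ref_db, ref_tx_id)$strand
  ref_sp <- extract_spliced(world$ref_genome, ref_cds[, c("seqid", "start", "end")], ref_strand)
  ref_protein <- translate_dna(ref_sp$dna)
  cds <- db_children(db, tx_id, "CDS")
  strand <- db_feature(db, tx_id)$strand
  sp <- extract_spliced(world$tgt_genome, cds[, c("seqid", "start", "end")], strand)
  protein_identity(align_protein(ref_protein, translate_dna(sp$dna)))
}
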