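# Shared fixtures, built in code and memoised for the session.

ALL_DECOYS <- c("ortholog_presence", "ortholog_proximity", "exonic_overlap",
                "synteny", "go", "frame")

# the funnel stage at which each decoy class must be rejected
DECOY_STAGE <- c(ortholog_presence = "ortholog_presence",
                 ortholog_proximity = "ortholog_proximity",
                 exonic_overlap = "exonic_overlap",
                 synteny = "synteny",
                 go = "developmental_flank",
                 frame = "frame")

.fixtures <- new.env(parent = emptyenv())

fixture_bundle <- function(seed = 42, decoys = character(0), n_genes = 3) {
  key <- paste0("b", seed, "_", n_genes, "_", paste(decoys, collapse = "."))
  if (is.null(.fixtures[[key]])) {
    .fixtures[[key]] <- generate_scenario(scenario_config(
      seed = seed, n_reference_genes = n_genes, decoy_classes = decoys))
  }
  .fixtures[[key]]
}

fixture_funnel <- function(seed = 42, decoys = character(0), n_genes = 3) {
  key <- paste0("f", seed, "_", n_genes, "_", paste(decoys, collapse = "."))
  if (is.null(.fixtures[[key]])) {
    .fixtures[[key]] <- run_funnel(fixture_bundle(seed, decoys, n_genes))
  }
  .fixtures[[key]]
}

# minimal hand-built annotation / hit rows for filter unit tests
mk_ann <- function(feature_id, gene_id, contig, start0, end0,
                   type = "gene", strand = "+") {
  data.frame(feature_id = feature_id, gene_id = gene_id, contig = contig,
             start0 = start0, end0 = end0, strand = strand, type = type,
             stringsAsFactors = FALSE)
}

mk_hit <- function(hit_id, exon_id, gene_id, contig, start0, end0,
                   strand = "+", score = 100) {
  data.frame(hit_id = hit_id, exon_id = exon_id, gene_id = gene_id,
             contig = contig, start0 = start0, end0 = end0, strand = strand,
             score = score, stringsAsFactors = FALSE)
}
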