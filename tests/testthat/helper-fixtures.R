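# In-code fixture builders shared across test files.

write_tsv_lines <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}

# A 3-protein toy: p1 {A}, p2 {B}, p3 {A, C}; template DDI (A, B).
toy_domains <- function() {
  data.table(protein_id = c("p1", "p2", "p3", "p3"),
             transcript_id = c("t1", "t2", "t3", "t3"),
             domain_id = c("A", "B", "A", "C"),
             aa_start = c(1L, 1L, 1L, 30L),
             aa_end = c(10L, 10L, 10L, 40L))
}

toy_ppi <- function(pairs, resource = "R1") {
  data.table(protein_a = vapply(pairs, `[[`, "", 1L),
             protein_b = vapply(pairs, `[[`, "", 2L),
             resource = resource)
}

# Random multi-domain network for brute-force comparisons.
random_network <- function(n_proteins = 12L, n_domains = 6L, n_edges = 30L,
                           n_templates = 6L) {
  prot <- sprintf("p%02d", seq_len(n_proteins))
  doms <- LETTERS[seq_len(n_domains)]
  occ <- rbindlist(lapply(prot, function(p) {
    k <- sample.int(3L, 1L)
    data.table(protein_id = p, transcript_id = paste0("t_", p),
               domain_id = sample(doms, k),
               aa_start = 1L, aa_end = 10L)
  }))
  pairs <- unique(rbindlist(lapply(seq_len(n_edges), function(i) {
    pq <- sample(prot, 2L, replace = TRUE)  # homodimers allowed
    data.table(protein_a = min(pq), protein_b = max(pq))
  })))
  tmpl_pool <- as.data.table(t(utils::combn(doms, 2L)))
  setnames(tmpl_pool, c("domain_a", "domain_b"))
  tmpl <- tmpl_pool[sample.int(nrow(tmpl_pool), min(n_templates, nrow(tmpl_pool)))]
  net <- suppressWarnings(build_joint_network(
    data.table(pairs, resource = "R1"), occ, ddi_templates = tmpl))
  list(network = net, domains = occ, templates = tmpl)
}

# Wrap a domain table into an affected_features object (no motifs/residues).
as_affected_features <- function(domains_dt) {
  empty_mot <- data.table(event_id = character(), gene_id = character(),
                          protein_id = character(), transcript_id = character(),
                          motif_start = integer(), motif_end = integer(),
                          overlap_nt = integer())
  empty_res <- data.table(event_id = character(), gene_id = character(),
                          protein_id = character(), transcript_id = character(),
                          position = integer())
  if (!"event_id" %in% names(domains_dt)) domains_dt[, event_id := "ev1"]
  for (col in c("gene_id", "transcript_id")) {
    if (!col %in% names(domains_dt)) domains_dt[, (col) := NA_character_]
  }
  if (!"overlap_nt" %in% names(domains_dt)) domains_dt[, overlap_nt := 1L]
  out <- list(domains = domains_dt, motifs = empty_mot, residues = empty_res,
              unmapped_events = character())
  class(out) <- "affected_features"
  out
}

# Small fixture bundle configs used by several test files.
small_bundle <- function(seed = 7L, dir = tempfile("bundle")) {
  simulate_interactome(fixture_config(seed = seed), dir)
}

# DDI-prediction benchmark world: domain types recur across enough proteins
# for co-occurrence counts to carry signal.
ddi_world_config <- function(noise, seed) {
  fixture_config(n_genes = 60L, n_domains = 12L, n_truth_ddis = 6L,
                 n_ppi_edges = 240L, ppi_from_truth_fraction = 1 - noise,
                 seed = seed)
}

enrich_world_config <- function(seed, factor) {
  fixture_config(n_genes = 220L, transcripts_per_gene = 2L,
                 exons_per_transcript = 5L, n_resources = 3L,
                 ppi_from_truth_fraction = 1, n_pathways = 11L,
                 pathway_size = 40L,
                 target_pathway_enrichment_factor = factor,
                 n_events = 15L, interaction_model = "matched_pairs",
                 seed = seed)
}

# One enrichment pass on a planted bundle, via the public API.
enrich_planted <- function(bundle, ctx, plant_seed) {
  pl <- plant_splice_events(bundle, seed = plant_seed, context = ctx,
                            out_file = tempfile(fileext = ".tsv"))
  ev <- read_splice_events(pl$path, "generic_bed")
  sig <- filter_events(ev)
  feats <- map_events_to_features(sig, ctx$models, ctx$dom_fp)
  aff <- derive_affected_edges(ctx$network, feats)
  stats <- network_characteristics(ctx$network, ctx$gsets, ctx$p2g)
  unlink(pl$path)
  enrich_pathways(stats, aff, ctx$gsets, ctx$p2g)$results
}
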