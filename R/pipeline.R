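# End-to-end pipeline driver: build -> filter -> map -> derive edges ->
# enrich -> detail/cluster, with a JSON run-metadata file and deterministic
# outputs.

#' Pipeline run configuration
#'
#' Collects input paths and parameters for [run_pipeline()]. Threshold
#' defaults are `dpsi_min = 0.05`, `p_max = 0.05` (inclusive comparisons);
#' the predicted-DDI tier filter defaults to none (experimental evidence
#' only).
#'
#' @param gtf path to the transcript-model GTF.
#' @param domains path to the domain occurrence TSV (`protein_id`,
#'   `transcript_id`, `domain_id`, `aa_start`, `aa_end`).
#' @param ppi named character vector/list of PPI TSV paths (names = resource
#'   labels).
#' @param ddi_templates path to the experimental DDI TSV (`domain_a`,
#'   `domain_b`); optional.
#' @param events path to the splicing event table.
#' @param dialect event dialect (see [read_splice_events()]).
#' @param gene_sets path to a GMT file.
#' @param protein_to_gene path to a `protein_id`/`gene_id` TSV.
#' @param out_dir output directory.
#' @param dmi,residue,predicted_ddis optional evidence TSV paths.
#' @param tier_filter one of `"none"`, `"gold"`, `"gold,silver"`,
#'   `"gold,silver,bronze"` (or a character vector of tiers).
#' @param dpsi_min,p_max event filter thresholds.
#' @param database_label label for the gene-set database.
#' @param organism_label free-text organism label (metadata only).
#' @param seed integer seed recorded in the metadata (the pipeline itself is
#'   deterministic).
#' @return a validated list of class `run_config`.
#' @export
run_config <- function(gtf, domains, ppi, events, gene_sets, protein_to_gene,
                       out_dir, ddi_templates = NULL, dmi = NULL,
                       residue = NULL, predicted_ddis = NULL,
                       tier_filter = "none", dialect = "generic_bed",
                       dpsi_min = 0.05, p_max = 0.05,
                       database_label = "DB", organism_label = "synthetic",
                       seed = 1L) {
  if (is.character(tier_filter) && length(tier_filter) == 1L) {
    tier_filter <- if (identical(tier_filter, "none")) character() else
      strsplit(tier_filter, ",", fixed = TRUE)[[1L]]
  }
  cfg <- list(gtf = gtf, domains = domains, ppi = as.list(ppi),
              events = events, gene_sets = gene_sets,
              protein_to_gene = protein_to_gene, out_dir = out_dir,
              ddi_templates = ddi_templates, dmi = dmi, residue = residue,
              predicted_ddis = predicted_ddis,
              tier_filter = trimws(tier_filter), dialect = dialect,
              dpsi_min = dpsi_min, p_max = p_max,
              database_label = database_label,
              organism_label = organism_label, seed = as.integer(seed))
  check_range(cfg$dpsi_min, 0, 1, "dpsi_min")
  check_range(cfg$p_max, 0, 1, "p_max")
  req <- c("gtf", "domains", "events", "gene_sets", "protein_to_gene")
  for (f in req) {
    if (!file.exists(cfg[[f]])) stopf("input path for '%s' does not exist: %s",
                                      f, cfg[[f]])
  }
  if (length(cfg$ppi) == 0L) stopf("at least one PPI table is required")
  if (is.null(names(cfg$ppi)) || any(!nzchar(names(cfg$ppi)))) {
    names(cfg$ppi) <- sprintf("R%02d", seq_along(cfg$ppi))
  }
  for (p in cfg$ppi) if (!file.exists(p)) stopf("PPI path does not exist: %s", p)
  for (f in c("ddi_templates", "dmi", "residue", "predicted_ddis")) {
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]])) {
      stopf("input path for '%s' does not exist: %s", f, cfg[[f]])
    }
  }
  class(cfg) <- "run_config"
  cfg
}

#' Run the full splicing-aware rewiring pipeline
#'
#' Executes: read inputs, build the joint network, filter events, map events
#' to affected features, derive affected edges, run the edge-level enrichment
#' and write all result tables plus `run_metadata.json` (package version,
#' config, per-stage counts). On any stage error a `FAILED` marker file is
#' written to the output directory (partial outputs are retained) and the
#' error is re-thrown.
#'
#' @param config a `run_config` (or a list accepted by [run_config()]).
#' @return invisibly, a list with the run metadata and the in-memory stage
#'   results (`network`, `events`, `features`, `affected`, `enrichment`).
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "run_config")) config else
    do.call(run_config, config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  fail_marker <- file.path(cfg$out_dir, "FAILED")
  if (file.exists(fail_marker)) unlink(fail_marker)

  res <- tryCatch({
    models <- read_transcript_models_gtf(cfg$gtf)
    dom <- fread(cfg$domains, sep = "\t")
    ppi <- rbindlist(lapply(names(cfg$ppi), function(r) {
      read_ppi_table(cfg$ppi[[r]], r)
    }))
    templates <- if (!is.null(cfg$ddi_templates))
      fread(cfg$ddi_templates, sep = "\t") else NULL
    dmi <- if (!is.null(cfg$dmi)) fread(cfg$dmi, sep = "\t") else NULL
    residue <- if (!is.null(cfg$residue)) fread(cfg$residue, sep = "\t") else NULL
    pddis <- if (!is.null(cfg$predicted_ddis))
      fread(cfg$predicted_ddis, sep = "\t") else NULL
    gsets <- read_gene_sets_gmt(cfg$gene_sets, cfg$database_label)
    p2g <- fread(cfg$protein_to_gene, sep = "\t")

    network <- build_joint_network(ppi, dom, ddi_templates = templates,
                                   dmi_records = dmi,
                                   residue_records = residue,
                                   predicted_ddis = pddis,
                                   tier_filter = cfg$tier_filter)
    stats <- network_characteristics(network, gsets, p2g)

    events <- read_splice_events(cfg$events, cfg$dialect)
    sig <- filter_events(events, cfg$dpsi_min, cfg$p_max)

    dom_fp <- add_domain_footprints(dom, models)
    # protein -> transcript associations, from the domain table and from GTF
    # protein_id attributes
    p2t <- unique(rbindlist(list(
      dom[, .(protein_id, transcript_id)],
      rbindlist(lapply(unclass(models), function(tm) {
        if (is.na(tm$protein_id)) NULL else
          data.table(protein_id = tm$protein_id,
                     transcript_id = tm$transcript_id)
      }))
    ), use.names = TRUE))
    motif_recs <- if (!is.null(dmi)) {
      mr <- as.data.table(dmi)
      mm <- merge(mr, p2t, by.x = "protein_motif", by.y = "protein_id",
                  allow.cartesian = TRUE)
      unique(mm[, .(protein_id = protein_motif, transcript_id,
                    motif_start = as.integer(motif_start),
                    motif_end = as.integer(motif_end))])
    } else NULL
    residue_recs <- if (!is.null(residue)) {
      rr <- as.data.table(residue)
      long <- rbindlist(list(
        rr[, .(protein_id = protein_a, pos = as.character(residues_a))],
        rr[, .(protein_id = protein_b, pos = as.character(residues_b))]
      ))
      long <- long[!is.na(pos) & nzchar(pos)]
      long <- long[, .(position = as.integer(strsplit(pos, ",", fixed = TRUE)[[1L]])),
                   by = .(protein_id, pos)][, .(protein_id, position)]
      unique(merge(unique(long), p2t, by = "protein_id",
                   allow.cartesian = TRUE))[, .(protein_id, transcript_id, position)]
    } else NULL

    features <- map_events_to_features(sig, models, dom_fp,
                                       motif_records = motif_recs,
                                       residue_records = residue_recs)
    affected <- derive_affected_edges(network, features)
    enr <- enrich_pathways(stats, affected, gsets, p2g)
    graph <- pathway_cluster_graph(enr)

    details <- list()
    for (pid in enr$results[p_adj <= 0.05, pathway_id]) {
      details[[pid]] <- pathway_detail(network, affected, pid, gsets, p2g)
    }
    feat_tab <- affected_features_table(features)
    aff_tab <- if (nrow(affected$edges)) {
      affected$edges[, .(protein_a, protein_b, lost_evidence = n_lost,
                         surviving_evidence = n_surviving, event_ids)]
    } else {
      data.table(protein_a = character(), protein_b = character(),
                 lost_evidence = integer(), surviving_evidence = integer(),
                 event_ids = character())
    }
    manifest <- write_results(list(enrichment = enr$results,
                                   affected_features = feat_tab,
                                   affected_edges = aff_tab,
                                   pathway_details = details), cfg$out_dir)
    export_network(network, file.path(cfg$out_dir, "network"))
    export_cluster_graph(graph, file.path(cfg$out_dir, "pathway_clusters"))

    counts <- list(
      ppi_edges_distinct = nrow(network$edges) + nrow(network$unannotated_edges),
      annotated_edges = nrow(network$edges),
      evidence_items = nrow(network$evidence),
      events_read = nrow(events),
      events_significant = nrow(sig),
      features_domains = nrow(features$domains),
      features_motifs = nrow(features$motifs),
      features_residues = nrow(features$residues),
      affected_edges = nrow(affected$edges),
      pathways_tested = nrow(enr$results),
      pathways_untestable = length(enr$untestable),
      pathways_significant = nrow(enr$results[p_adj <= 0.05])
    )
    meta <- list(package = "spliceRewire",
                 version = as.character(utils::packageVersion("spliceRewire")),
                 config = lapply(unclass(cfg), function(x)
                   if (is.null(x)) NULL else unname(unlist(x))),
                 counts = counts)
    jsonlite::write_json(meta, file.path(cfg$out_dir, "run_metadata.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    list(metadata = meta, network = network, stats = stats, events = sig,
         features = features, affected = affected, enrichment = enr,
         cluster_graph = graph, manifest = manifest)
  }, error = function(e) {
    writeLines(conditionMessage(e), fail_marker)
    stop(e)
  })
  invisible(res)
}
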