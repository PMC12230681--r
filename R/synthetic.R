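# Deterministic synthetic fixture generator: a toy genome with multi-exon
# transcripts, domain occurrences with in-CDS protein intervals, multi-resource
# PPI tables generated from a planted DDI ground truth, pathway gene sets, and
# splicing-event tables with a planted enrichment signal. Everything is
# emitted as files on disk so the reader / CLI path is exercised end to end.

#' Fixture generator configuration
#'
#' Validated configuration for [simulate_interactome()] /
#' [plant_splice_events()]. All randomness is driven by `seed`; a fixed seed
#' yields a byte-identical output bundle.
#'
#' Two interaction models are available:
#' \describe{
#'   \item{shared_domains}{every protein carries one domain drawn (with
#'     replacement) from `n_domains` types, so domain types recur across
#'     proteins and the co-occurrence signal accumulates over edges. Used to
#'     benchmark DDI prediction.}
#'   \item{matched_pairs}{every protein carries its own private domain type
#'     and the truth-derived PPIs form a perfect matching, so one splicing
#'     event disrupts exactly one annotated edge. Used to benchmark the
#'     enrichment test (the planted null is then an exact uniform edge draw).}
#' }
#'
#' @param n_genes number of genes (one protein per gene).
#' @param transcripts_per_gene transcripts per gene (first is canonical).
#' @param exons_per_transcript exons in the canonical transcript.
#' @param n_domains number of domain types (shared_domains model).
#' @param n_resources number of PPI resources.
#' @param ppi_from_truth_fraction fraction of PPI edges generated from the
#'   planted truth DDI set.
#' @param noise_edge_fraction fraction of uniformly random edges; defaults to
#'   `1 - ppi_from_truth_fraction` and must agree with it when given.
#' @param n_pathways number of pathway gene sets (first is the target).
#' @param pathway_size genes per pathway.
#' @param target_pathway_enrichment_factor sampling weight multiplier for
#'   target-incident edges when planting events.
#' @param n_events number of significant events to plant (an equal number of
#'   sub-threshold decoys is added).
#' @param n_ppi_edges total distinct PPI edges to generate.
#' @param resource_coverage fraction of edges each resource observes.
#' @param interaction_model `"shared_domains"` or `"matched_pairs"`.
#' @param n_truth_ddis size of the planted truth DDI set (shared_domains).
#' @param seed RNG seed.
#' @return a validated list of class `fixture_config`.
#' @export
fixture_config <- function(n_genes = 20L, transcripts_per_gene = 2L,
                           exons_per_transcript = 5L, n_domains = 15L,
                           n_resources = 3L, ppi_from_truth_fraction = 0.8,
                           noise_edge_fraction = NULL, n_pathways = 10L,
                           pathway_size = 6L,
                           target_pathway_enrichment_factor = 4,
                           n_events = 10L, n_ppi_edges = 4L * n_genes,
                           resource_coverage = 0.8,
                           interaction_model = c("shared_domains",
                                                 "matched_pairs"),
                           n_truth_ddis = max(3L, ceiling(n_domains / 2)),
                           seed = 1L) {
  interaction_model <- match.arg(interaction_model)
  cfg <- list(n_genes = as.integer(n_genes),
              transcripts_per_gene = as.integer(transcripts_per_gene),
              exons_per_transcript = as.integer(exons_per_transcript),
              n_domains = as.integer(n_domains),
              n_resources = as.integer(n_resources),
              ppi_from_truth_fraction = ppi_from_truth_fraction,
              noise_edge_fraction = noise_edge_fraction %||%
                (1 - ppi_from_truth_fraction),
              n_pathways = as.integer(n_pathways),
              pathway_size = as.integer(pathway_size),
              target_pathway_enrichment_factor = target_pathway_enrichment_factor,
              n_events = as.integer(n_events),
              n_ppi_edges = as.integer(n_ppi_edges),
              resource_coverage = resource_coverage,
              interaction_model = interaction_model,
              n_truth_ddis = as.integer(n_truth_ddis),
              seed = as.integer(seed))
  counts <- c("n_genes", "transcripts_per_gene", "exons_per_transcript",
              "n_domains", "n_resources", "n_pathways", "pathway_size",
              "n_events", "n_ppi_edges", "n_truth_ddis")
  for (f in counts) {
    if (is.na(cfg[[f]]) || cfg[[f]] < 1L) stopf("config field %s must be >= 1", f)
  }
  check_range(cfg$ppi_from_truth_fraction, 0, 1, "ppi_from_truth_fraction")
  check_range(cfg$noise_edge_fraction, 0, 1, "noise_edge_fraction")
  check_range(cfg$resource_coverage, 0, 1, "resource_coverage")
  if (abs(cfg$ppi_from_truth_fraction + cfg$noise_edge_fraction - 1) > 1e-9) {
    stopf("ppi_from_truth_fraction and noise_edge_fraction must sum to 1")
  }
  if (cfg$pathway_size > cfg$n_genes) {
    stopf("infeasible config: pathway_size > n_genes")
  }
  if (cfg$exons_per_transcript < 3L && cfg$transcripts_per_gene > 1L) {
    stopf("infeasible config: exon-skipping isoforms need >= 3 exons")
  }
  if (cfg$target_pathway_enrichment_factor < 0) {
    stopf("target_pathway_enrichment_factor must be >= 0")
  }
  class(cfg) <- "fixture_config"
  cfg
}

# draw the gene/transcript structures; RNG must already be seeded
.sim_genome <- function(cfg) {
  models <- list()
  domains <- list()
  for (i in seq_len(cfg$n_genes)) {
    gid <- sprintf("G%03d", i)
    pid <- sprintf("P%03d", i)
    chrom <- if (i %% 2L == 1L) "chr1" else "chr2"
    strand <- if (i %% 4L < 2L) "+" else "-"
    offset <- 1L + ((i - 1L) %/% 2L) * 100000L
    k <- cfg$exons_per_transcript
    # exon lengths multiples of 3 so every exon-skipping isoform stays in frame
    ex_len <- sample(seq(30L, 150L, by = 3L), k, replace = TRUE)
    introns <- if (k > 1L) sample(100:500, k - 1L, replace = TRUE) else integer()
    starts <- integer(k); ends <- integer(k)
    pos <- offset
    for (e in seq_len(k)) {
      starts[e] <- pos
      ends[e] <- pos + ex_len[e] - 1L
      pos <- ends[e] + 1L + (if (e < k) introns[e] else 0L)
    }
    exons <- cbind(start = starts, end = ends)
    tid0 <- sprintf("T%03d_1", i)
    models[[tid0]] <- transcript_model(tid0, gid, chrom, strand, exons,
                                       cds = exons, protein_id = pid)
    if (cfg$transcripts_per_gene > 1L) {
      skippable <- 2:(k - 1L)
      for (j in 2:cfg$transcripts_per_gene) {
        drop_ex <- if (length(skippable) == 1L) skippable else
          sample(skippable, 1L)
        sub <- exons[-drop_ex, , drop = FALSE]
        tid <- sprintf("T%03d_%d", i, j)
        models[[tid]] <- transcript_model(tid, gid, chrom, strand, sub,
                                          cds = sub)
      }
    }
    # one domain occurrence per protein on the canonical transcript
    plen <- sum(ex_len) %/% 3L
    dlen <- max(5L, as.integer(round(plen * 0.3)))
    dstart <- sample.int(plen - dlen + 1L, 1L)
    dom_type <- if (cfg$interaction_model == "shared_domains") {
      sprintf("D%03d", sample.int(cfg$n_domains, 1L))
    } else {
      sprintf("D%04d", i)  # private domain type per protein
    }
    domains[[i]] <- data.table(protein_id = pid, transcript_id = tid0,
                               domain_id = dom_type, aa_start = dstart,
                               aa_end = dstart + dlen - 1L)
  }
  list(models = structure(models, class = "transcript_models"),
       domains = rbindlist(domains))
}

#' Simulate a consistent interactome fixture bundle
#'
#' Generates and writes to `out_dir`: `transcripts.gtf`, `domains.tsv`,
#' one `ppi_<resource>.tsv` per resource, `truth_ddis.tsv`, `pathways.gmt`,
#' `protein2gene.tsv` and `fixture_manifest.json`. A fraction
#' `ppi_from_truth_fraction` of PPI edges connects proteins carrying a
#' planted truth DDI pair; the rest are uniformly random protein pairs. Each
#' resource observes an independent random subsample of the edges.
#'
#' @param config a `fixture_config`.
#' @param out_dir output directory (created).
#' @return a list of class `fixture_bundle`: `dir`, `files` (named paths),
#'   `config`, `truth` (the planted DDI table), `target_pathway`.
#' @export
simulate_interactome <- function(config, out_dir) {
  cfg <- if (inherits(config, "fixture_config")) config else
    do.call(fixture_config, config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)

  gen <- .sim_genome(cfg)
  dom <- gen$domains
  proteins <- dom$protein_id
  carrier <- split(dom$protein_id, dom$domain_id)

  if (cfg$interaction_model == "shared_domains") {
    types <- sort(unique(dom$domain_id))
    all_pairs <- as.data.table(t(utils::combn(types, 2L)))
    setnames(all_pairs, c("domain_a", "domain_b"))
    n_truth <- min(cfg$n_truth_ddis, nrow(all_pairs))
    truth <- all_pairs[sample.int(nrow(all_pairs), n_truth)]
    setorder(truth, domain_a, domain_b)

    # enumerate every feasible truth-generated edge (distinct proteins whose
    # domains form a planted pair), then sample without replacement; the
    # bundle is scaled down when the request exceeds feasibility so that the
    # requested truth/noise ratio is preserved
    feas <- unique(rbindlist(lapply(seq_len(nrow(truth)), function(i) {
      pa <- carrier[[truth$domain_a[i]]]; pb <- carrier[[truth$domain_b[i]]]
      if (is.null(pa) || is.null(pb)) return(NULL)
      g <- CJ(p = pa, q = pb)[p != q]
      if (nrow(g) == 0L) return(NULL)
      data.table(protein_a = pmin(g$p, g$q), protein_b = pmax(g$p, g$q))
    })))
    n_from_truth <- min(round(cfg$n_ppi_edges * cfg$ppi_from_truth_fraction),
                        nrow(feas))
    truth_edges <- feas[sample.int(nrow(feas), n_from_truth)]
    n_noise <- if (cfg$ppi_from_truth_fraction > 0) {
      round(n_from_truth * cfg$noise_edge_fraction /
              cfg$ppi_from_truth_fraction)
    } else cfg$n_ppi_edges
    all_pairs_pq <- CJ(p = proteins, q = proteins)[p < q]
    all_pairs_pq <- data.table(protein_a = all_pairs_pq$p,
                               protein_b = all_pairs_pq$q)
    pool <- all_pairs_pq[!paste(protein_a, protein_b) %in%
                           truth_edges[, paste(protein_a, protein_b)]]
    n_noise <- min(n_noise, nrow(pool))
    noise_edges <- pool[sample.int(nrow(pool), n_noise)]
    edge_set <- rbind(truth_edges, noise_edges)
    edges <- lapply(seq_len(nrow(edge_set)), function(i)
      c(edge_set$protein_a[i], edge_set$protein_b[i]))
  } else { # matched_pairs
    perm <- sample(proteins)
    n_match <- length(perm) %/% 2L
    edges <- lapply(seq_len(n_match), function(j) {
      c(perm[2L * j - 1L], perm[2L * j])
    })
    p2d <- setNames(dom$domain_id, dom$protein_id)
    truth <- rbindlist(lapply(edges, function(e) {
      cp <- canonical_pair(p2d[[e[1L]]], p2d[[e[2L]]])
      data.table(domain_a = cp$a, domain_b = cp$b)
    }))
    setorder(truth, domain_a, domain_b)
    seen <- vapply(edges, function(e) pair_key(e[1L], e[2L]), "")
    n_noise <- round(n_match * cfg$noise_edge_fraction /
                       max(cfg$ppi_from_truth_fraction, 1e-9))
    tries <- 0L
    while (cfg$noise_edge_fraction > 0 && length(edges) < n_match + n_noise &&
           tries < 1000L * (n_noise + 1L)) {
      tries <- tries + 1L
      pq <- proteins[sample.int(length(proteins), 2L)]
      key <- pair_key(pq[1L], pq[2L])
      if (key %in% seen) next
      seen <- c(seen, key)
      edges[[length(edges) + 1L]] <- pq
    }
  }
  edge_dt <- rbindlist(lapply(edges, function(e) {
    cp <- canonical_pair(e[1L], e[2L])
    data.table(protein_a = cp$a, protein_b = cp$b)
  }))

  res_names <- sprintf("R%02d", seq_len(cfg$n_resources))
  res_edges <- lapply(res_names, function(r) {
    n_keep <- max(1L, round(nrow(edge_dt) * cfg$resource_coverage))
    edge_dt[sort(sample.int(nrow(edge_dt), n_keep))]
  })
  names(res_edges) <- res_names

  gene_ids <- sprintf("G%03d", seq_len(cfg$n_genes))
  pw_ids <- sprintf("PW%03d", seq_len(cfg$n_pathways))
  pw_sets <- lapply(pw_ids, function(p)
    sort(sample(gene_ids, cfg$pathway_size)))
  names(pw_sets) <- pw_ids

  p2g <- data.table(protein_id = sprintf("P%03d", seq_len(cfg$n_genes)),
                    gene_id = gene_ids)

  files <- list()
  files$gtf <- file.path(out_dir, "transcripts.gtf")
  write_transcript_models_gtf(gen$models, files$gtf)
  files$domains <- file.path(out_dir, "domains.tsv")
  fwrite(dom, files$domains, sep = "\t", quote = FALSE)
  for (r in res_names) {
    f <- file.path(out_dir, sprintf("ppi_%s.tsv", r))
    fwrite(res_edges[[r]], f, sep = "\t", quote = FALSE)
    files[[paste0("ppi_", r)]] <- f
  }
  files$truth <- file.path(out_dir, "truth_ddis.tsv")
  fwrite(unique(truth), files$truth, sep = "\t", quote = FALSE)
  files$gmt <- file.path(out_dir, "pathways.gmt")
  writeLines(vapply(pw_ids, function(p) {
    paste(c(p, sprintf("simulated pathway %s", p), pw_sets[[p]]),
          collapse = "\t")
  }, character(1L)), files$gmt)
  files$protein2gene <- file.path(out_dir, "protein2gene.tsv")
  fwrite(p2g, files$protein2gene, sep = "\t", quote = FALSE)
  files$manifest <- file.path(out_dir, "fixture_manifest.json")
  jsonlite::write_json(list(config = unclass(cfg), resources = res_names,
                            target_pathway = pw_ids[1L]),
                       files$manifest, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)

  out <- list(dir = out_dir, files = files, config = cfg,
              truth = unique(truth), target_pathway = pw_ids[1L],
              resources = res_names)
  class(out) <- "fixture_bundle"
  out
}

#' @export
print.fixture_bundle <- function(x, ...) {
  cat(sprintf("<fixture_bundle> %s: %d genes, %d resources, model '%s'\n",
              x$dir, x$config$n_genes, x$config$n_resources,
              x$config$interaction_model))
  invisible(x)
}

#' Plant splicing events with a known enrichment signal
#'
#' Builds the joint network of the bundle (truth DDIs as templates), then
#' samples `n_events` annotated edges without replacement with sampling
#' weight `target_pathway_enrichment_factor` for edges incident to the target
#' pathway and 1 otherwise (factor 1 therefore yields a uniform edge draw:
#' the exact null of the edge-level hypergeometric test). For each sampled
#' edge one supporting domain occurrence is chosen and a significant event
#' (`|delta_psi| = 0.2`, `significance = 5e-4`) is placed on the first
#' genomic segment of its footprint. An equal number of sub-threshold decoy
#' events (`|delta_psi| = 0.02`, `significance = 0.5`) is placed on random
#' exons.
#'
#' Events are written in the `generic_bed` dialect.
#'
#' @param bundle a `fixture_bundle` from [simulate_interactome()].
#' @param target_pathway pathway id; default the bundle's target.
#' @param config a `fixture_config`; default the bundle's config.
#' @param out_file output TSV path (default `events.tsv` in the bundle dir).
#' @param seed RNG seed for the event draw; default `config$seed + 104729`
#'   (a fixed offset keeps it independent of the interactome draw).
#' @param context a precomputed [plant_context()]; pass it when planting
#'   repeatedly on one bundle to skip re-reading and rebuilding.
#' @return a list: `path`, `planted` (data.table of significant events with
#'   the intended protein/domain), `n_decoys`, `expected_edges` (edge ids the
#'   construction aimed at).
#' @export
plant_splice_events <- function(bundle, target_pathway = NULL, config = NULL,
                                out_file = NULL, seed = NULL,
                                context = NULL) {
  stopifnot(inherits(bundle, "fixture_bundle"))
  cfg <- config %||% bundle$config
  target <- target_pathway %||% bundle$target_pathway
  out_file <- out_file %||% file.path(bundle$dir, "events.tsv")
  set.seed(seed %||% (cfg$seed + 104729L))

  ctx <- context %||% plant_context(bundle)
  models <- ctx$models; dom <- ctx$dom; gsets <- ctx$gsets
  net <- ctx$network; dom_fp <- ctx$dom_fp
  if (!target %in% names(gsets$sets)) stopf("unknown target pathway '%s'", target)
  if (nrow(net$edges) == 0L) stopf("bundle has no annotated edges")
  map <- setNames(ctx$p2g$gene_id, ctx$p2g$protein_id)
  tgenes <- gsets$sets[[target]]
  dom_genes <- unique(unname(map[dom$protein_id]))
  if (!any(tgenes %in% dom_genes)) {
    stopf("target pathway '%s' has no domain-bearing genes", target)
  }
  ed <- net$edges
  incident <- (unname(map[ed$protein_a]) %in% tgenes) |
    (unname(map[ed$protein_b]) %in% tgenes)
  w <- ifelse(incident, cfg$target_pathway_enrichment_factor, 1)
  n_ev <- min(cfg$n_events, nrow(ed))
  picked <- sample.int(nrow(ed), n_ev, prob = w)

  planted <- vector("list", n_ev)
  for (i in seq_len(n_ev)) {
    e <- ed[picked[i]]
    ev_items <- net$evidence[edge_id == e$edge_id &
                               kind %in% c("ddi_experimental", "ddi_predicted")]
    it <- ev_items[sample.int(nrow(ev_items), 1L)]
    side <- sample(c("a", "b"), 1L)
    prot <- if (side == "a") it$protein_a else it$protein_b
    dtype <- if (side == "a") it$domain_a else it$domain_b
    occ <- dom_fp[protein_id == prot & domain_id == dtype][1L]
    fp <- occ$footprint[[1L]]
    if (is.null(fp) || nrow(fp) == 0L) stopf("domain occurrence without footprint")
    seg <- fp[1L, ]
    planted[[i]] <- data.table(
      chrom = occ$chrom, start0 = seg[[1L]] - 1L, end = seg[[2L]],
      gene_id = occ$gene_id, delta_psi = sample(c(-0.2, 0.2), 1L),
      strand = occ$strand, significance = 5e-4,
      protein_id = prot, domain_id = dtype, edge_id = e$edge_id)
  }
  planted <- rbindlist(planted)

  decoys <- vector("list", n_ev)
  tids <- names(models)
  for (i in seq_len(n_ev)) {
    tm <- models[[sample.int(length(tids), 1L)]]
    e <- tm$exons[sample.int(nrow(tm$exons), 1L), ]
    decoys[[i]] <- data.table(
      chrom = tm$chrom, start0 = e[[1L]] - 1L, end = e[[2L]],
      gene_id = tm$gene_id, delta_psi = sample(c(-0.02, 0.02), 1L),
      strand = tm$strand, significance = 0.5)
  }
  decoys <- rbindlist(decoys)

  bed <- rbind(planted[, .(chrom, start0, end, gene_id, delta_psi, strand,
                           significance)], decoys)
  fwrite(bed, out_file, sep = "\t", quote = FALSE, col.names = FALSE)
  list(path = out_file, planted = planted, n_decoys = nrow(decoys),
       expected_edges = sort(unique(planted$edge_id)))
}

#' Precompute the reusable context for event planting
#'
#' Reads the bundle files back through the package readers, builds the joint
#' network (truth DDIs as templates) and the domain footprints. Useful when
#' planting events repeatedly on the same bundle (e.g. null calibration).
#'
#' @param bundle a `fixture_bundle`.
#' @return a list with `models`, `dom`, `dom_fp`, `network`, `gsets`, `p2g`.
#' @export
plant_context <- function(bundle) {
  stopifnot(inherits(bundle, "fixture_bundle"))
  models <- read_transcript_models_gtf(bundle$files$gtf)
  dom <- fread(bundle$files$domains, sep = "\t")
  ppi <- rbindlist(lapply(bundle$resources, function(r) {
    read_ppi_table(bundle$files[[paste0("ppi_", r)]], r)
  }))
  truth <- fread(bundle$files$truth, sep = "\t")
  gsets <- read_gene_sets_gmt(bundle$files$gmt, "SIM")
  p2g <- fread(bundle$files$protein2gene, sep = "\t")
  net <- build_joint_network(ppi, dom, ddi_templates = truth)
  dom_fp <- add_domain_footprints(dom, models)
  list(models = models, dom = dom, dom_fp = dom_fp, network = net,
       gsets = gsets, p2g = p2g)
}
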