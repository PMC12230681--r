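# Edge-level hypergeometric pathway enrichment over rewired edges,
# Benjamini-Hochberg correction, per-pathway rewiring detail, and the
# pathway-cluster graph.

#' Edge-level hypergeometric test
#'
#' Upper-tail inclusive `P(X >= k)` for `X` hypergeometric with population
#' `N` (annotated edges in the network), `K` successes (edges incident to the
#' pathway) and `n` draws (affected edges).
#'
#' @param N,K,n,k non-negative integers with `K <= N`, `n <= N`,
#'   `k <= min(n, K)`.
#' @return the raw p-value.
#' @export
edge_level_test <- function(N, K, n, k) {
  v <- c(N = N, K = K, n = n, k = k)
  if (any(is.na(v)) || any(v < 0) || any(v != round(v))) {
    stopf("edge_level_test: N, K, n, k must be non-negative integers")
  }
  if (K > N || n > N || k > min(n, K)) {
    stopf("edge_level_test: need k <= min(n, K) and K, n <= N (got N=%d K=%d n=%d k=%d)",
          N, K, n, k)
  }
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Splicing-aware pathway enrichment
#'
#' For every pathway with `K > 0`: `k` = number of affected edges with at
#' least one endpoint gene in the pathway (an edge counts once even when both
#' endpoints are members); raw p from [edge_level_test()];
#' Benjamini-Hochberg adjustment across all tested pathways;
#' `nease_score = -log10(p_adj)`. Pathways with `K = 0` are excluded before
#' correction and reported as untestable. Results are sorted by
#' `(p_adj, pathway_id)`.
#'
#' @param network_stats a `network_stats` from [network_characteristics()],
#'   computed on the same network as `affected_edge_set`.
#' @param affected_edge_set an `affected_edge_set` from
#'   [derive_affected_edges()].
#' @param gene_sets the `gene_sets` collection used for `network_stats`.
#' @param protein_to_gene `data.table` with `protein_id`, `gene_id`.
#' @return a list of class `enrichment_results`: `results` (a `data.table`
#'   with `pathway_id`, `name`, `database`, `N`, `K`, `n`, `k`, `p_raw`,
#'   `p_adj`, `nease_score`, `contributing_genes` and a list-column
#'   `contributing` of per-gene affected-edge counts) and `untestable`
#'   (pathway ids with `K = 0`).
#' @export
enrich_pathways <- function(network_stats, affected_edge_set, gene_sets,
                            protein_to_gene) {
  stopifnot(inherits(network_stats, "network_stats"),
            inherits(affected_edge_set, "affected_edge_set"),
            inherits(gene_sets, "gene_sets"))
  if (!setequal(names(network_stats$K), names(gene_sets$sets))) {
    stopf("network_stats was not computed on this gene_sets collection")
  }
  p2g <- as.data.table(protein_to_gene)
  map <- setNames(p2g$gene_id, p2g$protein_id)
  aff <- affected_edge_set$edges
  n <- nrow(aff)
  N <- network_stats$N
  if (n > N) stopf("affected edge count exceeds network edge count")
  ga <- unname(map[aff$protein_a])
  gb <- unname(map[aff$protein_b])

  pids <- gene_sets$info$pathway_id
  K <- network_stats$K[pids]
  testable <- pids[K > 0L]
  untestable <- pids[K == 0L]

  rows <- lapply(testable, function(pid) {
    genes <- gene_sets$sets[[pid]]
    ina <- !is.na(ga) & ga %in% genes
    inb <- !is.na(gb) & gb %in% genes
    hit <- ina | inb
    k <- sum(hit)
    contrib_genes <- c(ga[ina], gb[inb])
    contrib <- if (length(contrib_genes)) {
      tab <- table(contrib_genes)
      data.table(gene = names(tab), count = as.integer(tab))[order(gene)]
    } else data.table(gene = character(), count = integer())
    list(pathway_id = pid, k = k, contrib = contrib)
  })
  kk <- vapply(rows, `[[`, integer(1L), "k")
  p_raw <- vapply(seq_along(rows), function(i) {
    edge_level_test(N, unname(K[testable[i]]), n, kk[i])
  }, numeric(1L))
  p_adj <- stats::p.adjust(p_raw, method = "BH")
  res <- data.table(
    pathway_id = testable,
    name = gene_sets$info[match(testable, pathway_id), name],
    database = gene_sets$info[match(testable, pathway_id), database],
    N = N, K = as.integer(unname(K[testable])), n = n, k = kk,
    p_raw = p_raw, p_adj = p_adj,
    nease_score = -log10(p_adj),
    contributing_genes = vapply(rows, function(r)
      paste(r$contrib$gene, collapse = ";"), character(1L))
  )
  res[, contributing := lapply(rows, `[[`, "contrib")]
  setorder(res, p_adj, pathway_id)
  out <- list(results = res[], untestable = untestable)
  class(out) <- "enrichment_results"
  out
}

#' @export
print.enrichment_results <- function(x, ...) {
  cat(sprintf("<enrichment_results> %d pathway(s) tested, %d untestable; top:\n",
              nrow(x$results), length(x$untestable)))
  print(head(x$results[, .(pathway_id, K, k, p_raw, p_adj, nease_score)], 5L))
  invisible(x)
}

#' Per-pathway rewiring detail
#'
#' One row per gene contributing at least one affected edge incident to the
#' pathway (i.e. the gene is an endpoint of an affected edge whose other or
#' own endpoint gene is a pathway member). Flags whether the gene itself
#' belongs to the pathway and lists its affected partner genes inside the
#' pathway (possibly none, for a member gene losing an edge to a non-member).
#'
#' @param network a `joint_network` (used for lost-evidence descriptions).
#' @param affected_edge_set an `affected_edge_set`.
#' @param pathway a pathway id present in `gene_sets`.
#' @param gene_sets the `gene_sets` collection.
#' @param protein_to_gene `data.table` with `protein_id`, `gene_id`.
#' @return a `data.table` with columns `pathway_id`, `gene`, `is_member`,
#'   `affected_edges`, `partners_in_pathway`, `lost_evidence`.
#' @export
pathway_detail <- function(network, affected_edge_set, pathway, gene_sets,
                           protein_to_gene) {
  stopifnot(inherits(gene_sets, "gene_sets"))
  if (!pathway %in% names(gene_sets$sets)) {
    stopf("unknown pathway '%s'", pathway)
  }
  members <- gene_sets$sets[[pathway]]
  p2g <- as.data.table(protein_to_gene)
  map <- setNames(p2g$gene_id, p2g$protein_id)
  aff <- affected_edge_set$edges
  empty <- data.table(pathway_id = character(), gene = character(),
                      is_member = logical(), affected_edges = integer(),
                      partners_in_pathway = character(),
                      lost_evidence = character())
  if (nrow(aff) == 0L) return(empty)
  ga <- unname(map[aff$protein_a]); gb <- unname(map[aff$protein_b])
  incident <- (!is.na(ga) & ga %in% members) | (!is.na(gb) & gb %in% members)
  if (!any(incident)) return(empty)
  aff <- aff[incident]
  ga <- ga[incident]; gb <- gb[incident]

  lost_desc <- vapply(seq_len(nrow(aff)), function(i) {
    ids <- affected_edge_set$lost[edge_id == aff$edge_id[i], evidence_id]
    ev <- network$evidence[ids]
    paste(vapply(seq_len(nrow(ev)), function(j) {
      e <- ev[j]
      if (e$kind %in% c("ddi_experimental", "ddi_predicted")) {
        sprintf("%s(%s-%s)", e$kind, e$domain_a, e$domain_b)
      } else if (e$kind == "dmi") {
        sprintf("dmi(%s:%d-%d)", e$motif_protein, e$motif_start, e$motif_end)
      } else {
        "residue"
      }
    }, character(1L)), collapse = "|")
  }, character(1L))

  per_gene <- rbindlist(list(
    data.table(edge = aff$edge_id, gene = ga, partner = gb, lost = lost_desc),
    data.table(edge = aff$edge_id, gene = gb, partner = ga, lost = lost_desc)
  ))
  per_gene <- per_gene[!is.na(gene)]
  # a homodimer contributes its two identical orientations once
  per_gene <- unique(per_gene)
  out <- per_gene[, .(
    affected_edges = uniqueN(edge),
    partners_in_pathway = paste(sort(unique(partner[!is.na(partner) &
                                                      partner %in% members])),
                                collapse = ";"),
    lost_evidence = paste(unique(lost), collapse = "|")
  ), by = gene]
  out[, `:=`(pathway_id = pathway, is_member = gene %in% members)]
  setcolorder(out, c("pathway_id", "gene", "is_member", "affected_edges",
                     "partners_in_pathway", "lost_evidence"))
  setorder(out, gene)
  out[]
}

#' Pathway-cluster graph over enriched pathways
#'
#' Nodes are the pathways with `p_adj <= significance_cutoff`; an undirected
#' link joins two pathways whose contributing gene sets overlap, weighted by
#' the Jaccard index of those sets (in (0, 1]).
#'
#' @param results an `enrichment_results` object.
#' @param significance_cutoff adjusted-p cutoff for node inclusion
#'   (default 0.05).
#' @return a list of class `pathway_cluster_graph`: `nodes` (a `data.table`
#'   with `pathway_id`, `p_adj`, `nease_score`, `k`) and `links`
#'   (`pathway_a`, `pathway_b`, `weight`).
#' @export
pathway_cluster_graph <- function(results, significance_cutoff = 0.05) {
  stopifnot(inherits(results, "enrichment_results"))
  res <- results$results[p_adj <= significance_cutoff]
  nodes <- res[, .(pathway_id, p_adj, nease_score, k)]
  links <- data.table(pathway_a = character(), pathway_b = character(),
                      weight = numeric())
  if (nrow(res) >= 2L) {
    gsets <- lapply(res$contributing, function(cc) cc$gene)
    names(gsets) <- res$pathway_id
    combs <- utils::combn(res$pathway_id, 2L)
    lw <- apply(combs, 2L, function(pq) {
      a <- gsets[[pq[1L]]]; b <- gsets[[pq[2L]]]
      u <- length(union(a, b))
      if (u == 0L) 0 else length(intersect(a, b)) / u
    })
    keep <- lw > 0
    if (any(keep)) {
      links <- data.table(pathway_a = combs[1L, keep],
                          pathway_b = combs[2L, keep],
                          weight = lw[keep])
      setorder(links, pathway_a, pathway_b)
    }
  }
  out <- list(nodes = nodes, links = links)
  class(out) <- "pathway_cluster_graph"
  out
}

#' @export
print.pathway_cluster_graph <- function(x, ...) {
  cat(sprintf("<pathway_cluster_graph> %d node(s), %d link(s)\n",
              nrow(x$nodes), nrow(x$links)))
  invisible(x)
}

#' Convert a pathway cluster graph to an igraph object
#'
#' @param graph a `pathway_cluster_graph`.
#' @return an undirected weighted `igraph` graph.
#' @export
cluster_graph_as_igraph <- function(graph) {
  stopifnot(inherits(graph, "pathway_cluster_graph"))
  g <- igraph::graph_from_data_frame(
    d = as.data.frame(graph$links[, .(pathway_a, pathway_b, weight)]),
    directed = FALSE,
    vertices = as.data.frame(graph$nodes))
  g
}

#' Export a pathway cluster graph as edge-list TSV and JSON node-link
#'
#' @param graph a `pathway_cluster_graph`.
#' @param path_prefix output prefix; writes `<prefix>_edges.tsv` and
#'   `<prefix>.json`.
#' @return invisibly, the written paths.
#' @export
export_cluster_graph <- function(graph, path_prefix) {
  stopifnot(inherits(graph, "pathway_cluster_graph"))
  tp <- paste0(path_prefix, "_edges.tsv")
  jp <- paste0(path_prefix, ".json")
  fwrite(graph$links, tp, sep = "\t", quote = FALSE)
  doc <- list(directed = FALSE,
              nodes = graph$nodes,
              links = graph$links)
  jsonlite::write_json(doc, jp, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(c(tsv = tp, json = jp))
}
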