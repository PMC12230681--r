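# Joint PPI/DDI network: PPI edges annotated with experimental DDI templates,
# predicted DDIs (tier-filtered), DMIs, and residue-level evidence.

#' Build the joint PPI/DDI network
#'
#' Annotates each distinct unordered PPI edge (p, q) with every evidence item
#' it can carry:
#' \itemize{
#'   \item a DDI item (a, b) iff `a` occurs on p, `b` occurs on q (or
#'     swapped) and the unordered pair (a, b) is an experimental template or
#'     a prediction passing `tier_filter`. For homodimers each unordered
#'     domain pair is counted once. A predicted DDI identical to an
#'     experimental template is stored once, as experimental.
#'   \item a DMI item iff the record's named edge exists in the PPI set;
#'   \item a residue item likewise.
#' }
#' Evidence records naming a protein absent from the PPI set (or an edge that
#' is not a PPI) are skipped with a warning and counted. Edges with no
#' evidence are kept in `unannotated_edges`.
#'
#' @param ppi_edges a `ppi_edges` table (possibly concatenated over
#'   resources); distinct unordered pairs are used.
#' @param domain_occurrences `data.table` with at least `protein_id`,
#'   `domain_id` (and usually `transcript_id`, `aa_start`, `aa_end`).
#' @param ddi_templates `data.table` with `domain_a`, `domain_b`
#'   (experimental DDIs); may be empty.
#' @param dmi_records optional `data.table`: `protein_domain`, `domain_id`,
#'   `protein_motif`, `motif_start`, `motif_end` (protein coordinates of the
#'   motif on `protein_motif`).
#' @param residue_records optional `data.table`: `protein_a`, `protein_b`,
#'   `residues_a`, `residues_b` (comma-separated protein positions on the
#'   respective endpoint).
#' @param predicted_ddis optional `data.table`: `domain_a`, `domain_b`,
#'   `tier` in gold/silver/bronze.
#' @param tier_filter character subset of `c("gold", "silver", "bronze")`;
#'   empty (default) = experimental evidence only.
#' @return a list of class `joint_network`: `proteins`, `edges`
#'   (annotated edges), `evidence`, `unannotated_edges`, `domains` (the
#'   occurrence table), `provenance`, `n_skipped_records`.
#' @export
build_joint_network <- function(ppi_edges, domain_occurrences,
                                ddi_templates = NULL, dmi_records = NULL,
                                residue_records = NULL, predicted_ddis = NULL,
                                tier_filter = character()) {
  tiers_ok <- c("gold", "silver", "bronze")
  if (length(tier_filter) && !all(tier_filter %in% tiers_ok)) {
    stopf("tier_filter must be a subset of gold/silver/bronze")
  }
  ppi <- as.data.table(ppi_edges)
  cp <- canonical_pair(ppi$protein_a, ppi$protein_b)
  ed <- unique(data.table(protein_a = cp$a, protein_b = cp$b))
  setorder(ed, protein_a, protein_b)
  ed[, edge_id := .I]
  proteins <- sort(unique(c(ed$protein_a, ed$protein_b)))

  dom <- as.data.table(domain_occurrences)
  dom_pairs <- if (nrow(dom)) unique(dom[, .(protein_id, domain_id)]) else
    data.table(protein_id = character(), domain_id = character())

  templates <- if (!is.null(ddi_templates) && nrow(as.data.table(ddi_templates))) {
    tt <- as.data.table(ddi_templates)
    cpt <- canonical_pair(tt$domain_a, tt$domain_b)
    unique(data.table(domain_a = cpt$a, domain_b = cpt$b))
  } else data.table(domain_a = character(), domain_b = character())
  template_keys <- paste(templates$domain_a, templates$domain_b, sep = "\r")

  preds <- if (!is.null(predicted_ddis) && nrow(as.data.table(predicted_ddis))) {
    pp <- as.data.table(predicted_ddis)
    if (!"tier" %in% names(pp)) stopf("predicted_ddis must carry a 'tier' column")
    cpp <- canonical_pair(pp$domain_a, pp$domain_b)
    pp <- unique(data.table(domain_a = cpp$a, domain_b = cpp$b, tier = pp$tier))
    pp <- pp[tier %in% tier_filter]
    # experimental evidence dominates: drop predictions equal to a template
    pp[!paste(domain_a, domain_b, sep = "\r") %in% template_keys]
  } else data.table(domain_a = character(), domain_b = character(),
                    tier = character())

  # candidate domain pairs per edge: dom(p) x dom(q), unordered, once per edge
  evid <- list()
  if (nrow(dom_pairs) && nrow(ed) && (nrow(templates) || nrow(preds))) {
    A <- merge(ed, dom_pairs, by.x = "protein_a", by.y = "protein_id",
               allow.cartesian = TRUE)
    setnames(A, "domain_id", "dom_a")
    B <- merge(ed[, .(edge_id, protein_b)], dom_pairs,
               by.x = "protein_b", by.y = "protein_id", allow.cartesian = TRUE)
    setnames(B, "domain_id", "dom_b")
    cand <- merge(A[, .(edge_id, protein_a, protein_b, dom_a)],
                  B[, .(edge_id, dom_b)], by = "edge_id",
                  allow.cartesian = TRUE)
    # dedup/match on the canonical (unordered) key, but keep the orientation:
    # domain_a sits on protein_a, domain_b on protein_b
    cpd <- canonical_pair(cand$dom_a, cand$dom_b)
    cand[, `:=`(key_a = cpd$a, key_b = cpd$b)]
    cand <- unique(cand, by = c("edge_id", "key_a", "key_b"))
    match_pairs <- function(pairs) {
      hit <- merge(cand,
                   setnames(copy(pairs), c("domain_a", "domain_b"),
                            c("key_a", "key_b")),
                   by = c("key_a", "key_b"))
      hit[, .(edge_id, protein_a, protein_b, domain_a = dom_a,
              domain_b = dom_b,
              tier = if ("tier" %in% names(hit)) tier else "n/a")]
    }
    if (nrow(templates)) {
      hit <- match_pairs(templates)
      if (nrow(hit)) {
        hit[, kind := "ddi_experimental"]
        evid$ddi_exp <- hit
      }
    }
    if (nrow(preds)) {
      hit <- match_pairs(preds)
      if (nrow(hit)) {
        hit[, kind := "ddi_predicted"]
        evid$ddi_pred <- hit
      }
    }
  }

  n_skipped <- 0L
  edge_lookup <- ed[, .(protein_a, protein_b, edge_id)]
  find_edge <- function(pa, pb) {
    cp2 <- canonical_pair(pa, pb)
    edge_lookup[data.table(protein_a = cp2$a, protein_b = cp2$b),
                on = c("protein_a", "protein_b"), edge_id]
  }
  if (!is.null(dmi_records) && nrow(as.data.table(dmi_records))) {
    dd <- as.data.table(dmi_records)
    known <- dd$protein_domain %in% proteins & dd$protein_motif %in% proteins
    eid <- rep(NA_integer_, nrow(dd))
    eid[known] <- find_edge(dd$protein_domain[known], dd$protein_motif[known])
    drop <- is.na(eid)
    if (any(drop)) {
      n_skipped <- n_skipped + sum(drop)
      warnf("build_joint_network: %d DMI record(s) skipped (unknown protein or edge)",
            sum(drop))
    }
    if (any(!drop)) {
      dd <- dd[!drop]
      eidk <- eid[!drop]
      dmi <- merge(data.table(edge_id = eidk, dd), ed[, .(edge_id, protein_a, protein_b)],
                   by = "edge_id")
      # orient the domain onto the endpoint that carries it
      on_a <- dmi$protein_domain == dmi$protein_a
      evid$dmi <- dmi[, .(edge_id, protein_a, protein_b,
                          domain_a = ifelse(on_a, domain_id, NA_character_),
                          domain_b = ifelse(on_a, NA_character_, domain_id),
                          kind = "dmi", tier = "n/a",
                          motif_protein = protein_motif,
                          motif_start = as.integer(motif_start),
                          motif_end = as.integer(motif_end))]
    }
  }
  if (!is.null(residue_records) && nrow(as.data.table(residue_records))) {
    rr <- as.data.table(residue_records)
    cpr <- canonical_pair(rr$protein_a, rr$protein_b)
    swap <- rr$protein_a != cpr$a
    res_a <- ifelse(swap, rr$residues_b, rr$residues_a)
    res_b <- ifelse(swap, rr$residues_a, rr$residues_b)
    rr <- data.table(protein_a = cpr$a, protein_b = cpr$b,
                     residues_a = as.character(res_a),
                     residues_b = as.character(res_b))
    known <- rr$protein_a %in% proteins & rr$protein_b %in% proteins
    eid <- rep(NA_integer_, nrow(rr))
    eid[known] <- find_edge(rr$protein_a[known], rr$protein_b[known])
    drop <- is.na(eid)
    if (any(drop)) {
      n_skipped <- n_skipped + sum(drop)
      warnf("build_joint_network: %d residue record(s) skipped (unknown protein or edge)",
            sum(drop))
    }
    if (any(!drop)) {
      evid$residue <- data.table(edge_id = eid[!drop],
                                 rr[!drop, .(protein_a, protein_b)],
                                 domain_a = NA_character_,
                                 domain_b = NA_character_,
                                 kind = "residue", tier = "n/a",
                                 residues_a = rr$residues_a[!drop],
                                 residues_b = rr$residues_b[!drop])
    }
  }

  evidence <- rbindlist(evid, use.names = TRUE, fill = TRUE)
  if (is.null(evidence) || nrow(evidence) == 0L) {
    evidence <- data.table(edge_id = integer(), protein_a = character(),
                           protein_b = character(), domain_a = character(),
                           domain_b = character(), kind = character(),
                           tier = character())
  }
  for (col in c("motif_protein", "residues_a", "residues_b")) {
    if (!col %in% names(evidence)) evidence[, (col) := NA_character_]
  }
  for (col in c("motif_start", "motif_end")) {
    if (!col %in% names(evidence)) evidence[, (col) := NA_integer_]
  }
  evidence <- unique(evidence)
  setorder(evidence, edge_id, kind, domain_a, domain_b, na.last = TRUE)
  annotated_ids <- sort(unique(evidence$edge_id))
  edges <- ed[edge_id %in% annotated_ids]
  edges <- merge(edges, evidence[, .(n_evidence = .N), by = edge_id], by = "edge_id")
  edges[, homodimer := protein_a == protein_b]
  unann <- ed[!edge_id %in% annotated_ids, .(protein_a, protein_b)]

  out <- list(proteins = proteins,
              edges = edges[],
              evidence = evidence[],
              unannotated_edges = unann[],
              domains = dom,
              provenance = list(
                resources = if ("resource" %in% names(ppi))
                  sort(unique(ppi$resource)) else character(),
                tier_filter = sort(tier_filter)),
              n_skipped_records = n_skipped)
  class(out) <- "joint_network"
  out
}

#' @export
print.joint_network <- function(x, ...) {
  cat(sprintf(paste0("<joint_network> %d proteins; %d annotated edge(s) ",
                     "(%d evidence items), %d unannotated; tier filter: %s\n"),
              length(x$proteins), nrow(x$edges), nrow(x$evidence),
              nrow(x$unannotated_edges),
              if (length(x$provenance$tier_filter))
                paste(x$provenance$tier_filter, collapse = ",") else "none"))
  invisible(x)
}

#' Isoform-level view of an annotated network
#'
#' For every annotated edge incident to the transcript's parent protein,
#' partitions the evidence into retained (every referenced domain on the
#' parent-protein side is present in `transcript_domain_set`) and lost.
#' Evidence that references no domain on the parent side (e.g. a motif on the
#' partner) is retained. An edge is classified lost iff its retained evidence
#' is empty.
#'
#' @param network a `joint_network` whose `domains` table carries
#'   `transcript_id`.
#' @param transcript_id the isoform to inspect.
#' @param transcript_domain_set character vector of domain ids retained by
#'   the isoform; must be a subset of the parent protein's domains.
#' @return a `data.table` with one row per incident annotated edge:
#'   `edge_id`, `protein_a`, `protein_b`, `partner`, `n_retained`, `n_lost`,
#'   `edge_lost`.
#' @export
isoform_view <- function(network, transcript_id, transcript_domain_set) {
  stopifnot(inherits(network, "joint_network"))
  dom <- network$domains
  if (!"transcript_id" %in% names(dom)) {
    stopf("network domain table has no transcript_id column")
  }
  tid <- transcript_id
  parent <- unique(dom[dom$transcript_id == tid, protein_id])
  if (length(parent) == 0L) stopf("unknown transcript '%s'", tid)
  parent <- parent[1L]
  parent_domains <- unique(dom[protein_id == parent, domain_id])
  extra <- setdiff(transcript_domain_set, parent_domains)
  if (length(extra)) {
    stopf("transcript_domain_set contains domain(s) not on protein '%s': %s",
          parent, paste(extra, collapse = ","))
  }
  evd <- network$evidence[protein_a == parent | protein_b == parent]
  if (nrow(evd) == 0L) {
    return(data.table(edge_id = integer(), protein_a = character(),
                      protein_b = character(), partner = character(),
                      n_retained = integer(), n_lost = integer(),
                      edge_lost = logical()))
  }
  retained <- vapply(seq_len(nrow(evd)), function(i) {
    e <- evd[i]
    refs <- character()
    if (e$protein_a == parent && !is.na(e$domain_a)) refs <- c(refs, e$domain_a)
    if (e$protein_b == parent && !is.na(e$domain_b)) refs <- c(refs, e$domain_b)
    all(refs %in% transcript_domain_set)  # TRUE when refs is empty
  }, logical(1L))
  evd[, retained := retained]
  out <- evd[, .(n_retained = sum(retained), n_lost = sum(!retained)),
             by = .(edge_id, protein_a, protein_b)]
  out[, partner := ifelse(protein_a == parent, protein_b, protein_a)]
  out[, edge_lost := n_retained == 0L]
  setorder(out, edge_id)
  out[]
}

#' Compute network characteristics (N and per-pathway K) on the fly
#'
#' `N` is the number of annotated edges; for each pathway `P`, `K(P)` is the
#' number of annotated edges with at least one endpoint mapping to a gene in
#' `P`. An edge is counted once even when both endpoints are members.
#'
#' @param network a `joint_network`.
#' @param gene_sets a `gene_sets` collection.
#' @param protein_to_gene `data.table` with `protein_id`, `gene_id`
#'   (many-to-one).
#' @return a list of class `network_stats`: `N`, `n_proteins`, `K` (named
#'   integer vector over pathway ids), `n_unmapped_proteins`, `database`.
#' @export
network_characteristics <- function(network, gene_sets, protein_to_gene) {
  stopifnot(inherits(network, "joint_network"), inherits(gene_sets, "gene_sets"))
  p2g <- as.data.table(protein_to_gene)
  if (!all(c("protein_id", "gene_id") %in% names(p2g))) {
    stopf("protein_to_gene needs columns protein_id, gene_id")
  }
  map <- setNames(p2g$gene_id, p2g$protein_id)
  unmapped <- setdiff(network$proteins, names(map))
  if (length(unmapped)) {
    warnf("network_characteristics: %d protein(s) without gene mapping excluded from K",
          length(unmapped))
  }
  ed <- network$edges
  ga <- unname(map[ed$protein_a])
  gb <- unname(map[ed$protein_b])
  K <- vapply(gene_sets$sets, function(genes) {
    sum((!is.na(ga) & ga %in% genes) | (!is.na(gb) & gb %in% genes))
  }, integer(1L))
  out <- list(N = nrow(ed), n_proteins = length(network$proteins), K = K,
              n_unmapped_proteins = length(unmapped),
              database = unique(gene_sets$info$database))
  class(out) <- "network_stats"
  out
}

#' @export
print.network_stats <- function(x, ...) {
  cat(sprintf("<network_stats> N = %d annotated edges, %d proteins, %d pathway(s)\n",
              x$N, x$n_proteins, length(x$K)))
  invisible(x)
}

#' Export a joint network as JSON and a flat edge-evidence TSV
#'
#' @param network a `joint_network`.
#' @param path_prefix output prefix; writes `<prefix>.json` and
#'   `<prefix>_evidence.tsv`.
#' @return invisibly, the two paths.
#' @export
export_network <- function(network, path_prefix) {
  stopifnot(inherits(network, "joint_network"))
  jp <- paste0(path_prefix, ".json")
  tp <- paste0(path_prefix, "_evidence.tsv")
  doc <- list(
    nodes = network$proteins,
    edges = lapply(seq_len(nrow(network$edges)), function(i) {
      e <- network$edges[i]
      ev <- network$evidence[edge_id == e$edge_id]
      list(protein_a = e$protein_a, protein_b = e$protein_b,
           evidence = lapply(seq_len(nrow(ev)), function(j) {
             it <- as.list(ev[j])
             it[!vapply(it, function(v) is.na(v) || identical(v, ""), logical(1L))]
           }))
    }),
    unannotated_edges = if (nrow(network$unannotated_edges))
      network$unannotated_edges else list(),
    provenance = network$provenance
  )
  jsonlite::write_json(doc, jp, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  fwrite(network$evidence, tp, sep = "\t", quote = FALSE)
  invisible(c(json = jp, tsv = tp))
}
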