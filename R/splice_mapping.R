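# Event filtering, protein <-> genomic coordinate lifting, exon-to-feature
# overlap mapping, and derivation of rewired (affected) interaction edges.

#' Filter differential splicing events
#'
#' Keeps events with `|delta_psi| >= dpsi_min` and `significance <= p_max`
#' (both comparisons inclusive). Both signs of `delta_psi` are retained; the
#' sign is recorded in a `direction` column (`"inclusion"` for positive,
#' `"exclusion"` for negative delta-PSI in the first condition).
#'
#' @param events a `splice_events` table from [read_splice_events()].
#' @param dpsi_min minimum absolute delta-PSI, in \[0, 1\] (default 0.05).
#' @param p_max maximum significance, in \[0, 1\] (default 0.05).
#' @return the significant subset, same class, plus a `direction` column.
#' @export
filter_events <- function(events, dpsi_min = 0.05, p_max = 0.05) {
  check_range(dpsi_min, 0, 1, "dpsi_min")
  check_range(p_max, 0, 1, "p_max")
  ev <- as.data.table(events)
  out <- ev[abs(delta_psi) >= dpsi_min & significance <= p_max]
  out[, direction := ifelse(delta_psi >= 0, "inclusion", "exclusion")]
  setattr(out, "class", c("splice_events", class(out)))
  out[]
}

.cds_check <- function(tm) {
  if (!inherits(tm, "transcript_model")) stopf("expected a transcript_model")
  if (is.null(tm$cds) || nrow(tm$cds) == 0L) {
    stopf("transcript '%s' has no CDS", tm$transcript_id)
  }
  cds_len <- sum(tm$cds[, 2L] - tm$cds[, 1L] + 1L)
  if (cds_len %% 3L != 0L) {
    stopf("transcript '%s': CDS length %d not divisible by 3; excluded from protein-coordinate lifting",
          tm$transcript_id, cds_len)
  }
  cds_len
}

#' Map a protein (amino-acid) interval to genomic intervals
#'
#' Amino acid `i` covers coding nucleotides `3i-2 .. 3i` counted 5'->3' along
#' the spliced CDS. The returned genomic intervals are maximal runs in
#' ascending genomic order and may span splice junctions. Total footprint
#' length is always `3 * (aa_end - aa_start + 1)` nucleotides.
#'
#' @param transcript_model a `transcript_model` with a CDS whose length is
#'   divisible by 3.
#' @param aa_start,aa_end 1-based inclusive protein coordinates.
#' @return 2-column integer matrix (`start`, `end`), 1-based inclusive.
#' @export
protein_to_genomic <- function(transcript_model, aa_start, aa_end) {
  tm <- transcript_model
  cds_len <- .cds_check(tm)
  plen <- cds_len %/% 3L
  if (!(aa_start >= 1L && aa_start <= aa_end)) {
    stopf("invalid aa interval (%s, %s)", aa_start, aa_end)
  }
  if (aa_end > plen) {
    stopf("aa_end %d beyond protein length %d of transcript '%s'",
          aa_end, plen, tm$transcript_id)
  }
  nt1 <- 3L * as.integer(aa_start) - 2L
  nt2 <- 3L * as.integer(aa_end)
  # CDS segments in transcription order
  segs <- tm$cds
  if (tm$strand == "-") segs <- segs[rev(seq_len(nrow(segs))), , drop = FALSE]
  out <- vector("list", nrow(segs))
  off <- 0L
  for (i in seq_len(nrow(segs))) {
    L <- segs[i, 2L] - segs[i, 1L] + 1L
    lo <- max(nt1, off + 1L); hi <- min(nt2, off + L)
    if (lo <= hi) {
      l_lo <- lo - off; l_hi <- hi - off  # 1-based within segment, 5'->3'
      if (tm$strand == "+") {
        out[[i]] <- c(segs[i, 1L] + l_lo - 1L, segs[i, 1L] + l_hi - 1L)
      } else {
        out[[i]] <- c(segs[i, 2L] - l_hi + 1L, segs[i, 2L] - l_lo + 1L)
      }
    }
    off <- off + L
  }
  iv <- do.call(rbind, out[!vapply(out, is.null, logical(1L))])
  merge_intervals(iv)
}

#' Map a genomic interval back to protein coordinates
#'
#' Returns the minimal amino-acid interval whose genomic footprint covers the
#' intersection of the input interval with the transcript's CDS, or `NULL`
#' when the interval does not overlap the CDS (e.g. entirely intronic).
#' A 1-nucleotide overlap with a codon maps to that codon.
#'
#' @param transcript_model a `transcript_model` with an in-frame CDS.
#' @param genomic_start,genomic_end 1-based inclusive genomic coordinates.
#' @return integer vector `c(aa_start, aa_end)`, or `NULL`.
#' @export
genomic_to_protein <- function(transcript_model, genomic_start, genomic_end) {
  tm <- transcript_model
  .cds_check(tm)
  if (genomic_start > genomic_end) stopf("genomic_start > genomic_end")
  segs <- tm$cds
  if (tm$strand == "-") segs <- segs[rev(seq_len(nrow(segs))), , drop = FALSE]
  off <- 0L
  pos_min <- Inf; pos_max <- -Inf
  for (i in seq_len(nrow(segs))) {
    s <- segs[i, 1L]; e <- segs[i, 2L]
    L <- e - s + 1L
    g_lo <- max(s, genomic_start); g_hi <- min(e, genomic_end)
    if (g_lo <= g_hi) {
      if (tm$strand == "+") {
        c_lo <- off + (g_lo - s + 1L); c_hi <- off + (g_hi - s + 1L)
      } else {
        c_lo <- off + (e - g_hi + 1L); c_hi <- off + (e - g_lo + 1L)
      }
      pos_min <- min(pos_min, c_lo); pos_max <- max(pos_max, c_hi)
    }
    off <- off + L
  }
  if (!is.finite(pos_min)) return(NULL)
  c(aa_start = as.integer(ceiling(pos_min / 3)),
    aa_end = as.integer(ceiling(pos_max / 3)))
}

#' Attach genomic footprints to a domain occurrence table
#'
#' Computes, once per (transcript, domain occurrence), the genomic footprint
#' of the occurrence's amino-acid interval via [protein_to_genomic()].
#' Occurrences on transcripts without an in-frame CDS, on unknown transcripts,
#' or with coordinates beyond the protein length get an empty footprint and
#' are counted in a warning.
#'
#' @param domain_occurrences `data.table` with columns `protein_id`,
#'   `transcript_id`, `domain_id`, `aa_start`, `aa_end`.
#' @param transcript_models a `transcript_models` collection.
#' @return the input with list-column `footprint` (2-column matrices) and
#'   columns `chrom`, `strand`, `gene_id` filled from the transcript model.
#' @export
add_domain_footprints <- function(domain_occurrences, transcript_models) {
  dom <- as.data.table(domain_occurrences)
  need <- c("protein_id", "transcript_id", "domain_id", "aa_start", "aa_end")
  miss <- setdiff(need, names(dom))
  if (length(miss)) stopf("domain table missing column '%s'", miss[1L])
  bad <- dom[!(aa_start >= 1L & aa_start <= aa_end), which = TRUE]
  if (length(bad)) stopf("domain occurrence row %d: invalid aa interval", bad[1L])
  n_skip <- 0L
  fps <- vector("list", nrow(dom))
  chrom_ <- character(nrow(dom)); strand_ <- character(nrow(dom))
  gene_ <- rep(NA_character_, nrow(dom))
  empty_fp <- merge_intervals(NULL)
  for (i in seq_len(nrow(dom))) {
    tm <- transcript_models[[dom$transcript_id[i]]]
    fp <- empty_fp
    if (is.null(tm)) {
      n_skip <- n_skip + 1L
      chrom_[i] <- NA_character_; strand_[i] <- NA_character_
    } else {
      chrom_[i] <- tm$chrom; strand_[i] <- tm$strand; gene_[i] <- tm$gene_id
      ok <- isTRUE(tm$cds_in_frame) &&
        dom$aa_end[i] <= sum(tm$cds[, 2L] - tm$cds[, 1L] + 1L) %/% 3L
      if (ok) {
        fp <- protein_to_genomic(tm, dom$aa_start[i], dom$aa_end[i])
      } else {
        n_skip <- n_skip + 1L
      }
    }
    fps[[i]] <- fp
  }
  if (n_skip > 0L) {
    warnf("add_domain_footprints: %d occurrence(s) without a liftable transcript (no/out-of-frame CDS or unknown transcript)",
          n_skip)
  }
  dom[, `:=`(chrom = chrom_, strand = strand_, gene_id = gene_)]
  dom[, footprint := fps]
  dom[]
}

#' Map one splicing event onto affected protein features
#'
#' A feature (domain occurrence, motif span, residue position) is affected iff
#' its genomic footprint intersects the event's exon interval by at least one
#' nucleotide on a transcript of the event's gene. The event maps through all
#' transcripts of its gene whose exon set contains an exon intersecting the
#' event, not only the canonical transcript.
#'
#' @param event a single-row `splice_events` table (or a list with the same
#'   fields).
#' @param transcript_models `transcript_models` collection.
#' @param domain_occurrences domain table with footprints
#'   (see [add_domain_footprints()]).
#' @param motif_records optional `data.table` of linear-motif spans:
#'   `protein_id`, `transcript_id`, `motif_start`, `motif_end` (protein
#'   coordinates); may be `NULL`.
#' @param residue_records optional `data.table` of interface residues:
#'   `protein_id`, `transcript_id`, `position` (protein coordinate);
#'   may be `NULL`.
#' @return a list of class `affected_features` with data.tables `domains`,
#'   `motifs`, `residues` and the logical `mapped` (FALSE when the gene has
#'   no overlapping transcript model).
#' @export
map_event_to_features <- function(event, transcript_models, domain_occurrences,
                                  motif_records = NULL, residue_records = NULL) {
  ev <- as.list(as.data.table(event)[1L])
  gid <- ev$gene_id
  tms <- Filter(function(tm) tm$gene_id == gid, unclass(transcript_models))
  # transcripts whose exon set contains an exon intersecting the event
  hit_tids <- names(Filter(function(tm) {
    tm$chrom == ev$chrom &&
      any(tm$exons[, 1L] <= ev$exon_end & tm$exons[, 2L] >= ev$exon_start)
  }, tms))
  empty_dom <- data.table(event_id = character(), gene_id = character(),
                          protein_id = character(), transcript_id = character(),
                          domain_id = character(), overlap_nt = integer())
  empty_mot <- data.table(event_id = character(), gene_id = character(),
                          protein_id = character(), transcript_id = character(),
                          motif_start = integer(), motif_end = integer(),
                          overlap_nt = integer())
  empty_res <- data.table(event_id = character(), gene_id = character(),
                          protein_id = character(), transcript_id = character(),
                          position = integer())
  out <- list(domains = empty_dom, motifs = empty_mot, residues = empty_res,
              mapped = length(hit_tids) > 0L, event_id = ev$event_id)
  class(out) <- "affected_features"
  if (length(hit_tids) == 0L) return(out)

  dom <- as.data.table(domain_occurrences)
  if (nrow(dom) && "footprint" %in% names(dom)) {
    dd <- dom[transcript_id %in% hit_tids]
    if (nrow(dd)) {
      ov <- vapply(seq_len(nrow(dd)), function(i) {
        overlap_nt_total(ev$exon_start, ev$exon_end, dd$footprint[[i]])
      }, integer(1L))
      dd <- dd[ov > 0L]
      if (nrow(dd)) {
        out$domains <- data.table(event_id = ev$event_id, gene_id = gid,
                                  protein_id = dd$protein_id,
                                  transcript_id = dd$transcript_id,
                                  domain_id = dd$domain_id,
                                  overlap_nt = ov[ov > 0L])
      }
    }
  }
  map_span <- function(rec, s_col, e_col) {
    rr <- as.data.table(rec)[transcript_id %in% hit_tids]
    if (!nrow(rr)) return(NULL)
    ov <- integer(nrow(rr))
    for (i in seq_len(nrow(rr))) {
      tm <- transcript_models[[rr$transcript_id[i]]]
      if (is.null(tm) || !isTRUE(tm$cds_in_frame)) next
      plen <- sum(tm$cds[, 2L] - tm$cds[, 1L] + 1L) %/% 3L
      if (rr[[e_col]][i] > plen) next
      fp <- protein_to_genomic(tm, rr[[s_col]][i], rr[[e_col]][i])
      ov[i] <- overlap_nt_total(ev$exon_start, ev$exon_end, fp)
    }
    rr[, overlap_nt := ov][ov > 0L]
  }
  if (!is.null(motif_records) && nrow(as.data.table(motif_records))) {
    mm <- map_span(motif_records, "motif_start", "motif_end")
    if (!is.null(mm) && nrow(mm)) {
      out$motifs <- data.table(event_id = ev$event_id, gene_id = gid,
                               protein_id = mm$protein_id,
                               transcript_id = mm$transcript_id,
                               motif_start = mm$motif_start,
                               motif_end = mm$motif_end,
                               overlap_nt = mm$overlap_nt)
    }
  }
  if (!is.null(residue_records) && nrow(as.data.table(residue_records))) {
    rr <- as.data.table(residue_records)
    rr <- rr[, .(protein_id, transcript_id, motif_start = position,
                 motif_end = position, position)]
    mm <- map_span(rr, "motif_start", "motif_end")
    if (!is.null(mm) && nrow(mm)) {
      out$residues <- data.table(event_id = ev$event_id, gene_id = gid,
                                 protein_id = mm$protein_id,
                                 transcript_id = mm$transcript_id,
                                 position = mm$position)
    }
  }
  out
}

#' Map a collection of events onto affected features
#'
#' Applies [map_event_to_features()] to every event and concatenates the
#' results.
#'
#' @inheritParams map_event_to_features
#' @param events a `splice_events` table.
#' @return a list of class `affected_features` with concatenated `domains`,
#'   `motifs`, `residues` tables and `unmapped_events` (event ids of events
#'   whose gene had no overlapping transcript model).
#' @export
map_events_to_features <- function(events, transcript_models, domain_occurrences,
                                   motif_records = NULL, residue_records = NULL) {
  ev <- as.data.table(events)
  parts <- lapply(seq_len(nrow(ev)), function(i) {
    map_event_to_features(ev[i], transcript_models, domain_occurrences,
                          motif_records, residue_records)
  })
  out <- list(
    domains = rbindlist(lapply(parts, `[[`, "domains")),
    motifs = rbindlist(lapply(parts, `[[`, "motifs")),
    residues = rbindlist(lapply(parts, `[[`, "residues")),
    unmapped_events = unlist(lapply(parts, function(p) if (!p$mapped) p$event_id else NULL))
  )
  class(out) <- "affected_features"
  out
}

#' @export
print.affected_features <- function(x, ...) {
  cat(sprintf("<affected_features> %d domain, %d motif, %d residue hits\n",
              nrow(x$domains %||% data.table()),
              nrow(x$motifs %||% data.table()),
              nrow(x$residues %||% data.table())))
  invisible(x)
}

#' Derive the set of rewired (affected) interaction edges
#'
#' An evidence item on an annotated edge is lost iff it references an affected
#' domain on the corresponding endpoint (DDI), an affected motif span (DMI),
#' or at least one affected residue position (residue evidence). An edge is
#' affected iff it loses at least one evidence item.
#'
#' @param network a `joint_network` from [build_joint_network()].
#' @param affected_features an `affected_features` collection from
#'   [map_events_to_features()].
#' @return a list of class `affected_edge_set` with `edges` (a `data.table`:
#'   `edge_id`, `protein_a`, `protein_b`, `n_lost`, `n_surviving`,
#'   `event_ids`) and `lost` (per lost evidence item: `edge_id`, evidence row
#'   id, `event_ids`).
#' @export
derive_affected_edges <- function(network, affected_features) {
  stopifnot(inherits(network, "joint_network"))
  af <- affected_features
  evd <- copy(network$evidence)
  empty <- list(edges = data.table(edge_id = integer(), protein_a = character(),
                                   protein_b = character(), n_lost = integer(),
                                   n_surviving = integer(), event_ids = character()),
                lost = data.table(edge_id = integer(), evidence_id = integer(),
                                  event_ids = character()))
  class(empty) <- "affected_edge_set"
  if (nrow(evd) == 0L) return(empty)

  adom <- unique(af$domains[, .(protein_id, domain_id, event_id)])
  amot <- unique(af$motifs[, .(protein_id, motif_start, motif_end, event_id)])
  ares <- unique(af$residues[, .(protein_id, position, event_id)])

  lost_events <- vector("list", nrow(evd))
  for (i in seq_len(nrow(evd))) {
    e <- evd[i]
    evs <- character()
    if (e$kind %in% c("ddi_experimental", "ddi_predicted")) {
      evs <- c(evs,
               adom[protein_id == e$protein_a & domain_id == e$domain_a, event_id],
               adom[protein_id == e$protein_b & domain_id == e$domain_b, event_id])
    } else if (e$kind == "dmi") {
      evs <- c(evs, amot[protein_id == e$motif_protein &
                           motif_start == e$motif_start &
                           motif_end == e$motif_end, event_id])
    } else if (e$kind == "residue") {
      pa <- as.integer(strsplit(e$residues_a %||% "", ",")[[1L]])
      pb <- as.integer(strsplit(e$residues_b %||% "", ",")[[1L]])
      evs <- c(evs,
               ares[protein_id == e$protein_a & position %in% pa, event_id],
               ares[protein_id == e$protein_b & position %in% pb, event_id])
    }
    lost_events[[i]] <- sort(unique(evs))
  }
  is_lost <- lengths(lost_events) > 0L
  if (!any(is_lost)) return(empty)

  evd[, lost := is_lost]
  lost_dt <- data.table(edge_id = evd$edge_id[is_lost],
                        evidence_id = which(is_lost),
                        event_ids = vapply(lost_events[is_lost],
                                           paste, "", collapse = ";"))
  per_edge <- evd[, .(n_lost = sum(lost), n_surviving = sum(!lost)),
                  by = edge_id][n_lost > 0L]
  ev_by_edge <- lost_dt[, .(event_ids = paste(sort(unique(unlist(
    strsplit(event_ids, ";", fixed = TRUE)))), collapse = ";")), by = edge_id]
  edges <- merge(per_edge, network$edges[, .(edge_id, protein_a, protein_b)],
                 by = "edge_id")
  edges <- merge(edges, ev_by_edge, by = "edge_id")
  setcolorder(edges, c("edge_id", "protein_a", "protein_b",
                       "n_lost", "n_surviving", "event_ids"))
  setorder(edges, edge_id)
  out <- list(edges = edges, lost = lost_dt)
  class(out) <- "affected_edge_set"
  out
}

#' @export
print.affected_edge_set <- function(x, ...) {
  cat(sprintf("<affected_edge_set> %d affected edge(s), %d lost evidence item(s)\n",
              nrow(x$edges), nrow(x$lost)))
  invisible(x)
}

#' Summarize affected features per gene and kind
#'
#' De-duplicates features hit by multiple events and counts distinct affected
#' features per gene and kind (`domain`, `dmi`, `residue`).
#'
#' @param affected_features an `affected_features` collection.
#' @return a `data.table` with columns `gene_id`, `kind`, `n_features`,
#'   sorted by `(gene_id, kind)`; zero rows for empty input.
#' @export
summarize_affected_features <- function(affected_features) {
  af <- affected_features
  parts <- list()
  if (nrow(af$domains)) {
    parts$domain <- unique(af$domains[, .(gene_id, protein_id, domain_id)])[
      , .(kind = "domain", n_features = .N), by = gene_id]
  }
  if (nrow(af$motifs)) {
    parts$dmi <- unique(af$motifs[, .(gene_id, protein_id, motif_start, motif_end)])[
      , .(kind = "dmi", n_features = .N), by = gene_id]
  }
  if (nrow(af$residues)) {
    parts$residue <- unique(af$residues[, .(gene_id, protein_id, position)])[
      , .(kind = "residue", n_features = .N), by = gene_id]
  }
  out <- rbindlist(parts, use.names = TRUE)
  if (is.null(out) || nrow(out) == 0L) {
    return(data.table(gene_id = character(), kind = character(),
                      n_features = integer()))
  }
  setorder(out, gene_id, kind)
  out[]
}

#' Flatten an affected-features collection into the exported table format
#'
#' @param affected_features an `affected_features` collection.
#' @return a `data.table` with columns `event_id`, `gene_id`,
#'   `transcript_id`, `feature_kind`, `feature_id`, `overlap_nt`.
#' @export
affected_features_table <- function(affected_features) {
  af <- affected_features
  parts <- list()
  if (nrow(af$domains)) {
    parts$dom <- af$domains[, .(event_id, gene_id, transcript_id,
                                feature_kind = "domain", feature_id = domain_id,
                                overlap_nt)]
  }
  if (nrow(af$motifs)) {
    parts$mot <- af$motifs[, .(event_id, gene_id, transcript_id,
                               feature_kind = "dmi",
                               feature_id = sprintf("%s:%d-%d", protein_id,
                                                    motif_start, motif_end),
                               overlap_nt)]
  }
  if (nrow(af$residues)) {
    parts$res <- af$residues[, .(event_id, gene_id, transcript_id,
                                 feature_kind = "residue",
                                 feature_id = sprintf("%s:%d", protein_id, position),
                                 overlap_nt = 1L)]
  }
  out <- rbindlist(parts, use.names = TRUE)
  if (is.null(out) || nrow(out) == 0L) {
    return(data.table(event_id = character(), gene_id = character(),
                      transcript_id = character(), feature_kind = character(),
                      feature_id = character(), overlap_nt = integer()))
  }
  setorder(out, event_id, gene_id, feature_kind, feature_id)
  out[]
}
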