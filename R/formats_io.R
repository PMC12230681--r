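# Readers and writers for every external file format the pipeline touches.
# All genomic coordinates are normalized to 1-based inclusive on read
# (GTF convention); rMATS exonStart_0base and BED starts get +1.

#' Read a PPI edge table
#'
#' Reads a two-column (or wider) TSV of protein-protein interactions from one
#' resource. Edges are stored unordered: endpoints are canonicalised so that
#' `protein_a <= protein_b` lexicographically, duplicate unordered pairs within
#' the resource are collapsed, and self-edges (homodimers) are flagged.
#'
#' A single header line is tolerated and sniffed: if the first token of the
#' first line matches a typical identifier-column name (`protein*`,
#' `interactor*`, `uniprot*`, `gene*`, `p_a`/`pA`) it is skipped.
#'
#' @param path path to a TSV file with at least two columns (protein_a,
#'   protein_b); extra columns are ignored.
#' @param resource_name label recorded in the `resource` column.
#' @return a `data.table` of class `ppi_edges` with columns `protein_a`,
#'   `protein_b`, `resource`, `homodimer`.
#' @export
read_ppi_table <- function(path, resource_name) {
  if (!file.exists(path)) stopf("PPI table not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    warnf("PPI table '%s' is empty", path)
    out <- data.table(protein_a = character(), protein_b = character(),
                      resource = character(), homodimer = logical())
    setattr(out, "class", c("ppi_edges", class(out)))
    return(out[])
  }
  first <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  has_header <- grepl("^(protein|interactor|uniprot|gene|p[._][ab12])",
                      tolower(first[1L]))
  body <- if (has_header) lines[-1L] else lines
  line_no <- seq_along(lines)
  if (has_header) line_no <- line_no[-1L]
  if (length(body) == 0L) {
    warnf("PPI table '%s' has a header but no rows", path)
    out <- data.table(protein_a = character(), protein_b = character(),
                      resource = character(), homodimer = logical())
    setattr(out, "class", c("ppi_edges", class(out)))
    return(out[])
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 2L)
  if (length(bad)) {
    stopf("malformed PPI row at line %d of '%s': expected >= 2 tab-separated fields",
          line_no[bad[1L]], path)
  }
  a <- trimws(vapply(fields, `[[`, "", 1L))
  b <- trimws(vapply(fields, `[[`, "", 2L))
  empty <- which(!nzchar(a) | !nzchar(b))
  if (length(empty)) {
    stopf("malformed PPI row at line %d of '%s': empty protein identifier",
          line_no[empty[1L]], path)
  }
  cp <- canonical_pair(a, b)
  dt <- data.table(protein_a = cp$a, protein_b = cp$b)
  n_in <- nrow(dt)
  dt <- unique(dt)
  n_dup <- n_in - nrow(dt)
  if (n_dup > 0L) {
    sr_log("read_ppi_table(%s): collapsed %d duplicate unordered pair(s)",
           resource_name, n_dup)
  }
  dt[, resource := resource_name]
  dt[, homodimer := protein_a == protein_b]
  setattr(dt, "class", c("ppi_edges", class(dt)))
  dt[]
}

#' Read transcript models from a GTF file
#'
#' Parses `exon` and `CDS` features (attributes `gene_id`, `transcript_id`,
#' optional `protein_id`) into one transcript model per `transcript_id`.
#' GTF coordinates are 1-based inclusive and are preserved as such. Exon and
#' CDS intervals are stored in ascending genomic order on both strands.
#'
#' Transcripts whose CDS falls outside the exon envelope are skipped with a
#' warning. Transcripts carrying a `protein_id` whose CDS length is not
#' divisible by 3 are kept (usable for exon overlap) but flagged
#' `cds_in_frame = FALSE` and excluded from protein-coordinate lifting.
#'
#' @param path path to a GTF file.
#' @return a named list of class `transcript_models`; each element is a
#'   `transcript_model` list with fields `transcript_id`, `gene_id`,
#'   `protein_id` (may be `NA`), `chrom`, `strand`, `exons`, `cds`
#'   (2-column integer matrices), `cds_in_frame`.
#' @export
read_transcript_models_gtf <- function(path) {
  if (!file.exists(path)) stopf("GTF not found: %s", path)
  gr <- rtracklayer::import(path, format = "gtf")
  mc <- S4Vectors::mcols(gr)
  keep <- mc$type %in% c("exon", "CDS")
  gr <- gr[keep]
  mc <- S4Vectors::mcols(gr)
  if (length(gr) == 0L) stopf("GTF '%s' contains no exon/CDS features", path)
  feat <- data.table(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(mc$type),
    gene_id = as.character(mc$gene_id),
    transcript_id = as.character(mc$transcript_id),
    protein_id = if ("protein_id" %in% names(mc)) as.character(mc$protein_id)
                 else NA_character_
  )
  if (anyNA(feat$transcript_id) || anyNA(feat$gene_id)) {
    stopf("GTF '%s': exon/CDS features must carry gene_id and transcript_id", path)
  }
  out <- list()
  skipped <- 0L
  for (tid in unique(feat$transcript_id)) {
    tf <- feat[transcript_id == tid]
    ex <- tf[type == "exon"][order(start)]
    cd <- tf[type == "CDS"][order(start)]
    strand_ <- ex$strand[1L] %||% cd$strand[1L]
    chrom_ <- tf$chrom[1L]
    exm <- as.matrix(ex[, .(start, end)])
    cdm <- as.matrix(cd[, .(start, end)])
    storage.mode(exm) <- "integer"; storage.mode(cdm) <- "integer"
    colnames(exm) <- colnames(cdm) <- c("start", "end")
    # every CDS interval must sit inside some exon
    if (nrow(cdm) > 0L && nrow(exm) > 0L) {
      inside <- vapply(seq_len(nrow(cdm)), function(i) {
        any(exm[, 1L] <= cdm[i, 1L] & cdm[i, 2L] <= exm[, 2L])
      }, logical(1L))
      if (!all(inside)) {
        warnf("transcript '%s': CDS outside exon envelope, transcript skipped", tid)
        skipped <- skipped + 1L
        next
      }
    }
    pid <- tf$protein_id[!is.na(tf$protein_id)][1L]
    if (length(pid) == 0L) pid <- NA_character_
    cds_len <- if (nrow(cdm)) sum(cdm[, 2L] - cdm[, 1L] + 1L) else 0L
    in_frame <- nrow(cdm) > 0L && cds_len %% 3L == 0L
    if (!is.na(pid) && nrow(cdm) > 0L && !in_frame) {
      warnf("transcript '%s' (protein '%s'): CDS length %d not divisible by 3; kept for exon overlap only",
            tid, pid, cds_len)
    }
    out[[tid]] <- structure(
      list(transcript_id = tid,
           gene_id = tf$gene_id[1L],
           protein_id = pid,
           chrom = chrom_,
           strand = tf$strand[1L],
           exons = exm,
           cds = cdm,
           cds_in_frame = in_frame),
      class = "transcript_model")
  }
  if (skipped > 0L) sr_log("read_transcript_models_gtf: skipped %d transcript(s)", skipped)
  structure(out, class = "transcript_models")
}

#' @export
print.transcript_models <- function(x, ...) {
  cat(sprintf("<transcript_models> %d transcripts, %d genes\n",
              length(x), length(unique(vapply(x, `[[`, "", "gene_id")))))
  invisible(x)
}

.splice_event_cols <- c("event_id", "gene_id", "chrom", "strand", "exon_start",
                        "exon_end", "delta_psi", "significance", "dialect")

.as_splice_events <- function(dt) {
  setcolorder(dt, .splice_event_cols)
  bad <- dt[exon_start > exon_end, which = TRUE]
  if (length(bad)) stopf("splice event row %d: exon_start > exon_end", bad[1L])
  bad <- dt[is.na(delta_psi) | delta_psi < -1 | delta_psi > 1, which = TRUE]
  if (length(bad)) stopf("splice event row %d: delta_psi outside [-1, 1]", bad[1L])
  bad <- dt[is.na(significance) | significance < 0 | significance > 1, which = TRUE]
  if (length(bad)) stopf("splice event row %d: significance outside [0, 1]", bad[1L])
  setattr(dt, "class", c("splice_events", class(dt)))
  dt[]
}

.need_cols <- function(dt, cols, dialect) {
  miss <- setdiff(cols, names(dt))
  if (length(miss)) {
    stopf("dialect '%s': missing mandatory column '%s'", dialect, miss[1L])
  }
}

#' Read differential splicing events
#'
#' Parses exon-skipping event tables from several tool dialects into a single
#' normalized representation: genomic coordinates 1-based inclusive, a signed
#' `delta_psi` in \[-1, 1\] (sign preserved as printed by the tool), and a
#' p-value-like `significance` in \[0, 1\] so that a single threshold
#' (`significance <= p_max`) covers all dialects.
#'
#' Dialects:
#' \describe{
#'   \item{rmats_se}{rMATS `SE.MATS.JC.txt`: columns `GeneID`, `chr`, `strand`,
#'     `exonStart_0base`, `exonEnd`, `PValue`, `FDR`, `IncLevelDifference`.
#'     0-based half-open starts get +1. `significance` is `PValue` by default,
#'     `FDR` when `use_fdr = TRUE`.}
#'   \item{whippet}{Whippet `.diff`: columns `Gene`, `Node`, `Coord`
#'     (`chrom:start-end`, treated as 1-based inclusive), `Strand`, `Type`,
#'     `DeltaPsi`, `Probability`. Only `Type == "CE"` (core exon) rows are
#'     consumed; `significance = 1 - Probability`.}
#'   \item{majiq}{simplified MAJIQ delta-PSI export, one row per junction:
#'     columns `gene_id`, `chrom`, `strand`, `exon_start`, `exon_end`,
#'     `E_dPSI`, `P_changing` (the posterior P(|dPSI| >= 0.2));
#'     `significance = 1 - P_changing`.}
#'   \item{generic_bed}{BED-like: `chrom`, `start` (0-based), `end`,
#'     `gene_id`, `delta_psi`, `strand`, optional `significance`
#'     (default 0 = always significant). No header.}
#' }
#'
#' @param path path to the event table.
#' @param dialect one of `"rmats_se"`, `"whippet"`, `"majiq"`, `"generic_bed"`.
#' @param condition_labels length-2 character, labels of the two compared
#'   conditions (recorded as an attribute; the sign convention is
#'   `delta_psi > 0` = higher inclusion in the first condition).
#' @param use_fdr for `rmats_se`, use the `FDR` column as significance.
#' @return a `data.table` of class `splice_events`.
#' @export
read_splice_events <- function(path, dialect,
                               condition_labels = c("A", "B"),
                               use_fdr = FALSE) {
  if (!file.exists(path)) stopf("event table not found: %s", path)
  dialects <- c("rmats_se", "whippet", "majiq", "generic_bed")
  if (!is.character(dialect) || length(dialect) != 1L || !dialect %in% dialects) {
    stopf("unknown dialect '%s' (expected one of %s)",
          paste(dialect, collapse = ","), paste(dialects, collapse = ", "))
  }
  if (dialect == "generic_bed") {
    dt <- fread(path, header = FALSE, sep = "\t", colClasses = list(character = 1L))
    if (ncol(dt) < 6L) stopf("dialect 'generic_bed': expected >= 6 columns, got %d", ncol(dt))
    ev <- data.table(
      gene_id = as.character(dt[[4L]]),
      chrom = as.character(dt[[1L]]),
      strand = as.character(dt[[6L]]),
      exon_start = as.integer(dt[[2L]]) + 1L,  # 0-based start -> 1-based
      exon_end = as.integer(dt[[3L]]),
      delta_psi = as.numeric(dt[[5L]]),
      significance = if (ncol(dt) >= 7L) as.numeric(dt[[7L]]) else 0
    )
  } else {
    dt <- fread(path, header = TRUE, sep = "\t")
    if (dialect == "rmats_se") {
      .need_cols(dt, c("GeneID", "chr", "strand", "exonStart_0base", "exonEnd",
                       "PValue", "FDR", "IncLevelDifference"), dialect)
      ev <- data.table(
        gene_id = as.character(dt$GeneID),
        chrom = as.character(dt$chr),
        strand = as.character(dt$strand),
        exon_start = as.integer(dt$exonStart_0base) + 1L,
        exon_end = as.integer(dt$exonEnd),
        delta_psi = as.numeric(dt$IncLevelDifference),
        significance = if (use_fdr) as.numeric(dt$FDR) else as.numeric(dt$PValue)
      )
    } else if (dialect == "whippet") {
      .need_cols(dt, c("Gene", "Node", "Coord", "Strand", "Type", "DeltaPsi",
                       "Probability"), dialect)
      dt <- dt[Type == "CE"]
      m <- regmatches(dt$Coord, regexec("^(.+):([0-9]+)-([0-9]+)$", dt$Coord))
      bad <- which(lengths(m) != 4L)
      if (length(bad)) stopf("dialect 'whippet': unparseable Coord '%s'", dt$Coord[bad[1L]])
      ev <- data.table(
        gene_id = as.character(dt$Gene),
        chrom = vapply(m, `[[`, "", 2L),
        strand = as.character(dt$Strand),
        exon_start = as.integer(vapply(m, `[[`, "", 3L)),
        exon_end = as.integer(vapply(m, `[[`, "", 4L)),
        delta_psi = as.numeric(dt$DeltaPsi),
        significance = 1 - as.numeric(dt$Probability)
      )
    } else { # majiq
      .need_cols(dt, c("gene_id", "chrom", "strand", "exon_start", "exon_end",
                       "E_dPSI", "P_changing"), dialect)
      ev <- data.table(
        gene_id = as.character(dt$gene_id),
        chrom = as.character(dt$chrom),
        strand = as.character(dt$strand),
        exon_start = as.integer(dt$exon_start),
        exon_end = as.integer(dt$exon_end),
        delta_psi = as.numeric(dt$E_dPSI),
        significance = 1 - as.numeric(dt$P_changing)
      )
    }
  }
  set(ev, j = "event_id", value = sprintf("%s_%05d", dialect, seq_len(nrow(ev))))
  set(ev, j = "dialect", value = rep(dialect, nrow(ev)))
  ev <- .as_splice_events(ev)
  setattr(ev, "condition_labels", condition_labels)
  ev
}

#' Read pathway gene sets (GMT)
#'
#' Standard GMT: one pathway per line, tab-separated fields
#' `name<TAB>description<TAB>gene1<TAB>gene2...`. Genes are de-duplicated
#' within a line; lines left with no genes are dropped with a warning;
#' a repeated pathway id is an error (ambiguous).
#'
#' @param path path to the GMT file.
#' @param database_label label (e.g. `"KEGG"`, `"Reactome"`) attached to
#'   every set.
#' @return a list of class `gene_sets` with elements `info` (a `data.table`
#'   with `pathway_id`, `name`, `database`, `n_genes`) and `sets` (a named
#'   list of character vectors keyed by `pathway_id`).
#' @export
read_gene_sets_gmt <- function(path, database_label) {
  if (!file.exists(path)) stopf("GMT not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  sets <- list(); nm <- character(); desc <- character()
  for (i in seq_along(lines)) {
    if (!keep[i]) next
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L) {
      stopf("GMT line %d of '%s': expected >= 3 tab-separated fields", i, path)
    }
    pid <- f[1L]
    if (pid %in% nm) stopf("GMT line %d: duplicate pathway id '%s'", i, pid)
    genes <- unique(f[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0L) {
      warnf("GMT line %d: pathway '%s' has no genes, dropped", i, pid)
      next
    }
    nm <- c(nm, pid); desc <- c(desc, f[2L])
    sets[[pid]] <- genes
  }
  info <- data.table(pathway_id = nm, name = desc,
                     database = database_label,
                     n_genes = lengths(sets)[nm])
  structure(list(info = info, sets = sets), class = "gene_sets")
}

#' @export
print.gene_sets <- function(x, ...) {
  cat(sprintf("<gene_sets> %d pathways [%s], %d distinct genes\n",
              nrow(x$info), paste(unique(x$info$database), collapse = ","),
              length(unique(unlist(x$sets)))))
  invisible(x)
}

# Expected schemas for the result tables (used by the writer and by the
# schema-enforcing reader).
.result_schemas <- list(
  enrichment = c("pathway_id", "name", "database", "N", "K", "n", "k",
                 "p_raw", "p_adj", "nease_score", "contributing_genes"),
  affected_features = c("event_id", "gene_id", "transcript_id", "feature_kind",
                        "feature_id", "overlap_nt"),
  affected_edges = c("protein_a", "protein_b", "lost_evidence",
                     "surviving_evidence", "event_ids"),
  pathway_detail = c("pathway_id", "gene", "is_member", "affected_edges",
                     "partners_in_pathway", "lost_evidence")
)

#' Write pipeline result tables
#'
#' Writes the enrichment table, flat affected-features table, affected-edges
#' table and per-pathway detail tables as TSV with a deterministic column
#' order and row sort, plus a `manifest.json` listing every file written.
#' Row sorts: enrichment by `(p_adj, pathway_id)`; affected features by
#' `(event_id, gene_id, feature_kind, feature_id)`; affected edges by
#' `(protein_a, protein_b)`; details by `gene`.
#'
#' @param tables a named list with any of `enrichment`, `affected_features`,
#'   `affected_edges` (data.tables matching the documented schemas) and
#'   `pathway_details` (a named list of detail tables keyed by pathway id).
#' @param out_dir output directory (created if missing).
#' @return (invisibly) the manifest as a list.
#' @export
write_results <- function(tables, out_dir) {
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stopf("cannot create output directory '%s'", out_dir)
  if (file.access(out_dir, mode = 2L) != 0L) stopf("output directory '%s' is not writable", out_dir)
  files <- list()
  emit <- function(dt, schema, fname, sort_cols) {
    dt <- as.data.table(dt)
    miss <- setdiff(schema, names(dt))
    if (length(miss)) stopf("table for '%s' missing column '%s'", fname, miss[1L])
    dt <- dt[, schema, with = FALSE]
    if (nrow(dt)) setorderv(dt, sort_cols)
    p <- file.path(out_dir, fname)
    fwrite(dt, p, sep = "\t", quote = FALSE)
    files[[fname]] <<- list(rows = nrow(dt), md5 = unname(tools::md5sum(p)))
  }
  if (!is.null(tables$enrichment)) {
    emit(tables$enrichment, .result_schemas$enrichment, "enrichment.tsv",
         c("p_adj", "pathway_id"))
  }
  if (!is.null(tables$affected_features)) {
    emit(tables$affected_features, .result_schemas$affected_features,
         "affected_features.tsv",
         c("event_id", "gene_id", "feature_kind", "feature_id"))
  }
  if (!is.null(tables$affected_edges)) {
    emit(tables$affected_edges, .result_schemas$affected_edges,
         "affected_edges.tsv", c("protein_a", "protein_b"))
  }
  if (!is.null(tables$pathway_details)) {
    for (pid in sort(names(tables$pathway_details))) {
      safe <- gsub("[^A-Za-z0-9._-]", "_", pid)
      emit(tables$pathway_details[[pid]], .result_schemas$pathway_detail,
           sprintf("pathway_detail_%s.tsv", safe), "gene")
    }
  }
  manifest <- list(files = files)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Read back a written result table, enforcing its schema
#'
#' Rejects files in which a mandatory column has been deleted or renamed.
#'
#' @param path path to a TSV written by [write_results()].
#' @param kind one of `"enrichment"`, `"affected_features"`,
#'   `"affected_edges"`, `"pathway_detail"`.
#' @return a `data.table`.
#' @export
read_result_table <- function(path, kind) {
  if (!kind %in% names(.result_schemas)) stopf("unknown result table kind '%s'", kind)
  if (!file.exists(path)) stopf("result table not found: %s", path)
  dt <- fread(path, sep = "\t", header = TRUE)
  schema <- .result_schemas[[kind]]
  miss <- setdiff(schema, names(dt))
  if (length(miss)) {
    stopf("result table '%s' (%s): missing mandatory column '%s'",
          path, kind, miss[1L])
  }
  dt[]
}

#' Write splice events in the generic BED-like dialect
#'
#' Inverse of `read_splice_events(..., dialect = "generic_bed")`: writes
#' `chrom, start (0-based), end, gene_id, delta_psi, strand, significance`.
#' The coordinate conversion is bijective: reading the written file yields
#' identical events (up to the regenerated `event_id`/`dialect` columns).
#'
#' @param events a `splice_events` table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_splice_events_bed <- function(events, path) {
  dt <- as.data.table(events)[, .(chrom, start = exon_start - 1L, end = exon_end,
                                  gene_id, delta_psi, strand, significance)]
  fwrite(dt, path, sep = "\t", quote = FALSE, col.names = FALSE)
  invisible(path)
}
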