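# In-memory constructors for transcript models (also used by the fixture
# generator and the test helpers).

#' Construct a transcript model
#'
#' Coordinates are 1-based inclusive. Intervals are sorted into ascending
#' genomic order and validated for non-overlap on both strands.
#'
#' @param transcript_id,gene_id identifiers.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons 2-column matrix/data.frame of exon intervals.
#' @param cds 2-column matrix/data.frame of CDS intervals (optional).
#' @param protein_id optional protein identifier.
#' @return an object of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, gene_id, chrom, strand,
                             exons, cds = NULL, protein_id = NA_character_) {
  if (!strand %in% c("+", "-")) stopf("strand must be '+' or '-'")
  norm <- function(x, what) {
    if (is.null(x)) {
      m <- matrix(integer(), ncol = 2L)
    } else {
      m <- as.matrix(x)
      if (ncol(m) != 2L) stopf("%s must have 2 columns", what)
      storage.mode(m) <- "integer"
      m <- m[order(m[, 1L]), , drop = FALSE]
      if (any(m[, 1L] > m[, 2L])) stopf("%s: start > end", what)
      if (nrow(m) > 1L && any(m[-1L, 1L] <= m[-nrow(m), 2L])) {
        stopf("%s intervals overlap", what)
      }
    }
    colnames(m) <- c("start", "end")
    m
  }
  exm <- norm(exons, "exons")
  cdm <- norm(cds, "cds")
  cds_len <- if (nrow(cdm)) sum(cdm[, 2L] - cdm[, 1L] + 1L) else 0L
  structure(
    list(transcript_id = transcript_id, gene_id = gene_id,
         protein_id = protein_id, chrom = chrom, strand = strand,
         exons = exm, cds = cdm,
         cds_in_frame = nrow(cdm) > 0L && cds_len %% 3L == 0L),
    class = "transcript_model")
}

#' Bundle transcript models into a collection
#'
#' @param models a list of `transcript_model` objects.
#' @return a named list of class `transcript_models` keyed by transcript id.
#' @export
transcript_models <- function(models) {
  stopifnot(all(vapply(models, inherits, logical(1L), "transcript_model")))
  names(models) <- vapply(models, `[[`, "", "transcript_id")
  structure(models, class = "transcript_models")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s (%s, %s%s): %d exon(s), %d CDS segment(s)\n",
              x$transcript_id, x$gene_id, x$chrom, x$strand,
              nrow(x$exons), nrow(x$cds)))
  invisible(x)
}

#' Write transcript models as GTF
#'
#' Emits `exon` and `CDS` features with `gene_id`, `transcript_id` and (when
#' present) `protein_id` attributes, 1-based inclusive.
#'
#' @param models a `transcript_models` collection.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_transcript_models_gtf <- function(models, path) {
  lines <- character()
  for (tm in models) {
    attrs <- sprintf('gene_id "%s"; transcript_id "%s";',
                     tm$gene_id, tm$transcript_id)
    if (!is.na(tm$protein_id)) {
      attrs <- paste0(attrs, sprintf(' protein_id "%s";', tm$protein_id))
    }
    for (i in seq_len(nrow(tm$exons))) {
      lines <- c(lines, paste(tm$chrom, "sim", "exon", tm$exons[i, 1L],
                              tm$exons[i, 2L], ".", tm$strand, ".", attrs,
                              sep = "\t"))
    }
    for (i in seq_len(nrow(tm$cds))) {
      lines <- c(lines, paste(tm$chrom, "sim", "CDS", tm$cds[i, 1L],
                              tm$cds[i, 2L], ".", tm$strand, "0", attrs,
                              sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
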