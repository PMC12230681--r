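test_that("read_ppi_table de-duplicates, flags homodimers, sniffs headers", {
  p <- write_tsv_lines(c("p1\tp2", "p2\tp1", "p1\tp3"))
  ed <- suppressMessages(read_ppi_table(p, "R1"))
  expect_equal(nrow(ed), 2L)
  expect_true(all(ed$protein_a <= ed$protein_b))

  p <- write_tsv_lines("p1\tp1")
  ed <- read_ppi_table(p, "R1")
  expect_equal(nrow(ed), 1L)
  expect_true(ed$homodimer)

  p <- write_tsv_lines(c("proteinA\tproteinB", "p1\tp2"))
  ed <- read_ppi_table(p, "R1")
  expect_equal(nrow(ed), 1L)
  expect_equal(ed$protein_a, "p1")

  # reading twice is idempotent
  p <- write_tsv_lines(c("p1\tp2", "p3\tp1"))
  e1 <- read_ppi_table(p, "R1"); e2 <- read_ppi_table(p, "R1")
  expect_identical(as.data.frame(e1), as.data.frame(e2))
})

test_that("read_ppi_table errors carry line numbers; empty file warns", {
  p <- write_tsv_lines(c("p1\tp2", "lonely"))
  expect_error(read_ppi_table(p, "R1"), "line 2")
  p <- write_tsv_lines(character())
  expect_warning(ed <- read_ppi_table(p, "R1"), "empty")
  expect_equal(nrow(ed), 0L)
})

test_that("splice event dialects normalize coordinates and significance", {
  # rMATS: 0-based half-open start gets +1; PValue is the default significance
  p <- write_tsv_lines(c(
    paste("GeneID", "geneSymbol", "chr", "strand", "exonStart_0base",
          "exonEnd", "PValue", "FDR", "IncLevelDifference", sep = "\t"),
    paste("g1", "G1", "chr1", "+", "100", "160", "0.01", "0.04", "0.25", sep = "\t")))
  ev <- read_splice_events(p, "rmats_se")
  expect_equal(ev$exon_start, 101L)
  expect_equal(ev$exon_end, 160L)
  expect_equal(ev$significance, 0.01)
  ev <- read_splice_events(p, "rmats_se", use_fdr = TRUE)
  expect_equal(ev$significance, 0.04)

  # Whippet: only CE rows; significance = 1 - Probability
  p <- write_tsv_lines(c(
    paste("Gene", "Node", "Coord", "Strand", "Type", "DeltaPsi", "Probability", sep = "\t"),
    paste("g1", "2", "chr1:200-260", "+", "CE", "0.3", "0.98", sep = "\t"),
    paste("g1", "3", "chr1:300-360", "+", "AA", "0.3", "0.99", sep = "\t"),
    paste("g2", "4", "chr2:500-520", "-", "CE", "-0.15", "0.5", sep = "\t")))
  ev <- read_splice_events(p, "whippet")
  expect_equal(nrow(ev), 2L)  # AA row dropped
  expect_equal(ev$significance[1L], 1 - 0.98)
  expect_equal(ev$exon_start[1L], 200L)
  expect_equal(ev$delta_psi[2L], -0.15)

  # MAJIQ-style: significance = 1 - P(changing)
  p <- write_tsv_lines(c(
    paste("gene_id", "chrom", "strand", "exon_start", "exon_end",
          "E_dPSI", "P_changing", sep = "\t"),
    paste("g1", "chr1", "+", "150", "210", "-0.4", "0.95", sep = "\t")))
  ev <- read_splice_events(p, "majiq")
  expect_equal(ev$significance, 1 - 0.95, tolerance = 1e-12)

  # generic BED: 0-based start; significance optional
  p <- write_tsv_lines("chr1\t100\t160\tgeneX\t0.2\t+")
  ev <- read_splice_events(p, "generic_bed")
  expect_equal(ev$exon_start, 101L)
  expect_equal(ev$delta_psi, 0.2)
  expect_equal(ev$significance, 0)
})

test_that("splice event readers reject bad dialects, columns and values", {
  p <- write_tsv_lines("chr1\t100\t160\tg\t0.2\t+")
  expect_error(read_splice_events(p, "nope"), "unknown dialect")
  p <- write_tsv_lines(c("GeneID\tchr\tstrand", "g1\tchr1\t+"))
  expect_error(read_splice_events(p, "rmats_se"), "exonStart_0base")
  p <- write_tsv_lines("chr1\t100\t160\tg\t1.7\t+")
  expect_error(read_splice_events(p, "generic_bed"), "delta_psi")
  p <- write_tsv_lines("chr1\t200\t160\tg\t0.2\t+")
  expect_error(read_splice_events(p, "generic_bed"), "exon_start")
})

test_that("generic_bed round trip is bijective", {
  p <- write_tsv_lines(c("chr1\t100\t160\tgX\t0.2\t+\t0.01",
                         "chr2\t5\t40\tgY\t-0.5\t-\t0.2"))
  ev <- read_splice_events(p, "generic_bed")
  out <- tempfile(fileext = ".bed")
  write_splice_events_bed(ev, out)
  ev2 <- read_splice_events(out, "generic_bed")
  cols <- c("gene_id", "chrom", "strand", "exon_start", "exon_end",
            "delta_psi", "significance")
  expect_identical(as.data.frame(ev[, cols, with = FALSE]),
                   as.data.frame(ev2[, cols, with = FALSE]))
})

test_that("GMT reader parses, de-duplicates and rejects ambiguity", {
  p <- write_tsv_lines(c("PW1\tdesc\tg1\tg2", "PW2\tdesc2\tg1\tg1"))
  gs <- read_gene_sets_gmt(p, "KEGG")
  expect_equal(length(gs$sets$PW1), 2L)
  expect_equal(length(gs$sets$PW2), 1L)  # duplicate gene collapsed
  expect_equal(unique(gs$info$database), "KEGG")

  p <- write_tsv_lines(c("PW1\tdesc\tg1", "PW1\tother\tg2"))
  expect_error(read_gene_sets_gmt(p, "X"), "duplicate pathway")
  p <- write_tsv_lines("PW1\tdesc")
  expect_error(read_gene_sets_gmt(p, "X"), "line 1")
  p <- write_tsv_lines(c("PW1\tdesc\t\t", "PW2\tdesc\tg1"))
  expect_warning(gs <- read_gene_sets_gmt(p, "X"), "no genes")
  expect_equal(names(gs$sets), "PW2")
})

test_that("GTF reader preserves coordinates, strand order, envelope checks", {
  g <- c(
    'chr1\tsim\texon\t101\t160\t.\t+\t.\tgene_id "g1"; transcript_id "t1"; protein_id "p1";',
    'chr1\tsim\texon\t201\t230\t.\t+\t.\tgene_id "g1"; transcript_id "t1"; protein_id "p1";',
    'chr1\tsim\tCDS\t101\t160\t.\t+\t0\tgene_id "g1"; transcript_id "t1"; protein_id "p1";',
    'chr1\tsim\tCDS\t201\t230\t.\t+\t0\tgene_id "g1"; transcript_id "t1"; protein_id "p1";',
    'chr1\tsim\texon\t501\t530\t.\t-\t.\tgene_id "g2"; transcript_id "t2";',
    'chr1\tsim\texon\t601\t660\t.\t-\t.\tgene_id "g2"; transcript_id "t2";')
  p <- write_tsv_lines(g, tempfile(fileext = ".gtf"))
  tms <- read_transcript_models_gtf(p)
  expect_equal(sum(tms$t1$cds[, 2] - tms$t1$cds[, 1] + 1), 90)
  expect_true(tms$t1$cds_in_frame)
  # minus strand exons stored ascending
  expect_equal(tms$t2$exons[, 1], c(501L, 601L))
  expect_equal(tms$t2$strand, "-")
  expect_equal(nrow(tms$t2$cds), 0L)

  # CDS outside the exon envelope: transcript skipped with a warning
  g2 <- c(
    'chr1\tsim\texon\t101\t160\t.\t+\t.\tgene_id "g3"; transcript_id "t3";',
    'chr1\tsim\tCDS\t150\t190\t.\t+\t0\tgene_id "g3"; transcript_id "t3";')
  p <- write_tsv_lines(g2, tempfile(fileext = ".gtf"))
  expect_warning(tms <- read_transcript_models_gtf(p), "envelope")
  expect_false("t3" %in% names(tms))

  # out-of-frame CDS with a protein id: kept but flagged
  g3 <- c(
    'chr1\tsim\texon\t101\t160\t.\t+\t.\tgene_id "g4"; transcript_id "t4"; protein_id "p4";',
    'chr1\tsim\tCDS\t101\t156\t.\t+\t0\tgene_id "g4"; transcript_id "t4"; protein_id "p4";')
  p <- write_tsv_lines(g3, tempfile(fileext = ".gtf"))
  expect_warning(tms <- read_transcript_models_gtf(p), "divisible by 3")
  expect_true("t4" %in% names(tms))
  expect_false(tms$t4$cds_in_frame)
})

test_that("write_results emits deterministic tables and a manifest; readers enforce schema", {
  enr <- data.table(pathway_id = c("PW2", "PW1"), name = c("b", "a"),
                    database = "X", N = 10L, K = c(3L, 4L), n = 5L,
                    k = c(1L, 2L), p_raw = c(0.5, 0.5), p_adj = c(0.5, 0.5),
                    nease_score = -log10(0.5),
                    contributing_genes = c("g1", "g2"))
  d <- tempfile("out")
  man <- write_results(list(enrichment = enr), d)
  expect_true(file.exists(file.path(d, "enrichment.tsv")))
  expect_true(file.exists(file.path(d, "manifest.json")))
  back <- read_result_table(file.path(d, "enrichment.tsv"), "enrichment")
  # tie on p_adj broken by pathway_id
  expect_equal(back$pathway_id, c("PW1", "PW2"))
  expect_equal(man$files[["enrichment.tsv"]]$rows, 2L)

  # round trip preserves content
  expect_equal(sort(back$contributing_genes), sort(enr$contributing_genes))

  # schema enforcement: a deleted column is rejected
  mut <- back[, !"p_adj"]
  mp <- tempfile(fileext = ".tsv")
  fwrite(mut, mp, sep = "\t")
  expect_error(read_result_table(mp, "enrichment"), "p_adj")

  # empty tables give header-only files that read back empty
  d2 <- tempfile("out")
  write_results(list(enrichment = enr[0L]), d2)
  empty <- read_result_table(file.path(d2, "enrichment.tsv"), "enrichment")
  expect_equal(nrow(empty), 0L)
})
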