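two_exon_plus <- function() {
  transcript_model("t1", "g1", "chr1", "+", rbind(c(101L, 160L), c(201L, 230L)),
                   cds = rbind(c(101L, 160L), c(201L, 230L)))
}

test_that("filter_events applies inclusive thresholds and keeps both signs", {
  ev <- data.table(event_id = sprintf("e%d", 1:4), gene_id = "g",
                   chrom = "chr1", strand = "+",
                   exon_start = 1L, exon_end = 10L,
                   delta_psi = c(0.2, -0.2, 0.1, 0.04),
                   significance = c(0.01, 0.01, 0.05, 0.01),
                   dialect = "generic_bed")
  out <- filter_events(ev, dpsi_min = 0.1, p_max = 0.05)
  expect_equal(out$event_id, c("e1", "e2", "e3"))  # boundary kept (inclusive)
  expect_equal(out$direction, c("inclusion", "exclusion", "inclusion"))
  expect_equal(nrow(filter_events(ev, 0.5, 0.0001)), 0L)
})

test_that("protein_to_genomic maps plus, minus and junction-spanning intervals", {
  tm <- two_exon_plus()
  expect_equal(unname(protein_to_genomic(tm, 1, 2)),
               unname(rbind(c(101L, 106L))))
  # aa 20-21 covers coding nt 58..63: spans the splice junction
  expect_equal(unname(protein_to_genomic(tm, 20, 21)),
               unname(rbind(c(158L, 160L), c(201L, 203L))))
  tmm <- transcript_model("t2", "g1", "chr1", "-",
                          rbind(c(101L, 160L), c(201L, 230L)),
                          cds = rbind(c(101L, 160L), c(201L, 230L)))
  expect_equal(unname(protein_to_genomic(tmm, 1, 1)),
               unname(rbind(c(228L, 230L))))
  expect_error(protein_to_genomic(tm, 1, 31), "beyond protein length")
  no_cds <- transcript_model("t3", "g1", "chr1", "+", rbind(c(1L, 30L)))
  expect_error(protein_to_genomic(no_cds, 1, 1), "no CDS")
})

test_that("genomic_to_protein inverts protein_to_genomic; 1-nt overlap maps to its codon", {
  tm <- two_exon_plus()
  fp <- protein_to_genomic(tm, 5, 10)
  expect_equal(unname(genomic_to_protein(tm, fp[1, 1], fp[nrow(fp), 2])),
               c(5L, 10L))
  # entirely intronic
  expect_null(genomic_to_protein(tm, 170, 180))
  # 1 nt of codon 7 (coding nt 19..21 -> genomic 119..121)
  expect_equal(unname(genomic_to_protein(tm, 119, 119)), c(7L, 7L))
})

test_that("coordinate mapping properties hold on randomized transcript models", {
  set.seed(99)
  for (i in 1:200) {
    tm <- random_transcript_model(sprintf("t%d", i))
    plen <- sum(tm$cds[, 2] - tm$cds[, 1] + 1) %/% 3L
    a <- sample.int(plen, 1L)
    b <- if (a == plen) plen else sample(a:plen, 1L)
    fp <- protein_to_genomic(tm, a, b)
    # footprint length is exactly 3x the aa span
    expect_equal(sum(fp[, 2] - fp[, 1] + 1L), 3L * (b - a + 1L))
    # positions agree with one-by-one enumeration
    expect_identical(positions_of(fp),
                     oracle_coding_positions(tm, 3L * a - 2L, 3L * b))
    # round trip is the identity
    g <- range(positions_of(fp))
    expect_equal(unname(genomic_to_protein(tm, g[1], g[2])), c(a, b))
    # additivity: consecutive aa intervals partition the merged footprint
    if (b > a) {
      mid <- if (a == b - 1L) a else sample(a:(b - 1L), 1L)
      left <- protein_to_genomic(tm, a, mid)
      right <- protein_to_genomic(tm, mid + 1L, b)
      expect_length(intersect(positions_of(left), positions_of(right)), 0L)
      expect_identical(sort(c(positions_of(left), positions_of(right))),
                       positions_of(fp))
    }
  }
})

test_that("map_event_to_features uses >=1 nt genomic intersection", {
  tm <- two_exon_plus()
  models <- transcript_models(list(tm))
  dom <- data.table(protein_id = "p1", transcript_id = "t1", domain_id = "A",
                    aa_start = 1L, aa_end = 30L)  # footprint = both exons
  dom_fp <- add_domain_footprints(dom, models)
  mk_event <- function(s, e) data.table(
    event_id = "ev1", gene_id = "g1", chrom = "chr1", strand = "+",
    exon_start = s, exon_end = e, delta_psi = 0.5, significance = 0.01,
    dialect = "generic_bed")

  af <- map_event_to_features(mk_event(150L, 160L), models, dom_fp)
  expect_equal(af$domains$domain_id, "A")
  expect_equal(af$domains$overlap_nt, 11L)
  # adjacency is not overlap
  af <- map_event_to_features(mk_event(161L, 200L), models, dom_fp)
  expect_equal(nrow(af$domains), 0L)
  # interval inside the intron between the two footprint segments
  af <- map_event_to_features(mk_event(170L, 180L), models, dom_fp)
  expect_equal(nrow(af$domains), 0L)
  # unknown gene: unmapped
  ev <- mk_event(150L, 160L); ev$gene_id <- "gX"
  af <- map_event_to_features(ev, models, dom_fp)
  expect_false(af$mapped)
})

test_that("motif spans and residue positions are mapped like domains", {
  tm <- two_exon_plus()
  models <- transcript_models(list(tm))
  dom_fp <- add_domain_footprints(
    data.table(protein_id = "p1", transcript_id = "t1", domain_id = "A",
               aa_start = 1L, aa_end = 2L), models)
  motifs <- data.table(protein_id = "p1", transcript_id = "t1",
                       motif_start = 20L, motif_end = 21L)
  residues <- data.table(protein_id = "p1", transcript_id = "t1",
                         position = c(1L, 25L))
  ev <- data.table(event_id = "ev1", gene_id = "g1", chrom = "chr1",
                   strand = "+", exon_start = 201L, exon_end = 230L,
                   delta_psi = 0.5, significance = 0.01, dialect = "x")
  af <- map_event_to_features(ev, models, dom_fp, motifs, residues)
  expect_equal(nrow(af$domains), 0L)      # aa 1-2 sits in exon 1
  expect_equal(nrow(af$motifs), 1L)       # aa 20-21 spans into exon 2
  expect_equal(af$residues$position, 25L) # aa 25 is in exon 2; aa 1 is not
})

test_that("derive_affected_edges matches the brute-force per-evidence scan", {
  for (s in 1:30) {
    set.seed(s)
    rn <- random_network(n_edges = 50L)
    occ <- rn$domains
    hit <- occ[sample.int(nrow(occ), max(1L, nrow(occ) %/% 4L)),
               .(protein_id, domain_id)]
    hit[, event_id := sprintf("ev%d", .I)]
    aff <- derive_affected_edges(rn$network, as_affected_features(copy(hit)))
    orc <- oracle_affected_edges(rn$network, hit)
    expect_equal(nrow(aff$edges), nrow(orc))
    if (nrow(orc)) {
      m <- merge(aff$edges, orc, by = c("edge_id", "protein_a", "protein_b"))
      expect_equal(nrow(m), nrow(orc))
      expect_equal(m$n_lost.x, m$n_lost.y)
      expect_equal(m$n_surviving.x, m$n_surviving.y)
    }
  }
})

test_that("derive_affected_edges handles partial loss and empty input", {
  dom <- data.table(protein_id = c("p1", "p1", "p2", "p2"),
                    transcript_id = c("t1", "t1", "t2", "t2"),
                    domain_id = c("A", "C", "B", "D"),
                    aa_start = 1L, aa_end = 10L)
  tmpl <- data.table(domain_a = c("A", "C"), domain_b = c("B", "D"))
  net <- build_joint_network(toy_ppi(list(c("p1", "p2"))), dom,
                             ddi_templates = tmpl)
  expect_equal(nrow(net$evidence), 2L)
  # only A affected: edge survives with 1 lost, 1 surviving item
  aff <- derive_affected_edges(net, as_affected_features(
    data.table(protein_id = "p1", domain_id = "A", event_id = "e1")))
  expect_equal(aff$edges$n_lost, 1L)
  expect_equal(aff$edges$n_surviving, 1L)
  expect_equal(aff$edges$event_ids, "e1")
  # nothing affected: empty set
  aff <- derive_affected_edges(net, as_affected_features(
    data.table(protein_id = character(), domain_id = character(),
               event_id = character())))
  expect_equal(nrow(aff$edges), 0L)
})

test_that("affected edge set is monotone in the event list", {
  set.seed(4)
  rn <- random_network(n_edges = 40L)
  occ <- unique(rn$domains[, .(protein_id, domain_id)])
  h1 <- occ[1:3][, event_id := sprintf("e%d", .I)]
  h2 <- occ[1:6][, event_id := sprintf("e%d", .I)]
  a1 <- derive_affected_edges(rn$network, as_affected_features(copy(h1)))
  a2 <- derive_affected_edges(rn$network, as_affected_features(copy(h2)))
  expect_true(all(a1$edges$edge_id %in% a2$edges$edge_id))
})

test_that("summarize_affected_features de-duplicates per gene and kind", {
  dom_hits <- data.table(
    event_id = c("e1", "e2", "e3", "e4"),
    gene_id = c("g1", "g1", "g1", "g2"),
    protein_id = c("p1", "p1", "p1", "p2"),
    transcript_id = "t",
    domain_id = c("A", "A", "B", "C"),  # A hit by two events: counted once
    overlap_nt = 5L)
  af <- as_affected_features(data.table())
  af$domains <- dom_hits
  out <- summarize_affected_features(af)
  expect_equal(out[gene_id == "g1" & kind == "domain", n_features], 2L)
  expect_equal(out[gene_id == "g2" & kind == "domain", n_features], 1L)
  expect_equal(nrow(summarize_affected_features(as_affected_features(
    data.table(protein_id = character(), domain_id = character(),
               event_id = character())))), 0L)
})
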