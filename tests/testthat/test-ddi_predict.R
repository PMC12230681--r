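test_that("resource index counts n and m correctly", {
  dom <- data.table(protein_id = c("p1", "q1", "q2"),
                    transcript_id = c("t1", "t2", "t3"),
                    domain_id = c("A", "B", "B"),
                    aa_start = 1L, aa_end = 5L)
  idx <- build_resource_index(toy_ppi(list(c("p1", "q1"))), dom)
  expect_equal(idx$pair_counts[domain_a == "A" & domain_b == "B", n], 1L)
  expect_equal(idx$domain_counts[domain_id == "A", m], 1L)
  expect_equal(idx$domain_counts[domain_id == "B", m], 1L)

  # two edges both supporting (A, B): n = 2, m(A) = 2, m(B) = 2
  idx <- build_resource_index(toy_ppi(list(c("p1", "q1"), c("p1", "q2"))), dom)
  expect_equal(idx$pair_counts[domain_a == "A" & domain_b == "B", n], 2L)
  expect_equal(idx$domain_counts[domain_id == "A", m], 2L)
  expect_equal(idx$domain_counts[domain_id == "B", m], 2L)

  # homodimer: self-pair counted once
  dom1 <- data.table(protein_id = "p1", transcript_id = "t1",
                     domain_id = "A", aa_start = 1L, aa_end = 5L)
  idx <- build_resource_index(toy_ppi(list(c("p1", "p1"))), dom1)
  expect_equal(idx$pair_counts[domain_a == "A" & domain_b == "A", n], 1L)
  expect_equal(idx$domain_counts[domain_id == "A", m], 1L)
})

test_that("pair score matches the cosine formula and its bounds", {
  dom <- data.table(protein_id = c("p1", "p2", "q1"),
                    transcript_id = c("t1", "t2", "t3"),
                    domain_id = c("A", "A", "B"),
                    aa_start = 1L, aa_end = 5L)
  # (p1,q1) supports (A,B); (p1,p2) gives m(A)=2 via an (A,A) pair edge
  idx <- build_resource_index(toy_ppi(list(c("p1", "q1"), c("p1", "p2"))), dom)
  # n(A,B)=1, m(A)=2, m(B)=1 -> 1/sqrt(2)
  expect_equal(resource_pair_score(idx, "A", "B"), 1 / sqrt(2), tolerance = 1e-12)
  expect_equal(resource_pair_score(idx, "B", "A"), 1 / sqrt(2), tolerance = 1e-12)
  # never co-occurring pair scores 0
  expect_equal(resource_pair_score(idx, "A", "Z"), 0)
  # pair occurring in every possible edge scores 1
  idx2 <- build_resource_index(toy_ppi(list(c("p1", "q1"))), dom)
  expect_equal(resource_pair_score(idx2, "A", "B"), 1)
})

test_that("combined_score is a weighted mean, scale invariant", {
  s <- c(R1 = 0.5, R2 = 0.1)
  expect_equal(combined_score(c(R1 = 1, R2 = 1), s), 0.3)
  expect_equal(combined_score(c(R1 = 10, R2 = 10), s), 0.3)
  expect_equal(combined_score(c(R1 = 99, R2 = 1), c(R1 = 1.0, R2 = 0.0)), 0.99)
  # missing resource in scores contributes 0
  expect_equal(combined_score(c(R1 = 1, R2 = 1), c(R1 = 0.5)), 0.25)
  expect_error(combined_score(numeric(), c(R1 = 1)), "empty")
})

test_that("score_all_candidates counts support and is symmetric", {
  dom <- data.table(protein_id = c("p1", "q1"), transcript_id = c("t1", "t2"),
                    domain_id = c("A", "B"), aa_start = 1L, aa_end = 5L)
  e1 <- toy_ppi(list(c("p1", "q1")), "R1")
  e2 <- toy_ppi(list(c("q1", "p1")), "R2")  # endpoint-swapped input
  e3 <- toy_ppi(list(c("p1", "p1")), "R3")  # no (A,B) support here
  idx <- list(R1 = build_resource_index(e1, dom),
              R2 = build_resource_index(e2, dom),
              R3 = build_resource_index(e3, dom))
  sc <- score_all_candidates(idx)
  ab <- sc[domain_a == "A" & domain_b == "B"]
  expect_equal(ab$n_supporting_resources, 2L)
  expect_equal(ab$s_R1, ab$s_R2)  # swap symmetry
  expect_true(all(sc$S >= 0 & sc$S <= 1))
  expect_true(all(sc$S > 0))
})

test_that("calibration maximizes F1 over observed thresholds", {
  rec <- data.table(domain_a = c("A", "C", "E"), domain_b = c("B", "D", "F"),
                    S = c(0.9, 0.8, 0.2), n_supporting_resources = 1L)
  truth <- data.table(domain_a = c("A", "C"), domain_b = c("B", "D"))
  cal <- calibrate_threshold(rec, truth)
  expect_equal(cal$threshold, 0.8)
  expect_equal(cal$f1, 1.0)
  # exhaustive check of the full curve against the brute-force oracle
  orc <- oracle_calibrate(rec$S, c(TRUE, TRUE, FALSE))
  expect_equal(cal$threshold, orc$threshold)
  expect_equal(cal$f1, orc$f1)
  expect_true(all(cal$curve$f1 <= cal$f1 + 1e-12))

  # all records true: t = min score, F1 = 1
  cal <- calibrate_threshold(rec, rbind(truth,
    data.table(domain_a = "E", domain_b = "F")))
  expect_equal(cal$threshold, 0.2)
  expect_equal(cal$f1, 1.0)

  # disjoint truth: uncalibratable
  expect_error(calibrate_threshold(rec, data.table(domain_a = "X",
                                                   domain_b = "Y")),
               "uncalibratable")
})

test_that("calibration agrees with the oracle on random score sets", {
  for (s in 1:20) {
    set.seed(s)
    n <- sample(5:40, 1L)
    rec <- data.table(domain_a = sprintf("a%02d", 1:n),
                      domain_b = sprintf("b%02d", 1:n),
                      S = round(runif(n), 2), n_supporting_resources = 1L)
    truth_idx <- sample.int(n, max(1L, n %/% 3L))
    truth <- rec[truth_idx, .(domain_a, domain_b)]
    cal <- calibrate_threshold(rec, truth)
    orc <- oracle_calibrate(rec$S, seq_len(n) %in% truth_idx)
    expect_equal(cal$f1, orc$f1, tolerance = 1e-12)
    expect_equal(cal$threshold, orc$threshold)
  }
})

test_that("confidence tiers follow the stated rule", {
  rec <- data.table(domain_a = c("A", "C", "E", "G"),
                    domain_b = c("B", "D", "F", "H"),
                    S = c(0.9, 0.6, 0.3, 0.1),
                    n_supporting_resources = c(3L, 1L, 2L, 1L))
  out <- assign_confidence(rec, 0.5)
  expect_equal(out$tier, c("gold", "silver", "bronze", "below"))
})

test_that("random_weight_search is deterministic and scale-invariant for one resource", {
  dom <- data.table(protein_id = sprintf("p%d", 1:6),
                    transcript_id = sprintf("t%d", 1:6),
                    domain_id = c("A", "B", "A", "C", "D", "B"),
                    aa_start = 1L, aa_end = 5L)
  edges <- toy_ppi(list(c("p1", "p2"), c("p3", "p6"), c("p4", "p5"),
                        c("p1", "p6")), "R1")
  idx <- list(R1 = build_resource_index(edges, dom))
  truth <- data.table(domain_a = "A", domain_b = "B")
  r1 <- random_weight_search(idx, truth, n_iter = 50L, seed = 11L)
  r2 <- random_weight_search(idx, truth, n_iter = 50L, seed = 11L)
  expect_identical(r1$weights, r2$weights)
  # one resource: weights cancel, F1 equals the equal-weight calibration
  base <- calibrate_threshold(score_all_candidates(idx), truth)
  expect_equal(r1$f1, base$f1)
})

test_that("weight search finds the exhaustive-search optimum on a 2-resource toy", {
  # resource R1 separates truth perfectly, R2 is misleading
  dom <- data.table(protein_id = sprintf("p%d", 1:8),
                    transcript_id = sprintf("t%d", 1:8),
                    domain_id = c("A", "B", "A", "B", "C", "D", "C", "D"),
                    aa_start = 1L, aa_end = 5L)
  r1 <- toy_ppi(list(c("p1", "p2"), c("p3", "p4")), "R1")        # only (A,B)
  r2 <- toy_ppi(list(c("p5", "p6"), c("p7", "p8"),
                     c("p5", "p8")), "R2")                        # only (C,D)
  idx <- list(R1 = build_resource_index(r1, dom),
              R2 = build_resource_index(r2, dom))
  truth <- data.table(domain_a = "A", domain_b = "B")
  best_exhaustive <- -Inf
  for (w1 in 1:3) for (w2 in 1:3) {
    sc <- score_all_candidates(idx, c(R1 = w1, R2 = w2))
    cal <- calibrate_threshold(sc, truth)
    best_exhaustive <- max(best_exhaustive, cal$f1)
  }
  found <- random_weight_search(idx, truth, n_iter = 200L, weight_min = 1L,
                                weight_max = 3L, seed = 5L)
  expect_equal(found$f1, best_exhaustive, tolerance = 1e-12)
  # and the searched optimum is at least as good as equal weights
  eq <- calibrate_threshold(score_all_candidates(idx), truth)
  expect_gte(found$f1, eq$f1)
})

test_that("adding a supporting PPI never decreases the pair score", {
  dom <- data.table(protein_id = c("p1", "p2", "q1", "q2"),
                    transcript_id = paste0("t", 1:4),
                    domain_id = c("A", "A", "B", "B"),
                    aa_start = 1L, aa_end = 5L)
  base_edges <- list(c("p1", "q1"))
  more_edges <- list(c("p1", "q1"), c("p2", "q2"))
  s0 <- resource_pair_score(build_resource_index(toy_ppi(base_edges), dom), "A", "B")
  s1 <- resource_pair_score(build_resource_index(toy_ppi(more_edges), dom), "A", "B")
  expect_gte(s1, s0)
})

test_that("score_all_candidates matches a brute-force double loop on small instances", {
  for (s in 1:5) {
    set.seed(s)
    prot <- sprintf("p%02d", 1:10)
    doms <- LETTERS[1:6]
    occ <- rbindlist(lapply(prot, function(p) {
      data.table(protein_id = p, transcript_id = paste0("t", p),
                 domain_id = sample(doms, sample.int(2L, 1L)),
                 aa_start = 1L, aa_end = 5L)
    }))
    edges <- unique(data.table(
      protein_a = sample(prot, 15, replace = TRUE),
      protein_b = sample(prot, 15, replace = TRUE)))
    edges[, `:=`(a = pmin(protein_a, protein_b), b = pmax(protein_a, protein_b))]
    edges <- unique(edges[, .(protein_a = a, protein_b = b)])
    edges[, resource := "R1"]
    idx <- build_resource_index(edges, occ)
    sc <- score_all_candidates(list(R1 = idx))
    # brute force over all unordered domain pairs
    dmap <- split(occ$domain_id, occ$protein_id)
    for (i in seq_along(doms)) for (j in i:length(doms)) {
      a <- doms[i]; b <- doms[j]
      n <- 0L; ma <- 0L; mb <- 0L
      for (r in seq_len(nrow(edges))) {
        dp <- unique(dmap[[edges$protein_a[r]]] %||% character())
        dq <- unique(dmap[[edges$protein_b[r]]] %||% character())
        if ((a %in% dp && b %in% dq) || (a %in% dq && b %in% dp)) n <- n + 1L
        if (a %in% c(dp, dq)) ma <- ma + 1L
        if (b %in% c(dp, dq)) mb <- mb + 1L
      }
      expected <- if (n == 0L) 0 else n / sqrt(ma * mb)
      got <- sc[domain_a == a & domain_b == b, S]
      if (expected == 0) {
        expect_equal(length(got), 0L)
      } else {
        expect_equal(got, expected, tolerance = 1e-12)
      }
    }
  }
})
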