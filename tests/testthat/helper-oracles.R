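# Independent oracles used to freeze expected values. These never call the
# implementation paths they check.

library(data.table)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Exhaustive hypergeometric upper tail: enumerate all C(N, n) draw subsets of
# items 1..N (successes = items 1..K) and count subsets with >= k successes.
oracle_hyper_tail <- function(N, K, n, k) {
  if (k == 0L) return(1)
  if (n == 0L) return(0)  # k >= 1 impossible with no draws
  subs <- utils::combn(N, n)
  hits <- colSums(subs <= K)
  sum(hits >= k) / ncol(subs)
}

# Literal Benjamini-Hochberg step-up on a raw p vector.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  sorted <- p[o] * m / seq_len(m)
  # step-up: running minimum from the largest rank down
  run <- rev(cummin(rev(sorted)))
  adj[o] <- pmin(run, 1)
  adj
}

# Random in-frame transcript model; exon lengths are NOT multiples of 3 so
# codons span junctions; the last exon is padded to make the total in frame.
random_transcript_model <- function(id = "t", max_exons = 5L) {
  k <- sample.int(max_exons, 1L)
  lens <- sample(4:60, k, replace = TRUE)
  rem <- sum(lens) %% 3L
  if (rem != 0L) lens[k] <- lens[k] + (3L - rem)
  gaps <- sample(5:200, k, replace = TRUE)
  start <- sample.int(1000L, 1L)
  iv <- matrix(0L, k, 2L)
  pos <- start
  for (i in seq_len(k)) {
    iv[i, 1L] <- pos
    iv[i, 2L] <- pos + lens[i] - 1L
    pos <- iv[i, 2L] + 1L + gaps[i]
  }
  strand <- sample(c("+", "-"), 1L)
  transcript_model(id, paste0("g_", id), "chrT", strand, iv, cds = iv)
}

# Enumerate the genomic positions of coding nucleotides nt1..nt2 one by one
# (the slow, obviously-correct mapping used to check protein_to_genomic).
oracle_coding_positions <- function(tm, nt1, nt2) {
  segs <- tm$cds
  ord <- if (tm$strand == "+") seq_len(nrow(segs)) else rev(seq_len(nrow(segs)))
  genome <- unlist(lapply(ord, function(i) {
    p <- segs[i, 1L]:segs[i, 2L]
    if (tm$strand == "-") rev(p) else p
  }))
  sort(genome[nt1:nt2])
}

# Flatten an interval matrix to its covered positions.
positions_of <- function(iv) {
  if (is.null(iv) || nrow(iv) == 0L) return(integer())
  sort(unlist(lapply(seq_len(nrow(iv)), function(i) iv[i, 1L]:iv[i, 2L])))
}

# Brute-force affected-edge scan: loops over every evidence row and applies
# the loss rule literally.
oracle_affected_edges <- function(network, affected_domains) {
  evd <- network$evidence
  lost <- logical(nrow(evd))
  for (i in seq_len(nrow(evd))) {
    e <- as.list(evd[i])
    if (e$kind %in% c("ddi_experimental", "ddi_predicted")) {
      hit_a <- !is.na(e$domain_a) &&
        nrow(affected_domains[protein_id == e$protein_a &
                                domain_id == e$domain_a]) > 0L
      hit_b <- !is.na(e$domain_b) &&
        nrow(affected_domains[protein_id == e$protein_b &
                                domain_id == e$domain_b]) > 0L
      lost[i] <- hit_a || hit_b
    }
  }
  evd2 <- copy(evd)[, lost_ := lost]
  evd2[, .(n_lost = sum(lost_), n_surviving = sum(!lost_)),
       by = .(edge_id, protein_a, protein_b)][n_lost > 0L]
}

# Brute-force precision/recall/F1 over every candidate threshold.
oracle_calibrate <- function(S, is_true) {
  best <- list(f1 = -1, threshold = NA_real_)
  for (t in sort(unique(S))) {
    pos <- S >= t
    tp <- sum(pos & is_true); fp <- sum(pos & !is_true)
    fn <- sum(!pos & is_true)
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    if (f1 > best$f1 || (f1 == best$f1 && t < best$threshold)) {
      best <- list(f1 = f1, threshold = t, precision = prec, recall = rec)
    }
  }
  best
}
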