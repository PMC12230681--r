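# Domain-domain interaction prediction from multi-resource PPI co-occurrence:
# per-resource cosine co-occurrence scores, reliability-weighted combination,
# ground-truth threshold calibration, confidence tiers, and a randomized
# integer weight search.

#' Build a per-resource co-occurrence index
#'
#' For one PPI resource, counts for every unordered domain pair (a, b) the
#' number of distinct PPIs \{p, q\} with `a` on one endpoint and `b` on the
#' other (`n_r(a, b)`; a PPI contributes at most 1 to any pair), and for
#' every domain `d` the number of PPIs with `d` on at least one endpoint
#' (`m_r(d)`). Homodimer PPIs contribute to self-pairs (A, A) and to pairs
#' (A, B) when both domains sit on the one protein, counted once.
#'
#' @param edges a `ppi_edges` table for one resource.
#' @param domain_occurrences `data.table` with `protein_id`, `domain_id`.
#' @return a list of class `resource_index`: `resource`, `n_edges`,
#'   `pair_counts` (`domain_a`, `domain_b`, `n`), `domain_counts`
#'   (`domain_id`, `m`).
#' @export
build_resource_index <- function(edges, domain_occurrences) {
  ppi <- as.data.table(edges)
  resource <- if ("resource" %in% names(ppi) && nrow(ppi))
    ppi$resource[1L] else NA_character_
  cp <- canonical_pair(ppi$protein_a, ppi$protein_b)
  ed <- unique(data.table(protein_a = cp$a, protein_b = cp$b))
  ed[, edge_id := .I]
  dom <- unique(as.data.table(domain_occurrences)[, .(protein_id, domain_id)])
  empty <- list(resource = resource, n_edges = nrow(ed),
                pair_counts = data.table(domain_a = character(),
                                         domain_b = character(), n = integer()),
                domain_counts = data.table(domain_id = character(), m = integer()))
  class(empty) <- "resource_index"
  if (nrow(ed) == 0L || nrow(dom) == 0L) return(empty)

  A <- merge(ed, dom, by.x = "protein_a", by.y = "protein_id",
             allow.cartesian = TRUE)
  setnames(A, "domain_id", "dom_a")
  B <- merge(ed[, .(edge_id, protein_b)], dom, by.x = "protein_b",
             by.y = "protein_id", allow.cartesian = TRUE)
  setnames(B, "domain_id", "dom_b")
  cand <- merge(A[, .(edge_id, dom_a)], B[, .(edge_id, dom_b)],
                by = "edge_id", allow.cartesian = TRUE)
  if (nrow(cand) == 0L) return(empty)
  cpd <- canonical_pair(cand$dom_a, cand$dom_b)
  cand[, `:=`(domain_a = cpd$a, domain_b = cpd$b)]
  cand <- unique(cand[, .(edge_id, domain_a, domain_b)])
  pair_counts <- cand[, .(n = .N), by = .(domain_a, domain_b)]
  setorder(pair_counts, domain_a, domain_b)

  # m(d): PPIs with d on >= 1 endpoint
  touched <- unique(rbindlist(list(
    merge(ed[, .(edge_id, protein = protein_a)], dom,
          by.x = "protein", by.y = "protein_id")[, .(edge_id, domain_id)],
    merge(ed[, .(edge_id, protein = protein_b)], dom,
          by.x = "protein", by.y = "protein_id")[, .(edge_id, domain_id)]
  )))
  domain_counts <- touched[, .(m = .N), by = domain_id]
  setorder(domain_counts, domain_id)

  out <- list(resource = resource, n_edges = nrow(ed),
              pair_counts = pair_counts[], domain_counts = domain_counts[])
  class(out) <- "resource_index"
  out
}

#' @export
print.resource_index <- function(x, ...) {
  cat(sprintf("<resource_index> '%s': %d edges, %d co-occurring domain pairs, %d domains\n",
              x$resource, x$n_edges, nrow(x$pair_counts), nrow(x$domain_counts)))
  invisible(x)
}

#' Per-resource cosine co-occurrence score
#'
#' `s_r(a, b) = n_r(a, b) / sqrt(m_r(a) * m_r(b))`, 0 when either `m` is 0.
#' Always in \[0, 1\] and symmetric in (a, b).
#'
#' @param index a `resource_index`.
#' @param a,b domain identifiers.
#' @return numeric scalar in \[0, 1\].
#' @export
resource_pair_score <- function(index, a, b) {
  stopifnot(inherits(index, "resource_index"))
  cp <- canonical_pair(a, b)
  n <- index$pair_counts[data.table(domain_a = cp$a, domain_b = cp$b),
                         on = c("domain_a", "domain_b"), n]
  if (is.na(n)) return(0)
  ma <- index$domain_counts[domain_id == cp$a, m]
  mb <- index$domain_counts[domain_id == cp$b, m]
  if (length(ma) == 0L || length(mb) == 0L || ma == 0L || mb == 0L) return(0)
  n / sqrt(as.numeric(ma) * as.numeric(mb))
}

#' Reliability-weighted combined score
#'
#' `S = sum_r w_r s_r / sum_r w_r` over all configured resources; a resource
#' without the pair contributes `s_r = 0`, so breadth of support raises `S`.
#' Invariant under uniform weight scaling.
#'
#' @param weights named numeric vector of resource weights (all >= some
#'   positive value); must cover every name of `per_resource_scores`.
#' @param per_resource_scores named numeric vector of `s_r` values.
#' @return numeric scalar in \[0, 1\].
#' @export
combined_score <- function(weights, per_resource_scores) {
  if (length(weights) == 0L) stopf("empty resource set")
  rs <- names(per_resource_scores)
  if (is.null(rs) || !all(rs %in% names(weights))) {
    stopf("weights must cover all resources present in per_resource_scores")
  }
  w <- weights[names(weights)]
  s <- setNames(rep(0, length(w)), names(w))
  s[rs] <- per_resource_scores
  sum(w * s) / sum(w)
}

#' Score all candidate domain pairs across resources
#'
#' One record per unordered domain pair with combined score `S > 0` (i.e.
#' co-occurring in at least one resource). `n_supporting_resources` is the
#' number of resources with `s_r > 0`.
#'
#' @param resource_indexes named list of `resource_index` objects (names =
#'   resource names).
#' @param weights named numeric vector over the same resources; `NULL` =
#'   equal weights.
#' @return a `data.table` of class `ddi_scores` with columns `domain_a`,
#'   `domain_b`, one `s_<resource>` column per resource, `S`,
#'   `n_supporting_resources`.
#' @export
score_all_candidates <- function(resource_indexes, weights = NULL) {
  if (length(resource_indexes) == 0L) stopf("need at least one resource index")
  rn <- names(resource_indexes)
  if (is.null(rn) || any(!nzchar(rn))) {
    rn <- vapply(resource_indexes, `[[`, "", "resource")
    names(resource_indexes) <- rn
  }
  rn <- sort(rn)
  if (is.null(weights)) weights <- setNames(rep(1, length(rn)), rn)
  if (!all(rn %in% names(weights))) stopf("weights must cover every resource")
  w <- weights[rn]

  per_res <- lapply(rn, function(r) {
    idx <- resource_indexes[[r]]
    pc <- copy(idx$pair_counts)
    if (nrow(pc) == 0L) {
      return(data.table(domain_a = character(), domain_b = character(),
                        s = numeric()))
    }
    mc <- setNames(idx$domain_counts$m, idx$domain_counts$domain_id)
    pc[, s := n / sqrt(as.numeric(mc[domain_a]) * as.numeric(mc[domain_b]))]
    pc[, .(domain_a, domain_b, s)]
  })
  names(per_res) <- rn
  pairs <- unique(rbindlist(lapply(per_res, function(p)
    p[, .(domain_a, domain_b)])))
  if (nrow(pairs) == 0L) {
    out <- data.table(domain_a = character(), domain_b = character())
    for (r in rn) out[, (paste0("s_", r)) := numeric()]
    out[, `:=`(S = numeric(), n_supporting_resources = integer())]
    setattr(out, "class", c("ddi_scores", class(out)))
    return(out[])
  }
  setorder(pairs, domain_a, domain_b)
  smat <- matrix(0, nrow(pairs), length(rn), dimnames = list(NULL, rn))
  for (r in rn) {
    p <- per_res[[r]]
    if (nrow(p)) {
      m <- merge(pairs[, .(domain_a, domain_b, row = .I)], p,
                 by = c("domain_a", "domain_b"))
      smat[m$row, r] <- m$s
    }
  }
  out <- copy(pairs)
  for (r in rn) out[, (paste0("s_", r)) := smat[, r]]
  out[, S := as.numeric(smat %*% w) / sum(w)]
  out[, n_supporting_resources := as.integer(rowSums(smat > 0))]
  setattr(out, "class", c("ddi_scores", class(out)))
  out[]
}

# Fast calibration core on a numeric score vector + logical truth vector.
# Returns list(threshold, precision, recall, f1, curve).
.calibrate_core <- function(S, is_true, n_truth_unscored = 0L) {
  o <- order(-S, method = "radix")
  Ss <- S[o]; ts <- is_true[o]
  cum_tp <- cumsum(ts)
  cum_fp <- cumsum(!ts)
  # distinct thresholds: take the last index of each run of equal scores
  last_of_run <- which(diff(Ss) != 0)
  idx <- c(last_of_run, length(Ss))
  thr <- Ss[idx]
  tp <- cum_tp[idx]; fp <- cum_fp[idx]
  total_true <- sum(ts)
  fn <- (total_true - tp) + n_truth_unscored
  prec <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  rec <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  # maximize F1; ties broken toward the smallest threshold
  best <- which(f1 == max(f1))
  best <- best[which.min(thr[best])]
  list(threshold = thr[best], precision = prec[best], recall = rec[best],
       f1 = f1[best],
       curve = data.table(threshold = thr, precision = prec,
                          recall = rec, f1 = f1))
}

#' Calibrate the score threshold against ground-truth DDIs
#'
#' Candidate thresholds are the distinct observed combined scores. At each
#' threshold `t`, positives are the records with `S >= t`; precision and
#' recall are computed against the ground truth restricted to the scored
#' candidate universe (default), or counting never-scored truth pairs as
#' false negatives when `count_unscored_truth = TRUE`. The returned threshold
#' maximizes F1, ties broken toward the smallest `t`.
#'
#' @param records a `ddi_scores` table.
#' @param ground_truth_pairs `data.table` with `domain_a`, `domain_b`.
#' @param count_unscored_truth logical; see above.
#' @return a list of class `calibration_result`: `threshold`, `precision`,
#'   `recall`, `f1`, `curve` (threshold/precision/recall/F1 table).
#' @export
calibrate_threshold <- function(records, ground_truth_pairs,
                                count_unscored_truth = FALSE) {
  rec <- as.data.table(records)
  if (nrow(rec) == 0L) stopf("no scored records to calibrate on")
  gt <- as.data.table(ground_truth_pairs)
  if (nrow(gt) == 0L) stopf("ground truth is empty")
  cp <- canonical_pair(gt$domain_a, gt$domain_b)
  truth_keys <- unique(paste(cp$a, cp$b, sep = "\r"))
  rec_keys <- paste(rec$domain_a, rec$domain_b, sep = "\r")
  is_true <- rec_keys %in% truth_keys
  if (!any(is_true)) {
    stopf("uncalibratable: no scored record intersects the ground truth")
  }
  n_unscored <- if (count_unscored_truth)
    sum(!truth_keys %in% rec_keys) else 0L
  out <- .calibrate_core(rec$S, is_true, n_unscored)
  class(out) <- "calibration_result"
  out
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("<calibration_result> t = %.6g, precision = %.3f, recall = %.3f, F1 = %.3f\n",
              x$threshold, x$precision, x$recall, x$f1))
  invisible(x)
}

#' Assign confidence tiers to scored records
#'
#' gold: `S >= t` and supported by >= 2 resources; silver: `S >= t` and one
#' resource; bronze: `t/2 <= S < t`; below otherwise.
#'
#' @param records a `ddi_scores` table.
#' @param threshold calibrated threshold `t`.
#' @return the records with a `tier` column added.
#' @export
assign_confidence <- function(records, threshold) {
  rec <- copy(as.data.table(records))
  rec[, tier := fifelse(S >= threshold & n_supporting_resources >= 2L, "gold",
                fifelse(S >= threshold, "silver",
                fifelse(S >= threshold / 2, "bronze", "below")))]
  setattr(rec, "class", c("ddi_scores", class(rec)))
  rec[]
}

#' Randomized search over integer resource weights
#'
#' Draws `n_iter` integer weight vectors uniformly from
#' `[weight_min, weight_max]^n_resources` with the given seed (one seeded
#' generator for the whole search; draws are vectors in the order of the
#' sorted resource names), scores all candidates and calibrates for each,
#' and returns the vector maximizing calibrated F1 (ties: first encountered).
#' Deterministic for a fixed seed.
#'
#' @param resource_indexes named list of `resource_index` objects.
#' @param ground_truth_pairs `data.table` with `domain_a`, `domain_b`.
#' @param n_iter number of random draws (default 10000).
#' @param weight_min,weight_max inclusive integer weight range (default 1, 100).
#' @param seed RNG seed.
#' @param count_unscored_truth see [calibrate_threshold()].
#' @return a list of class `weight_search_result`: `weights` (named integer),
#'   `calibration` (a `calibration_result`), `f1`, `n_iter`, `seed`.
#' @export
random_weight_search <- function(resource_indexes, ground_truth_pairs,
                                 n_iter = 10000L, weight_min = 1L,
                                 weight_max = 100L, seed = 1L,
                                 count_unscored_truth = FALSE) {
  if (n_iter < 1L) stopf("n_iter must be >= 1")
  if (weight_min < 1L || weight_max < weight_min) stopf("invalid weight range")
  rn <- sort(names(resource_indexes))
  if (is.null(rn)) stopf("resource_indexes must be a named list")
  base <- score_all_candidates(resource_indexes,
                               setNames(rep(1, length(rn)), rn))
  if (nrow(base) == 0L) stopf("no candidate pairs to score")
  smat <- as.matrix(base[, paste0("s_", rn), with = FALSE])
  gt <- as.data.table(ground_truth_pairs)
  cp <- canonical_pair(gt$domain_a, gt$domain_b)
  truth_keys <- unique(paste(cp$a, cp$b, sep = "\r"))
  rec_keys <- paste(base$domain_a, base$domain_b, sep = "\r")
  is_true <- rec_keys %in% truth_keys
  if (!any(is_true)) {
    stopf("uncalibratable: no scored record intersects the ground truth")
  }
  n_unscored <- if (count_unscored_truth)
    sum(!truth_keys %in% rec_keys) else 0L

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  span <- weight_max - weight_min + 1L
  best_f1 <- -Inf; best_w <- NULL
  for (it in seq_len(n_iter)) {
    w <- sample.int(span, length(rn), replace = TRUE) + weight_min - 1L
    S <- as.numeric(smat %*% w) / sum(w)
    cal <- .calibrate_core(S, is_true, n_unscored)
    if (cal$f1 > best_f1) {
      best_f1 <- cal$f1
      best_w <- w
    }
  }
  names(best_w) <- rn
  S <- as.numeric(smat %*% best_w) / sum(best_w)
  cal <- .calibrate_core(S, is_true, n_unscored)
  class(cal) <- "calibration_result"
  out <- list(weights = best_w, calibration = cal, f1 = cal$f1,
              n_iter = n_iter, seed = seed)
  class(out) <- "weight_search_result"
  out
}

#' @export
print.weight_search_result <- function(x, ...) {
  cat(sprintf("<weight_search_result> best F1 = %.3f over %d draws; weights: %s\n",
              x$f1, x$n_iter,
              paste(sprintf("%s=%d", names(x$weights), x$weights), collapse = ", ")))
  invisible(x)
}

#' Write scored DDI predictions and a calibration curve
#'
#' @param records a `ddi_scores` table (typically after
#'   [assign_confidence()]).
#' @param calibration a `calibration_result` (optional).
#' @param path_prefix output prefix; writes `<prefix>_predictions.tsv` and,
#'   when calibration is given, `<prefix>_calibration.tsv`.
#' @return invisibly, the written paths.
#' @export
write_ddi_predictions <- function(records, calibration = NULL, path_prefix) {
  pp <- paste0(path_prefix, "_predictions.tsv")
  rec <- as.data.table(records)
  setorder(rec, -S, domain_a, domain_b)
  fwrite(rec, pp, sep = "\t", quote = FALSE)
  paths <- c(predictions = pp)
  if (!is.null(calibration)) {
    cpth <- paste0(path_prefix, "_calibration.tsv")
    fwrite(calibration$curve, cpth, sep = "\t", quote = FALSE)
    paths <- c(paths, calibration = cpth)
  }
  invisible(paths)
}
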