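# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
sr_log <- function(fmt, ..., level = "INFO") {
  message(sprintf("[%s] %s", level, sprintf(fmt, ...)))
}

#' Canonical unordered pair key
#'
#' Orders the two identifiers lexicographically so that an unordered pair has
#' a single representation.
#' @noRd
canonical_pair <- function(a, b) {
  swap <- a > b
  list(a = ifelse(swap, b, a), b = ifelse(swap, a, b))
}

pair_key <- function(a, b) {
  cp <- canonical_pair(a, b)
  paste(cp$a, cp$b, sep = "\r")
}

# Merge sorted (by start) 1-based inclusive intervals into maximal runs.
# `iv` is a 2-column matrix (start, end). Adjacent intervals (gap 0) merge.
merge_intervals <- function(iv) {
  if (is.null(iv) || nrow(iv) == 0L) {
    return(matrix(integer(), ncol = 2L, dimnames = list(NULL, c("start", "end"))))
  }
  iv <- iv[order(iv[, 1L], iv[, 2L]), , drop = FALSE]
  out <- list()
  cs <- iv[1L, 1L]; ce <- iv[1L, 2L]
  if (nrow(iv) > 1L) {
    for (i in 2L:nrow(iv)) {
      if (iv[i, 1L] <= ce + 1L) {
        ce <- max(ce, iv[i, 2L])
      } else {
        out[[length(out) + 1L]] <- c(cs, ce)
        cs <- iv[i, 1L]; ce <- iv[i, 2L]
      }
    }
  }
  out[[length(out) + 1L]] <- c(cs, ce)
  m <- do.call(rbind, out)
  dimnames(m) <- list(NULL, c("start", "end"))
  storage.mode(m) <- "integer"
  m
}

# Total number of overlapping nucleotides between interval (s, e) and the
# rows of a (start, end) matrix. All coordinates 1-based inclusive.
overlap_nt_total <- function(s, e, iv) {
  if (is.null(iv) || nrow(iv) == 0L) return(0L)
  ov <- pmin(iv[, 2L], e) - pmax(iv[, 1L], s) + 1L
  sum(pmax(ov, 0L))
}

# Validate a scalar numeric in [lo, hi]
check_range <- function(x, lo, hi, what) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi) {
    stop(sprintf("%s must be a number in [%s, %s]", what, lo, hi), call. = FALSE)
  }
  invisible(x)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
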