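# Internal interval arithmetic on 0-based half-open [start, end) matrices.
# Per-contig intervals are stored as integer matrices with columns start, end;
# IRanges does the set operations (shifted +1 at the boundary since IRanges is
# 1-based closed).

.empty_iv <- function() {
  matrix(integer(0), ncol = 2, dimnames = list(NULL, c("start", "end")))
}

.as_iranges <- function(iv) {
  IRanges::IRanges(start = iv[, 1] + 1L, end = iv[, 2])
}

.from_iranges <- function(ir) {
  m <- cbind(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
  storage.mode(m) <- "integer"
  m
}

# union (merge overlapping/adjacent-overlapping), returns sorted matrix
iv_union <- function(iv) {
  if (is.null(iv) || nrow(iv) == 0) return(.empty_iv())
  .from_iranges(IRanges::reduce(.as_iranges(iv)))
}

# total length of (union of iv) within window c(start, end)
iv_overlap_len <- function(window, iv) {
  if (is.null(iv) || nrow(iv) == 0) return(0L)
  w <- IRanges::IRanges(start = window[1] + 1L, end = window[2])
  hit <- IRanges::intersect(IRanges::reduce(.as_iranges(iv)), w)
  sum(IRanges::width(hit))
}

# TRUE for each position (0-based point) covered by iv
iv_covers <- function(pos, iv) {
  if (is.null(iv) || nrow(iv) == 0) return(rep(FALSE, length(pos)))
  p <- IRanges::IRanges(start = pos + 1L, width = 1L)
  IRanges::overlapsAny(p, .as_iranges(iv))
}

# vectorised masked length of many windows [ws, we) against a disjoint
# sorted interval set (as produced by iv_union): uses the cumulative masked
# coverage F(t) so each window costs O(log n)
iv_masked_len_vec <- function(ws, we, iv) {
  if (is.null(iv) || nrow(iv) == 0) return(numeric(length(ws)))
  s <- iv[, 1]; e <- iv[, 2]
  cl <- cumsum(e - s)
  Fcum <- function(t) {
    i <- findInterval(t, s)
    out <- numeric(length(t))
    pos <- i > 0
    ii <- i[pos]
    out[pos] <- cl[ii] - pmax(0, e[ii] - t[pos])
    out
  }
  Fcum(we) - Fcum(ws)
}

# fetch per-contig intervals from a list keyed by contig
iv_for_contig <- function(lst, contig) {
  iv <- lst[[contig]]
  if (is.null(iv)) .empty_iv() else iv
}
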