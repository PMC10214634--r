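# Core diversity estimators and the sliding-window engine.
#
# All functions take a plain 0/1 haplotype matrix (haplotypes in rows, sites
# in columns) or a variant_table slice; per-site quantities divide by a
# mask-corrected effective length, never the raw window size.

#' Harmonic number a_n = sum_{i=1}^{n-1} 1/i
#' @param n haplotype sample size.
#' @return numeric.
#' @export
harmonic_a <- function(n) sum(1 / seq_len(n - 1))

#' Count segregating sites
#' @param H 0/1 haplotype matrix (haplotypes in rows).
#' @return number of columns where both alleles are present.
#' @export
seg_sites <- function(H) {
  if (nrow(H) == 0) stop("zero haplotypes")
  if (ncol(H) == 0) return(0L)
  cs <- colSums(H)
  sum(cs > 0 & cs < nrow(H))
}

# mean pairwise difference over all C(n,2) haplotype pairs (not per site)
.pi_total <- function(H) {
  n <- nrow(H)
  if (n < 2) stop("need at least 2 haplotypes")
  if (ncol(H) == 0) return(0)
  cs <- colSums(H)
  sum(cs * (n - cs)) / (n * (n - 1) / 2)
}

#' Per-site nucleotide diversity (pi)
#'
#' Mean pairwise difference over all C(n,2) haplotype pairs divided by the
#' effective length.  This is the unbiased all-pairs estimator (equivalently
#' the per-site `(1 - sum p^2) * n/(n-1)` form); no additional `n/(n-1)`
#' factor is applied on top.
#'
#' @param H 0/1 haplotype matrix.
#' @param effective_length accessible bp (window minus masks); must be > 0.
#' @return per-site pi.
#' @export
nucleotide_diversity <- function(H, effective_length) {
  if (effective_length <= 0) stop("effective_length must be > 0")
  .pi_total(H) / effective_length
}

#' Watterson's theta per site
#'
#' `theta_hat = S / (a_n * effective_length)` with
#' `a_n = sum_{i=1}^{n-1} 1/i`.
#'
#' @param S segregating-site count.
#' @param n haplotype sample size (>= 2).
#' @param effective_length accessible bp; must be > 0.
#' @return per-site Watterson estimate.
#' @export
watterson_theta <- function(S, n, effective_length) {
  if (n < 2) stop("need n >= 2")
  if (effective_length <= 0) stop("effective_length must be > 0")
  S / (harmonic_a(n) * effective_length)
}

#' Tajima's D
#'
#' Normalised difference between the pairwise-diversity and segregating-site
#' estimates of theta.  With `S = 0` the statistic is undefined and `NA` is
#' returned (flagged, not an error): empty windows are routine in sliding
#' scans.
#'
#' @param H 0/1 haplotype matrix with `n >= 4` haplotypes.
#' @return numeric D, or `NA_real_` when `S = 0`.
#' @export
tajimas_d <- function(H) {
  n <- nrow(H)
  if (n < 4) stop("need n >= 4 for Tajima's D")
  S <- seg_sites(H)
  if (S == 0) return(NA_real_)
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (.pi_total(H) - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

#' Effective length of a window under masks
#'
#' Window length minus the length of the union of gap and repeat intervals
#' intersected with the window (union, not sum: overlapping masks are not
#' double-counted).
#'
#' @param window length-2 vector `[start, end)`.
#' @param masks a [mask_set()] (or NULL for no masking).
#' @param contig contig the window lies on.
#' @return integer bp, possibly 0 for a fully masked window.
#' @export
effective_length <- function(window, masks, contig) {
  len <- window[2] - window[1]
  if (is.null(masks)) return(as.integer(len))
  as.integer(len - iv_overlap_len(window, .ef_masks(masks, contig)))
}

#' Sliding-window diversity track
#'
#' Windows tile `[start, end)` of the region anchored at its start; the step
#' grid continues past the last full window and one final truncated window is
#' emitted if at least 25% of the window size would otherwise remain
#' uncovered (a region shorter than one window yields a single truncated
#' window).  Each window's statistics use only the SNPs inside it and its own
#' mask-corrected effective length; fully masked or empty windows carry
#' zero/NA statistics.
#'
#' @param vt a [variant_table()].
#' @param contig contig name.
#' @param region length-2 vector `[start, end)`.
#' @param masks a [mask_set()] or NULL.
#' @param size window size in bp.
#' @param step step in bp, `0 < step <= size`.
#' @return a `data.frame` of class `diversity_track` with columns contig,
#'   start, end, eff_len, S, pi_site, theta_w_site, tajima_d.
#' @export
sliding_windows <- function(vt, contig, region, masks = NULL,
                            size = 2000L, step = 500L) {
  stopifnot(step > 0, step <= size)
  rs <- region[1]; re <- region[2]
  starts <- seq(rs, by = step, length.out = max(1, floor((re - rs - size) / step) + 1))
  starts <- starts[starts + size <= re]
  if (!length(starts)) {
    wins <- cbind(rs, re)                      # region shorter than one window
  } else {
    wins <- cbind(starts, starts + size)
    covered <- max(wins[, 2])
    if (re - covered >= 0.25 * size) {
      wins <- rbind(wins, c(max(starts) + step, re))
    }
  }
  n <- nrow(vt$geno)
  sub <- vt$contig == contig
  pos <- vt$pos0[sub]
  G <- vt$geno[, sub, drop = FALSE]
  rows <- lapply(seq_len(nrow(wins)), function(i) {
    w <- wins[i, ]
    eff <- effective_length(w, masks, contig)
    Hw <- G[, pos >= w[1] & pos < w[2], drop = FALSE]
    S <- seg_sites(Hw)
    if (eff > 0) {
      pi_s <- nucleotide_diversity(Hw, eff)
      th_s <- watterson_theta(S, n, eff)
    } else {
      pi_s <- NA_real_; th_s <- NA_real_
    }
    data.frame(contig = contig, start = w[1], end = w[2], eff_len = eff,
               S = S, pi_site = pi_s, theta_w_site = th_s,
               tajima_d = if (S > 0 && n >= 4) tajimas_d(Hw) else NA_real_)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("diversity_track", "data.frame")
  out
}

#' Plot a diversity track
#'
#' Minimal base-graphics helper: one panel per statistic along the window
#' midpoints.
#'
#' @param x a `diversity_track`.
#' @param ... passed to [plot()].
#' @return `x` invisibly.
#' @export
plot.diversity_track <- function(x, ...) {
  mid <- (x$start + x$end) / 2
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  plot(mid, x$pi_site, type = "l", xlab = "position (bp)", ylab = "pi / site", ...)
  plot(mid, x$tajima_d, type = "l", xlab = "position (bp)", ylab = "Tajima's D", ...)
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}

#' Per-tile Watterson theta map
#'
#' Non-overlapping tiles (default 10 kb, origin 0 on every contig) each
#' mapped to a per-bp Watterson estimate using the tile's mask-corrected
#' effective length.  Tiles with zero effective length get `NA` (explicitly
#' missing, never 0).
#'
#' @param vt a [variant_table()] covering the genome (or region) of interest.
#' @param masks a [mask_set()] or NULL.
#' @param tile tile size in bp.
#' @return a `data.frame` of class `theta_map` with columns contig, start,
#'   end, S, eff_len, theta_bp.
#' @export
theta_map <- function(vt, masks = NULL, tile = 10000L) {
  n <- nrow(vt$geno)
  a <- harmonic_a(n)
  rows <- lapply(unique(vt$contig), function(ctg) {
    pos <- vt$pos0[vt$contig == ctg]
    last <- if (length(pos)) max(pos) else 0L
    starts <- seq(0L, last, by = tile)
    S <- tabulate(findInterval(pos, starts), nbins = length(starts))
    eff <- vapply(starts, function(s)
      effective_length(c(s, s + tile), masks, ctg), integer(1))
    data.frame(contig = ctg, start = starts, end = starts + tile, S = S,
               eff_len = eff,
               theta_bp = ifelse(eff > 0, S / (a * eff), NA_real_))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("theta_map", "data.frame")
  out
}

#' Look up per-bp theta for positions
#'
#' @param tm a [theta_map()].
#' @param contig contig name (scalar or vector recycled against `pos`).
#' @param pos 0-based positions.
#' @return per-bp theta for the tile containing each position; `NA` for
#'   positions in tiles that are missing (zero effective length) or outside
#'   the map.
#' @export
theta_lookup <- function(tm, contig, pos) {
  contig <- rep_len(contig, length(pos))
  out <- rep(NA_real_, length(pos))
  for (ctg in unique(contig)) {
    i <- which(contig == ctg)
    sub <- tm[tm$contig == ctg, , drop = FALSE]
    if (!nrow(sub)) next
    idx <- findInterval(pos[i], sub$start)
    ok <- idx >= 1 & pos[i] < sub$end[pmax(idx, 1)]
    out[i[ok]] <- sub$theta_bp[idx[ok]]
  }
  out
}
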