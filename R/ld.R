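# Pairwise linkage disequilibrium and Gabriel haplotype blocks.

#' Pairwise D, D-prime and r-squared from phased haplotypes
#'
#' Direct haplotype counting on two phased binary site columns:
#' `D = p_AB - p_A p_B`; `D' = |D| / D_max` with
#' `D_max = min(p_A (1-p_B), (1-p_A) p_B)` for `D > 0` and
#' `min(p_A p_B, (1-p_A)(1-p_B))` otherwise;
#' `r^2 = D^2 / (p_A (1-p_A) p_B (1-p_B))`.
#'
#' @param hapA,hapB 0/1 vectors of equal length (both sites polymorphic).
#' @return list of class `ld_pair`: D, Dprime, r2 (confidence bounds are
#'   added by [dprime_ci()]).
#' @export
dprime <- function(hapA, hapB) {
  stopifnot(length(hapA) == length(hapB))
  pA <- mean(hapA); pB <- mean(hapB)
  if (pA <= 0 || pA >= 1 || pB <= 0 || pB >= 1)
    stop("monomorphic site in D' computation")
  pAB <- mean(hapA == 1 & hapB == 1)
  D <- pAB - pA * pB
  Dmax <- if (D > 0) min(pA * (1 - pB), (1 - pA) * pB)
          else min(pA * pB, (1 - pA) * (1 - pB))
  structure(list(D = D, Dprime = if (Dmax == 0) 0 else min(1, abs(D) / Dmax),
                 r2 = D^2 / (pA * (1 - pA) * pB * (1 - pB))),
            class = "ld_pair")
}

#' Likelihood confidence bounds on D-prime
#'
#' The multinomial likelihood of the four observed two-site haplotype counts
#' is evaluated on a D-prime grid in \[0, 1\] at the observed allele-frequency
#' margins (sign of D fixed at its point estimate), normalised to a weight
#' distribution; the bounds are its 5th and 95th percentiles.  Deterministic
#' by construction; the default 1001-point grid changes the bounds by well
#' under 0.01 relative to a grid twice as fine.
#'
#' @param hapA,hapB 0/1 vectors as in [dprime()].
#' @param grid_n grid resolution.
#' @return numeric `c(ci_low, ci_high)`.
#' @export
dprime_ci <- function(hapA, hapB, grid_n = 1001) {
  pA <- mean(hapA); pB <- mean(hapB)
  if (pA <= 0 || pA >= 1 || pB <= 0 || pB >= 1) stop("degenerate margins")
  n11 <- sum(hapA == 1 & hapB == 1)
  n10 <- sum(hapA == 1 & hapB == 0)
  n01 <- sum(hapA == 0 & hapB == 1)
  n00 <- sum(hapA == 0 & hapB == 0)
  ci <- .dprime_ci_counts(n11, n10, n01, n00, pA, pB, grid_n)
  c(ci_low = ci[1], ci_high = ci[2])
}

# grid likelihood on two-site haplotype counts (hot path of dprime_pairs)
.dprime_ci_counts <- function(n11, n10, n01, n00, pA, pB, grid_n) {
  Dhat <- n11 / (n11 + n10 + n01 + n00) - pA * pB
  Dmax <- if (Dhat >= 0) min(pA * (1 - pB), (1 - pA) * pB)
          else min(pA * pB, (1 - pA) * (1 - pB))
  dp <- seq(0, 1, length.out = grid_n)
  D <- sign(Dhat + (Dhat == 0)) * dp * Dmax
  eps <- 1e-12
  ll <- n11 * log(pmax(pA * pB + D, eps)) +
    n10 * log(pmax(pA * (1 - pB) - D, eps)) +
    n01 * log(pmax((1 - pA) * pB - D, eps)) +
    n00 * log(pmax((1 - pA) * (1 - pB) + D, eps))
  w <- exp(ll - max(ll))
  cw <- cumsum(w) / sum(w)
  c(dp[which(cw >= 0.05)[1]], dp[which(cw >= 0.95)[1]])
}

#' Gabriel block-calling configuration
#'
#' Published default thresholds: a pair is "strong LD" when its D' CI has
#' `ci_low >= 0.70` and `ci_high >= 0.98`; "strong recombination" when
#' `ci_high < 0.90`; other pairs are uninformative.  A run of SNPs is a block
#' when at least `frac_strong` of its informative pairs are strong LD.
#'
#' @param strong_low,strong_high,recomb_high,frac_strong,maf_min thresholds.
#' @return a `ld_block_config` list.
#' @export
ld_block_config <- function(strong_low = 0.70, strong_high = 0.98,
                            recomb_high = 0.90, frac_strong = 0.95,
                            maf_min = 0.15) {
  structure(list(strong_low = strong_low, strong_high = strong_high,
                 recomb_high = recomb_high, frac_strong = frac_strong,
                 maf_min = maf_min),
            class = "ld_block_config")
}

#' All pairwise D-prime results for a region
#'
#' @param H 0/1 haplotype matrix (MAF filtering is the caller's duty; see
#'   [ld_region()] for the VCF-driven path).
#' @param pos site positions (columns of `H`).
#' @param grid_n CI grid resolution.
#' @return data.frame: i, j (column indices), pos_a, pos_b, D, Dprime, r2,
#'   ci_low, ci_high.
#' @export
dprime_pairs <- function(H, pos = seq_len(ncol(H)), grid_n = 1001) {
  m <- ncol(H)
  if (m < 2)
    return(data.frame(i = integer(0), j = integer(0), pos_a = integer(0),
                      pos_b = integer(0), D = numeric(0), Dprime = numeric(0),
                      r2 = numeric(0), ci_low = numeric(0),
                      ci_high = numeric(0)))
  pr <- t(combn(m, 2))
  n <- nrow(H)
  # vectorised counting: haplotype-pair tables from one cross-product
  N11 <- crossprod(H)
  cs <- colSums(H)
  i <- pr[, 1]; j <- pr[, 2]
  n11 <- N11[cbind(i, j)]
  pA <- cs[i] / n; pB <- cs[j] / n
  D <- n11 / n - pA * pB
  Dmax <- ifelse(D > 0, pmin(pA * (1 - pB), (1 - pA) * pB),
                 pmin(pA * pB, (1 - pA) * (1 - pB)))
  Dprime <- ifelse(Dmax == 0, 0, pmin(1, abs(D) / Dmax))
  r2 <- D^2 / (pA * (1 - pA) * pB * (1 - pB))
  # identical 2x2 count tables share one CI evaluation
  key <- paste(n11, cs[i], cs[j])
  uq <- which(!duplicated(key))
  ci_u <- vapply(uq, function(r) {
    .dprime_ci_counts(n11[r], cs[i[r]] - n11[r], cs[j[r]] - n11[r],
                      n - cs[i[r]] - cs[j[r]] + n11[r],
                      pA[r], pB[r], grid_n)
  }, numeric(2))
  ci <- ci_u[, match(key, key[uq]), drop = FALSE]
  data.frame(i = i, j = j, pos_a = pos[i], pos_b = pos[j], D = D,
             Dprime = Dprime, r2 = r2, ci_low = ci[1, ], ci_high = ci[2, ])
}

# classify pairs: 1 strong LD, -1 strong recombination, 0 uninformative
.classify_pairs <- function(pairs, cfg) {
  ifelse(pairs$ci_low >= cfg$strong_low & pairs$ci_high >= cfg$strong_high, 1L,
         ifelse(pairs$ci_high < cfg$recomb_high, -1L, 0L))
}

#' Call Gabriel haplotype blocks
#'
#' Every SNP interval is scored under the Gabriel rules (at least
#' `frac_strong` of its informative — strong-LD or strong-recombination —
#' pairs must be strong LD, with at least one strong-LD pair); eligible
#' intervals are taken greedily, longest span first (ties: most SNPs, then
#' leftmost), without overlap.
#'
#' @param pairs output of [dprime_pairs()] over the region's MAF-filtered
#'   SNPs.
#' @param cfg a [ld_block_config()].
#' @return data.frame of blocks: first, last (SNP indices), start, end
#'   (positions), n_snps, frac_strong; empty for fewer than two sites.
#' @export
gabriel_blocks <- function(pairs, cfg = ld_block_config()) {
  empty <- data.frame(first = integer(0), last = integer(0),
                      start = integer(0), end = integer(0),
                      n_snps = integer(0), frac_strong = numeric(0))
  if (!nrow(pairs)) return(empty)
  cls <- .classify_pairs(pairs, cfg)
  idx <- sort(unique(c(pairs$i, pairs$j)))
  m <- max(idx)
  pos <- integer(m)
  pos[pairs$i] <- pairs$pos_a; pos[pairs$j] <- pairs$pos_b
  # 2-D cumulative pair counts: C[a, b] = number of pairs with i >= a, j <= b
  cum2 <- function(X) {
    R <- apply(X, 2, function(v) rev(cumsum(rev(v))))
    t(apply(R, 1, cumsum))
  }
  Xs <- matrix(0L, m, m); Xi <- matrix(0L, m, m)
  Xs[cbind(pairs$i, pairs$j)] <- as.integer(cls == 1L)
  Xi[cbind(pairs$i, pairs$j)] <- as.integer(cls != 0L)
  Cs <- cum2(Xs); Ci <- cum2(Xi)
  ab <- which(upper.tri(diag(m)), arr.ind = TRUE)
  ok <- ab[, 1] %in% idx & ab[, 2] %in% idx
  ab <- ab[ok, , drop = FALSE]
  ns <- Cs[ab]; ni <- Ci[ab]
  keep <- ni > 0 & ns > 0 & ns / ni >= cfg$frac_strong
  if (!any(keep)) return(empty)
  cm <- cbind(ab[keep, 1], ab[keep, 2], (ns / ni)[keep])
  span <- pos[cm[, 2]] - pos[cm[, 1]]
  ord <- order(-span, -(cm[, 2] - cm[, 1]), cm[, 1])
  cm <- cm[ord, , drop = FALSE]
  taken <- rep(FALSE, max(idx))
  out <- list()
  for (r in seq_len(nrow(cm))) {
    a <- cm[r, 1]; b <- cm[r, 2]
    if (any(taken[a:b])) next
    taken[a:b] <- TRUE
    out[[length(out) + 1]] <- data.frame(first = a, last = b,
                                         start = pos[a], end = pos[b],
                                         n_snps = sum(idx >= a & idx <= b),
                                         frac_strong = cm[r, 3])
  }
  res <- do.call(rbind, out)
  res[order(res$first), , drop = FALSE]
}

#' LD pairs and blocks for a VCF region
#'
#' Convenience wrapper: slices the variant table, applies the MAF filter and
#' runs [dprime_pairs()] + [gabriel_blocks()].
#'
#' @param vt a [variant_table()].
#' @param contig,start,end region (0-based half-open).
#' @param cfg a [ld_block_config()].
#' @return list with `pairs`, `blocks`, `positions`.
#' @export
ld_region <- function(vt, contig, start, end, cfg = ld_block_config()) {
  sl <- vt_region(vt, contig, start, end)
  n <- nrow(sl$geno)
  cs <- colSums(sl$geno)
  keep <- cs > 0 & cs < n & pmin(cs, n - cs) / n >= cfg$maf_min
  H <- sl$geno[, keep, drop = FALSE]
  pos <- sl$pos0[keep]
  pairs <- dprime_pairs(H, pos)
  list(pairs = pairs, blocks = gabriel_blocks(pairs, cfg), positions = pos)
}
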