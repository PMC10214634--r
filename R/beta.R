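# Folded beta allele-frequency-correlation scan.
#
# For a core SNP at folded frequency x_core, neighbouring SNPs at similar
# folded frequencies are evidence of a linked balanced polymorphism.  The
# statistic contrasts a similarity-weighted mutation-supply estimate with
# the plain Watterson count on the same window:
#
#   beta = theta_beta - theta_W,win
#   theta_beta = sum_{i != core} s(x_i, x_core) / A(x_core)
#   s(x, y)    = (1 - |x - y| / 0.5)^p
#   A(y)       = sum_{k : k/n >= maf_min} s(k/n, y) * e(k)
#   e(k)       = 1/k + 1/(n-k)  (2/n at k = n/2)
#   theta_W,win = (# neighbours) / sum_{k : k/n >= maf_min} e(k)
#
# Both normalisers run only over folded classes at or above the minor-allele
# frequency floor, so the MAF filter itself does not bias the statistic, and
# the core SNP is excluded from both sums, so E[beta] = 0 exactly when
# flanking frequencies are independent draws from the neutral folded
# spectrum (linkage equilibrium).  Both estimators are on the whole-window
# mutation-supply scale, not per bp.

#' Beta-scan configuration
#'
#' @param window_bp total window width around each core SNP (the window is
#'   `+/- window_bp/2`).
#' @param maf_min folded-frequency floor; SNPs below it are excluded both as
#'   cores and as neighbours.
#' @param sharpness_p similarity-kernel exponent.
#' @param indel_radius bp radius around indels within which beta values are
#'   masked.
#' @param percentile_q control-distribution percentile for outlier calling.
#' @return a `beta_config` list.
#' @export
beta_config <- function(window_bp = 2000L, maf_min = 0.15, sharpness_p = 2,
                        indel_radius = 1000L, percentile_q = 95) {
  stopifnot(window_bp > 0, maf_min >= 0, maf_min < 0.5, sharpness_p > 0,
            indel_radius >= 0)
  structure(list(window_bp = as.integer(window_bp), maf_min = maf_min,
                 sharpness_p = sharpness_p,
                 indel_radius = as.integer(indel_radius),
                 percentile_q = percentile_q),
            class = "beta_config")
}

#' Folded (minor) allele frequency
#'
#' @param alt_count alternate-allele count(s), strictly between 0 and `n`
#'   (monomorphic sites should have been filtered and are an error).
#' @param n haplotype count.
#' @return `min(c, n - c) / n` in (0, 0.5].
#' @export
folded_freq <- function(alt_count, n) {
  if (any(alt_count <= 0 | alt_count >= n))
    stop("monomorphic site: alt_count must be in (0, n)")
  pmin(alt_count, n - alt_count) / n
}

#' Folded-frequency similarity kernel
#'
#' @param x_i,x_core folded frequencies in (0, 0.5].
#' @param p sharpness exponent.
#' @return `(1 - |x_i - x_core| / 0.5)^p` in \[0, 1\].
#' @export
similarity <- function(x_i, x_core, p = 2) {
  (1 - abs(x_i - x_core) / 0.5)^p
}

# per-(n, maf, p) normaliser constants: retained folded classes k, their
# neutral-spectrum weights e(k), and a' = sum e(k)
beta_consts <- function(n, maf_min, p = 2) {
  ks <- seq_len(floor(n / 2))
  ks <- ks[ks / n >= maf_min]
  if (!length(ks)) stop("maf_min leaves no folded frequency classes")
  ek <- ifelse(ks < n / 2, 1 / ks + 1 / (n - ks), 2 / n)
  list(x = ks / n, ek = ek, aprime = sum(ek), p = p)
}

#' Raw beta for one core SNP
#'
#' @param x folded frequencies of all MAF-filtered SNPs in the core's window
#'   (core included in the vector).
#' @param core index of the core SNP within `x`.
#' @param n haplotype count.
#' @param cfg a [beta_config()].
#' @return raw beta on the whole-window scale, or `NA` (flagged missing)
#'   when the window holds no neighbour besides the core.
#' @export
beta1 <- function(x, core, n, cfg = beta_config()) {
  cc <- beta_consts(n, cfg$maf_min, cfg$sharpness_p)
  .beta1_fast(x[core], x[-core], cc)
}

# kernel evaluation with precomputed constants (hot path of the scan)
.beta1_fast <- function(x_core, x_nb, cc) {
  if (!length(x_nb)) return(NA_real_)
  A <- sum((1 - abs(cc$x - x_core) / 0.5)^cc$p * cc$ek)
  theta_beta <- sum((1 - abs(x_nb - x_core) / 0.5)^cc$p) / A
  theta_beta - length(x_nb) / cc$aprime
}

#' Standardise beta by the local mutation supply
#'
#' Divides raw beta by the expected window mutation supply
#' `theta_tile * eff_window`, making values comparable across genes that sit
#' in regions of different mutation rate.
#'
#' @param beta_raw raw beta value(s).
#' @param theta_tile per-bp Watterson theta of the enclosing tile (`NA` when
#'   the tile is missing).
#' @param eff_window mask-corrected window length in bp.
#' @return standardised beta; `NA` when the tile is missing or the window is
#'   fully masked (callers flag the reason).
#' @export
standardize <- function(beta_raw, theta_tile, eff_window) {
  out <- beta_raw / (theta_tile * eff_window)
  out[is.na(theta_tile) | eff_window <= 0 | theta_tile <= 0] <- NA_real_
  out
}

#' Scan a variant table for beta
#'
#' Every SNP at or above the MAF floor is scored as a core against the
#' MAF-filtered SNPs within `+/- window_bp/2` on its contig.  Raw values are
#' standardised by the theta-map tile containing the core and the window's
#' mask-corrected effective length; SNPs within `indel_radius` of an indel
#' are masked (reason "indel"), cores without a theta tile are masked
#' ("no-theta"), fully masked windows ("zero-eff") and windows with no
#' neighbours ("empty-window") likewise.
#'
#' @param vt a [variant_table()].
#' @param masks a [mask_set()] or NULL.
#' @param theta a [theta_map()] or NULL (beta_std then masked "no-theta").
#' @param cfg a [beta_config()].
#' @return `data.frame` with one row per retained core SNP: contig, pos0,
#'   folded_freq, beta_raw, beta_std, masked, mask_reason.
#' @export
beta_scan <- function(vt, masks = NULL, theta = NULL, cfg = beta_config()) {
  n <- nrow(vt$geno)
  cc <- beta_consts(n, cfg$maf_min, cfg$sharpness_p)
  half <- cfg$window_bp / 2
  cs <- colSums(vt$geno)
  poly <- cs > 0 & cs < n
  x_all <- rep(NA_real_, length(cs))
  x_all[poly] <- pmin(cs[poly], n - cs[poly]) / n
  keep <- which(poly & x_all >= cfg$maf_min)
  out <- vector("list", length(unique(vt$contig)))
  ci <- 0L
  for (ctg in unique(vt$contig)) {
    idx <- keep[vt$contig[keep] == ctg]
    if (!length(idx)) next
    pos <- vt$pos0[idx]
    x <- x_all[idx]
    lo <- findInterval(pos - half - 0.5, pos) + 1L # first neighbour index
    hi <- findInterval(pos + half, pos)            # last neighbour index
    braw <- vapply(seq_along(idx), function(i) {
      nb <- lo[i]:hi[i]
      .beta1_fast(x[i], x[nb[nb != i]], cc)
    }, numeric(1))
    th <- if (is.null(theta)) rep(NA_real_, length(idx))
          else theta_lookup(theta, ctg, pos)
    emsk <- .ef_masks(masks, ctg)
    eff <- cfg$window_bp - iv_masked_len_vec(pos - half, pos + half, emsk)
    bstd <- standardize(braw, th, eff)
    reason <- rep(NA_character_, length(idx))
    reason[is.na(braw)] <- "empty-window"
    reason[is.na(reason) & eff <= 0] <- "zero-eff"
    reason[is.na(reason) & (is.na(th) | th <= 0)] <- "no-theta"
    ci <- ci + 1L
    out[[ci]] <- data.frame(contig = ctg, pos0 = pos, folded_freq = x,
                            beta_raw = braw, beta_std = bstd,
                            masked = !is.na(reason), mask_reason = reason,
                            stringsAsFactors = FALSE)
  }
  res <- if (ci) do.call(rbind, out[seq_len(ci)])
         else data.frame(contig = character(0), pos0 = integer(0),
                         folded_freq = numeric(0), beta_raw = numeric(0),
                         beta_std = numeric(0), masked = logical(0),
                         mask_reason = character(0))
  mask_near_indels(res, masks, cfg$indel_radius)
}

#' Mask beta results near indels
#'
#' Flags any SNP whose position lies within `radius` bp of an indel
#' point/interval (reason "indel"); other rows are untouched.  Enlarging the
#' radius can only add masked SNPs, never unmask one.
#'
#' @param results a [beta_scan()] data.frame.
#' @param masks a [mask_set()] carrying indels, or NULL.
#' @param radius bp.
#' @return the results data.frame with updated masked/mask_reason.
#' @export
mask_near_indels <- function(results, masks, radius = 1000L) {
  if (is.null(masks) || !nrow(results)) return(results)
  for (ctg in unique(results$contig)) {
    iv <- iv_for_contig(masks$indels, ctg)
    if (!nrow(iv)) next
    grown <- cbind(iv[, 1] - radius, iv[, 2] + radius)
    i <- which(results$contig == ctg)
    hit <- iv_covers(results$pos0[i], grown)
    newly <- i[hit & !results$masked[i]]
    results$masked[newly] <- TRUE
    results$mask_reason[newly] <- "indel"
    results$beta_std[newly] <- NA_real_   # beta_std present iff not masked
  }
  results
}

#' Per-gene maximum standardised beta
#'
#' @param gene a [gene_model()].
#' @param results a [beta_scan()] data.frame covering the gene's contig.
#' @return one-row `data.frame`: gene_id, beta_std_max (`NA` when no usable
#'   SNP), n_snps_used.  The gene span is half-open: a SNP exactly at the
#'   span end is excluded.
#' @export
gene_beta_max <- function(gene, results) {
  i <- results$contig == gene$contig & results$pos0 >= gene$span[1] &
    results$pos0 < gene$span[2] & !results$masked & !is.na(results$beta_std)
  vals <- results$beta_std[i]
  data.frame(gene_id = gene$gene_id,
             beta_std_max = if (length(vals)) max(vals) else NA_real_,
             n_snps_used = sum(i), stringsAsFactors = FALSE)
}

# nearest-rank percentile: q-th percentile of sorted x (no interpolation)
nearest_rank <- function(x, q) {
  x <- sort(x)
  x[max(1L, ceiling(q / 100 * length(x)))]
}

#' Call outlier genes against the control distribution
#'
#' The threshold is the nearest-rank `q`-th percentile of the control genes'
#' beta_std_max values; a candidate equal to the threshold is an outlier
#' (>=).  percentile_rank is 100 times the fraction of controls strictly
#' below the candidate's value.
#'
#' @param candidates,controls data.frames from [gene_beta_max()] rows.
#' @param q percentile (default 95).
#' @return `candidates` with added columns percentile_rank and outlier;
#'   attribute `threshold` carries the control cutoff.
#' @export
outlier_call <- function(candidates, controls, q = 95) {
  cv <- controls$beta_std_max[!is.na(controls$beta_std_max)]
  if (length(cv) < 20)
    stop("need >= 20 control genes with non-missing beta_std_max (have ",
         length(cv), ")")
  thr <- nearest_rank(cv, q)
  candidates$percentile_rank <- vapply(candidates$beta_std_max, function(v)
    if (is.na(v)) NA_real_ else 100 * mean(cv < v), numeric(1))
  candidates$outlier <- !is.na(candidates$beta_std_max) &
    candidates$beta_std_max >= thr
  attr(candidates, "threshold") <- thr
  candidates
}
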