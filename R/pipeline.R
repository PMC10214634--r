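# Pipeline orchestration: theta map -> beta scan -> gene maxima ->
# control-percentile outlier call -> ML-HKA on outliers -> diversity tracks,
# LD blocks and networks for hits -> gene-category comparison.

#' Mann-Whitney U test
#'
#' Rank-sum U with midrank ties; the p-value is exact (by enumeration) when
#' `min(n_a, n_b) <= 8` and there are no ties, otherwise a normal
#' approximation with tie and continuity correction is used (both routes via
#' [stats::wilcox.test()]).
#'
#' @param group_a,group_b non-empty numeric vectors.
#' @return list: U (pairs where `a > b`, plus half-ties), p_value
#'   (two-sided), exact flag.
#' @export
mann_whitney_u <- function(group_a, group_b) {
  if (!length(group_a) || !length(group_b)) stop("empty group")
  ties <- anyDuplicated(c(group_a, group_b)) > 0
  exact <- min(length(group_a), length(group_b)) <= 8 && !ties
  wt <- suppressWarnings(wilcox.test(group_a, group_b, exact = exact,
                                     correct = TRUE))
  list(U = unname(wt$statistic), p_value = wt$p.value, exact = exact)
}

#' Compare beta_std_max between gene categories
#'
#' Two Mann-Whitney comparisons: candidates-of-balancing-selection versus
#' other complement genes, and all complement genes versus controls.  Genes
#' with missing beta_std_max are excluded and counted.
#'
#' @param summaries per-gene data.frame (gene_id, beta_std_max) for the
#'   complement set.
#' @param labels named character vector gene_id -> "candidate" / "other".
#' @param controls per-gene data.frame for the control set.
#' @return data.frame with one row per comparison: n_a, n_b, median_a,
#'   median_b, U, p (all `NA`-flagged when a group has < 2 usable genes),
#'   n_excluded.
#' @export
category_compare <- function(summaries, labels, controls = NULL) {
  usable <- !is.na(summaries$beta_std_max)
  lab <- labels[summaries$gene_id]
  row <- function(name, a, b, excl) {
    if (length(a) < 2 || length(b) < 2) {
      data.frame(comparison = name, n_a = length(a), n_b = length(b),
                 median_a = NA_real_, median_b = NA_real_, U = NA_real_,
                 p = NA_real_, n_excluded = excl)
    } else {
      mw <- mann_whitney_u(a, b)
      data.frame(comparison = name, n_a = length(a), n_b = length(b),
                 median_a = median(a), median_b = median(b), U = mw$U,
                 p = mw$p_value, n_excluded = excl)
    }
  }
  out <- row("candidate_vs_other",
             summaries$beta_std_max[usable & lab == "candidate"],
             summaries$beta_std_max[usable & lab == "other"],
             sum(!usable))
  if (!is.null(controls)) {
    cu <- !is.na(controls$beta_std_max)
    out <- rbind(out, row("complement_vs_control",
                          summaries$beta_std_max[usable],
                          controls$beta_std_max[cu],
                          sum(!usable) + sum(!cu)))
  }
  out
}

#' Read a scan configuration file
#'
#' A flat YAML file with sections mirroring the pipeline stages (paths,
#' genes, beta, ld, windows, hka, seeds).
#'
#' @param path YAML file.
#' @return config list.
#' @export
read_scan_config <- function(path) yaml::read_yaml(path)

# resolve an input that may be an in-memory object or a file path
.resolve <- function(x, reader) {
  if (is.null(x) || !is.character(x)) x else reader(x)
}

#' Run the full balancing-selection scan
#'
#' Executes, in order: theta map; beta scan with MAF and indel filters;
#' per-gene beta_std maxima; control-percentile outlier call; ML-HKA for
#' each outlier that has polymorphism/divergence input (outliers without it
#' carry an explicit skip reason); sliding-window pi / Tajima's D tracks for
#' outliers (the short-gene preset 500/50 triggers when the gene is shorter
#' than four window sizes); LD blocks and a median-joining network for
#' ML-HKA-significant genes; and the gene-category Mann-Whitney comparison.
#' Fully deterministic for a fixed config.
#'
#' @param config list (or YAML path) with elements: `variants`
#'   ([variant_table()] or VCF path), `genes` (gene-model list or GFF3
#'   path), `masks` ([mask_set()] or list of BED paths), `candidates` and
#'   `controls` (gene-id vectors), optional `categories` (named vector
#'   gene_id -> "candidate"/"other"), optional `hka` (list: `neutral_loci`
#'   data.frame/TSV and `divergence` named vector gene_id -> D count, plus
#'   optional `k_on_divergence`), `beta` ([beta_config()] or its fields),
#'   `ld` ([ld_block_config()] or fields), `window`/`step` presets, `q`
#'   percentile, `alpha`, `hka_all` flag to run HKA on every candidate.
#' @param out_dir optional output directory for the TSV/GraphML report
#'   files.
#' @return an object of class `scan_report`.
#' @export
run_scan <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_scan_config(config)
  cfg <- config
  vt <- .resolve(cfg$variants, read_vcf)
  genes <- .resolve(cfg$genes, read_gff)
  masks <- cfg$masks
  if (is.list(masks) && !inherits(masks, "mask_set"))
    masks <- read_masks(masks$repeats, masks$gaps, masks$indels)
  bcfg <- cfg$beta %||% beta_config()
  if (!inherits(bcfg, "beta_config")) bcfg <- do.call(beta_config, bcfg)
  lcfg <- cfg$ld %||% ld_block_config()
  if (!inherits(lcfg, "ld_block_config")) lcfg <- do.call(ld_block_config, lcfg)
  q <- cfg$q %||% bcfg$percentile_q
  alpha <- cfg$alpha %||% 0.05
  win <- cfg$window %||% 2000L
  stp <- cfg$step %||% 500L
  log <- list()

  tm <- theta_map(vt, masks)
  scan <- beta_scan(vt, masks, tm, bcfg)
  log$snps_scored <- nrow(scan)
  log$snps_masked <- sum(scan$masked)

  gsum <- do.call(rbind, lapply(genes, gene_beta_max, results = scan))
  cand <- gsum[gsum$gene_id %in% cfg$candidates, , drop = FALSE]
  ctrl <- gsum[gsum$gene_id %in% cfg$controls, , drop = FALSE]
  cand <- outlier_call(cand, ctrl, q)
  outliers <- cand$gene_id[cand$outlier]
  log$n_outliers <- length(outliers)

  # ML-HKA on outliers (or on all candidates when hka_all is set)
  hka_targets <- if (isTRUE(cfg$hka_all)) cand$gene_id else outliers
  hka_rows <- list(); hka_skips <- list()
  neutral <- if (!is.null(cfg$hka)) .resolve(cfg$hka$neutral_loci, read_hka_loci)
  kdiv <- if (!is.null(cfg$hka)) cfg$hka$k_on_divergence %||% TRUE else TRUE
  n_hap <- nrow(vt$geno)
  for (g in hka_targets) {
    gn <- genes[[g]]
    Dg <- cfg$hka$divergence[[g]]
    if (is.null(neutral) || is.null(Dg)) {
      hka_skips[[g]] <- "no-hka-input"
      next
    }
    cds <- gn$cds
    Sg <- sum(vapply(seq_len(nrow(cds)), function(i) {
      seg_sites(vt_region(vt, gn$contig, cds[i, 1], cds[i, 2])$geno)
    }, integer(1)))
    loci <- rbind(neutral[, c("locus_id", "S", "D", "n")],
                  data.frame(locus_id = g, S = Sg, D = Dg, n = n_hap))
    res <- hka_test(loci, g, k_on_divergence = kdiv)
    hka_rows[[g]] <- data.frame(gene_id = g, S = Sg, D = Dg,
                                k_hat = res$fit1$k_hat[nrow(loci)],
                                T_hat = res$fit1$T_hat,
                                lrt = res$test$lrt_stat, df = res$test$df,
                                p = res$test$p_value)
  }
  hka_tab <- if (length(hka_rows)) do.call(rbind, hka_rows) else NULL
  if (!is.null(hka_tab)) {
    n_tested <- sum(!is.na(cand$beta_std_max))   # Bonferroni over genes scanned
    hka_tab$p_bonferroni <- pmin(1, hka_tab$p * n_tested)
  }

  tracks <- list()
  for (g in outliers) {
    gn <- genes[[g]]
    glen <- gn$span[2] - gn$span[1]
    short <- glen < 4 * win
    tracks[[g]] <- sliding_windows(vt, gn$contig, gn$span, masks,
                                   size = if (short) 500L else win,
                                   step = if (short) 50L else stp)
  }

  sig <- if (!is.null(hka_tab)) hka_tab$gene_id[hka_tab$p < alpha] else character(0)
  ld <- list(); nets <- list()
  for (g in sig) {
    gn <- genes[[g]]
    ld[[g]] <- ld_region(vt, gn$contig, gn$span[1], gn$span[2], lcfg)
    nets[[g]] <- median_joining_network(
      hap_sequences(vt, gn$contig, gn$span[1], gn$span[2]))
  }

  cats <- NULL
  if (!is.null(cfg$categories)) {
    cats <- category_compare(cand, unlist(cfg$categories), ctrl)
  }

  per_gene <- .table1(genes, cand, ctrl, vt, masks, hka_tab)
  report <- structure(list(
    per_gene = per_gene, candidates = cand, controls = ctrl,
    threshold = attr(cand, "threshold"), outliers = outliers,
    hka = hka_tab, hka_skips = unlist(hka_skips), tracks = tracks,
    ld = ld, networks = nets, category_tests = cats, scan = scan,
    theta_map = tm, log = log,
    provenance = list(package = as.character(utils::packageVersion("balsel")),
                      q = q, alpha = alpha, seed = cfg$seed)),
    class = "scan_report")
  if (!is.null(out_dir)) write_tables(report, out_dir)
  report
}

# Table-1-style per-gene summary: gene, CDS length, S, pi, k, p,
# beta_std_max, percentile rank (plus diagnostics)
.table1 <- function(genes, cand, ctrl, vt, masks, hka_tab) {
  rows <- lapply(cand$gene_id, function(g) {
    gn <- genes[[g]]
    Hg <- vt_region(vt, gn$contig, gn$span[1], gn$span[2])$geno
    eff <- effective_length(gn$span, masks, gn$contig)
    S <- seg_sites(Hg)
    pi_s <- if (eff > 0) nucleotide_diversity(Hg, eff) else NA_real_
    hk <- if (!is.null(hka_tab) && g %in% hka_tab$gene_id)
      hka_tab[hka_tab$gene_id == g, ] else NULL
    i <- match(g, cand$gene_id)
    data.frame(gene = g, cds_length = cds_length(gn), S = S, pi = pi_s,
               k = if (is.null(hk)) NA_real_ else hk$k_hat,
               p = if (is.null(hk)) NA_real_ else hk$p,
               beta_std_max = cand$beta_std_max[i],
               percentile_rank = cand$percentile_rank[i],
               n_snps_used = cand$n_snps_used[i],
               outlier = cand$outlier[i], stringsAsFactors = FALSE)
  })
  if (!length(rows))
    return(data.frame(gene = character(0), cds_length = integer(0),
                      S = integer(0), pi = numeric(0), k = numeric(0),
                      p = numeric(0), beta_std_max = numeric(0),
                      percentile_rank = numeric(0), n_snps_used = integer(0),
                      outlier = logical(0)))
  do.call(rbind, rows)
}

#' @export
print.scan_report <- function(x, ...) {
  cat("balancing-selection scan report\n")
  cat(sprintf("  SNPs scored: %d (%d masked)\n", x$log$snps_scored,
              x$log$snps_masked))
  cat(sprintf("  control threshold (beta_std.max %sth pct): %.4g\n",
              x$provenance$q, x$threshold))
  cat(sprintf("  outliers: %s\n",
              if (length(x$outliers)) paste(x$outliers, collapse = ", ")
              else "none"))
  if (!is.null(x$hka)) {
    cat("  ML-HKA:\n")
    print(x$hka[, c("gene_id", "k_hat", "lrt", "p", "p_bonferroni")],
          row.names = FALSE)
  }
  if (!is.null(x$category_tests)) {
    cat("  category tests:\n")
    print(x$category_tests, row.names = FALSE)
  }
  invisible(x)
}

#' Write the report tables of a scan
#'
#' Per-gene summary TSV (Table-1 schema: gene, CDS length, S, pi, k, p,
#' beta_std_max, percentile rank), per-SNP beta track (BED-like TSV), LD
#' blocks (BED), networks (GraphML + haplotype table) and a run log.
#'
#' @param report a `scan_report` (or a list with compatible elements).
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_tables <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(d, f) write.table(d, file.path(out_dir, f), sep = "\t",
                                    quote = FALSE, row.names = FALSE)
  if (!is.null(report$per_gene)) tsv(report$per_gene, "gene_summary.tsv")
  if (!is.null(report$scan)) {
    tr <- report$scan
    out <- data.frame(contig = tr$contig, start = tr$pos0, end = tr$pos0 + 1L,
                      folded_freq = tr$folded_freq, beta_raw = tr$beta_raw,
                      beta_std = tr$beta_std,
                      mask_reason = ifelse(is.na(tr$mask_reason), ".",
                                           tr$mask_reason))
    tsv(out, "beta_track.tsv")
  }
  if (!is.null(report$hka)) tsv(report$hka, "hka.tsv")
  for (g in names(report$tracks %||% list()))
    tsv(report$tracks[[g]], paste0("track_", g, ".tsv"))
  for (g in names(report$ld %||% list())) {
    tsv(report$ld[[g]]$pairs, paste0("ld_pairs_", g, ".tsv"))
    bl <- report$ld[[g]]$blocks
    if (nrow(bl)) tsv(bl, paste0("ld_blocks_", g, ".tsv"))
  }
  for (g in names(report$networks %||% list())) {
    write_graphml(report$networks[[g]], file.path(out_dir,
                                                  paste0("network_", g, ".graphml")))
    write_hap_table(report$networks[[g]],
                    file.path(out_dir, paste0("haplotypes_", g, ".tsv")))
  }
  if (!is.null(report$category_tests))
    tsv(report$category_tests, "category_tests.tsv")
  if (!is.null(report$log)) {
    lg <- data.frame(stage = names(report$log),
                     count = unlist(report$log, use.names = FALSE))
    tsv(lg, "run_log.tsv")
  }
  invisible(out_dir)
}
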