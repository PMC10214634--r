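#' Configuration for a synthetic genome
#'
#' Defaults emulate the structure of the study system this package targets:
#' 62 haplotypes (31 diploids), one gene per 10 kb tile, per-bp theta
#' heterogeneous across tiles (log-normal around `theta_bp`), a large
#' control-gene set beside a small candidate set, a minority of candidate
#' loci carrying an old balanced polymorphism, and outgroup divergence at
#' roughly mouse-to-vole distance (T = 2 in units of 2N generations).
#'
#' @param n_control,n_candidate numbers of control and candidate genes.
#' @param frac_balanced fraction of candidate genes simulated under the
#'   balanced model.
#' @param n_hap haplotype count.
#' @param theta_bp median per-bp theta across tiles.
#' @param sigma_log log-normal sd of per-tile theta.
#' @param tile tile length in bp (one gene per tile).
#' @param gene_len_range min/max gene length in bp (uniform draw).
#' @param contig contig name used throughout.
#' @param f_eq,m_switch,t_balance,T_div balanced-model parameters, see
#'   [sim_params()].
#' @param repeat_rate,gap_rate,indel_rate expected mask features per tile.
#' @return a `genome_config` list.
#' @export
genome_config <- function(n_control = 99L, n_candidate = 5L,
                          frac_balanced = 0, n_hap = 62L, theta_bp = 0.005,
                          sigma_log = 0.5, tile = 10000L,
                          gene_len_range = c(1000L, 10000L),
                          contig = "ctg1", f_eq = 0.5, m_switch = 0.05,
                          t_balance = 8, T_div = 2,
                          repeat_rate = 2, gap_rate = 0.3, indel_rate = 0.5) {
  structure(as.list(environment()), class = "genome_config")
}

#' Simulate a multi-gene genome
#'
#' One gene per non-overlapping 10 kb tile on a single contig.  Each tile is
#' one coalescent locus (neutral, or balanced for flagged candidates) whose
#' per-bp theta is drawn log-normal with median `theta_bp`; the gene span is
#' a sub-interval of the tile.  Repeat/gap intervals and indel points are
#' scattered per tile.  The truth table records each gene's role, balanced
#' flag and true tile theta.
#'
#' @param config a [genome_config()].
#' @param seed RNG seed (full determinism for a fixed seed).
#' @param out_dir optional directory; when given, VCF/GFF3/BED/truth TSV are
#'   written there via the io layer.
#' @return a list (class `sim_genome`): `variants` ([variant_table()]),
#'   `genes` (list of [gene_model()]), `masks` ([mask_set()]), `truth`
#'   (data.frame), `candidates`/`controls` (gene-id vectors), `config`.
#' @export
simulate_genome <- function(config = genome_config(), seed = 1L,
                            out_dir = NULL) {
  set.seed(seed)
  cfg <- config
  n_gene <- cfg$n_control + cfg$n_candidate
  roles <- sample(c(rep("candidate", cfg$n_candidate),
                    rep("control", cfg$n_control)))
  ids <- character(n_gene)
  ids[roles == "candidate"] <- sprintf("cand_%02d", seq_len(cfg$n_candidate))
  ids[roles == "control"] <- sprintf("ctrl_%03d", seq_len(cfg$n_control))
  n_bal_target <- round(cfg$frac_balanced * cfg$n_candidate)
  bal_ids <- if (n_bal_target > 0)
    sprintf("cand_%02d", sample.int(cfg$n_candidate, n_bal_target)) else character(0)

  theta_tile <- rlnorm(n_gene, meanlog = log(cfg$theta_bp), sdlog = cfg$sigma_log)
  pos_all <- integer(0); geno_all <- NULL
  genes <- vector("list", n_gene)
  rep_iv <- NULL; gap_iv <- NULL; ind_iv <- NULL
  truth <- data.frame(gene_id = ids, role = roles, balanced = ids %in% bal_ids,
                      tile_start = (seq_len(n_gene) - 1L) * cfg$tile,
                      theta_bp = theta_tile, stringsAsFactors = FALSE)
  for (i in seq_len(n_gene)) {
    t0 <- (i - 1L) * cfg$tile
    glen <- as.integer(round(runif(1, cfg$gene_len_range[1],
                                   min(cfg$gene_len_range[2], cfg$tile))))
    gstart <- t0 + as.integer((cfg$tile - glen) %/% 2)
    gspan <- c(gstart, gstart + glen)
    genes[[i]] <- gene_model(ids[i], cfg$contig, "+", gspan,
                             exons = matrix(gspan, ncol = 2),
                             cds = matrix(gspan, ncol = 2))
    prm <- sim_params(n_hap = cfg$n_hap, locus_len = cfg$tile,
                      theta_bp = theta_tile[i],
                      model = if (truth$balanced[i]) "balanced" else "neutral",
                      f_eq = cfg$f_eq, m_switch = cfg$m_switch,
                      t_balance = cfg$t_balance, T_div = cfg$T_div)
    loc <- if (truth$balanced[i]) simulate_balanced_locus(prm)
           else simulate_neutral_locus(prm)
    keep <- colSums(loc$haplotypes) > 0 & colSums(loc$haplotypes) < cfg$n_hap
    H <- loc$haplotypes[, keep, drop = FALSE]
    pos_all <- c(pos_all, loc$positions[keep] + t0)
    geno_all <- if (is.null(geno_all)) H else cbind(geno_all, H)
    # masks: a few repeats/gaps, Poisson indel points
    for (r in seq_len(rpois(1, cfg$repeat_rate))) {
      s <- t0 + sample.int(cfg$tile - 500L, 1)
      rep_iv <- rbind(rep_iv, c(s, s + sample(100:500, 1)))
    }
    for (r in seq_len(rpois(1, cfg$gap_rate))) {
      s <- t0 + sample.int(cfg$tile - 300L, 1)
      gap_iv <- rbind(gap_iv, c(s, s + sample(100:300, 1)))
    }
    for (r in seq_len(rpois(1, cfg$indel_rate))) {
      s <- t0 + sample.int(cfg$tile, 1) - 1L
      ind_iv <- rbind(ind_iv, c(s, s + 1L))
    }
  }
  n_dip <- cfg$n_hap %/% 2
  rownames(geno_all) <- as.vector(rbind(paste0(sprintf("S%02d", 1:n_dip), "_1"),
                                        paste0(sprintf("S%02d", 1:n_dip), "_2")))
  ref <- sample(.SNP_ALLELES, length(pos_all), replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(.SNP_ALLELES, r), 1), "")
  vt <- variant_table(rep(cfg$contig, length(pos_all)), pos_all, ref, alt,
                      geno_all)
  masks <- mask_set(
    repeats = if (is.null(rep_iv)) NULL else setNames(list(rep_iv), cfg$contig),
    gaps = if (is.null(gap_iv)) NULL else setNames(list(gap_iv), cfg$contig),
    indels = if (is.null(ind_iv)) NULL else setNames(list(ind_iv), cfg$contig))
  names(genes) <- ids
  out <- structure(list(variants = vt, genes = genes, masks = masks,
                        truth = truth,
                        candidates = ids[roles == "candidate"],
                        controls = ids[roles == "control"],
                        config = cfg, seed = seed),
                   class = "sim_genome")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_vcf(vt, file.path(out_dir, "variants.vcf"))
    write_gff(genes, file.path(out_dir, "genes.gff3"))
    write_bed(masks$repeats, file.path(out_dir, "repeats.bed"))
    write_bed(masks$gaps, file.path(out_dir, "gaps.bed"))
    write_bed(masks$indels, file.path(out_dir, "indels.bed"))
    write.table(truth, file.path(out_dir, "truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  out
}
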