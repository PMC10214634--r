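# Coalescent synthetic-data generators.
#
# The neutral model is the standard Hudson coalescent without recombination:
# while k lineages remain, an exponential waiting time with rate C(k,2)
# elapses and a uniform pair coalesces; mutations are Poisson(theta/2 * total
# branch length), placed uniformly on branches under infinite sites.  The
# balanced model is a two-class structured coalescent (class sizes f_eq and
# 1 - f_eq): within a class of relative size f, pairs coalesce at rate
# C(k,2)/f; each lineage exchanges class at rate m_switch; at time t_balance
# (units of 2N generations) all lineages merge into one panmictic class.
# This is the standard strong-balancing-selection approximation producing
# two deep haplotype clades at intermediate frequency.

#' Simulation parameters
#'
#' @param n_hap haplotype count (default 62 = 31 diploids).
#' @param locus_len locus length in bp.
#' @param theta_bp per-bp population mutation rate; the per-locus rate is
#'   `theta_bp * locus_len`.
#' @param model "neutral" or "balanced".
#' @param f_eq balanced-class equilibrium frequency in (0,1).
#' @param m_switch scaled class-exchange rate per lineage.
#' @param t_balance age of the balanced polymorphism (units of 2N gens).
#' @param T_div outgroup divergence time (same units).
#' @param seed optional RNG seed applied by the simulators.
#' @return a `sim_params` list.
#' @export
sim_params <- function(n_hap = 62L, locus_len = 2000L, theta_bp = 0.005,
                       model = c("neutral", "balanced"), f_eq = 0.5,
                       m_switch = 0.05, t_balance = 8, T_div = 2,
                       seed = NULL) {
  model <- match.arg(model)
  stopifnot(n_hap >= 2, locus_len >= 1, theta_bp > 0,
            f_eq > 0, f_eq < 1, m_switch >= 0, t_balance >= 0, T_div >= 0)
  structure(list(n_hap = as.integer(n_hap), locus_len = as.integer(locus_len),
                 theta_bp = theta_bp, model = model, f_eq = f_eq,
                 m_switch = m_switch, t_balance = t_balance, T_div = T_div,
                 seed = seed),
            class = "sim_params")
}

# structured two-class coalescent tree; f = class-1 relative size, m = switch
# rate, tb = merge time (0 = panmictic from the start).  Returns branches as
# tip-index sets with lengths, plus the initial class labels.
.sim_tree <- function(n, f = 0.5, m = 0, tb = 0, cls = NULL) {
  if (is.null(cls)) cls <- rep(1L, n)
  tips <- as.list(seq_len(n))
  birth <- numeric(n)
  cl <- cls
  t <- 0
  br_tips <- vector("list", 2 * n - 2)
  br_len <- numeric(2 * n - 2)
  bi <- 0L
  k <- n
  while (k > 1) {
    if (t >= tb) {                       # panmictic phase
      t <- t + rexp(1, k * (k - 1) / 2)
      pair <- sample.int(k, 2)
    } else {
      kA <- sum(cl == 1L); kB <- k - kA
      rA <- if (kA >= 2) kA * (kA - 1) / 2 / f else 0
      rB <- if (kB >= 2) kB * (kB - 1) / 2 / (1 - f) else 0
      rM <- m * k
      tot <- rA + rB + rM
      if (tot == 0) { t <- tb; next }
      dt <- rexp(1, tot)
      if (t + dt >= tb) { t <- tb; next } # structure dissolves
      t <- t + dt
      u <- runif(1) * tot
      if (u < rA) {
        pair <- sample(which(cl == 1L), 2)
      } else if (u < rA + rB) {
        pair <- sample(which(cl == 2L), 2)
      } else {
        j <- sample.int(k, 1)
        cl[j] <- 3L - cl[j]
        next
      }
    }
    for (j in pair) {
      bi <- bi + 1L
      br_tips[[bi]] <- tips[[j]]
      br_len[bi] <- t - birth[j]
    }
    merged <- c(tips[[pair[1]]], tips[[pair[2]]])
    keep <- setdiff(seq_len(k), pair)
    tips <- c(tips[keep], list(merged))
    birth <- c(birth[keep], t)
    cl <- c(cl[keep], cl[pair[1]])
    k <- k - 1L
  }
  list(tips = br_tips, len = br_len, cls = cls)
}

# drop mutations on a tree: haplotype matrix + distinct integer positions
.mutate <- function(tree, n, theta_locus, locus_len) {
  total_len <- sum(tree$len)
  S <- rpois(1, theta_locus / 2 * total_len)
  S <- min(S, locus_len)                  # infinite sites on a finite grid
  H <- matrix(0L, n, S)
  if (S > 0) {
    b <- sample.int(length(tree$len), S, replace = TRUE, prob = tree$len)
    for (j in seq_len(S)) H[tree$tips[[b[j]]], j] <- 1L
    pos <- sort(sample.int(locus_len, S)) - 1L
  } else {
    pos <- integer(0)
  }
  list(H = H, pos = pos, total_len = total_len)
}

.new_sim_locus <- function(H, pos, total_len, cls, D) {
  structure(list(haplotypes = H, positions = pos, tree_total_len = total_len,
                 class_labels = cls, divergent_sites = D),
            class = "sim_locus")
}

#' Simulate a neutral locus
#'
#' Hudson coalescent without recombination; mutations under infinite sites,
#' positions uniform on the locus.  The outgroup divergence count is drawn
#' from the HKA Poisson model, `D ~ Poisson(theta_locus * (T_div + 1))` (one
#' coalescent unit of ancestral depth on top of the split time).
#'
#' @param params a [sim_params()] with `model = "neutral"`.
#' @param seed optional seed (overrides `params$seed`).
#' @return a `sim_locus`: haplotype matrix, positions, total branch length,
#'   `class_labels = NULL`, divergence count.
#' @export
simulate_neutral_locus <- function(params, seed = NULL) {
  stopifnot(params$model == "neutral")
  seed <- seed %||% params$seed
  if (!is.null(seed)) set.seed(seed)
  theta <- params$theta_bp * params$locus_len
  tr <- .sim_tree(params$n_hap)
  mt <- .mutate(tr, params$n_hap, theta, params$locus_len)
  D <- rpois(1, theta * (params$T_div + 1))
  .new_sim_locus(mt$H, mt$pos, mt$total_len, NULL, D)
}

#' Simulate a locus carrying an old balanced polymorphism
#'
#' Two-class structured coalescent (see file header): haplotypes are assigned
#' to the balanced class with probability `f_eq`, coalesce only within class
#' (rate scaled by class size), exchange classes at rate `m_switch`, and the
#' structure dissolves at `t_balance`.  One extra "balanced site" column
#' encoding the class assignment is inserted at the locus midpoint when both
#' classes are represented in the sample.
#'
#' @param params a [sim_params()] with `model = "balanced"`.
#' @param seed optional seed.
#' @return a `sim_locus` with per-haplotype `class_labels`.
#' @export
simulate_balanced_locus <- function(params, seed = NULL) {
  stopifnot(params$model == "balanced")
  seed <- seed %||% params$seed
  if (!is.null(seed)) set.seed(seed)
  n <- params$n_hap
  theta <- params$theta_bp * params$locus_len
  cls <- ifelse(runif(n) < params$f_eq, 1L, 2L)
  tr <- .sim_tree(n, f = params$f_eq, m = params$m_switch,
                  tb = params$t_balance, cls = cls)
  mt <- .mutate(tr, n, theta, params$locus_len)
  H <- mt$H; pos <- mt$pos
  bal_col <- as.integer(cls == 1L)
  if (sum(bal_col) > 0 && sum(bal_col) < n) {
    bp <- as.integer(params$locus_len %/% 2)
    if (bp %in% pos) {                    # midpoint taken: displace the old site
      j <- which(pos == bp)
      H <- H[, -j, drop = FALSE]; pos <- pos[-j]
    }
    ins <- findInterval(bp, pos)
    H <- cbind(H[, seq_len(ins), drop = FALSE], bal_col,
               H[, seq_len(ncol(H)) > ins, drop = FALSE])
    pos <- append(pos, bp, after = ins)
    dimnames(H) <- NULL
  }
  D <- rpois(1, theta * (params$T_div + 1))
  .new_sim_locus(H, as.integer(pos), mt$total_len, cls, D)
}

#' Simulate a linkage-equilibrium window of SNP frequencies
#'
#' The free-recombination limit of the neutral model: the segregating-site
#' count is Poisson(`theta_locus * a_n`) and folded frequency classes are
#' drawn independently from the neutral folded spectrum
#' (P(minor count = k) proportional to `1/k + 1/(n-k)`, `2/n` at `k = n/2`).
#' Each site's column is constructed by assigning the minor allele to a
#' uniform random haplotype subset.  This is the null against which the beta
#' statistic is calibrated to zero mean (see the methods vignette: under a
#' single shared genealogy neighbouring frequencies are correlated with the
#' core and beta has a positive neutral mean, which the empirical
#' control-gene null absorbs).
#'
#' @param params a [sim_params()].
#' @param seed optional seed.
#' @return a `sim_locus` (tree_total_len is `NA`: no single genealogy).
#' @export
simulate_le_window <- function(params, seed = NULL) {
  seed <- seed %||% params$seed
  if (!is.null(seed)) set.seed(seed)
  n <- params$n_hap
  theta <- params$theta_bp * params$locus_len
  ks <- seq_len(floor(n / 2))
  ek <- ifelse(ks < n / 2, 1 / ks + 1 / (n - ks), 2 / n)
  S <- rpois(1, theta * harmonic_a(n))
  S <- min(S, params$locus_len)
  H <- matrix(0L, n, S)
  if (S > 0) {
    kdraw <- sample(ks, S, replace = TRUE, prob = ek)
    for (j in seq_len(S)) H[sample.int(n, kdraw[j]), j] <- 1L
    pos <- sort(sample.int(params$locus_len, S)) - 1L
  } else {
    pos <- integer(0)
  }
  D <- rpois(1, theta * (params$T_div + 1))
  .new_sim_locus(H, pos, NA_real_, NULL, D)
}

#' Simulate an HKA polymorphism/divergence dataset
#'
#' Counts are drawn directly from the Poisson model the ML-HKA fit assumes,
#' giving a clean parameter-recovery loop:
#' `S_l ~ Poisson(k_l * theta_l * a_n)` and
#' `D_l ~ Poisson(theta_l * (T + k_l))` when `k_on_divergence = TRUE`
#' (the selection parameter deepens the locus genealogy, inflating both
#' polymorphism and the ancestral share of divergence), else
#' `D_l ~ Poisson(theta_l * (T + 1))`.
#'
#' @param theta per-locus theta vector (> 0).
#' @param T_div divergence-time parameter (>= 0).
#' @param k per-locus selection parameter (recycled; 1 = neutral).
#' @param n haplotype sample size (recycled).
#' @param k_on_divergence whether k also scales the ancestral component of
#'   divergence (default TRUE, matching the default likelihood).
#' @param L aligned length bookkeeping column (recycled; `NA` allowed).
#' @param seed optional seed.
#' @return a `data.frame` of HKA loci: locus_id, S, D, n, L, is_candidate.
#' @export
simulate_hka_dataset <- function(theta, T_div, k = 1, n = 62L,
                                 k_on_divergence = TRUE, L = NA_integer_,
                                 seed = NULL) {
  stopifnot(all(theta > 0), T_div >= 0, all(k > 0))
  if (!is.null(seed)) set.seed(seed)
  nl <- length(theta)
  k <- rep_len(k, nl); n <- rep_len(as.integer(n), nl); L <- rep_len(L, nl)
  a <- vapply(n, harmonic_a, numeric(1))
  S <- rpois(nl, k * theta * a)
  Dmean <- if (k_on_divergence) theta * (T_div + k) else theta * (T_div + 1)
  D <- rpois(nl, Dmean)
  data.frame(locus_id = sprintf("locus_%02d", seq_len(nl)), S = S, D = D,
             n = n, L = L, is_candidate = k != 1,
             stringsAsFactors = FALSE)
}
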