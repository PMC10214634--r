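test_that("D-prime matches hand counts and the contingency oracle", {
  a <- rep(c(1L, 0L), each = 5)
  d <- dprime(a, a)
  expect_equal(d$D, 0.25)
  expect_equal(d$Dprime, 1)
  expect_equal(d$r2, 1)
  # independent sites with p_AB = p_A p_B exactly
  hA <- c(1, 1, 0, 0); hB <- c(1, 0, 1, 0)
  d2 <- dprime(hA, hB)
  expect_equal(d2$D, 0)
  expect_equal(d2$Dprime, 0)
  expect_error(dprime(rep(1L, 4), hB), "monomorphic")

  # exhaustive 2x2 contingency oracle on random phased pairs
  set.seed(51)
  for (r in 1:100) {
    n <- sample(c(10, 30, 62), 1)
    hA <- rbinom(n, 1, runif(1, 0.2, 0.8))
    hB <- rbinom(n, 1, runif(1, 0.2, 0.8))
    if (length(unique(hA)) < 2 || length(unique(hB)) < 2) next
    pA <- mean(hA); pB <- mean(hB)
    tab <- table(factor(hA, 0:1), factor(hB, 0:1)) / n
    D <- tab["1", "1"] - pA * pB
    Dmax <- if (D > 0) min(pA * (1 - pB), (1 - pA) * pB)
            else min(pA * pB, (1 - pA) * (1 - pB))
    d3 <- dprime(hA, hB)
    expect_equal(d3$D, unname(D), tolerance = 1e-12)
    expect_equal(d3$Dprime, if (Dmax == 0) 0 else unname(abs(D) / Dmax),
                 tolerance = 1e-12)
    expect_gte(d3$Dprime, 0); expect_lte(d3$Dprime, 1 + 1e-12)
  }
})

test_that("D-prime confidence bounds behave like a concentrating likelihood", {
  a <- rep(c(1L, 0L), each = 50)
  ci <- dprime_ci(a, a)
  expect_gt(ci[["ci_low"]], 0.9)
  set.seed(52)
  for (r in 1:20) {
    hA <- rbinom(40, 1, 0.5); hB <- rbinom(40, 1, 0.5)
    if (length(unique(hA)) < 2 || length(unique(hB)) < 2) next
    ci <- dprime_ci(hA, hB)
    dp <- dprime(hA, hB)$Dprime
    expect_lte(ci[["ci_low"]], dp + 1e-9)
    expect_gte(ci[["ci_high"]], dp - 1e-9)
    fine <- dprime_ci(hA, hB, grid_n = 2001)
    expect_lt(max(abs(ci - fine)), 0.01)
  }
})

test_that("Gabriel blocks match an independent all-intervals oracle", {
  set.seed(53)
  # perfect LD region: one block spanning all SNPs
  core <- rep(c(1L, 0L), each = 40)
  H <- matrix(rep(core, 6), ncol = 6)
  pr <- dprime_pairs(H, pos = seq(0, 5000, by = 1000))
  bl <- gabriel_blocks(pr)
  expect_equal(nrow(bl), 1L)
  expect_equal(c(bl$first, bl$last), c(1L, 6L))

  # all pairs in strong recombination: no blocks
  H2 <- sapply(1:6, function(j) rbinom(80, 1, 0.5))
  pr2 <- dprime_pairs(H2, pos = seq(0, 5000, by = 1000))
  pr2$ci_low <- 0.01; pr2$ci_high <- 0.2
  expect_equal(nrow(gabriel_blocks(pr2)), 0L)

  # oracle: independent re-derivation over every interval, greedy longest
  gabriel_oracle <- function(pairs, cfg = ld_block_config()) {
    cls <- ifelse(pairs$ci_low >= cfg$strong_low &
                    pairs$ci_high >= cfg$strong_high, 1,
                  ifelse(pairs$ci_high < cfg$recomb_high, -1, 0))
    idx <- sort(unique(c(pairs$i, pairs$j)))
    pos <- integer(max(idx)); pos[pairs$i] <- pairs$pos_a
    pos[pairs$j] <- pairs$pos_b
    ok <- NULL
    for (a in idx) for (b in idx[idx > a]) {
      sel <- pairs$i >= a & pairs$j <= b
      ni <- sum(sel & cls != 0); ns <- sum(sel & cls == 1)
      if (ni > 0 && ns > 0 && ns / ni >= cfg$frac_strong)
        ok <- rbind(ok, c(a, b, pos[b] - pos[a]))
    }
    if (is.null(ok)) return(NULL)
    ok <- ok[order(-ok[, 3], -(ok[, 2] - ok[, 1]), ok[, 1]), , drop = FALSE]
    used <- rep(FALSE, max(idx)); res <- NULL
    for (r in seq_len(nrow(ok))) {
      if (any(used[ok[r, 1]:ok[r, 2]])) next
      used[ok[r, 1]:ok[r, 2]] <- TRUE
      res <- rbind(res, ok[r, 1:2])
    }
    res[order(res[, 1]), , drop = FALSE]
  }
  for (rep_i in 1:10) {
    m <- 12
    pos <- sort(sample.int(20000, m))
    pairs <- expand.grid(i = 1:m, j = 1:m)
    pairs <- pairs[pairs$i < pairs$j, ]
    pairs$pos_a <- pos[pairs$i]; pairs$pos_b <- pos[pairs$j]
    pairs$ci_low <- runif(nrow(pairs), 0, 1)
    pairs$ci_high <- pmin(1, pairs$ci_low + runif(nrow(pairs), 0, 0.4))
    got <- gabriel_blocks(pairs)
    want <- gabriel_oracle(pairs)
    if (is.null(want)) {
      expect_equal(nrow(got), 0L)
    } else {
      expect_equal(unname(as.matrix(got[, c("first", "last")])),
                   unname(want))
    }
  }
})

test_that("median-joining network handles degenerate and hand-solved cases", {
  n1 <- median_joining_network(rep("0101", 7))
  expect_equal(nrow(n1$nodes), 1L)
  expect_equal(nrow(n1$edges), 0L)
  expect_equal(n1$nodes$freq, 7L)

  n2 <- median_joining_network(c("00", "11"))
  expect_equal(nrow(n2$nodes), 2L)
  expect_equal(n2$edges$weight, 2L)

  n3 <- median_joining_network(c("000", "011", "101"))
  expect_setequal(n3$nodes$seq, c("000", "011", "101", "001"))
  expect_equal(sort(n3$edges$weight), c(1L, 1L, 1L))
  expect_equal(sum(n3$nodes$freq), 3L)
})

test_that("median network achieves the Steiner minimum on small cases", {
  # exhaustive Steiner enumeration: try every added vertex set over {0,1}^L
  steiner_min <- function(seqs) {
    L <- nchar(seqs[1])
    all_seqs <- apply(expand.grid(rep(list(c("0", "1")), L)), 1, paste,
                      collapse = "")
    extra <- setdiff(all_seqs, seqs)
    best <- Inf
    subsets <- unlist(lapply(0:2, function(k)
      combn(extra, k, simplify = FALSE)), recursive = FALSE)
    for (ss in subsets) {
      nodes <- c(seqs, ss)
      M <- do.call(rbind, strsplit(nodes, ""))
      d <- as.matrix(dist(apply(M, 2, as.integer), method = "manhattan"))
      g <- igraph::graph_from_adjacency_matrix(d, mode = "undirected",
                                               weighted = TRUE)
      w <- sum(igraph::E(igraph::mst(g))$weight)
      best <- min(best, w)
    }
    best
  }
  seqs <- c("000", "011", "101")
  net <- median_joining_network(seqs)
  g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                     vertices = net$nodes)
  total <- sum(igraph::E(igraph::mst(g, weights = igraph::E(g)$weight))$weight)
  expect_equal(total, steiner_min(seqs))   # = 3 via the 001 median

  # MSN edges always include every minimum-spanning-tree edge set
  set.seed(54)
  for (r in 1:5) {
    seqs <- apply(matrix(rbinom(4 * 6, 1, 0.5), 4), 1, paste, collapse = "")
    net <- median_joining_network(seqs)
    expect_equal(sum(net$nodes$freq), 4L)
    g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                       vertices = net$nodes)
    expect_true(igraph::is_connected(g))
  }
})

test_that("two-group separation cuts the deepest bridge", {
  star <- median_joining_network(c("0000", "1000", "0100", "0010"))
  expect_equal(two_group_separation(star)$bridge_weight, 1)
  two <- median_joining_network(c(rep("0000000000", 6), rep("1111111111", 4)))
  sep <- two_group_separation(two)
  expect_equal(sep$bridge_weight, 10)
  expect_equal(sep$group_freqs, c(6, 4))
  one <- median_joining_network(rep("01", 3))
  expect_true(is.na(two_group_separation(one)$bridge_weight))
})

test_that("network groups recover the true allelic classes of balanced loci", {
  # slow class exchange: with appreciable m_switch the sampled labels and
  # the genealogy genuinely disagree (switched lineages), which is not the
  # network property under test
  set.seed(55)
  p <- sim_params(n_hap = 30, locus_len = 1000, theta_bp = 0.005,
                  model = "balanced", f_eq = 0.5, t_balance = 8,
                  m_switch = 0.01)
  hits <- replicate(100, {
    l <- simulate_balanced_locus(p)
    cl <- l$class_labels
    if (length(unique(cl)) < 2 || ncol(l$haplotypes) < 2) return(NA)
    seqs <- apply(l$haplotypes, 1, paste, collapse = "")
    net <- median_joining_network(seqs)
    sep <- two_group_separation(net)
    if (is.null(sep$membership)) return(NA)
    side <- sep$membership[match(seqs, net$nodes$seq)]
    agree <- max(mean((side == 1) == (cl == 1L)),
                 mean((side == 1) == (cl == 2L)))
    agree == 1
  })
  expect_gte(mean(hits, na.rm = TRUE), 0.85)
})
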