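test_that("folded frequency and similarity kernel follow their definitions", {
  expect_equal(folded_freq(40, 62), 22 / 62, tolerance = 1e-12)
  expect_equal(folded_freq(31, 62), 0.5)
  expect_error(folded_freq(62, 62), "monomorphic")
  expect_error(folded_freq(0, 62), "monomorphic")

  expect_equal(similarity(0.3, 0.3), 1)
  expect_equal(similarity(0.5, 0.0), 0)   # maximal folded dissimilarity
  expect_equal(similarity(0.2, 0.4, p = 2), 0.36, tolerance = 1e-12)
})

test_that("beta is positive when neighbours cluster at the core frequency", {
  cfg <- beta_config()
  n <- 62
  x <- rep(0.3, 13)                       # core + 12 neighbours, all identical
  expect_gt(beta1(x, core = 1, n, cfg), 0)
  # empty window is flagged missing, not an error
  expect_true(is.na(beta1(0.3, core = 1, n, cfg)))
})

test_that("beta has mean zero over linkage-equilibrium neutral windows", {
  set.seed(31)
  cfg <- beta_config()
  p <- sim_params(n_hap = 62, locus_len = 2000, theta_bp = 0.005) # theta_win 10
  vals <- replicate(800, {
    H <- simulate_le_window(p)$haplotypes
    cs <- colSums(H)
    x <- pmin(cs, 62 - cs) / 62
    x <- x[x >= cfg$maf_min]
    if (length(x) < 2) return(c(NA, NA))
    i <- sample.int(length(x), 1)
    A <- sum(similarity(balsel:::beta_consts(62, 0.15)$x, x[i]) *
               balsel:::beta_consts(62, 0.15)$ek)
    c(beta = beta1(x, i, 62, cfg),
      theta_b = sum(similarity(x[-i], x[i])) / A)
  })
  b <- vals[1, !is.na(vals[1, ])]
  expect_lt(abs(mean(b)), 3 * sd(b) / sqrt(length(b)))
  # the similarity-weighted estimator alone recovers theta minus the
  # removed core's expected contribution 1/a'
  tb <- vals[2, !is.na(vals[2, ])]
  aprime <- balsel:::beta_consts(62, 0.15)$aprime
  expect_lt(abs(mean(tb) - (10 - 1 / aprime)), 3 * sd(tb) / sqrt(length(tb)))
})

test_that("standardisation divides by the window mutation supply", {
  expect_equal(standardize(5, 0.005, 2000), 0.5)
  expect_true(is.na(standardize(5, NA_real_, 2000)))
  expect_true(is.na(standardize(5, 0.005, 0)))
  b <- runif(20, -2, 8)
  expect_equal(standardize(b, 0.01, 1500), standardize(b, 0.005, 1500) / 2,
               tolerance = 1e-12)
})

test_that("indel masking flags by distance and is monotone in the radius", {
  res <- data.frame(contig = "c1", pos0 = c(5800L, 6100L),
                    folded_freq = 0.3, beta_raw = 1, beta_std = 1,
                    masked = FALSE, mask_reason = NA_character_)
  m <- mask_set(indels = list(c1 = rbind(c(5000L, 5001L))))
  out <- mask_near_indels(res, m, 1000L)
  expect_equal(out$masked, c(TRUE, FALSE))             # 800 <= 1000 < 1100
  expect_equal(out$mask_reason[1], "indel")

  set.seed(33)
  pos <- sort(sample.int(20000, 10))
  res10 <- data.frame(contig = "c1", pos0 = pos, folded_freq = 0.3,
                      beta_raw = 1, beta_std = 1, masked = FALSE,
                      mask_reason = NA_character_)
  ind <- 9000L
  m2 <- mask_set(indels = list(c1 = rbind(c(ind, ind + 1L))))
  out10 <- mask_near_indels(res10, m2, 1000L)
  expect_equal(out10$masked, abs(pos - ind) <= 1000 | abs(pos - ind - 1) < 1000)
  for (r in c(500L, 1000L, 2000L, 5000L)) {
    small <- mask_near_indels(res10, m2, r)
    big <- mask_near_indels(res10, m2, r + 500L)
    expect_true(all(big$masked[small$masked]))         # enlarging never unmasks
  }
})

test_that("gene maxima respect masks and half-open spans", {
  gn <- gene_model("g", "c1", "+", c(100L, 500L),
                   exons = rbind(c(100L, 500L)))
  res <- data.frame(contig = "c1", pos0 = c(150L, 200L, 300L, 499L, 500L),
                    folded_freq = 0.3,
                    beta_raw = 1,
                    beta_std = c(1.2, 7.9, 3.3, 9.9, 50),
                    masked = c(FALSE, FALSE, FALSE, TRUE, FALSE),
                    mask_reason = c(NA, NA, NA, "indel", NA))
  s <- gene_beta_max(gn, res)
  expect_equal(s$beta_std_max, 7.9)        # 9.9 masked, 50 outside half-open span
  expect_equal(s$n_snps_used, 3L)
  res$masked <- TRUE
  s2 <- gene_beta_max(gn, res)
  expect_true(is.na(s2$beta_std_max))
  expect_equal(s2$n_snps_used, 0L)
})

test_that("outlier calling uses the nearest-rank control percentile", {
  ctrl <- data.frame(gene_id = paste0("c", 1:100), beta_std_max = 1:100,
                     n_snps_used = 5L)
  cand <- data.frame(gene_id = c("a", "b", "c"),
                     beta_std_max = c(95, 94.5, 0.5), n_snps_used = 5L)
  out <- outlier_call(cand, ctrl, q = 95)
  expect_equal(attr(out, "threshold"), 95)
  expect_equal(out$outlier, c(TRUE, FALSE, FALSE))     # ties count as outliers
  expect_equal(out$percentile_rank, c(94, 94, 0))
  expect_error(outlier_call(cand, ctrl[1:10, ], 95), "20 control")

  # brute-force sort-and-threshold oracle on random inputs
  set.seed(34)
  ctrl2 <- data.frame(gene_id = paste0("k", 1:200),
                      beta_std_max = rexp(200, 0.2), n_snps_used = 5L)
  cand2 <- data.frame(gene_id = paste0("q", 1:5),
                      beta_std_max = rexp(5, 0.1), n_snps_used = 5L)
  out2 <- outlier_call(cand2, ctrl2, 95)
  thr_oracle <- sort(ctrl2$beta_std_max)[ceiling(0.95 * 200)]
  expect_equal(out2$outlier, cand2$beta_std_max >= thr_oracle)
})

test_that("beta_scan pipes theta tiles, masks and reasons coherently", {
  g <- simulate_genome(genome_config(n_control = 8, n_candidate = 2,
                                     n_hap = 62), seed = 35)
  tm <- theta_map(g$variants, g$masks)
  sc <- beta_scan(g$variants, g$masks, tm)
  expect_true(all(sc$folded_freq >= 0.15))
  expect_true(all(is.na(sc$beta_std[sc$masked])))
  expect_true(all(!is.na(sc$beta_std[!sc$masked])))
  # every unmasked value re-derives from its tile and window
  i <- which(!sc$masked)[c(10, 100, 400)]
  th <- theta_lookup(tm, "ctg1", sc$pos0[i])
  eff <- 2000 - balsel:::iv_masked_len_vec(sc$pos0[i] - 1000,
                                           sc$pos0[i] + 1000,
                                           balsel:::.ef_masks(g$masks, "ctg1"))
  expect_equal(sc$beta_std[i], sc$beta_raw[i] / (th * eff), tolerance = 1e-12)
  # indel-masked SNPs are within the radius of a real indel
  im <- sc$pos0[sc$mask_reason %in% "indel"]
  if (length(im)) {
    iv <- g$masks$indels$ctg1
    dmin <- vapply(im, function(p) min(abs(p - iv[, 1])), numeric(1))
    expect_true(all(dmin <= 1000))
  }
})
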