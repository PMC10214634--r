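test_that("segregating sites are counted by hand-checkable rules", {
  expect_equal(seg_sites(matrix(0L, 3, 3)), 0L)
  H <- rbind(c(0L, 0L, 1L, 0L), c(1L, 0L, 1L, 1L))
  expect_equal(seg_sites(H), 2L)
  expect_error(seg_sites(matrix(0L, 0, 3)), "zero haplotypes")
  l <- simulate_neutral_locus(sim_params(n_hap = 10, locus_len = 1000,
                                         theta_bp = 0.01), seed = 5)
  expect_equal(seg_sites(l$haplotypes), ncol(l$haplotypes))
})

test_that("nucleotide diversity equals the all-pairs oracle", {
  H <- rbind(c(0L, 0L, 0L), c(0L, 1L, 1L), c(1L, 1L, 0L))
  expect_equal(nucleotide_diversity(H, 3), 2 / 3, tolerance = 1e-12)
  expect_equal(nucleotide_diversity(rbind(H[1, ], H[1, ]), 3), 0)
  expect_error(nucleotide_diversity(H, 0), "effective_length")
  set.seed(11)
  for (r in 1:100) {
    H <- random_hap_matrix(8, 20)
    expect_equal(nucleotide_diversity(H, 20), pi_oracle(H, 20),
                 tolerance = 1e-12)
  }
})

test_that("Watterson's theta follows S / (a_n L)", {
  expect_equal(watterson_theta(3, 4, 1), 3 / (1 + 1 / 2 + 1 / 3),
               tolerance = 1e-12)
  expect_equal(watterson_theta(0, 10, 100), 0)
  expect_error(watterson_theta(3, 1, 100), "n >= 2")
})

test_that("pi and Watterson's theta are unbiased under neutral simulation", {
  set.seed(12)
  p <- sim_params(n_hap = 62, locus_len = 1000, theta_bp = 0.01) # theta = 10
  reps <- replicate(1200, {
    l <- simulate_neutral_locus(p)
    c(pi = nucleotide_diversity(l$haplotypes, 1) ,
      tw = watterson_theta(ncol(l$haplotypes), 62, 1))
  })
  se_pi <- sd(reps["pi", ]) / sqrt(ncol(reps))
  se_tw <- sd(reps["tw", ]) / sqrt(ncol(reps))
  expect_lt(abs(mean(reps["pi", ]) - 10), 3 * se_pi)
  expect_lt(abs(mean(reps["tw", ]) - 10), 3 * se_tw)
})

test_that("Tajima's D matches an independently coded oracle", {
  set.seed(13)
  H6 <- random_hap_matrix(6, 10)
  expect_equal(tajimas_d(H6), tajima_oracle(H6), tolerance = 1e-12)
  for (r in 1:25) {
    H <- random_hap_matrix(sample(4:12, 1), sample(5:30, 1))
    expect_equal(tajimas_d(H), tajima_oracle(H), tolerance = 1e-12)
  }
  expect_true(is.na(tajimas_d(matrix(0L, 5, 4))))      # S = 0 flagged, no error
  expect_error(tajimas_d(matrix(0L, 3, 4)), "n >= 4")
})

test_that("Tajima's D is near zero under neutrality, positive under balancing", {
  set.seed(14)
  p <- sim_params(n_hap = 62, locus_len = 1000, theta_bp = 0.01)
  d_neu <- replicate(600, tajimas_d(simulate_neutral_locus(p)$haplotypes))
  expect_lt(abs(mean(d_neu, na.rm = TRUE)), 0.3)
  pb <- sim_params(n_hap = 62, locus_len = 1000, theta_bp = 0.01,
                   model = "balanced", f_eq = 0.5, t_balance = 8,
                   m_switch = 0.05)
  d_bal <- replicate(100, tajimas_d(simulate_balanced_locus(pb)$haplotypes))
  expect_gte(mean(d_bal > 0, na.rm = TRUE), 0.8)
})

test_that("effective length subtracts the mask union, not the sum", {
  m <- mask_set(repeats = list(c1 = rbind(c(500L, 900L))),
                gaps = list(c1 = rbind(c(1500L, 1600L))))
  expect_equal(effective_length(c(0L, 2000L), m, "c1"), 1500L)
  m2 <- mask_set(repeats = list(c1 = rbind(c(500L, 900L))),
                 gaps = list(c1 = rbind(c(850L, 1000L))))   # 50 bp overlap
  expect_equal(effective_length(c(0L, 2000L), m2, "c1"), 1500L)
  m3 <- mask_set(gaps = list(c1 = rbind(c(0L, 2000L))))
  expect_equal(effective_length(c(0L, 2000L), m3, "c1"), 0L)
  expect_equal(effective_length(c(0L, 2000L), NULL, "c1"), 2000L)
})

test_that("sliding windows tile by rule and degenerate to whole-region stats", {
  g <- simulate_genome(genome_config(n_control = 4, n_candidate = 1,
                                     n_hap = 10), seed = 21)
  vt <- g$variants
  tr <- sliding_windows(vt, "ctg1", c(0L, 10000L), size = 2000L, step = 500L)
  expect_equal(nrow(tr), 17L)
  expect_equal(tr$start, seq(0L, 8000L, by = 500L))
  # a >= 25%-of-size uncovered tail is emitted as one truncated window
  tr2 <- sliding_windows(vt, "ctg1", c(0L, 4300L), size = 2000L, step = 1500L)
  expect_equal(tr2$start, c(0L, 1500L, 3000L))
  expect_equal(tail(tr2$end, 1), 4300L)
  tr3 <- sliding_windows(vt, "ctg1", c(0L, 3600L), size = 2000L, step = 1500L)
  expect_equal(tr3$start, c(0L, 1500L))                # 100 bp tail dropped
  # region shorter than a window: one truncated window, equal to region stats
  tr4 <- sliding_windows(vt, "ctg1", c(100L, 1100L), size = 2000L, step = 500L)
  expect_equal(nrow(tr4), 1L)
  one <- sliding_windows(vt, "ctg1", c(0L, 10000L), size = 10000L,
                         step = 10000L)
  Hall <- vt_region(vt, "ctg1", 0L, 10000L)$geno
  expect_equal(one$S, seg_sites(Hall))
  expect_equal(one$pi_site, nucleotide_diversity(Hall, 10000L))
  # windows without SNPs carry S = 0 and flagged-undefined D
  empty <- tr$tajima_d[tr$S == 0]
  expect_true(all(is.na(empty)))
})

test_that("theta map instantiates the tile formula and flags missing tiles", {
  g <- simulate_genome(genome_config(n_control = 5, n_candidate = 1,
                                     n_hap = 62), seed = 22)
  tm <- theta_map(g$variants, g$masks)
  i <- which(tm$S > 0 & tm$eff_len > 0)[1]
  expect_equal(tm$theta_bp[i], tm$S[i] / (harmonic_a(62) * tm$eff_len[i]),
               tolerance = 1e-12)
  # lookup returns the containing tile
  pos <- g$variants$pos0[5]
  j <- findInterval(pos, tm$start)
  expect_equal(theta_lookup(tm, "ctg1", pos), tm$theta_bp[j])
  # positions outside the map are explicitly missing, never zero
  expect_true(is.na(theta_lookup(tm, "other_contig", 100L)))
  m_all <- mask_set(gaps = list(ctg1 = rbind(c(0L, 10000L))))
  tm2 <- theta_map(vt_region(g$variants, "ctg1", 0L, 10000L), m_all)
  expect_true(is.na(tm2$theta_bp[1]))
})
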