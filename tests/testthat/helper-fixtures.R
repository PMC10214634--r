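# Shared fixtures: tiny on-the-fly input files and independent oracles.

write_toy_vcf <- function(path, records, samples = c("S1", "S2")) {
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(header, records), path)
  path
}

vcf_record <- function(chrom, pos, ref, alt, gts) {
  paste(c(chrom, pos, ".", ref, alt, ".", "PASS", ".", "GT", gts),
        collapse = "\t")
}

random_hap_matrix <- function(n, S, p = NULL) {
  if (is.null(p)) p <- runif(S, 0.1, 0.9)
  H <- sapply(p, function(pp) rbinom(n, 1, pp))
  # ensure polymorphic columns
  for (j in seq_len(S)) {
    if (all(H[, j] == H[1, j])) {
      H[sample.int(n, 1), j] <- 1L - H[1, j]
    }
  }
  storage.mode(H) <- "integer"
  H
}

# O(n^2) all-pairs nucleotide-diversity oracle
pi_oracle <- function(H, L) {
  n <- nrow(H)
  tot <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    tot <- tot + sum(H[i, ] != H[j, ])
  }
  tot / choose(n, 2) / L
}

# independently coded Tajima's D (constant by constant, per the 1989 forms)
tajima_oracle <- function(H) {
  n <- nrow(H)
  cs <- colSums(H)
  seg <- cs > 0 & cs < n
  S <- sum(seg)
  if (S == 0) return(NA_real_)
  pi_tot <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    pi_tot <- pi_tot + sum(H[i, ] != H[j, ])
  }
  pi_tot <- pi_tot / choose(n, 2)
  a1 <- sum(1 / (1:(n - 1)))
  a2 <- sum(1 / (1:(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  (pi_tot - S / a1) / sqrt((c1 / a1) * S + (c2 / (a1^2 + a2)) * S * (S - 1))
}

# exhaustive-permutation Mann-Whitney oracle (two-sided, no ties)
mw_exact_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  vals <- c(a, b)
  u_obs <- sum(outer(a, b, ">"))
  combs <- combn(na + nb, na)
  us <- apply(combs, 2, function(ix) {
    sum(outer(vals[ix], vals[-ix], ">"))
  })
  mu <- na * nb / 2
  mean(abs(us - mu) >= abs(u_obs - mu))
}
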