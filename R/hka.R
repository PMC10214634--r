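# Maximum-likelihood HKA test.
#
# Each locus l contributes two independent Poisson observations:
#
#   S_l ~ Poisson(k_l * theta_l * a_{n_l})        polymorphism
#   D_l ~ Poisson(theta_l * (T + k_l))            divergence (default)
#
# where a_n is the Watterson harmonic factor, T the divergence-time
# parameter shared across loci, and k_l a per-locus selection parameter
# (fixed at 1 for the neutral reference panel).  k scales the locus's
# effective coalescent depth, so by default it multiplies both polymorphism
# and the ancestral-polymorphism component of divergence but not the fixed
# split time T; setting `k_on_divergence = FALSE` restricts k to
# polymorphism (D_l ~ Poisson(theta_l * (T + 1))).  Balancing selection
# deepening the genealogy corresponds to k > 1.
#
# For fixed (T, k) the theta maximising the likelihood has the closed form
# theta_l = (S_l + D_l) / (k_l a_l + T + k_l), so fitting reduces to a 1-D
# (neutral) or low-dimensional (selection) bounded search with theta
# profiled out — a deterministic replacement for the Markov-chain maximiser
# of the original program (an optional chain-based maximiser over the same
# likelihood is provided for cross-checking).

.hka_check <- function(data) {
  stopifnot(is.data.frame(data), all(c("locus_id", "S", "D", "n") %in% names(data)))
  if (any(data$S < 0 | data$D < 0)) stop("negative counts")
  if (any(data$n < 2)) stop("need n >= 2 haplotypes per locus")
  data
}

#' HKA log-likelihood
#'
#' @param data data.frame of loci with columns locus_id, S, D, n (see
#'   [simulate_hka_dataset()] / [read_hka_loci()]).
#' @param theta per-locus theta vector (> 0).
#' @param T_div divergence-time parameter (>= 0).
#' @param k per-locus selection parameter (recycled; 1 = neutral).
#' @param k_on_divergence whether k scales the ancestral component of
#'   divergence (default TRUE).
#' @return the summed Poisson log-likelihood.
#' @export
hka_loglik <- function(data, theta, T_div, k = 1, k_on_divergence = TRUE) {
  .hka_check(data)
  k <- rep_len(k, nrow(data))
  if (any(theta <= 0) || T_div < 0 || any(k <= 0)) stop("invalid parameters")
  a <- vapply(data$n, harmonic_a, numeric(1))
  dmean <- if (k_on_divergence) theta * (T_div + k) else theta * (T_div + 1)
  sum(dpois(data$S, k * theta * a, log = TRUE)) +
    sum(dpois(data$D, dmean, log = TRUE))
}

# profiled theta given (T, k)
.theta_profile <- function(data, a, T_div, k, k_on_divergence) {
  denom <- if (k_on_divergence) k * a + T_div + k else k * a + T_div + 1
  (data$S + data$D) / denom
}

.profile_loglik <- function(data, a, T_div, k, k_on_divergence) {
  theta <- .theta_profile(data, a, T_div, k, k_on_divergence)
  if (any(theta <= 0)) return(-Inf)
  dmean <- if (k_on_divergence) theta * (T_div + k) else theta * (T_div + 1)
  sum(dpois(data$S, k * theta * a, log = TRUE)) +
    sum(dpois(data$D, dmean, log = TRUE))
}

.new_hka_fit <- function(data, theta, T_div, k, ll, converged,
                         k_on_divergence, model) {
  structure(list(data = data, theta_hat = theta, T_hat = T_div, k_hat = k,
                 loglik = ll, converged = converged,
                 k_on_divergence = k_on_divergence, model = model),
            class = "hka_fit")
}

#' Fit the neutral HKA model
#'
#' Maximises the likelihood with all `k = 1`: theta is profiled in closed
#' form and a 1-D bounded search runs over T.  A single locus admits an
#' exact solution (`theta = S/a`, `T = D/theta - 1`) which the optimiser
#' reproduces to tolerance.
#'
#' @param data HKA locus data.frame (>= 1 locus; all-zero data is an error —
#'   theta would be unidentifiable).
#' @param T_max upper bound of the T search.
#' @return an `hka_fit` object.
#' @export
hka_fit_neutral <- function(data, T_max = 100) {
  .hka_check(data)
  if (all(data$S + data$D == 0)) stop("all-zero data: theta unidentifiable")
  a <- vapply(data$n, harmonic_a, numeric(1))
  k <- rep(1, nrow(data))
  obj <- function(T_div) .profile_loglik(data, a, T_div, k, TRUE)
  op <- optimize(obj, c(0, T_max), maximum = TRUE, tol = 1e-10)
  T_hat <- op$maximum
  # boundary polish: profile is unimodal, check the T = 0 edge
  if (obj(0) > op$objective) T_hat <- 0
  theta <- .theta_profile(data, a, T_hat, k, TRUE)
  .new_hka_fit(data, theta, T_hat, k, obj(T_hat), TRUE, TRUE, "neutral")
}

#' Fit the HKA selection model
#'
#' Frees the selection parameter k for the named candidate loci (k = 1
#' elsewhere) and maximises over (T, log k) with theta profiled, from a
#' log-scale grid of k starting points in \[0.02, 50\].
#'
#' @param data HKA locus data.frame.
#' @param candidate_ids non-empty subset of `data$locus_id` whose k is free.
#' @param k_on_divergence see [hka_loglik()].
#' @param T_max upper bound for T.
#' @param k_bounds bounds for each free k.
#' @param n_starts number of log-spaced k grid starts.
#' @return an `hka_fit` object (error carrying the best point if no start
#'   converges).
#' @export
hka_fit_selection <- function(data, candidate_ids, k_on_divergence = TRUE,
                              T_max = 100, k_bounds = c(0.02, 50),
                              n_starts = 5) {
  .hka_check(data)
  cand <- match(candidate_ids, data$locus_id)
  if (!length(cand) || anyNA(cand)) stop("candidate_ids must name loci in data")
  a <- vapply(data$n, harmonic_a, numeric(1))
  nk <- length(cand)
  obj <- function(par) {
    T_div <- par[1]
    k <- rep(1, nrow(data))
    k[cand] <- exp(par[-1])
    -.profile_loglik(data, a, T_div, k, k_on_divergence)
  }
  T0 <- hka_fit_neutral(data, T_max)$T_hat
  kg <- exp(seq(log(k_bounds[1]), log(k_bounds[2]), length.out = n_starts))
  best <- NULL
  for (k0 in kg) {
    fit <- tryCatch(
      optim(c(max(T0, 1e-3), rep(log(k0), nk)), obj, method = "L-BFGS-B",
            lower = c(0, rep(log(k_bounds[1]), nk)),
            upper = c(T_max, rep(log(k_bounds[2]), nk))),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("selection fit failed from every start")
  k <- rep(1, nrow(data))
  k[cand] <- exp(best$par[-1])
  theta <- .theta_profile(data, a, best$par[1], k, k_on_divergence)
  .new_hka_fit(data, theta, best$par[1], k, -best$value,
               best$convergence == 0, k_on_divergence, "selection")
}

#' Likelihood-ratio test between nested HKA fits
#'
#' @param fit0 neutral fit (nested in `fit1`).
#' @param fit1 selection fit.
#' @return list of class `hka_test`: `lrt_stat = max(0, 2 * (l1 - l0))`,
#'   `df` (number of free k), `p_value` from the chi-squared distribution.
#' @export
hka_lrt <- function(fit0, fit1) {
  df <- sum(fit1$k_hat != 1)
  if (df <= 0) stop("selection fit has no free k (df = 0)")
  stat <- max(0, 2 * (fit1$loglik - fit0$loglik))
  structure(list(lrt_stat = stat, df = df,
                 p_value = pchisq(stat, df, lower.tail = FALSE)),
            class = "hka_test")
}

#' One-call ML-HKA test for a candidate locus
#'
#' @param data HKA locus data.frame (neutral panel plus the candidate).
#' @param candidate_ids locus id(s) to test.
#' @param ... passed to [hka_fit_selection()].
#' @return list with `fit0`, `fit1` and the `hka_test` result.
#' @export
hka_test <- function(data, candidate_ids, ...) {
  fit0 <- hka_fit_neutral(data)
  fit1 <- hka_fit_selection(data, candidate_ids, ...)
  list(fit0 = fit0, fit1 = fit1, test = hka_lrt(fit0, fit1))
}

#' @export
print.hka_fit <- function(x, ...) {
  cat(sprintf("ML-HKA %s fit: %d loci, logL = %.4f, T = %.4f%s\n",
              x$model, nrow(x$data), x$loglik, x$T_hat,
              if (x$converged) "" else " (NOT converged)"))
  free <- which(x$k_hat != 1)
  if (length(free))
    cat("  k:", paste(sprintf("%s = %.3f", x$data$locus_id[free],
                              x$k_hat[free]), collapse = ", "), "\n")
  invisible(x)
}

#' @export
logLik.hka_fit <- function(object, ...) {
  free <- sum(object$k_hat != 1)
  structure(object$loglik, df = nrow(object$data) + 1 + free,
            class = "logLik")
}

#' @export
coef.hka_fit <- function(object, ...) {
  c(setNames(object$theta_hat, paste0("theta_", object$data$locus_id)),
    T = object$T_hat,
    setNames(object$k_hat[object$k_hat != 1],
             paste0("k_", object$data$locus_id[object$k_hat != 1])))
}

#' @export
print.hka_test <- function(x, ...) {
  cat(sprintf("LRT = %.4f, df = %d, p = %.4g\n", x$lrt_stat, x$df, x$p_value))
  invisible(x)
}

#' Chain-based maximiser over the same likelihood (cross-check)
#'
#' A simple Metropolis-style stochastic hill-climb on (T, log k) with theta
#' profiled, provided to cross-check the deterministic optimiser; not the
#' default path.
#'
#' @param data HKA locus data.frame.
#' @param candidate_ids free-k loci (empty vector for the neutral model).
#' @param chain_length proposals.
#' @param k_on_divergence see [hka_loglik()].
#' @param seed RNG seed.
#' @return an `hka_fit`.
#' @export
hka_fit_chain <- function(data, candidate_ids = character(0),
                          chain_length = 10000, k_on_divergence = TRUE,
                          seed = 1) {
  .hka_check(data)
  set.seed(seed)
  a <- vapply(data$n, harmonic_a, numeric(1))
  cand <- match(candidate_ids, data$locus_id)
  nk <- length(cand)
  par <- c(1, rep(0, nk))                # (T, log k)
  ll_of <- function(par) {
    k <- rep(1, nrow(data)); if (nk) k[cand] <- exp(par[-1])
    .profile_loglik(data, a, par[1], k, k_on_divergence)
  }
  ll <- ll_of(par)
  best <- par; best_ll <- ll
  for (i in seq_len(chain_length)) {
    prop <- par + rnorm(length(par), 0, 0.1)
    prop[1] <- abs(prop[1])
    llp <- ll_of(prop)
    if (is.finite(llp) && log(runif(1)) < llp - ll) { par <- prop; ll <- llp }
    if (ll > best_ll) { best <- par; best_ll <- ll }
  }
  k <- rep(1, nrow(data)); if (nk) k[cand] <- exp(best[-1])
  theta <- .theta_profile(data, a, best[1], k, k_on_divergence)
  .new_hka_fit(data, theta, best[1], k, best_ll, TRUE, k_on_divergence,
               if (nk) "selection" else "neutral")
}

#' Read an HKA locus table
#'
#' @param path TSV with columns locus_id, S, D, n, L, is_candidate.
#' @return validated data.frame.
#' @export
read_hka_loci <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  .hka_check(d)
}

#' Count divergent sites against an outgroup
#'
#' Alignment columns containing a gap in any sequence are removed, then
#' mismatching columns between the outgroup and one randomly chosen ingroup
#' haplotype (seed-controlled) are counted.
#'
#' @param ingroup_cds character vector of aligned ingroup CDS haplotypes (or
#'   a `Biostrings::DNAStringSet`).
#' @param outgroup_cds single aligned outgroup sequence.
#' @param hap_choice seed controlling which ingroup haplotype is compared.
#' @return integer divergence count.
#' @export
count_divergence <- function(ingroup_cds, outgroup_cds, hap_choice = 1) {
  as_chr <- function(x) if (inherits(x, "XStringSet")) as.character(x) else x
  ing <- toupper(as_chr(ingroup_cds))
  outg <- toupper(as_chr(outgroup_cds))[1]
  if (any(nchar(ing) != nchar(outg)))
    stop("aligned sequences must have equal length")
  set.seed(hap_choice)
  hap <- ing[sample.int(length(ing), 1)]
  h <- strsplit(hap, "")[[1]]
  o <- strsplit(outg, "")[[1]]
  gap_any <- h == "-" | o == "-"
  for (s in ing) gap_any <- gap_any | strsplit(s, "")[[1]] == "-"
  h <- h[!gap_any]; o <- o[!gap_any]
  if (!length(h)) stop("empty alignment after gap-column removal")
  sum(h != o)
}
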