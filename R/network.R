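# Median-joining haplotype networks (Bandelt et al. construction, epsilon 0).

# split equal-length sequences into a character matrix
.seq_mat <- function(seqs) {
  L <- unique(nchar(seqs))
  if (length(L) != 1) stop("sequences must have equal length")
  do.call(rbind, strsplit(seqs, ""))
}

# pairwise Hamming distances via per-symbol indicator cross-products
.hamming <- function(M) {
  n <- nrow(M)
  if (n == 1) return(matrix(0L, 1, 1))
  L <- ncol(M)
  same <- matrix(0, n, n)
  for (s in unique(as.vector(M))) {
    X <- (M == s) * 1
    same <- same + tcrossprod(X)
  }
  d <- L - same
  diag(d) <- 0
  storage.mode(d) <- "integer"
  d
}

# minimum-spanning network: union of all minimum spanning trees (edges are
# added level by level; every tie that joins two distinct components at its
# level is kept)
.msn_edges <- function(d) {
  n <- nrow(d)
  if (n == 1) return(matrix(integer(0), ncol = 2))
  comp <- seq_len(n)
  find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  ut <- which(upper.tri(d), arr.ind = TRUE)
  lev_of <- d[ut]
  ord <- order(lev_of)
  ut <- ut[ord, , drop = FALSE]; lev_of <- lev_of[ord]
  edges <- matrix(integer(0), ncol = 2)
  for (lev in unique(lev_of)) {
    pr <- ut[lev_of == lev, , drop = FALSE]
    keep <- vapply(seq_len(nrow(pr)), function(r)
      find(pr[r, 1]) != find(pr[r, 2]), logical(1))
    pr <- pr[keep, , drop = FALSE]
    for (r in seq_len(nrow(pr))) comp[find(pr[r, 1])] <- find(pr[r, 2])
    edges <- rbind(edges, pr)
  }
  unname(edges)
}

# majority-rule median of three rows; ties (all three distinct) fall back to
# the first row (the reference among the triplet): if b == c that value has
# a majority (or is unanimous), otherwise a is either the majority partner
# or the tie-break
.median_vec <- function(M3) {
  a <- M3[1, ]; b <- M3[2, ]; c <- M3[3, ]
  ifelse(b == c, b, a)
}

#' Median-joining haplotype network
#'
#' Construction with epsilon = 0: (1) collapse identical sequences, keeping
#' observed multiplicities; (2) connect nodes by the minimum-spanning
#' network (union of all minimum spanning trees over Hamming distances,
#' keeping ties); (3) for every triplet formed by a node and two of its
#' network neighbours, add the per-column majority median vector if it is
#' new; (4) iterate to a fixpoint; (5) delete median (unsampled) vectors
#' that end with fewer than three connections, since they shorten no path.
#' Edge weights are Hamming distances between linked nodes.
#'
#' @param haplotypes character vector of equal-length sequences (binary or
#'   nucleotide), one entry per sampled haplotype, or unique sequences with
#'   `freq` giving multiplicities.
#' @param freq optional observed multiplicities matching `haplotypes`.
#' @param max_iter,max_nodes safety caps on median augmentation.
#' @return an object of class `hap_network`: `nodes` (data.frame id, seq,
#'   freq; freq 0 marks inferred medians) and `edges` (from, to, weight).
#' @export
median_joining_network <- function(haplotypes, freq = NULL, max_iter = 25,
                                   max_nodes = 2000) {
  if (is.null(freq)) {
    tb <- table(haplotypes)
    seqs <- names(tb)
    freq <- as.integer(tb)
  } else {
    stopifnot(length(freq) == length(haplotypes))
    seqs <- haplotypes
    freq <- as.integer(freq)
  }
  M <- .seq_mat(seqs)
  nobs <- length(seqs)
  for (it in seq_len(max_iter)) {
    d <- .hamming(M)
    ed <- .msn_edges(d)
    if (!nrow(ed) || nrow(M) >= max_nodes) break
    adj <- lapply(seq_len(nrow(M)), function(i)
      sort(unique(c(ed[ed[, 1] == i, 2], ed[ed[, 2] == i, 1]))))
    existing <- apply(M, 1, paste, collapse = "")
    new_seqs <- character(0)
    for (u in seq_len(nrow(M))) {
      nb <- adj[[u]]
      if (length(nb) < 2) next
      for (a in seq_len(length(nb) - 1)) for (b in (a + 1):length(nb)) {
        med <- paste(.median_vec(M[c(u, nb[a], nb[b]), , drop = FALSE]),
                     collapse = "")
        if (!(med %in% existing) && !(med %in% new_seqs))
          new_seqs <- c(new_seqs, med)
      }
    }
    if (!length(new_seqs)) break
    M <- rbind(M, .seq_mat(new_seqs))
    freq <- c(freq, rep(0L, length(new_seqs)))
  }
  # prune medians that do not join at least three lineages
  repeat {
    d <- .hamming(M)
    ed <- .msn_edges(d)
    deg <- tabulate(c(ed), nbins = nrow(M))
    drop <- which(freq == 0L & deg < 3)
    if (!length(drop) || nrow(M) == 1) break
    keep <- setdiff(seq_len(nrow(M)), drop[1])
    M <- M[keep, , drop = FALSE]
    freq <- freq[keep]
  }
  d <- .hamming(M)
  ed <- .msn_edges(d)
  seqs <- apply(M, 1, paste, collapse = "")
  nodes <- data.frame(id = sprintf("H%02d", seq_along(seqs)), seq = seqs,
                      freq = freq, stringsAsFactors = FALSE)
  edges <- if (nrow(ed))
    data.frame(from = nodes$id[ed[, 1]], to = nodes$id[ed[, 2]],
               weight = d[ed], stringsAsFactors = FALSE)
  else data.frame(from = character(0), to = character(0), weight = integer(0))
  structure(list(nodes = nodes, edges = edges), class = "hap_network")
}

#' @export
print.hap_network <- function(x, ...) {
  cat(sprintf("hap_network: %d nodes (%d observed, %d median), %d edges\n",
              nrow(x$nodes), sum(x$nodes$freq > 0), sum(x$nodes$freq == 0),
              nrow(x$edges)))
  invisible(x)
}

.net_igraph <- function(net) {
  g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                     vertices = net$nodes)
  g
}

#' Two-group separation summary of a haplotype network
#'
#' Reports the largest-weight bridge on the network's minimum-spanning
#' backbone and the observed-frequency totals on either side after cutting
#' it — a descriptive statistic of "two well separated haplotype groups",
#' not a test.
#'
#' @param net a [median_joining_network()] result with >= 2 observed nodes.
#' @return list: bridge_weight, group_freqs (sorted decreasing), membership
#'   (per-node side); all `NA` (flagged undefined) for a single-node network.
#' @export
two_group_separation <- function(net) {
  if (sum(net$nodes$freq > 0) < 2 || !nrow(net$edges))
    return(list(bridge_weight = NA_real_, group_freqs = c(NA_real_, NA_real_),
                membership = NULL))
  g <- .net_igraph(net)
  mst <- igraph::mst(g, weights = igraph::E(g)$weight)
  w <- igraph::E(mst)$weight
  cut <- which.max(w)                     # deterministic: first maximal edge
  mst2 <- igraph::delete_edges(mst, cut)
  memb <- igraph::components(mst2)$membership
  freqs <- tapply(net$nodes$freq[match(names(memb), net$nodes$id)], memb, sum)
  list(bridge_weight = max(w),
       group_freqs = sort(as.numeric(freqs), decreasing = TRUE),
       membership = setNames(as.integer(memb), names(memb)))
}

#' Write a haplotype network as GraphML
#'
#' @param net a `hap_network`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(net, path) {
  if (nrow(net$edges)) {
    g <- .net_igraph(net)
  } else {
    g <- igraph::make_empty_graph(n = nrow(net$nodes), directed = FALSE)
    igraph::V(g)$name <- net$nodes$id
    igraph::V(g)$seq <- net$nodes$seq
    igraph::V(g)$freq <- net$nodes$freq
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Write the haplotype table behind a network
#'
#' Plain TSV (id, freq, seq) loadable next to the GraphML by common network
#' viewers.
#'
#' @param net a `hap_network`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_hap_table <- function(net, path) {
  write.table(net$nodes[, c("id", "freq", "seq")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Haplotype sequences from a variant-table region
#'
#' Binary haplotype strings (presence of the non-reference allele) for the
#' SNPs of a sub-region, the substrate of [median_joining_network()].
#' Externally phased haplotypes (e.g. Sanger-derived) can be appended from a
#' FASTA of the same binary coding via `extra_fasta`.
#'
#' @param vt a [variant_table()].
#' @param contig,start,end region (0-based half-open).
#' @param extra_fasta optional FASTA of equal-length 0/1 strings to merge.
#' @return character vector of haplotype strings, one per haplotype.
#' @export
hap_sequences <- function(vt, contig, start, end, extra_fasta = NULL) {
  sl <- vt_region(vt, contig, start, end)
  seqs <- apply(sl$geno, 1, paste, collapse = "")
  if (!is.null(extra_fasta)) {
    ex <- as.character(Biostrings::readBStringSet(extra_fasta))
    if (length(ex) && any(nchar(ex) != ncol(sl$geno)))
      stop("extra haplotypes must match the region's SNP count")
    seqs <- c(seqs, ex)
  }
  seqs
}
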