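#' Gene model
#'
#' Genomic intervals for a gene: span, exons and CDS, all 0-based half-open
#' and sorted.  CDS must lie within exons, exons within the span.
#'
#' @param gene_id gene identifier.
#' @param contig contig name.
#' @param strand "+" or "-".
#' @param span length-2 integer vector `[start, end)`.
#' @param exons,cds 2-column matrices of `[start, end)` intervals
#'   (non-overlapping; sorted on construction).
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, contig, strand, span, exons, cds = NULL) {
  norm <- function(m) {
    if (is.null(m) || nrow(m) == 0) return(.empty_iv())
    m <- m[order(m[, 1]), , drop = FALSE]
    storage.mode(m) <- "integer"
    colnames(m) <- c("start", "end")
    m
  }
  exons <- norm(exons); cds <- norm(cds)
  if (nrow(exons) == 0) stop("gene ", gene_id, ": no exons")
  contained <- function(inner, outer) {
    nrow(inner) == 0 ||
      all(vapply(seq_len(nrow(inner)), function(i) {
        iv_overlap_len(c(inner[i, 1], inner[i, 2]), outer) ==
          inner[i, 2] - inner[i, 1]
      }, logical(1)))
  }
  if (!all(exons[, 1] >= span[1] & exons[, 2] <= span[2]))
    stop("gene ", gene_id, ": exon outside gene span")
  if (!contained(cds, exons))
    stop("gene ", gene_id, ": CDS outside exons")
  structure(list(gene_id = gene_id, contig = contig, strand = strand,
                 span = as.integer(span), exons = exons, cds = cds),
            class = "gene_model")
}

#' Total CDS length of a gene model
#' @param gene a [gene_model()].
#' @return integer bp.
#' @export
cds_length <- function(gene) {
  if (nrow(gene$cds) == 0) 0L else sum(gene$cds[, 2] - gene$cds[, 1])
}

#' Read gene models from GFF3
#'
#' GFF3 1-based inclusive coordinates are converted to 0-based half-open.
#' One model is returned per gene; when a gene has several mRNAs, the mRNA
#' with the longest total CDS is used (ties: longest exonic length, then
#' first in file).  A gene whose chosen transcript has no exons, or whose CDS
#' falls outside the gene span, is an error naming the gene.
#'
#' @param path GFF3 file with gene/mRNA/exon/CDS features.
#' @return named list of [gene_model()] objects.
#' @export
read_gff <- function(path) {
  g <- rtracklayer::readGFF(path)
  g <- as.data.frame(g)
  g$type <- as.character(g$type)
  feat_id <- as.character(g$ID)
  parent <- vapply(g$Parent, function(p) if (length(p)) as.character(p)[1] else NA_character_,
                   character(1))
  genes <- which(g$type == "gene")
  if (!length(genes)) stop("no gene features in ", path)
  out <- list()
  for (gi in genes) {
    gid <- feat_id[gi]
    if (is.na(gid)) stop("gene feature without ID in ", path)
    span <- c(g$start[gi] - 1L, g$end[gi])
    mr <- which(g$type %in% c("mRNA", "transcript") & parent == gid)
    iv_of <- function(rows) {
      if (!length(rows)) return(.empty_iv())
      m <- cbind(start = g$start[rows] - 1L, end = g$end[rows])
      storage.mode(m) <- "integer"
      m
    }
    if (length(mr)) {
      cds_len <- vapply(mr, function(mi) {
        rows <- which(g$type == "CDS" & parent == feat_id[mi])
        sum(g$end[rows] - g$start[rows] + 1L)
      }, numeric(1))
      ex_len <- vapply(mr, function(mi) {
        rows <- which(g$type == "exon" & parent == feat_id[mi])
        sum(g$end[rows] - g$start[rows] + 1L)
      }, numeric(1))
      best <- mr[order(-cds_len, -ex_len)[1]]
      exons <- iv_of(which(g$type == "exon" & parent == feat_id[best]))
      cds <- iv_of(which(g$type == "CDS" & parent == feat_id[best]))
    } else {
      exons <- iv_of(which(g$type == "exon" & parent == gid))
      cds <- iv_of(which(g$type == "CDS" & parent == gid))
    }
    if (nrow(exons) == 0 && nrow(cds) > 0) exons <- cds
    if (nrow(exons) == 0) stop("gene ", gid, ": no exons")
    if (nrow(cds) > 0 && (min(cds[, 1]) < span[1] || max(cds[, 2]) > span[2]))
      stop("gene ", gid, ": CDS outside gene span")
    out[[gid]] <- gene_model(gid, as.character(g$seqid[gi]),
                             as.character(g$strand[gi]), span, exons, cds)
  }
  out
}

#' Write gene models as GFF3
#'
#' @param genes list of [gene_model()] objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gff <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (gn in genes) {
    row <- function(type, s, e, id, par = NULL) {
      attrs <- paste0("ID=", id, if (!is.null(par)) paste0(";Parent=", par))
      paste(gn$contig, "balsel", type, s + 1L, e, ".", gn$strand, ".", attrs,
            sep = "\t")
    }
    mid <- paste0(gn$gene_id, ".t1")
    lines <- c(row("gene", gn$span[1], gn$span[2], gn$gene_id),
               row("mRNA", gn$span[1], gn$span[2], mid, gn$gene_id))
    for (i in seq_len(nrow(gn$exons)))
      lines <- c(lines, row("exon", gn$exons[i, 1], gn$exons[i, 2],
                            paste0(mid, ".e", i), mid))
    for (i in seq_len(nrow(gn$cds)))
      lines <- c(lines, row("CDS", gn$cds[i, 1], gn$cds[i, 2],
                            paste0(mid, ".c", i), mid))
    writeLines(lines, con)
  }
  invisible(path)
}
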