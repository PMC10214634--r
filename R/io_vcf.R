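#' Phased biallelic SNP table
#'
#' The substrate of all statistics: a haplotype-by-site matrix of 0/1 alleles
#' with genomic anchors.  Coordinates are 0-based half-open internally
#' (`pos0`); conversion to/from the 1-based VCF convention happens only in
#' [read_vcf()] and [write_vcf()].
#'
#' @param contig character vector, one entry per site.
#' @param pos0 integer vector of 0-based site positions, strictly increasing
#'   within each contig.
#' @param ref,alt single-character reference/alternate alleles per site.
#' @param geno integer matrix of 0/1 alleles, haplotypes in rows (two per
#'   diploid, row names suffixed `_1`/`_2`), sites in columns.
#' @param report optional list of load diagnostics (dropped-record counts).
#' @return An object of class `variant_table`.
#' @export
variant_table <- function(contig, pos0, ref, alt, geno, report = list()) {
  stopifnot(is.matrix(geno), length(contig) == ncol(geno),
            length(pos0) == ncol(geno))
  if (!all(geno %in% c(0L, 1L))) stop("genotype matrix must be 0/1")
  if (nrow(geno) %% 2 != 0) stop("haplotype count must be even (2 per diploid)")
  for (ctg in unique(contig)) {
    p <- pos0[contig == ctg]
    if (anyDuplicated(p)) stop("duplicate positions on contig ", ctg)
    if (is.unsorted(p, strictly = TRUE)) stop("positions not increasing on contig ", ctg)
  }
  structure(list(contig = as.character(contig), pos0 = as.integer(pos0),
                 ref = as.character(ref), alt = as.character(alt),
                 geno = geno, report = report),
            class = "variant_table")
}

#' @export
print.variant_table <- function(x, ...) {
  cat(sprintf("variant_table: %d haplotypes x %d biallelic SNPs on %d contig(s)\n",
              nrow(x$geno), ncol(x$geno), length(unique(x$contig))))
  if (length(x$report)) {
    dr <- x$report
    cat(sprintf("  load report: dropped %d non-SNP/multiallelic, %d with missing GT\n",
                dr$dropped_non_snp %||% 0L, dr$dropped_missing %||% 0L))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Number of sites in a variant table
#' @param vt a [variant_table()].
#' @return integer count.
#' @export
n_sites <- function(vt) ncol(vt$geno)

#' Subset a variant table by region
#'
#' @param vt a [variant_table()].
#' @param contig contig name.
#' @param start,end 0-based half-open bounds (defaults: whole contig).
#' @return a `variant_table` restricted to `[start, end)` on `contig`; an
#'   empty region yields an empty table, not an error.
#' @export
vt_region <- function(vt, contig, start = 0L, end = .Machine$integer.max) {
  keep <- vt$contig == contig & vt$pos0 >= start & vt$pos0 < end
  variant_table(vt$contig[keep], vt$pos0[keep], vt$ref[keep], vt$alt[keep],
                vt$geno[, keep, drop = FALSE], vt$report)
}

.SNP_ALLELES <- c("A", "C", "G", "T")

#' Read a phased VCF into a variant table
#'
#' Only biallelic SNP records are retained; multiallelic records, indels and
#' records with missing genotypes are dropped and counted in the load report.
#' Any unphased genotype ("/" separator) among retained records is a hard
#' error naming the first offending record: the scan's contract is fully
#' phased input (phasing itself is upstream of this package).
#'
#' @param path VCF 4.x file (plain text or gzip).
#' @param region optional `list(contig=, start=, end=)` with 0-based half-open
#'   bounds; an empty region returns an empty table.
#' @return a [variant_table()]; its `report` holds dropped-record counts.
#' @export
read_vcf <- function(path, region = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1, dimnames = list(NULL, names(gt)))
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  is_snp <- ref %in% .SNP_ALLELES & alt %in% .SNP_ALLELES & !is.na(alt)
  miss <- apply(gt, 1, function(g) any(is.na(g) | grepl("\\.", g)))
  keep <- is_snp & !miss
  # phasing contract checked on records that survive the SNP/missing filters
  unph <- keep & apply(gt, 1, function(g) any(grepl("/", g, fixed = TRUE)))
  if (any(unph)) {
    i <- which(unph)[1]
    stop(sprintf("unphased genotype at %s:%s — phased input required",
                 fix[i, "CHROM"], fix[i, "POS"]))
  }
  report <- list(dropped_non_snp = sum(!is_snp),
                 dropped_missing = sum(is_snp & miss))
  fix <- fix[keep, , drop = FALSE]
  gt <- gt[keep, , drop = FALSE]
  samples <- colnames(gt)
  n_dip <- length(samples)
  S <- nrow(fix)
  geno <- matrix(0L, nrow = 2 * n_dip, ncol = S)
  rownames(geno) <- as.vector(rbind(paste0(samples, "_1"), paste0(samples, "_2")))
  if (S > 0) {
    a1 <- substr(gt, 1, 1); a2 <- substr(gt, 3, 3)
    geno[seq(1, 2 * n_dip, by = 2), ] <- t(matrix(as.integer(a1), nrow = S))
    geno[seq(2, 2 * n_dip, by = 2), ] <- t(matrix(as.integer(a2), nrow = S))
  }
  vt <- variant_table(fix[, "CHROM"], as.integer(fix[, "POS"]) - 1L,
                      fix[, "REF"], fix[, "ALT"], geno, report)
  if (!is.null(region)) {
    vt <- vt_region(vt, region$contig, region$start %||% 0L,
                    region$end %||% .Machine$integer.max)
  }
  vt
}

#' Write a variant table as a phased VCF
#'
#' @param vt a [variant_table()].
#' @param path output file; positions are converted back to 1-based.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(vt, path) {
  hap <- rownames(vt$geno)
  samples <- unique(sub("_[12]$", "", hap))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", samples), collapse = "\t")), con)
  if (n_sites(vt) > 0) {
    g1 <- vt$geno[seq(1, nrow(vt$geno), by = 2), , drop = FALSE]
    g2 <- vt$geno[seq(2, nrow(vt$geno), by = 2), , drop = FALSE]
    gt <- matrix(paste0(g1, "|", g2), nrow = nrow(g1))
    lines <- vapply(seq_len(n_sites(vt)), function(j) {
      paste(c(vt$contig[j], vt$pos0[j] + 1L, ".", vt$ref[j], vt$alt[j], ".",
              "PASS", ".", "GT", gt[, j]), collapse = "\t")
    }, character(1))
    writeLines(lines, con)
  }
  invisible(path)
}
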