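#' Mask set: repeats, gaps and indel positions
#'
#' Per-contig interval lists (0-based half-open) driving window
#' effective-length correction (repeats + gaps) and indel-proximity masking
#' of beta values.  Source intervals may overlap; they are unioned on load.
#' Indels are stored as given (typically single-bp points); expansion by the
#' masking radius happens in [mask_near_indels()].
#'
#' @param repeats,gaps,indels named lists (contig -> 2-column start/end
#'   matrix) or NULL.
#' @return An object of class `mask_set`.
#' @export
mask_set <- function(repeats = NULL, gaps = NULL, indels = NULL) {
  norm <- function(lst) {
    if (is.null(lst)) return(list())
    lapply(lst, iv_union)
  }
  structure(list(repeats = norm(repeats), gaps = norm(gaps),
                 indels = norm(indels)),
            class = "mask_set")
}

# parse one BED file into a per-contig interval list; errors carry line numbers
.parse_bed <- function(path) {
  if (is.null(path)) return(list())
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (!length(lines)) return(list())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  out <- list()
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (length(p) < 3) stop(path, " line ", i, ": fewer than 3 BED columns")
    s <- suppressWarnings(as.integer(p[2])); e <- suppressWarnings(as.integer(p[3]))
    if (is.na(s) || is.na(e)) stop(path, " line ", i, ": non-numeric coordinates")
    if (s >= e) stop(path, " line ", i, ": start >= end")
    out[[p[1]]] <- rbind(out[[p[1]]], c(s, e))
  }
  out
}

#' Read repeat/gap/indel masks from BED files
#'
#' @param repeat_bed,gap_bed,indel_bed BED file paths (0-based half-open);
#'   any may be NULL for an empty mask.
#' @return a [mask_set()] with per-contig unioned intervals.
#' @export
read_masks <- function(repeat_bed = NULL, gap_bed = NULL, indel_bed = NULL) {
  mask_set(repeats = .parse_bed(repeat_bed), gaps = .parse_bed(gap_bed),
           indels = .parse_bed(indel_bed))
}

#' Write per-contig intervals as BED
#'
#' @param ivs named list (contig -> start/end matrix).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bed <- function(ivs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (ctg in names(ivs)) {
    iv <- ivs[[ctg]]
    if (nrow(iv))
      writeLines(paste(ctg, iv[, 1], iv[, 2], sep = "\t"), con)
  }
  invisible(path)
}

# combined repeat+gap intervals for a contig (effective-length masking)
.ef_masks <- function(masks, contig) {
  if (is.null(masks)) return(.empty_iv())
  iv_union(rbind(iv_for_contig(masks$repeats, contig),
                 iv_for_contig(masks$gaps, contig)))
}
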