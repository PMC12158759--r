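#' Read a FASTA file into a named character vector
#'
#' Wraps [Biostrings::readDNAStringSet()]. Sequence names are truncated at the
#' first whitespace, sequences are upper-cased and IUPAC ambiguity letters are
#' preserved.
#'
#' @param path path to a FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) stop("duplicate FASTA id(s): ", paste(unique(dup), collapse = ", "))
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path) {
  hg_assert(length(seqs) == 0 || !is.null(names(seqs)), "sequences must be named")
  set <- Biostrings::DNAStringSet(toupper(seqs))
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, filepath = path)
  invisible(path)
}

#' Read a BED mask into a normalized region table
#'
#' Regions are parsed with [rtracklayer::import()], merged with
#' [GenomicRanges::reduce()] and returned 0-based half-open, sorted and
#' non-overlapping.
#'
#' @param path path to a BED file.
#' @return `data.frame` with columns `chrom`, `start`, `end` (0-based
#'   half-open).
#' @export
read_region_mask <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  gr <- GenomicRanges::reduce(GenomicRanges::sort(gr))
  region_mask(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
}

#' Construct a region mask
#'
#' @param chrom chromosome names.
#' @param start,end 0-based half-open interval bounds.
#' @return `data.frame` of class `region_mask`, sorted with overlapping
#'   intervals merged.
#' @export
region_mask <- function(chrom, start, end) {
  hg_assert(all(start < end), "mask intervals need start < end")
  df <- data.frame(chrom = as.character(chrom), start = as.integer(start),
                   end = as.integer(end), stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  # merge overlapping / touching intervals per chromosome
  out <- lapply(split(df, df$chrom), function(d) {
    s <- d$start; e <- d$end
    keep_s <- s[1]; keep_e <- e[1]; res <- NULL
    if (nrow(d) > 1) {
      for (i in 2:nrow(d)) {
        if (s[i] <= keep_e) {
          keep_e <- max(keep_e, e[i])
        } else {
          res <- rbind(res, c(keep_s, keep_e))
          keep_s <- s[i]; keep_e <- e[i]
        }
      }
    }
    res <- rbind(res, c(keep_s, keep_e))
    data.frame(chrom = d$chrom[1], start = res[, 1], end = res[, 2],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("region_mask", "data.frame")
  out
}

# does window [start, end) overlap any mask interval on chrom?
mask_overlaps <- function(mask, chrom, start, end) {
  if (is.null(mask)) return(rep(FALSE, length(start)))
  vapply(seq_along(start), function(i) {
    m <- mask[mask$chrom == chrom[i], , drop = FALSE]
    any(m$start < end[i] & m$end > start[i])
  }, logical(1))
}

# complement of the mask within [start, end): intervals eligible for marker
# candidates when the mask denotes syntenic regions
mask_intersect <- function(mask, chrom, start, end) {
  m <- mask[mask$chrom == chrom, , drop = FALSE]
  s <- pmax(m$start, start)
  e <- pmin(m$end, end)
  keep <- s < e
  data.frame(start = s[keep], end = e[keep])
}
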