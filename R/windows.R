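#' Construct a reference index
#'
#' @param chrom chromosome names (unique).
#' @param length chromosome lengths in bp (> 0).
#' @return `data.frame` of class `reference_index` with columns `chrom`,
#'   `length`.
#' @export
reference_index <- function(chrom, length) {
  hg_assert(!anyDuplicated(chrom), "chromosome names must be unique")
  hg_assert(all(length > 0), "chromosome lengths must be > 0")
  df <- data.frame(chrom = as.character(chrom), length = as.integer(length),
                   stringsAsFactors = FALSE)
  class(df) <- c("reference_index", "data.frame")
  df
}

# reference index from a named sequence set
reference_index_from_seqs <- function(seqs) {
  reference_index(names(seqs), nchar(seqs))
}

#' Tile chromosomes into non-overlapping windows
#'
#' Windows are 0-based half-open, tile each chromosome without gaps or
#' overlaps, and the last window of a chromosome may be shorter than `width`.
#'
#' @param ref a [reference_index()] (or named vector of chromosome lengths).
#' @param width nominal window width in bp (default 100 kb).
#' @return `data.frame` with columns `chrom`, `index` (1-based within
#'   chromosome), `start`, `end`.
#' @export
#' @examples
#' make_windows(reference_index("chr01", 250000), width = 100000)
make_windows <- function(ref, width = 100000L) {
  if (!inherits(ref, "reference_index")) {
    hg_assert(!is.null(names(ref)), "ref must be a reference_index or named lengths")
    ref <- reference_index(names(ref), ref)
  }
  hg_assert(width > 0, "window width must be > 0")
  width <- as.integer(width)
  out <- lapply(seq_len(nrow(ref)), function(i) {
    len <- ref$length[i]
    starts <- seq.int(0L, len - 1L, by = width)
    data.frame(chrom = ref$chrom[i], index = seq_along(starts),
               start = starts, end = pmin(starts + width, len),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
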