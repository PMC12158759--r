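#' SNP profile of one haplotype in one window
#'
#' @param chrom,window_index,start,end window coordinates (0-based half-open).
#' @param haplotype haplotype id.
#' @param alleles integer vector over the window's variant positions: 0 (ref),
#'   1 (alt), `NA` (missing).
#' @return Object of class `snp_profile`.
#' @export
snp_profile <- function(chrom, window_index, start, end, haplotype, alleles) {
  obj <- list(chrom = chrom, window_index = as.integer(window_index),
              start = as.integer(start), end = as.integer(end),
              haplotype = haplotype, alleles = as.integer(alleles))
  class(obj) <- "snp_profile"
  obj
}

#' SNP-profile distance between two haplotypes
#'
#' Counts positions where both profiles are non-missing and the alleles
#' differ (`differences`), and positions where both are non-missing
#' (`compared_sites`). Both profiles must belong to the same window.
#'
#' @param p,q `snp_profile` objects (or plain allele vectors of equal length).
#' @return List with `differences` and `compared_sites`.
#' @export
profile_distance <- function(p, q) {
  if (inherits(p, "snp_profile") || inherits(q, "snp_profile")) {
    hg_assert(inherits(p, "snp_profile") && inherits(q, "snp_profile"),
              "p and q must both be snp_profile objects")
    same <- identical(p$chrom, q$chrom) && p$window_index == q$window_index
    if (!same) stop("profiles belong to different windows")
    a <- p$alleles; b <- q$alleles
  } else {
    a <- as.integer(p); b <- as.integer(q)
  }
  hg_assert(length(a) == length(b), "profiles have different lengths")
  both <- !is.na(a) & !is.na(b)
  list(differences = sum(a[both] != b[both]), compared_sites = sum(both))
}

# pairwise difference and comparable-site counts for an allele matrix
# (sites x haplotypes); returns haplotype x haplotype matrices
profile_distance_matrix <- function(alleles) {
  if (nrow(alleles) == 0) {
    n <- ncol(alleles)
    z <- matrix(0, n, n, dimnames = list(colnames(alleles), colnames(alleles)))
    return(list(diffs = z, compared = z))
  }
  A <- alleles == 1L; A[is.na(A)] <- FALSE; storage.mode(A) <- "numeric"
  R <- alleles == 0L; R[is.na(R)] <- FALSE; storage.mode(R) <- "numeric"
  M <- !is.na(alleles); storage.mode(M) <- "numeric"
  list(diffs = crossprod(A, R) + crossprod(R, A), compared = crossprod(M))
}

#' Extract per-window SNP profiles from a variant table
#'
#' @param vt a [variant_table()].
#' @param windows window table from [make_windows()].
#' @return List with one element per window: the allele sub-matrix (sites x
#'   haplotypes) plus window coordinates.
#' @export
snp_profiles <- function(vt, windows) {
  lapply(seq_len(nrow(windows)), function(i) {
    rows <- variant_rows_in_window(vt, windows$chrom[i], windows$start[i], windows$end[i])
    list(chrom = windows$chrom[i], window_index = windows$index[i],
         start = windows$start[i], end = windows$end[i],
         pos = vt$sites$pos[rows],
         alleles = vt$alleles[rows, , drop = FALSE])
  })
}
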