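# union-find single linkage over a pairwise merge relation
single_linkage <- function(diffs, compared, threshold,
                           type = c("fraction", "absolute")) {
  type <- match.arg(type)
  ids <- colnames(diffs)
  n <- length(ids)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (n > 1) {
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        lim <- if (type == "fraction") threshold * compared[i, j] else threshold
        if (diffs[i, j] < lim) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[ri] <- rj
        }
      }
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  groups <- split(ids, root)
  groups <- lapply(groups, sort)
  # deterministic cluster ids: ordered by smallest member haplotype id
  groups[order(vapply(groups, `[`, character(1), 1))]
}

#' Cluster haplotypes within one window by SNP-profile distance
#'
#' Haplotypes are merged by single linkage under the pairwise relation
#' "differences < threshold x compared sites" (default threshold 0.10, i.e.
#' less than 10 differences per 100 compared SNPs; a pair at exactly 10% is
#' not merged). With `denominator = "window"` the threshold is applied to the
#' window's total SNP count instead of the pairwise non-missing count.
#'
#' @param profiles allele matrix (sites x haplotypes) for one window, or a
#'   window element from [snp_profiles()], or a list of [snp_profile()]s
#'   sharing one window.
#' @param threshold merge threshold as a fraction of compared sites.
#' @param denominator `"pairwise"` (non-missing sites of the pair) or
#'   `"window"` (all variant sites of the window).
#' @return Object of class `window_partition`: list of clusters (sorted
#'   haplotype ids), a `membership` vector mapping haplotype to cluster
#'   index, and a `flagged` indicator (see [cluster_empty_window()]).
#' @export
cluster_window <- function(profiles, threshold = 0.10,
                           denominator = c("pairwise", "window")) {
  denominator <- match.arg(denominator)
  alleles <- cluster_input_matrix(profiles)
  hg_assert(ncol(alleles) > 0, "no profiles supplied")
  if (nrow(alleles) == 0) return(cluster_empty_window(colnames(alleles)))
  d <- profile_distance_matrix(alleles)
  compared <- d$compared
  if (denominator == "window") compared[] <- nrow(alleles)
  clusters <- single_linkage(d$diffs, compared, threshold, "fraction")
  window_partition(clusters, flagged = FALSE)
}

cluster_input_matrix <- function(profiles) {
  if (is.matrix(profiles)) return(profiles)
  if (is.list(profiles) && !is.null(profiles$alleles)) return(profiles$alleles)
  if (is.list(profiles) && length(profiles) > 0 &&
      inherits(profiles[[1]], "snp_profile")) {
    key <- vapply(profiles, function(p) paste(p$chrom, p$window_index), character(1))
    hg_assert(length(unique(key)) == 1, "profiles must share one window")
    mat <- vapply(profiles, function(p) p$alleles,
                  integer(length(profiles[[1]]$alleles)))
    mat <- matrix(mat, ncol = length(profiles))
    colnames(mat) <- vapply(profiles, function(p) p$haplotype, character(1))
    return(mat)
  }
  if (is.list(profiles) && length(profiles) == 0) {
    stop("no profiles supplied")
  }
  stop("unsupported profiles input")
}

#' Collapse haplotypes of a window without variant information
#'
#' A window with zero variant positions carries no evidence to separate
#' haplotypes: all collapse into a single cluster flagged
#' "indistinguishable". The flag propagates into marker extraction.
#'
#' @param haplotypes haplotype ids.
#' @return A `window_partition` with one flagged cluster.
#' @export
cluster_empty_window <- function(haplotypes) {
  hg_assert(length(haplotypes) > 0, "no haplotypes supplied")
  window_partition(list(sort(as.character(haplotypes))), flagged = TRUE)
}

window_partition <- function(clusters, flagged) {
  membership <- integer(0)
  for (i in seq_along(clusters)) {
    membership[clusters[[i]]] <- i
  }
  obj <- list(clusters = unname(clusters), membership = membership,
              flagged = flagged)
  class(obj) <- "window_partition"
  obj
}

#' @export
print.window_partition <- function(x, ...) {
  cat("window_partition:", length(x$clusters), "cluster(s)",
      if (x$flagged) "[indistinguishable]" else "", "\n")
  invisible(x)
}
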