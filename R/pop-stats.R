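#' Window-based diversity statistics
#'
#' Per window: the number of segregating sites S, pairwise nucleotide
#' diversity per bp (`pi = sum_sites 2 p (1-p) n_s/(n_s - 1) / L`, the mean
#' pairwise difference per bp with pairwise-complete handling of missing
#' calls, where `n_s` is the number of non-missing calls at the site) and
#' Watterson's theta per bp (`theta_w = S / (a_{n-1} L)` with
#' `a_{n-1} = sum_{i=1}^{n-1} 1/i`). `L` defaults to the window width; an
#' effective length per window can be supplied when parts of the window are
#' unalignable.
#'
#' @param vt a [variant_table()] (n >= 2 haplotypes).
#' @param windows window table from [make_windows()] (10-kb windows are the
#'   conventional scale for these statistics).
#' @param eff_length optional numeric vector of effective window lengths.
#' @param count_blocks if `TRUE`, also report distinct haplotype counts per
#'   window via [count_haplotype_blocks()].
#' @param block_threshold absolute difference threshold for block counting.
#' @return `data.frame` (bedGraph-compatible) with columns `chrom`, `start`,
#'   `end`, `variant_sites`, `pi`, `theta_w` and optionally
#'   `distinct_haplotypes`.
#' @export
window_diversity <- function(vt, windows, eff_length = NULL,
                             count_blocks = FALSE, block_threshold = 10) {
  n <- n_haplotypes(vt)
  hg_assert(n >= 2, "need at least 2 haplotypes")
  a_n <- sum(1 / seq_len(n - 1))
  out <- windows[, c("chrom", "start", "end")]
  out$variant_sites <- 0L
  out$pi <- 0
  out$theta_w <- 0
  if (count_blocks) out$distinct_haplotypes <- NA_integer_
  for (i in seq_len(nrow(windows))) {
    L <- if (is.null(eff_length)) windows$end[i] - windows$start[i] else eff_length[i]
    rows <- variant_rows_in_window(vt, windows$chrom[i], windows$start[i], windows$end[i])
    al <- vt$alleles[rows, , drop = FALSE]
    ns <- rowSums(!is.na(al))
    nalt <- rowSums(al == 1L, na.rm = TRUE)
    seg <- ns >= 2 & nalt > 0 & nalt < ns
    out$variant_sites[i] <- sum(seg)
    p <- nalt[seg] / ns[seg]
    out$pi[i] <- sum(2 * p * (1 - p) * ns[seg] / (ns[seg] - 1)) / L
    out$theta_w[i] <- sum(seg) / (a_n * L)
    if (count_blocks)
      out$distinct_haplotypes[i] <- count_haplotype_blocks(al, block_threshold)
  }
  out
}

#' Worked-example equivalents of a diversity value
#'
#' Inverts per-bp nucleotide diversity into the average spacing between
#' pairwise differences and the expected number of pairwise variant sites in
#' a window (e.g. pi = 0.018 corresponds to one difference per ~56 bp and
#' 180 variants per 10 kb between a haplotype pair).
#'
#' @param pi per-bp nucleotide diversity.
#' @param window_width window width in bp.
#' @return List with `site_spacing_bp` and `variants_per_window`.
#' @export
diversity_equivalents <- function(pi, window_width = 10000) {
  hg_assert(pi > 0, "pi must be positive")
  list(site_spacing_bp = 1 / pi, variants_per_window = pi * window_width)
}

#' Count distinct haplotype blocks in a window
#'
#' Single-linkage clusters of haplotypes whose pairwise profile difference is
#' below an absolute threshold (default: fewer than 10 differing variants per
#' window, the conventional identity cutoff at the 10-kb scale; a pair at
#' exactly the threshold is split).
#'
#' @param alleles allele matrix (sites x haplotypes) for one window; zero
#'   rows mean no variant evidence and yield a single block.
#' @param identity_threshold absolute difference threshold.
#' @return Integer: number of distinct haplotype blocks.
#' @export
count_haplotype_blocks <- function(alleles, identity_threshold = 10) {
  hg_assert(is.matrix(alleles) && ncol(alleles) > 0, "empty window")
  d <- profile_distance_matrix(alleles)
  clusters <- single_linkage(d$diffs, d$compared, identity_threshold, "absolute")
  length(clusters)
}

#' Pairwise haplotype sharing matrix
#'
#' Entry (h1, h2) is the fraction of windows in which the pair falls into the
#' same cluster.
#'
#' @param partitions list of per-window partitions: [cluster_window()]
#'   results or named haplotype -> cluster vectors.
#' @return Symmetric numeric matrix with unit diagonal, class
#'   `sharing_matrix`.
#' @export
sharing_matrix <- function(partitions) {
  memb <- lapply(partitions, function(p) {
    if (inherits(p, "window_partition")) p$membership else p
  })
  haps <- sort(names(memb[[1]]))
  acc <- matrix(0, length(haps), length(haps), dimnames = list(haps, haps))
  for (m in memb) {
    same <- outer(m[haps], m[haps], "==")
    acc <- acc + same
  }
  acc <- acc / length(memb)
  class(acc) <- c("sharing_matrix", class(acc))
  acc
}

#' Expected r-squared under the drift-recombination (Hill-Weir) model
#'
#' @param d distance in bp.
#' @param rho per-bp recombination-rate parameter.
#' @param n number of sampled haplotypes.
#' @return Expected r-squared at distance `d`.
#' @export
ld_expected_r2 <- function(d, rho, n) {
  C <- rho * d
  ((10 + C) / ((2 + C) * (11 + C))) *
    (1 + ((3 + C) * (12 + 12 * C + C^2)) / (n * (2 + C) * (11 + C)))
}

#' Fit the LD-decay curve to (distance, r-squared) pairs
#'
#' Least-squares fit of [ld_expected_r2()] over `log(rho)`; the half-decay
#' distance is the smallest d at which the fitted curve reaches half its
#' value at d = 0.
#'
#' @param dist distances in bp.
#' @param r2 observed r-squared values.
#' @param n number of haplotypes underlying the r-squared values.
#' @param n_bins number of distance bins for the summarized curve.
#' @return Object of class `ld_fit` with `rho`, `half_decay`, the binned
#'   `curve` and `n`.
#' @export
fit_ld_curve <- function(dist, r2, n, n_bins = 25) {
  hg_assert(length(dist) == length(r2), "dist/r2 length mismatch")
  hg_assert(length(dist) >= 100, "fewer than 100 usable pairs")
  sse <- function(lrho) sum((r2 - ld_expected_r2(dist, exp(lrho), n))^2)
  starts <- log(10^seq(-9, -3, by = 1))
  fits <- lapply(starts, function(s)
    optim(s, sse, method = "BFGS", control = list(maxit = 500)))
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
  rho <- exp(best$par)
  r2_0 <- ld_expected_r2(0, rho, n)
  half <- tryCatch(
    uniroot(function(d) ld_expected_r2(d, rho, n) - r2_0 / 2,
            lower = 1, upper = 1e12)$root,
    error = function(e) NA_real_)
  brk <- seq(min(dist), max(dist), length.out = n_bins + 1)
  bin <- cut(dist, brk, include.lowest = TRUE)
  curve <- data.frame(
    distance = tapply(dist, bin, mean),
    mean_r2 = tapply(r2, bin, mean),
    n_pairs = as.integer(table(bin))
  )
  curve <- curve[!is.na(curve$distance), ]
  obj <- list(rho = rho, half_decay = half, curve = curve, n = n,
              sse = best$value)
  class(obj) <- "ld_fit"
  obj
}

#' @export
print.ld_fit <- function(x, ...) {
  cat(sprintf("ld_fit: rho = %.3g, half-decay = %.3g bp (n = %d)\n",
              x$rho, x$half_decay, x$n))
  invisible(x)
}

#' @export
plot.ld_fit <- function(x, ...) {
  graphics::plot(x$curve$distance, x$curve$mean_r2, xlab = "distance (bp)",
                 ylab = expression(r^2), pch = 16, col = "grey40", ...)
  d <- seq(0, max(x$curve$distance), length.out = 200)
  graphics::lines(d, ld_expected_r2(d, x$rho, x$n), col = "firebrick")
  invisible(x)
}

#' Genome-wide LD decay from phased haplotypes
#'
#' Computes r-squared (`D^2 / (p(1-p)q(1-q))`, pairwise-complete) for a
#' seeded, distance-stratified sample of site pairs within `max_dist`, after
#' a minor-allele-frequency filter, and fits the decay curve with
#' [fit_ld_curve()].
#'
#' @param vt a [variant_table()] with phased haplotype alleles (n >= 4).
#' @param maf_min minor-allele-frequency filter.
#' @param max_dist maximum pair distance in bp.
#' @param n_pairs_cap number of site pairs to sample.
#' @param seed RNG seed for the pair subsample.
#' @return An `ld_fit` object.
#' @export
ld_decay <- function(vt, maf_min = 0.05, max_dist = 1e6, n_pairs_cap = 10000,
                     seed = 1) {
  n <- n_haplotypes(vt)
  hg_assert(n >= 4, "need at least 4 haplotypes")
  al <- vt$alleles
  freq <- rowMeans(al, na.rm = TRUE)
  keep <- !is.na(freq) & pmin(freq, 1 - freq) >= maf_min
  al <- al[keep, , drop = FALSE]
  sites <- vt$sites[keep, , drop = FALSE]
  pairs <- with_seed(seed, sample_site_pairs(sites, max_dist, n_pairs_cap))
  hg_assert(nrow(pairs) >= 100, "fewer than 100 usable pairs")
  r2 <- pair_r2(al, pairs$i, pairs$j)
  ok <- !is.na(r2)
  fit_ld_curve(pairs$dist[ok], r2[ok], n)
}

sample_site_pairs <- function(sites, max_dist, cap) {
  ns <- nrow(sites)
  if (ns < 2) return(data.frame(i = integer(0), j = integer(0), dist = numeric(0)))
  # distance-stratified: draw target distances uniformly, then the nearest pair
  i <- sample.int(ns, 3 * cap, replace = TRUE)
  tgt <- runif(3 * cap, 1, max_dist)
  pos <- sites$pos
  j <- findInterval(pos[i] + tgt, pos)
  ok <- j >= 1 & j <= ns & j != i & sites$chrom[i] == sites$chrom[pmax(j, 1)]
  i <- i[ok]; j <- j[ok]
  d <- abs(pos[j] - pos[i])
  ok2 <- d > 0 & d <= max_dist
  out <- data.frame(i = i[ok2], j = j[ok2], dist = d[ok2])
  head(out, cap)
}

# r-squared for site pairs, pairwise-complete over haplotypes
pair_r2 <- function(al, i, j) {
  vapply(seq_along(i), function(k) {
    a <- al[i[k], ]; b <- al[j[k], ]
    ok <- !is.na(a) & !is.na(b)
    a <- a[ok]; b <- b[ok]
    if (length(a) < 4) return(NA_real_)
    p <- mean(a); q <- mean(b)
    den <- p * (1 - p) * q * (1 - q)
    if (den == 0) return(NA_real_)
    D <- mean(a * b) - p * q
    D^2 / den
  }, numeric(1))
}

#' r-squared from two-locus haplotype counts
#'
#' @param n_AB,n_ab,n_Ab,n_aB haplotype counts of the four two-locus classes.
#' @return r-squared.
#' @export
#' @examples
#' r2_from_counts(40, 40, 10, 10) # 0.36
r2_from_counts <- function(n_AB, n_ab, n_Ab, n_aB) {
  tot <- n_AB + n_ab + n_Ab + n_aB
  p <- (n_AB + n_Ab) / tot
  q <- (n_AB + n_aB) / tot
  D <- n_AB / tot - p * q
  D^2 / (p * (1 - p) * q * (1 - q))
}
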