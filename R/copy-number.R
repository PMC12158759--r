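#' K-mer count table
#'
#' @param kmer character vector of k-mers (canonicalized on construction).
#' @param count non-negative integer counts.
#' @return Named integer vector (canonical k-mer -> count) of class
#'   `kmer_count_table`.
#' @export
kmer_count_table <- function(kmer, count) {
  hg_assert(length(kmer) == length(count), "kmer/count length mismatch")
  hg_assert(all(count >= 0), "counts must be non-negative")
  if (length(kmer) > 0)
    hg_assert(length(unique(nchar(kmer))) == 1, "k-mers must share one length")
  key <- canonicalize_kmers(kmer)
  x <- tapply(as.integer(count), key, sum)
  out <- setNames(as.integer(x), names(x))
  class(out) <- "kmer_count_table"
  out
}

#' Read a Jellyfish-style k-mer count TSV (`kmer<TAB>count`, no header)
#'
#' @param path file path.
#' @return A [kmer_count_table()].
#' @export
read_kmer_counts <- function(path) {
  df <- read.table(path, header = FALSE, sep = "\t", stringsAsFactors = FALSE,
                   col.names = c("kmer", "count"))
  kmer_count_table(df$kmer, df$count)
}

#' Collect per-node marker count vectors
#'
#' Each node's vector has one entry per marker; markers absent from the count
#' table get 0. Nodes without markers are flagged uninformative and excluded
#' from EM fitting.
#'
#' @param markers named list node -> marker k-mers (disjoint across nodes).
#' @param counts a [kmer_count_table()] (or named numeric vector).
#' @return Object of class `node_counts`: named list of numeric vectors with
#'   attribute `uninformative` (character vector of node ids).
#' @export
collect_node_counts <- function(markers, counts) {
  cnt <- unclass(counts)
  out <- lapply(markers, function(mk) {
    if (length(mk) == 0) return(numeric(0))
    x <- cnt[mk]
    x[is.na(x)] <- 0
    as.numeric(unname(x))
  })
  attr(out, "uninformative") <- names(markers)[lengths(markers) == 0]
  class(out) <- "node_counts"
  out
}

#' Mixture parameters for the copy-number model
#'
#' Component means are tied to a single haploid depth `lambda`: `mu_c =
#' c * lambda` for copies 1..4 and `mu_0 = epsilon` (a small error mean
#' absorbing sequencing-error k-mers). Component variance is
#' `alpha * max(mu_c, 1)` (Poisson-like scaling with overdispersion factor
#' `alpha`).
#'
#' @param lambda haploid k-mer depth (counts per marker).
#' @param epsilon zero-copy (error) mean, `0 < epsilon < lambda`.
#' @param alpha variance scale.
#' @param weights component weights over copies 0..4 (simplex).
#' @return Object of class `mixture_params`.
#' @export
mixture_params <- function(lambda, epsilon = 1, alpha = 1,
                           weights = rep(0.2, 5)) {
  hg_assert(lambda > 0, "lambda must be positive")
  hg_assert(epsilon > 0 && epsilon < lambda, "need 0 < epsilon < lambda")
  hg_assert(alpha > 0, "alpha must be positive")
  hg_assert(length(weights) == 5 && all(weights >= 0) &&
              abs(sum(weights) - 1) < 1e-8, "weights must be a 5-simplex")
  obj <- list(lambda = lambda, epsilon = epsilon, alpha = alpha,
              weights = as.numeric(weights))
  class(obj) <- "mixture_params"
  obj
}

#' @export
print.mixture_params <- function(x, ...) {
  cat(sprintf("mixture_params: lambda = %.3f, epsilon = %.3f, alpha = %.3f\n",
              x$lambda, x$epsilon, x$alpha))
  cat("  weights (copy 0..4):", paste(sprintf("%.3f", x$weights), collapse = " "), "\n")
  invisible(x)
}

#' Initialize mixture parameters from marker counts
#'
#' The haploid depth is initialized at the tallest non-zero mode of a
#' smoothed histogram of the counts; the error mean starts at 1, weights
#' uniform, variance scale 1.
#'
#' @param counts numeric vector of all marker counts (or a `node_counts`
#'   object); at least 100 values.
#' @return A [mixture_params()] object.
#' @export
init_mixture <- function(counts) {
  if (is.list(counts)) counts <- unlist(counts, use.names = FALSE)
  hg_assert(length(counts) >= 100, "need at least 100 marker counts")
  if (all(counts == 0)) stop("no signal: all marker counts are zero")
  nz <- counts[counts > 0]
  # counts of just a few reads are sequencing-error k-mers (the epsilon
  # component), not a depth mode; ignore them if enough signal remains
  hi <- nz[nz >= 6]
  if (length(hi) >= 100) nz <- hi
  d <- density(nz, bw = max(1, stats::bw.nrd0(nz)), n = 512,
               from = 0.5, to = max(nz))
  peak <- which(diff(sign(diff(d$y))) < 0) + 1L
  if (length(peak) == 0) peak <- which.max(d$y)
  # the haploid depth is the lowest substantial mode: higher modes are the
  # 2x/3x/4x copy peaks of the same depth
  prominent <- peak[d$y[peak] >= 0.25 * max(d$y[peak])]
  lambda0 <- d$x[min(prominent)]
  mixture_params(lambda = lambda0, epsilon = min(1, lambda0 / 8), alpha = 1,
                 weights = rep(0.2, 5))
}

# component means / variances under params
mixture_moments <- function(params) {
  mu <- c(params$epsilon, params$lambda * 1:4)
  list(mu = mu, var = params$alpha * pmax(mu, 1))
}

# sufficient statistics per node after winsorization at 8*lambda
node_suff_stats <- function(node_counts, lambda) {
  cap <- 8 * lambda
  m <- lengths(node_counts)
  x <- pmin(unlist(node_counts, use.names = FALSE), cap)
  idx <- rep.int(seq_along(node_counts), m)
  s1 <- rowsum(x, idx, reorder = TRUE)[, 1]
  s2 <- rowsum(x^2, idx, reorder = TRUE)[, 1]
  list(m = as.numeric(m), s1 = as.numeric(s1), s2 = as.numeric(s2))
}

# E-step: log posterior over copies 0..4 for each node, from sufficient stats
posterior_matrix <- function(st, params) {
  mm <- mixture_moments(params)
  ll <- sapply(1:5, function(c) {
    mu <- mm$mu[c]; v <- mm$var[c]
    -0.5 * st$m * log(2 * pi * v) -
      (st$s2 - 2 * mu * st$s1 + st$m * mu^2) / (2 * v) +
      log(params$weights[c])
  })
  ll <- matrix(ll, ncol = 5)
  mx <- apply(ll, 1, max)
  p <- exp(ll - mx)
  p <- p / rowSums(p)
  if (anyNA(p)) stop("NaN in copy-number posterior")
  p
}

#' Classify nodes under fixed mixture parameters (E-step only)
#'
#' @param node_counts a [collect_node_counts()] result (or plain list of
#'   numeric count vectors).
#' @param params a [mixture_params()] object.
#' @return `data.frame` with node, assigned copy (argmax posterior) and
#'   posterior columns `post0..post4`.
#' @export
classify_nodes <- function(node_counts, params) {
  informative <- lengths(node_counts) > 0
  nc <- node_counts[informative]
  st <- node_suff_stats(nc, params$lambda)
  p <- posterior_matrix(st, params)
  df <- data.frame(node = if (is.null(names(nc))) as.character(seq_along(nc))
                   else names(nc),
                   copy = max.col(p, ties.method = "first") - 1L,
                   n_markers = lengths(nc), stringsAsFactors = FALSE)
  colnames(p) <- paste0("post", 0:4)
  cbind(df, as.data.frame(p))
}

#' Estimate node copy numbers by Gaussian-mixture EM
#'
#' Each informative node's marker counts are modelled as conditionally
#' independent draws from a Gaussian with mean `mu_c` (`mu_0 = epsilon`,
#' `mu_c = c * lambda` for c >= 1) and variance `alpha * max(mu_c, 1)`. The
#' E-step computes per-node posteriors over copies 0..4 (in log space); the
#' M-step re-estimates `lambda` (depth-weighted least squares), `epsilon`
#' (capped below `lambda / 4`), `alpha` and the weights. Counts above
#' `8 * lambda` are winsorized before each E-step. Iteration stops when the
#' maximum absolute change across (`lambda`, `epsilon`, `alpha`, weights)
#' falls below `tol`, or after `max_iter` iterations.
#'
#' @param node_counts a [collect_node_counts()] result.
#' @param params0 initial [mixture_params()]; default [init_mixture()].
#' @param tol convergence tolerance on the maximum absolute parameter change.
#' @param max_iter iteration cap.
#' @return Object of class `copy_number_fit` with the assignment table,
#'   fitted `params`, `converged` flag and `iterations` used.
#' @export
em_copy_numbers <- function(node_counts, params0 = NULL, tol = 0.001,
                            max_iter = 100L) {
  informative <- lengths(node_counts) > 0
  hg_assert(any(informative), "no informative node (all marker sets empty)")
  nc <- node_counts[informative]
  if (is.null(params0)) params0 <- init_mixture(nc)
  params <- params0
  converged <- FALSE
  iter <- 0L
  p <- NULL
  while (iter < max_iter) {
    iter <- iter + 1L
    st <- node_suff_stats(nc, params$lambda)
    p <- posterior_matrix(st, params)
    mm <- mixture_moments(params)
    # M-step
    w_new <- colMeans(p)
    num <- 0; den <- 0
    for (c in 1:4) {
      v <- mm$var[c + 1]
      num <- num + sum(p[, c + 1] * c * st$s1) / v
      den <- den + sum(p[, c + 1] * c^2 * st$m) / v
    }
    lambda_new <- if (den > 0) num / den else params$lambda
    if (lambda_new <= 0) lambda_new <- params$lambda
    e_den <- sum(p[, 1] * st$m)
    eps_new <- if (e_den > 0) sum(p[, 1] * st$s1) / e_den else params$epsilon
    eps_new <- min(max(eps_new, 1e-3), lambda_new / 4)
    mu_new <- c(eps_new, lambda_new * 1:4)
    a_num <- 0
    for (c in 0:4) {
      mu <- mu_new[c + 1]
      a_num <- a_num + sum(p[, c + 1] *
                             (st$s2 - 2 * mu * st$s1 + st$m * mu^2)) / max(mu, 1)
    }
    alpha_new <- max(a_num / sum(p * st$m), 1e-3)
    delta <- max(abs(c(lambda_new - params$lambda, eps_new - params$epsilon,
                       alpha_new - params$alpha, w_new - params$weights)))
    w_new <- pmax(w_new, 1e-12); w_new <- w_new / sum(w_new)
    params <- mixture_params(lambda_new, eps_new, alpha_new, w_new)
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  st <- node_suff_stats(nc, params$lambda)
  p <- posterior_matrix(st, params)
  assign <- classify_nodes(nc, params)
  fit <- list(
    assignments = assign,
    params = params,
    converged = converged,
    iterations = iter,
    n_nodes = length(node_counts),
    uninformative = attr(node_counts, "uninformative"),
    loglik = NA_real_
  )
  # total log-likelihood from the final E-step in log space
  mm <- mixture_moments(params)
  ll <- sapply(1:5, function(c) {
    mu <- mm$mu[c]; v <- mm$var[c]
    -0.5 * st$m * log(2 * pi * v) -
      (st$s2 - 2 * mu * st$s1 + st$m * mu^2) / (2 * v) + log(params$weights[c])
  })
  ll <- matrix(ll, ncol = 5)
  mx <- apply(ll, 1, max)
  fit$loglik <- sum(mx + log(rowSums(exp(ll - mx))))
  class(fit) <- "copy_number_fit"
  fit
}

#' @export
print.copy_number_fit <- function(x, ...) {
  cat("copy_number_fit:", nrow(x$assignments), "informative node(s)\n")
  cat(sprintf("  lambda = %.3f, epsilon = %.3f, alpha = %.3f\n",
              x$params$lambda, x$params$epsilon, x$params$alpha))
  cat("  ", if (x$converged) "converged" else "NOT converged",
      "after", x$iterations, "iteration(s)\n")
  tab <- table(factor(x$assignments$copy, levels = 0:4))
  cat("  copies 0..4:", paste(as.integer(tab), collapse = " "), "\n")
  invisible(x)
}

#' @export
summary.copy_number_fit <- function(object, ...) {
  tab <- table(factor(object$assignments$copy, levels = 0:4))
  res <- list(copy_table = tab, params = object$params,
              converged = object$converged, iterations = object$iterations,
              loglik = object$loglik,
              mean_max_posterior = mean(apply(
                as.matrix(object$assignments[, paste0("post", 0:4)]), 1, max)),
              n_uninformative = length(object$uninformative))
  class(res) <- "summary.copy_number_fit"
  res
}

#' @export
print.summary.copy_number_fit <- function(x, ...) {
  cat("copy-number EM summary\n")
  print(x$params)
  cat("  copies 0..4:", paste(as.integer(x$copy_table), collapse = " "), "\n")
  cat(sprintf("  mean max posterior: %.4f\n", x$mean_max_posterior))
  cat(sprintf("  log-likelihood: %.2f (%s, %d iterations)\n", x$loglik,
              if (x$converged) "converged" else "not converged", x$iterations))
  cat("  uninformative nodes:", x$n_uninformative, "\n")
  invisible(x)
}

#' @export
coef.copy_number_fit <- function(object, ...) {
  c(lambda = object$params$lambda, epsilon = object$params$epsilon,
    alpha = object$params$alpha,
    setNames(object$params$weights, paste0("w", 0:4)))
}

#' @export
plot.copy_number_fit <- function(x, node_counts = NULL, ...) {
  mm <- mixture_moments(x$params)
  if (!is.null(node_counts)) {
    cnt <- unlist(node_counts, use.names = FALSE)
    graphics::hist(cnt, breaks = 60, main = "marker k-mer counts",
                   xlab = "count", col = "grey85", border = "white", ...)
  } else {
    graphics::plot(NULL, xlim = c(0, mm$mu[5] * 1.3), ylim = 0:1,
                   xlab = "count", ylab = "", yaxt = "n",
                   main = "mixture component means")
  }
  graphics::abline(v = mm$mu, col = c("grey40", rep("firebrick", 4)), lty = 2)
  invisible(x)
}

#' Per-window copy-number consistency report
#'
#' In a tetraploid query, the copies of a window's nodes should sum to 4.
#' Windows deviating from 4 are flagged.
#'
#' @param fit a [em_copy_numbers()] fit (or its assignment table).
#' @param graph the [build_haplotype_graph()] the nodes came from.
#' @param expected_total expected per-window copy sum (4 for a tetraploid).
#' @return `data.frame` with one row per window: `chrom`, `window_index`,
#'   `copy_sum`, `flagged`.
#' @export
window_consistency_report <- function(fit, graph, expected_total = 4L) {
  assign <- if (inherits(fit, "copy_number_fit")) fit$assignments else fit
  copies <- setNames(assign$copy, assign$node)
  nd <- graph$nodes
  nd$copy <- copies[nd$node]
  nd$copy[is.na(nd$copy)] <- 0L
  agg <- stats::aggregate(copy ~ chrom + window_index, data = nd, FUN = sum)
  agg <- agg[order(agg$chrom, agg$window_index), ]
  rownames(agg) <- NULL
  names(agg)[names(agg) == "copy"] <- "copy_sum"
  agg$flagged <- agg$copy_sum != expected_total
  agg
}
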