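#' Pan-genome growth points over haplotype orderings
#'
#' Pan-genome size after adding the first x haplotypes is the cardinality of
#' the union of their content-token sets (k-mers, segment ids or any fixed
#' -size sequence unit), times the token size. Orderings are seeded random
#' permutations of the haplotypes.
#'
#' @param content_sets named list: haplotype -> vector of content tokens.
#' @param orderings number of random orderings (>= 1).
#' @param seed RNG seed for the permutations.
#' @param token_size size of one token in the output unit (e.g. Mb per
#'   token).
#' @return `data.frame` with columns `ordering`, `x`, `y`.
#' @export
growth_points <- function(content_sets, orderings = 1, seed = 1, token_size = 1) {
  hg_assert(orderings >= 1, "need at least one ordering")
  hg_assert(length(content_sets) >= 1 && all(lengths(content_sets) > 0),
            "content sets must be non-empty")
  n <- length(content_sets)
  sets <- lapply(content_sets, unique)
  with_seed(seed, {
    do.call(rbind, lapply(seq_len(orderings), function(o) {
      ord <- if (o == 1) seq_len(n) else sample.int(n)
      seen <- character(0)
      y <- numeric(n)
      for (x in seq_len(n)) {
        seen <- union(seen, as.character(sets[[ord[x]]]))
        y[x] <- length(seen) * token_size
      }
      data.frame(ordering = o, x = seq_len(n), y = y)
    }))
  })
}

#' Fit the pan-genome saturation model
#'
#' Least-squares fit of `y = a1 * x / (x + a2) + a3` by BFGS with multiple
#' starts (`a3 ~ y(1)`, `a1 ~ 2 (max y - y(1))`, `a2` in 1/5/20). The
#' asymptotic pan-genome size is `a1 + a3`.
#'
#' @param points `data.frame` with columns `x` and `y` (>= 4 distinct x).
#' @return Object of class `saturation_fit` with `a1`, `a2`, `a3`,
#'   `asymptote` and the residual sum of squares.
#' @export
fit_saturation <- function(points) {
  x <- points$x; y <- points$y
  hg_assert(length(unique(x)) >= 4, "need at least 4 distinct x values")
  sse <- function(p) {
    pred <- p[1] * x / (x + p[2]) + p[3]
    sum((y - pred)^2)
  }
  y1 <- mean(y[x == min(x)])
  a1_0 <- max(2 * (max(y) - y1), 1e-6)
  fits <- list()
  for (a2_0 in c(1, 5, 20)) {
    f <- tryCatch(
      optim(c(a1_0, a2_0, y1), sse, method = "BFGS",
            control = list(maxit = 2000, reltol = 1e-14)),
      error = function(e) NULL)
    if (!is.null(f)) fits[[length(fits) + 1L]] <- f
  }
  if (length(fits) == 0) stop("saturation fit failed from all starts")
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
  obj <- list(a1 = best$par[1], a2 = best$par[2], a3 = best$par[3],
              asymptote = best$par[1] + best$par[3], residual = best$value,
              n_points = length(x))
  class(obj) <- "saturation_fit"
  obj
}

#' @export
print.saturation_fit <- function(x, ...) {
  cat(sprintf(
    "saturation_fit: y = %.4g * x / (x + %.4g) + %.4g\n", x$a1, x$a2, x$a3))
  cat(sprintf("  asymptote a1 + a3 = %.4g, residual SS = %.4g (%d points)\n",
              x$asymptote, x$residual, x$n_points))
  invisible(x)
}

#' @export
coef.saturation_fit <- function(object, ...) {
  c(a1 = object$a1, a2 = object$a2, a3 = object$a3)
}

#' @export
predict.saturation_fit <- function(object, newdata, ...) {
  x <- if (is.data.frame(newdata)) newdata$x else newdata
  object$a1 * x / (x + object$a2) + object$a3
}

#' @export
plot.saturation_fit <- function(x, points = NULL, ...) {
  xs <- seq(1, max(40, if (is.null(points)) 40 else max(points$x)),
            length.out = 200)
  graphics::plot(xs, predict(x, xs), type = "l", col = "firebrick",
                 xlab = "haplotypes included", ylab = "pan-genome size", ...)
  if (!is.null(points)) graphics::points(points$x, points$y, pch = 16,
                                         col = "grey40")
  graphics::abline(h = x$asymptote, lty = 2, col = "grey60")
  invisible(x)
}

#' Number of genomes needed to reach a fraction of the asymptote
#'
#' Closed-form inversion of the saturation model: with
#' `g = q (a1 + a3) - a3`, `x = a2 g / (a1 - g)`.
#'
#' @param fit a [fit_saturation()] result.
#' @param q target fraction of the asymptotic pan-genome size; must satisfy
#'   `a3 < q (a1 + a3) < a1 + a3`.
#' @return Number of genomes x (real).
#' @export
genomes_for_fraction <- function(fit, q) {
  g <- q * (fit$a1 + fit$a3) - fit$a3
  if (!(g > 0 && g < fit$a1))
    stop("q outside the attainable range (a3 < q*(a1+a3) < a1+a3)")
  fit$a2 * g / (fit$a1 - g)
}

#' Partition gene families into core / softcore / dispensable / private
#'
#' With n haplotypes the bands are: core = present in all n; softcore =
#' `ceil(0.925 n) .. n - 1` (37--39 of 40); dispensable = 2 up to the
#' softcore lower bound minus one (2--36 of 40); private = exactly 1. Custom
#' bands can be supplied.
#'
#' @param mat presence/absence matrix (families x haplotypes, 0/1), no
#'   all-zero rows.
#' @param softcore_low optional lower bound of the softcore band (default
#'   `ceiling(0.925 * n)`).
#' @return Object of class `family_categories`: per-family table plus count
#'   and percentage summaries.
#' @export
family_categories <- function(mat, softcore_low = NULL) {
  mat <- as.matrix(mat)
  n <- ncol(mat)
  k <- rowSums(mat > 0)
  if (any(k == 0)) stop("all-zero family row(s): ",
                        paste(head(which(k == 0)), collapse = ", "))
  if (is.null(softcore_low)) softcore_low <- ceiling(0.925 * n)
  category <- ifelse(k == n, "core",
                     ifelse(k >= softcore_low, "softcore",
                            ifelse(k >= 2, "dispensable", "private")))
  lev <- c("core", "softcore", "dispensable", "private")
  counts <- table(factor(category, levels = lev))
  obj <- list(
    table = data.frame(family = rownames(mat) %||% as.character(seq_len(nrow(mat))),
                       n_present = as.integer(k), category = category,
                       stringsAsFactors = FALSE),
    counts = setNames(as.integer(counts), lev),
    percentages = setNames(100 * as.integer(counts) / nrow(mat), lev),
    n_haplotypes = n, softcore_low = softcore_low
  )
  class(obj) <- "family_categories"
  obj
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.family_categories <- function(x, ...) {
  cat("family_categories over", x$n_haplotypes, "haplotypes\n")
  for (cl in names(x$counts))
    cat(sprintf("  %-11s %6d (%5.2f%%)\n", cl, x$counts[[cl]],
                x$percentages[[cl]]))
  invisible(x)
}

#' Pan- and core-genome family curves by resampling
#'
#' For each sample size s, random subsets of s haplotypes are drawn (all
#' subsets enumerated when there are no more than `resamples` of them) and
#' the number of families present in at least one member (pan) and in all
#' members (core) is recorded.
#'
#' @param mat presence/absence matrix (families x haplotypes).
#' @param sizes sample sizes (default 1..n).
#' @param resamples number of random subsets per size (>= 1; up to 2000 in
#'   the conventional setting).
#' @param seed RNG seed.
#' @return `data.frame` with columns `size`, `pan_mean`, `pan_sd`,
#'   `core_mean`, `core_sd`, `n_draws`, `exhaustive`.
#' @export
pan_core_curves <- function(mat, sizes = NULL, resamples = 2000, seed = 1) {
  hg_assert(resamples >= 1, "resamples must be >= 1")
  mat <- as.matrix(mat) > 0
  n <- ncol(mat)
  if (is.null(sizes)) sizes <- seq_len(n)
  with_seed(seed, {
    out <- lapply(sizes, function(s) {
      n_sub <- choose(n, s)
      if (n_sub <= resamples) {
        subs <- combn(n, s, simplify = FALSE)
      } else {
        subs <- replicate(resamples, sort(sample.int(n, s)), simplify = FALSE)
      }
      pan <- vapply(subs, function(ix)
        sum(rowSums(mat[, ix, drop = FALSE]) >= 1), numeric(1))
      core <- vapply(subs, function(ix)
        sum(rowSums(mat[, ix, drop = FALSE]) == s), numeric(1))
      data.frame(size = s,
                 pan_mean = mean(pan), pan_sd = if (length(pan) > 1) sd(pan) else 0,
                 core_mean = mean(core), core_sd = if (length(core) > 1) sd(core) else 0,
                 n_draws = length(subs), exhaustive = n_sub <= resamples)
    })
    do.call(rbind, out)
  })
}

#' Random-tetraploid gene-family null test
#'
#' Compares the number of gene families present in a focal genome's four
#' haplotypes against a null distribution obtained by repeatedly drawing
#' four random haplotypes (without replacement within a draw). The default
#' empirical p-value is lower-tail (fraction of null draws less than or
#' equal to the observation), matching the question of whether a real
#' tetraploid carries fewer families than a random combination.
#'
#' @param mat presence/absence matrix (families x haplotypes).
#' @param focal character or integer vector of the focal genome's 4
#'   haplotype columns.
#' @param draws number of null draws (>= 100).
#' @param seed RNG seed.
#' @param alternative `"less"` (default) or `"two.sided"`.
#' @return List with `observed`, `null_mean`, `null_sd`, `p_value`, `draws`,
#'   class `tetraploid_null`.
#' @export
tetraploid_family_null <- function(mat, focal, draws = 10000, seed = 1,
                                   alternative = c("less", "two.sided")) {
  alternative <- match.arg(alternative)
  hg_assert(draws >= 100, "need at least 100 null draws")
  mat <- as.matrix(mat) > 0
  if (is.character(focal)) focal <- match(focal, colnames(mat))
  hg_assert(length(focal) == 4 && !anyNA(focal), "focal must name 4 haplotypes")
  fam_count <- function(ix) sum(rowSums(mat[, ix, drop = FALSE]) >= 1)
  observed <- fam_count(focal)
  null <- with_seed(seed, vapply(seq_len(draws), function(i)
    fam_count(sample.int(ncol(mat), 4)), numeric(1)))
  p_low <- mean(null <= observed)
  p <- switch(alternative, less = p_low,
              two.sided = min(1, 2 * min(p_low, mean(null >= observed))))
  obj <- list(observed = observed, null_mean = mean(null), null_sd = sd(null),
              p_value = p, draws = draws, alternative = alternative)
  class(obj) <- "tetraploid_null"
  obj
}

#' @export
print.tetraploid_null <- function(x, ...) {
  cat(sprintf(
    "tetraploid_null: observed %d families; null %.1f +/- %.1f (%d draws)\n",
    x$observed, x$null_mean, x$null_sd, x$draws))
  cat(sprintf("  empirical p (%s) = %.4g\n", x$alternative, x$p_value))
  invisible(x)
}
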