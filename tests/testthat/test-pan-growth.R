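test_that("growth points are set-union cardinalities", {
  gp <- growth_points(list(a = 1:10, b = 11:20))
  expect_equal(gp$y, c(10, 20))
  gp2 <- growth_points(list(a = 1:10, b = 1:10, c = 1:10), orderings = 3)
  expect_true(all(gp2$y == 10))
  # nested random sets against a brute-force union oracle over each ordering
  set.seed(3)
  sets <- lapply(1:6, function(i) sample(1:200, sample(20:80, 1)))
  names(sets) <- paste0("h", 1:6)
  gp3 <- growth_points(sets, orderings = 4, seed = 9)
  for (o in unique(gp3$ordering)) {
    ys <- gp3$y[gp3$ordering == o]
    expect_true(all(diff(ys) >= 0))       # non-decreasing within an ordering
    expect_equal(ys[6], length(unique(unlist(sets))))
  }
  expect_error(growth_points(sets, orderings = 0), "ordering")
})

test_that("saturation fit recovers noiseless generating parameters", {
  x <- 1:40
  y <- 1000 * x / (x + 10) + 700
  fit <- fit_saturation(data.frame(x = x, y = y))
  expect_lt(abs(fit$a1 - 1000) / 1000, 0.01)
  expect_lt(abs(fit$a2 - 10) / 10, 0.01)
  expect_lt(abs(fit$a3 - 700) / 700, 0.01)
  expect_equal(fit$asymptote, fit$a1 + fit$a3)
  # curve at large x approaches a1 + a3
  expect_equal(predict(fit, 1e9), fit$asymptote, tolerance = 1e-6)
  # constant y degenerates to a1 -> 0 with asymptote y
  fc <- fit_saturation(data.frame(x = 1:10, y = rep(500, 10)))
  expect_lt(abs(fc$a1), 1)
  expect_equal(fc$asymptote, 500, tolerance = 1)
  expect_error(fit_saturation(data.frame(x = c(1, 1, 2), y = 1:3)), "4 distinct")
})

test_that("saturation fit tolerates multiplicative noise", {
  set.seed(19)
  x <- 1:40
  y <- (1000 * x / (x + 10) + 700) * (1 + rnorm(40, 0, 0.02))
  fit <- fit_saturation(data.frame(x = x, y = y))
  expect_lt(abs(fit$a1 - 1000) / 1000, 0.10)
  expect_lt(abs(fit$a3 - 700) / 700, 0.10)
})

test_that("genomes_for_fraction inverts the fitted curve", {
  fit <- structure(list(a1 = 1000, a2 = 10, a3 = 700, asymptote = 1700),
                   class = "saturation_fit")
  expect_equal(genomes_for_fraction(fit, 0.5), 10 * 150 / 850)
  expect_error(genomes_for_fraction(fit, 1), "attainable")
  expect_error(genomes_for_fraction(fit, 0.2), "attainable") # below a3 share
  set.seed(5)
  for (i in 1:20) {
    f <- structure(list(a1 = runif(1, 100, 2000), a2 = runif(1, 1, 30),
                        a3 = runif(1, 50, 900)), class = "saturation_fit")
    f$asymptote <- f$a1 + f$a3
    q <- runif(1, f$a3 / f$asymptote + 0.01, 0.99)
    x <- genomes_for_fraction(f, q)
    expect_equal(predict(f, x) / f$asymptote, q, tolerance = 1e-9)
  }
})

test_that("family categories follow the sharing bands and sum to totals", {
  set.seed(2)
  n <- 40
  k <- c(40, 38, 1, 20, 40, 37, 39, 2, 36, 1, 5)
  mat <- t(vapply(k, function(ki) sample(c(rep(1L, ki), rep(0L, n - ki))),
                  integer(n)))
  rownames(mat) <- paste0("fam", seq_along(k))
  fc <- family_categories(mat)
  expect_equal(unname(fc$table$category[1:3]), c("core", "softcore", "private"))
  expect_equal(fc$counts[["core"]], 2L)
  expect_equal(fc$counts[["softcore"]], 3L)     # 38, 37, 39
  expect_equal(fc$counts[["dispensable"]], 4L)  # 20, 2, 36, 5
  expect_equal(fc$counts[["private"]], 2L)
  expect_equal(sum(fc$counts), nrow(mat))
  expect_equal(sum(fc$percentages), 100, tolerance = 0.01)
  bad <- rbind(mat, fam99 = rep(0L, n))
  expect_error(family_categories(bad), "all-zero")
})

test_that("pan/core curves equal exhaustive subset enumeration on a fixture", {
  mat <- rbind(
    f1 = c(1, 1, 1, 1, 1),
    f2 = c(1, 0, 1, 0, 1),
    f3 = c(0, 0, 1, 0, 0),
    f4 = c(1, 1, 0, 1, 1),
    f5 = c(0, 1, 1, 1, 0),
    f6 = c(1, 0, 0, 0, 0)
  )
  colnames(mat) <- paste0("h", 1:5)
  got <- pan_core_curves(mat, resamples = 2000, seed = 4)
  # independent oracle: enumerate all subsets of each size directly
  for (s in 1:5) {
    subs <- combn(5, s, simplify = FALSE)
    pan <- vapply(subs, function(ix) sum(rowSums(mat[, ix, drop = FALSE]) >= 1),
                  numeric(1))
    core <- vapply(subs, function(ix) sum(rowSums(mat[, ix, drop = FALSE]) == s),
                   numeric(1))
    expect_equal(got$pan_mean[s], mean(pan))
    expect_equal(got$core_mean[s], mean(core))
    expect_equal(got$pan_sd[s], if (length(pan) > 1) sd(pan) else 0)
    expect_equal(got$core_sd[s], if (length(core) > 1) sd(core) else 0)
    # monotonicity holds subset-wise: adding any haplotype never shrinks the
    # pan set nor grows the core set
    for (ix in subs) {
      for (add in setdiff(1:5, ix)) {
        expect_gte(sum(rowSums(mat[, c(ix, add), drop = FALSE]) >= 1),
                   sum(rowSums(mat[, ix, drop = FALSE]) >= 1))
        expect_lte(sum(rowSums(mat[, c(ix, add), drop = FALSE]) == s + 1),
                   sum(rowSums(mat[, ix, drop = FALSE]) == s))
      }
    }
  }
  expect_equal(got$pan_sd[5], 0)
  expect_equal(got$pan_mean[5], 6)
  expect_equal(got$core_mean[5], 1)
})

test_that("tetraploid null test behaves at its extremes and calibrates", {
  set.seed(77)
  mat <- matrix(rbinom(300 * 12, 1, 0.5), 300, 12,
                dimnames = list(paste0("f", 1:300), paste0("h", 1:12)))
  mat[rowSums(mat) == 0, 1] <- 1L
  # focal set covering all families -> p ~ 1
  mat2 <- mat; mat2[, 1] <- 1L
  rich <- tetraploid_family_null(mat2, c("h1", "h2", "h3", "h4"), draws = 500,
                                 seed = 1)
  expect_gt(rich$p_value, 0.95)
  # four identical, family-poor haplotypes dominate any distinct 4-subset
  mat3 <- mat
  poor <- which(rowSums(mat) <= 4)
  mat3[, 9:12] <- 0L; mat3[poor, 9:12] <- 1L
  low <- tetraploid_family_null(mat3, c("h9", "h10", "h11", "h12"),
                                draws = 500, seed = 2)
  expect_lt(low$observed, low$null_mean)
  expect_lt(low$p_value, 0.1)
  # random focal subsets give p spread over (0, 1)
  ps <- vapply(1:20, function(i) {
    focal <- sample(colnames(mat), 4)
    tetraploid_family_null(mat, focal, draws = 400, seed = i)$p_value
  }, numeric(1))
  expect_gt(mean(ps), 0.2); expect_lt(mean(ps), 0.8)
  expect_error(tetraploid_family_null(mat, paste0("h", 1:4), draws = 50),
               "100")
})
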