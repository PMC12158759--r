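test_that("windows tile each chromosome without gaps or overlaps", {
  w <- make_windows(reference_index("chr01", 250000), 100000)
  expect_equal(w$start, c(0L, 100000L, 200000L))
  expect_equal(w$end, c(100000L, 200000L, 250000L))
  expect_equal(make_windows(reference_index("c", 100000), 100000)$end, 100000L)
  expect_equal(make_windows(reference_index("c", 1), 100000)[, c("start", "end")],
               data.frame(start = 0L, end = 1L))
  expect_error(make_windows(reference_index("c", 10), 0), "width")
  # multi-chromosome tiling covers [0, length) exactly
  w2 <- make_windows(reference_index(c("a", "b"), c(250000, 70000)), 100000)
  for (ch in c("a", "b")) {
    ww <- w2[w2$chrom == ch, ]
    expect_equal(ww$start, c(0L, head(ww$end, -1)))
  }
})

test_that("profile distance counts pairwise-complete differences", {
  p <- snp_profile("c", 1, 0, 1000, "A", rep(0L, 100))
  q <- snp_profile("c", 1, 0, 1000, "B", rep(0L, 100))
  expect_equal(profile_distance(p, p), list(differences = 0L, compared_sites = 100L))
  q$alleles[1:9] <- 1L
  expect_equal(profile_distance(p, q)$differences, 9L)
  # 20 missing in q, 5 diffs among the remaining 80: verify against a direct
  # per-position recount
  set.seed(1)
  q2 <- q
  q2$alleles <- rep(0L, 100)
  q2$alleles[sample(100, 20)] <- NA_integer_
  left <- which(!is.na(q2$alleles))
  q2$alleles[left[1:5]] <- 1L
  got <- profile_distance(p, q2)
  both <- !is.na(p$alleles) & !is.na(q2$alleles)
  expect_equal(got$differences, sum(p$alleles[both] != q2$alleles[both]))
  expect_equal(got, list(differences = 5L, compared_sites = 80L))
  r <- snp_profile("c", 2, 1000, 2000, "C", rep(0L, 100))
  expect_error(profile_distance(p, r), "different windows")
})

test_that("clustering merges below 10% of compared SNPs and splits at 10%", {
  base <- matrix(0L, 100, 2, dimnames = list(NULL, c("A", "B")))
  m9 <- base; m9[1:9, "B"] <- 1L
  expect_length(cluster_window(m9)$clusters, 1)
  m10 <- base; m10[1:10, "B"] <- 1L
  expect_length(cluster_window(m10)$clusters, 2)
})

test_that("single linkage chains non-transitive merges", {
  # the merge relation is not transitive: B is close to both A and C, but
  # A and C are too far from each other; single linkage still joins all three
  mA <- rep(0L, 100)
  mB <- mA; mB[1:5] <- 1L          # A-B = 5
  mC <- mB; mC[6:10] <- 1L         # B-C = 5, A-C = 10 (not < 10%)
  mm <- cbind(A = mA, B = mB, C = mC)
  d <- haplograph:::profile_distance_matrix(mm)
  expect_equal(unname(d$diffs["A", "C"]), 10)
  expect_length(cluster_window(mm)$clusters, 1)
  # and with B removed, A and C stay apart
  expect_length(cluster_window(mm[, c("A", "C")])$clusters, 2)
})

test_that("zero-variant windows collapse into one flagged node", {
  p <- cluster_empty_window(paste0("h", 1:40))
  expect_length(p$clusters, 1)
  expect_length(p$clusters[[1]], 40)
  expect_true(p$flagged)
  expect_true(cluster_empty_window("h1")$flagged)
  m <- matrix(0L, 1, 3, dimnames = list(NULL, c("a", "b", "c")))
  expect_false(cluster_window(m)$flagged)
  expect_error(cluster_window(matrix(0L, 5, 0)), "no profiles")
})

test_that("edges carry haplotype support across adjacent windows", {
  win <- make_windows(reference_index("c", 200), 100)
  memb1 <- list(`c 1` = c(A = "n1", B = "n1", C = "n1", D = "n1"),
                `c 2` = c(A = "n2", B = "n2", C = "n2", D = "n2"))
  e <- build_edges(memb1, win)
  expect_equal(nrow(e), 1)
  expect_equal(e$n_support, 4L)
  memb2 <- list(`c 1` = c(A = "p1", B = "p1", C = "p2", D = "p2"),
                `c 2` = c(A = "q1", B = "q2", C = "q1", D = "q2"))
  e2 <- build_edges(memb2, win)
  expect_equal(nrow(e2), 4)
  expect_true(all(e2$n_support == 1L))
  # single window: no edges
  e3 <- build_edges(memb1[1], win[1, , drop = FALSE])
  expect_equal(nrow(e3), 0)
  memb_bad <- memb1
  memb_bad[[2]] <- memb_bad[[2]][-1]
  expect_error(build_edges(memb_bad, win), "missing")
})

test_that("per-window node member sets partition the haplotype set", {
  sim <- small_sim()
  g <- small_graph(sim)
  haps <- sort(sim$haplotypes)
  for (i in seq_len(nrow(g$windows))) {
    nd <- g$nodes[g$nodes$window_index == g$windows$index[i] &
                    g$nodes$chrom == g$windows$chrom[i], ]
    mem <- unlist(nd$members)
    expect_equal(sort(mem), haps)       # disjoint union = all haplotypes
  }
  # edge support is a subset of both endpoint member sets
  mem_of <- setNames(g$nodes$members, g$nodes$node)
  for (r in seq_len(nrow(g$edges))) {
    sup <- g$edges$support[[r]]
    expect_true(all(sup %in% mem_of[[g$edges$from[r]]]))
    expect_true(all(sup %in% mem_of[[g$edges$to[r]]]))
  }
})

test_that("graph construction is deterministic under haplotype relabeling order", {
  sim <- small_sim()
  vt <- sim$variants
  perm <- rev(colnames(vt$alleles))
  vt2 <- variant_table(vt$sites$chrom, vt$sites$pos,
                       vt$alleles[, perm, drop = FALSE])
  ref <- reference_index(sim$chrom, sim$config$genome_length)
  g1 <- build_haplotype_graph(vt, ref, width = 5e4)
  g2 <- build_haplotype_graph(vt2, ref, width = 5e4)
  expect_identical(g1$nodes, g2$nodes)
  expect_identical(g1$edges, g2$edges)
})

test_that("mean nodes per window tracks the simulated founder sharing", {
  sim <- simulate_pangenome(seed = 21, n_founders = 12, genome_length = 6e5,
                            window_width = 5e4, founders_per_window = 4,
                            n_haplotypes = 24)
  g <- small_graph(sim)
  truth_founders <- mean(apply(sim$truth, 1, function(z) length(unique(z))))
  nodes_per_window <- nrow(g$nodes) / nrow(g$windows)
  expect_lt(abs(nodes_per_window - truth_founders), 1)
})
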