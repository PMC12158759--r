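test_that("realized inter-founder divergence matches the target", {
  sim <- simulate_pangenome(seed = 11, n_founders = 2, genome_length = 1e5,
                            window_width = 1e5, target_pi = 0.02,
                            founders_per_window = 2, n_haplotypes = 4)
  # count mismatches directly between the two founder strings
  a <- strsplit(sim$founders[[1]], "")[[1]]
  b <- strsplit(sim$founders[[2]], "")[[1]]
  div <- mean(a != b)
  expect_gte(div, 0.018); expect_lte(div, 0.022)
  expect_equal(audit_pangenome(sim)$founder_pi, div, tolerance = 1e-12)
})

test_that("one founder per window collapses all haplotypes", {
  sim <- simulate_pangenome(seed = 13, n_founders = 5, genome_length = 2e5,
                            window_width = 5e4, founders_per_window = 1,
                            n_haplotypes = 8)
  expect_true(all(apply(sim$truth, 1, function(z) length(unique(z))) == 1))
  s <- pangenome_sequences(sim)
  expect_true(all(s == s[[1]]))
})

test_that("simulation is deterministic in the seed", {
  s1 <- simulate_pangenome(seed = 5, genome_length = 1e5, n_founders = 4,
                           founders_per_window = 2, n_haplotypes = 8)
  s2 <- simulate_pangenome(seed = 5, genome_length = 1e5, n_founders = 4,
                           founders_per_window = 2, n_haplotypes = 8)
  s3 <- simulate_pangenome(seed = 6, genome_length = 1e5, n_founders = 4,
                           founders_per_window = 2, n_haplotypes = 8)
  expect_identical(s1$founders, s2$founders)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$variants$alleles, s2$variants$alleles)
  expect_false(identical(s1$truth, s3$truth))
  # and the RNG state of the caller is untouched
  set.seed(123); before <- .Random.seed
  invisible(simulate_pangenome(seed = 5, genome_length = 1e5))
  expect_identical(before, .Random.seed)
})

test_that("query modes produce the documented truth structure", {
  sim <- small_sim()
  qm <- simulate_query(sim, "member", seed = 2)
  expect_true(all(apply(qm$sources, 2, function(z) length(unique(z)) == 1)))
  g <- small_graph(sim)
  truth <- query_truth_nodes(g, qm)
  expect_equal(sum(truth$copies), nrow(sim$windows) * 4)
  # member truth equals the graph membership of the source haplotypes
  for (w in c(1, nrow(sim$windows))) {
    expected <- g$membership[[w]][qm$sources[w, ]]
    inst <- unlist(lapply(seq_len(nrow(truth)), function(i)
      rep(truth$node[i], truth$copies[i])))
    expect_true(all(expected %in% inst))
  }
  qr <- simulate_query(sim, "recombinant", n_breakpoints = 1, seed = 3)
  for (j in 1:4) {
    switches <- sum(qr$sources[-1, j] != qr$sources[-nrow(qr$sources), j])
    expect_equal(switches, 1L)
  }
})

test_that("novel windows are marked absent at the configured rate", {
  sim <- simulate_pangenome(seed = 17, n_founders = 5, genome_length = 5e5,
                            window_width = 1000, founders_per_window = 3,
                            n_haplotypes = 8, target_pi = 0.018)
  q <- simulate_query(sim, "novel", n_breakpoints = 2, novel_fraction = 0.1,
                      seed = 19)
  frac <- mean(q$novel)
  expect_gte(frac, 0.08); expect_lte(frac, 0.12)
  expect_true(all(is.na(q$sources[q$novel])))
})

test_that("simulated k-mer counts follow the copy-depth law", {
  sim <- small_sim()
  g <- small_graph(sim)
  mk <- extract_markers(g, pangenome_sequences(sim), k = 31, max_per_node = 40)
  q <- simulate_query(sim, "member", seed = 3)
  kc <- simulate_kmer_counts(mk, q$sequences, lambda = 30, error_fraction = 0,
                             overdispersion = 0.05, seed = 5)
  nc <- collect_node_counts(mk, kc)
  truth <- query_truth_nodes(g, q)
  copies <- setNames(truth$copies, truth$node)
  # c = 0 and error_fraction = 0 -> all counts zero
  absent <- setdiff(names(nc), truth$node)
  expect_true(all(unlist(nc[absent]) == 0))
  # c = 2 nodes: mean count near 60 over their pooled markers
  two <- names(copies)[copies == 2]
  x2 <- unlist(nc[two])
  expect_gte(length(x2), 150)
  expect_gte(mean(x2), 57); expect_lte(mean(x2), 63)
  # doubling lambda doubles the mean (within 5%)
  kc2 <- simulate_kmer_counts(mk, q$sequences, lambda = 60, error_fraction = 0,
                              overdispersion = 0.05, seed = 5)
  x2b <- unlist(collect_node_counts(mk, kc2)[two])
  expect_lt(abs(mean(x2b) / mean(x2) - 2), 0.1)
  expect_error(simulate_kmer_counts(mk, q$sequences, lambda = 0), "lambda")
})

test_that("written pan-genome files round-trip through the io layer", {
  sim <- simulate_pangenome(seed = 23, n_founders = 4, genome_length = 1e5,
                            window_width = 5e4, founders_per_window = 2,
                            n_haplotypes = 8)
  dir <- withr::local_tempdir()
  write_pangenome(sim, dir, variants = TRUE)
  ref <- read_fasta(file.path(dir, "reference.fa"))
  expect_identical(unname(ref), unname(sim$reference))
  haps <- read_fasta(file.path(dir, "haplotypes.fa"))
  expect_identical(haps, pangenome_sequences(sim))
  vt <- read_variants(file.path(dir, "variants.tsv"), format = "tsv")
  expect_equal(vt$sites, sim$variants$sites)
  expect_equal(vt$alleles[, colnames(sim$variants$alleles)],
               sim$variants$alleles)
})
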