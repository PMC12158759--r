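# hand-built linear graph: `spec` gives per window the node -> members map
toy_graph <- function(spec, width = 100L) {
  W <- length(spec)
  win <- make_windows(reference_index("c", W * width), width)
  membership <- vector("list", W)
  names(membership) <- paste(win$chrom, win$index)
  nodes <- list()
  for (i in seq_len(W)) {
    ids <- names(spec[[i]])
    nodes[[i]] <- data.frame(
      node = ids, chrom = "c", window_index = i,
      start = win$start[i], end = win$end[i],
      representative = vapply(spec[[i]], `[`, character(1), 1),
      n_members = lengths(spec[[i]]), indistinguishable = FALSE,
      stringsAsFactors = FALSE)
    nodes[[i]]$members <- unname(spec[[i]])
    m <- character(0)
    for (j in seq_along(spec[[i]])) m[spec[[i]][[j]]] <- ids[j]
    membership[[i]] <- m
  }
  nodes <- do.call(rbind, nodes)
  rownames(nodes) <- NULL
  g <- list(windows = win, nodes = nodes,
            edges = build_edges(membership, win),
            membership = membership, threshold = 0.1, width = width)
  class(g) <- "haplotype_graph"
  g
}

test_that("a fully supported chain yields one pseudo-contig per lane", {
  haps <- paste0("h", 1:4)
  spec <- lapply(1:5, function(i) setNames(list(haps), paste0("n", i)))
  g <- toy_graph(spec)
  copies <- setNames(rep(4L, 5), paste0("n", 1:5))
  ps <- stitch(g, copies)
  expect_equal(nrow(ps$contigs), 4)
  expect_true(all(ps$contigs$n_windows == 5))
  expect_true(all(ps$contigs$length == 500))
})

test_that("a zero-copy window splits pseudo-contigs", {
  haps <- paste0("h", 1:4)
  spec <- lapply(1:5, function(i) setNames(list(haps), paste0("n", i)))
  g <- toy_graph(spec)
  copies <- setNames(c(1L, 1L, 0L, 1L, 1L), paste0("n", 1:5))
  ps <- stitch(g, copies)
  expect_equal(nrow(ps$contigs), 2)
  expect_equal(sort(ps$contigs$n_windows), c(2L, 2L))
})

test_that("two supported successors terminate the lane (ambiguity)", {
  # window 1: one node with all haplotypes; window 2: split into two
  # supported nodes -> the single lane cannot choose and stops
  spec <- list(list(a = c("h1", "h2")), list(b1 = "h1", b2 = "h2"))
  g <- toy_graph(spec)
  ps <- stitch(g, c(a = 1L, b1 = 1L, b2 = 1L))
  expect_equal(nrow(ps$contigs), 3)
  expect_true(all(ps$contigs$n_windows == 1))
  # with only one successor supported the lane extends
  ps2 <- stitch(g, c(a = 1L, b1 = 1L, b2 = 0L))
  paths <- ps2$contigs$path
  expect_true(any(vapply(paths, function(p) identical(p, c("a", "b1")), TRUE)))
})

test_that("every supported lane-window instance lands in exactly one contig", {
  sim <- small_sim()
  g <- small_graph(sim)
  q <- simulate_query(sim, "member", seed = 3)
  truth <- query_truth_nodes(g, q)
  copies <- setNames(truth$copies, truth$node)
  ps <- stitch(g, copies)
  inst <- table(unlist(ps$contigs$path))
  expect_equal(sort(names(inst)), sort(truth$node))
  expect_equal(as.integer(inst[sort(truth$node)]),
               truth$copies[order(truth$node)])
})

test_that("recombination switch points break contigs or fall on shared nodes", {
  sim <- small_sim()
  g <- small_graph(sim)
  q <- simulate_query(sim, "recombinant", n_breakpoints = 2, seed = 13)
  truth <- query_truth_nodes(g, q)
  ps <- stitch(g, setNames(truth$copies, truth$node))
  starts <- unique(ps$contigs$start)
  win <- g$windows
  for (j in 1:4) {
    for (w in q$breakpoints[[j]]) {
      prev <- g$membership[[w]][q$sources[w - 1, j]]
      new <- g$membership[[w]][q$sources[w, j]]
      shared <- identical(unname(prev), unname(new))
      broke <- win$start[w] %in% starts
      expect_true(shared || broke)
    }
  }
})

test_that("assembly metrics follow their definitions", {
  expect_equal(n50(c(5, 4, 3, 2, 1)), 4L)
  set.seed(6)
  lens <- sample(1:1000, 60, replace = TRUE)
  expect_equal(n50(lens), oracle_n50(lens))

  # 4 truth instances, 3 predicted correctly + 1 false
  spec <- lapply(1:4, function(i) setNames(list(c("h1", "h2")), paste0("n", i)))
  g <- toy_graph(spec)
  ps <- stitch(g, c(n1 = 1L, n2 = 1L, n3 = 1L, n4 = 1L))
  truth <- data.frame(node = c("n1", "n2", "n3", "x9"),
                      copies = c(1L, 1L, 1L, 1L))
  m <- score_assembly(ps, truth, g)
  expect_equal(m$recall, 0.75)
  expect_equal(m$precision, 0.75)
  # identical prediction and truth
  m2 <- score_assembly(ps, data.frame(node = paste0("n", 1:4), copies = 1L), g)
  expect_equal(m2$recall, 1); expect_equal(m2$precision, 1)
  expect_equal(m2$coverage, 400 / (4 * 400))
  expect_error(score_assembly(ps, data.frame(node = character(0),
                                             copies = integer(0)), g),
               "empty truth")
})

test_that("masked scoring drops masked windows from all four metrics", {
  spec <- lapply(1:4, function(i) setNames(list(c("h1", "h2")), paste0("n", i)))
  g <- toy_graph(spec)
  ps <- stitch(g, c(n1 = 1L, n2 = 1L, n3 = 1L, n4 = 1L))
  truth <- data.frame(node = paste0("n", 1:4), copies = 1L)
  mask <- region_mask("c", 100L, 200L)  # covers window 2
  m <- score_assembly(ps, truth, g, mask = mask)
  expect_equal(m$recall, 1)
  expect_equal(m$masked$recall, 1)
  expect_equal(m$masked$total_length, 300)
  expect_equal(m$masked$coverage, 300 / (4 * 300))
  # dropping window 2 splits the single contig into 100 + 200
  expect_equal(m$masked$n_contigs, 2L)
  expect_equal(m$masked$n50, 200L)
})

test_that("pseudo-contig FASTA concatenates representative window sequences", {
  sim <- small_sim()
  g <- small_graph(sim)
  q <- simulate_query(sim, "member", seed = 3)
  truth <- query_truth_nodes(g, q)
  ps <- stitch(g, setNames(truth$copies, truth$node))
  seqs <- pangenome_sequences(sim)
  fa <- export_pseudo_fasta(ps, g, seqs)
  expect_length(fa, nrow(ps$contigs))
  expect_equal(unname(nchar(fa)), ps$contigs$length)
  # spot-check one record against a direct concatenation
  i <- which.max(ps$contigs$n_windows)
  nd <- g$nodes; rownames(nd) <- nd$node
  manual <- paste(vapply(ps$contigs$path[[i]], function(n)
    substr(seqs[[nd[n, "representative"]]], nd[n, "start"] + 1, nd[n, "end"]),
    character(1)), collapse = "")
  expect_equal(unname(fa[i]), manual)
  # empty assembly -> empty FASTA
  ps0 <- ps; ps0$contigs <- ps$contigs[0, , drop = FALSE]
  expect_length(export_pseudo_fasta(ps0, g, seqs), 0)
})
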