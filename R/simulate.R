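transition_of <- function(x) chartr("ACGT", "GTAC", x)

#' Simulate a pan-genome with founder-sharing structure
#'
#' Emulates the statistical structure the haplotype-graph method assumes: a
#' small pool of founder haplotypes is mutated from a random reference so
#' that inter-founder diversity matches `target_pi`; each output haplotype
#' is a per-window mosaic over a window-specific founder subset (mean size
#' `founders_per_window`), with contiguity controlled by `switch_prob`.
#' Mutations are SNP-only, each site flipped to a fixed transition
#' alternative, so every site is biallelic. The per-site mutation rate r
#' solves `2 r (1 - r) = target_pi`.
#'
#' @param seed RNG seed; together with the configuration it determines every
#'   output byte.
#' @param n_founders number of founder haplotypes in the pool.
#' @param genome_length chromosome length in bp.
#' @param window_width window width in bp.
#' @param target_pi target inter-founder per-bp diversity.
#' @param founders_per_window mean number of distinct founders available per
#'   window (haplotype sharing; about 9 of 40 in European potato).
#' @param n_haplotypes number of output haplotypes (40 = 10 tetraploid
#'   cultivars).
#' @param switch_prob probability that a haplotype's founder lineage
#'   resamples at a window boundary.
#' @param missing_rate fraction of genotype calls set to missing.
#' @param chrom chromosome name.
#' @return Object of class `sim_pangenome` with the reference, founder
#'   sequences, window table, truth (window x haplotype founder index),
#'   founder subsets, and a [variant_table()] over the output haplotypes.
#' @export
simulate_pangenome <- function(seed = 1, n_founders = 20, genome_length = 1e6,
                               window_width = 1e5, target_pi = 0.018,
                               founders_per_window = 9, n_haplotypes = 40,
                               switch_prob = 0.1, missing_rate = 0,
                               chrom = "chr01") {
  hg_assert(target_pi > 0 && target_pi < 0.5, "target_pi must be in (0, 0.5)")
  hg_assert(founders_per_window <= n_founders,
            "founders-per-window exceeds the founder pool")
  hg_assert(n_founders >= 1 && genome_length >= window_width,
            "invalid simulation config")
  with_seed(seed, {
    L <- as.integer(genome_length)
    ref_vec <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    reference <- paste(ref_vec, collapse = "")
    r <- (1 - sqrt(1 - 2 * target_pi)) / 2
    founder_pos <- lapply(seq_len(n_founders), function(f) which(runif(L) < r))
    founders <- vapply(seq_len(n_founders), function(f) {
      v <- ref_vec
      v[founder_pos[[f]]] <- transition_of(v[founder_pos[[f]]])
      paste(v, collapse = "")
    }, character(1))
    names(founders) <- sprintf("F%02d", seq_len(n_founders))

    sites <- sort(unique(unlist(founder_pos)))
    founder_alleles <- matrix(0L, length(sites), n_founders)
    for (f in seq_len(n_founders))
      founder_alleles[match(founder_pos[[f]], sites), f] <- 1L

    windows <- make_windows(reference_index(chrom, L), window_width)
    W <- nrow(windows)
    fpw_floor <- floor(founders_per_window)
    founder_sets <- lapply(seq_len(W), function(w) {
      k <- fpw_floor + rbinom(1, 1, founders_per_window - fpw_floor)
      k <- max(1, min(k, n_founders))
      sort(sample.int(n_founders, k))
    })

    haps <- if (n_haplotypes %% 4 == 0) {
      paste0(rep(sprintf("cv%02d", seq_len(n_haplotypes / 4)), each = 4),
             "_hap", rep(1:4, n_haplotypes / 4))
    } else {
      sprintf("hap%02d", seq_len(n_haplotypes))
    }
    truth <- matrix(NA_integer_, W, n_haplotypes,
                    dimnames = list(NULL, haps))
    for (h in seq_len(n_haplotypes)) {
      for (w in seq_len(W)) {
        S <- founder_sets[[w]]
        prev <- if (w > 1) truth[w - 1, h] else NA_integer_
        truth[w, h] <- if (!is.na(prev) && prev %in% S &&
                           runif(1) > switch_prob) prev else
                             S[sample.int(length(S), 1)]
      }
    }

    alleles <- matrix(0L, length(sites), n_haplotypes,
                      dimnames = list(NULL, haps))
    site_w <- (sites - 1L) %/% as.integer(window_width) + 1L
    for (w in seq_len(W)) {
      rows <- which(site_w == w)
      if (length(rows) > 0)
        alleles[rows, ] <- founder_alleles[rows, truth[w, ], drop = FALSE]
    }
    if (missing_rate > 0)
      alleles[runif(length(alleles)) < missing_rate] <- NA_integer_

    obj <- list(
      config = list(seed = seed, n_founders = n_founders,
                    genome_length = L, window_width = window_width,
                    target_pi = target_pi,
                    founders_per_window = founders_per_window,
                    n_haplotypes = n_haplotypes, switch_prob = switch_prob,
                    missing_rate = missing_rate, mutation_rate = r),
      chrom = chrom, reference = setNames(reference, chrom),
      founders = founders, founder_sites = sites,
      founder_alleles = founder_alleles,
      windows = windows, founder_sets = founder_sets, truth = truth,
      haplotypes = haps,
      variants = variant_table(rep(chrom, length(sites)), sites, alleles)
    )
    class(obj) <- "sim_pangenome"
    obj
  })
}

#' @export
print.sim_pangenome <- function(x, ...) {
  cat("sim_pangenome:", x$config$n_haplotypes, "haplotypes over",
      x$config$n_founders, "founders,", x$config$genome_length, "bp\n")
  cat("  windows:", nrow(x$windows), " variant sites:",
      length(x$founder_sites), "\n")
  invisible(x)
}

#' Materialize the sequence of one simulated haplotype
#'
#' @param sim a [simulate_pangenome()] result.
#' @param hap haplotype id or column index.
#' @return Character scalar: the haplotype's chromosome sequence.
#' @export
hap_sequence <- function(sim, hap) {
  h <- if (is.character(hap)) match(hap, sim$haplotypes) else hap
  hg_assert(!is.na(h), "unknown haplotype")
  win <- sim$windows
  paste(vapply(seq_len(nrow(win)), function(w)
    substr(sim$founders[[sim$truth[w, h]]], win$start[w] + 1L, win$end[w]),
    character(1)), collapse = "")
}

#' All simulated haplotype sequences
#'
#' @param sim a [simulate_pangenome()] result.
#' @return Named character vector (one sequence per output haplotype).
#' @export
pangenome_sequences <- function(sim) {
  setNames(vapply(seq_along(sim$haplotypes), function(h) hap_sequence(sim, h),
                  character(1)), sim$haplotypes)
}

#' Audit realized simulation statistics
#'
#' @param sim a [simulate_pangenome()] result.
#' @return List with realized inter-founder diversity (`founder_pi`),
#'   output-haplotype diversity (`haplotype_pi`), and the realized mean
#'   number of distinct founders per window.
#' @export
audit_pangenome <- function(sim) {
  nf <- sim$config$n_founders
  L <- sim$config$genome_length
  fd <- 0; np <- 0
  if (nf > 1) {
    for (i in 1:(nf - 1)) for (j in (i + 1):nf) {
      fd <- fd + sum(sim$founder_alleles[, i] != sim$founder_alleles[, j])
      np <- np + 1
    }
  }
  div <- window_diversity(sim$variants, sim$windows)
  list(
    founder_pi = if (np > 0) fd / np / L else 0,
    haplotype_pi = sum(div$pi * (div$end - div$start)) / sum(div$end - div$start),
    founders_per_window = mean(apply(sim$truth, 1, function(z) length(unique(z)))),
    realized_switches = if (nrow(sim$truth) > 1) {
      W <- nrow(sim$truth)
      mean(colSums(sim$truth[-1, , drop = FALSE] !=
                     sim$truth[-W, , drop = FALSE]))
    } else 0
  )
}

#' Simulate a tetraploid query genome
#'
#' Modes: `member` copies four of the simulated haplotypes; `recombinant`
#' builds each query haplotype as a crossover mosaic of simulated haplotypes
#' with `n_breakpoints` recorded switch points at window boundaries;
#' `novel` additionally replaces a fraction of windows with sequence mutated
#' away from the graph (truth marks them absent).
#'
#' @param sim a [simulate_pangenome()] result.
#' @param mode `"member"`, `"recombinant"` or `"novel"`.
#' @param n_breakpoints crossovers per query haplotype (recombinant/novel).
#' @param novel_fraction fraction of windows replaced by novel sequence
#'   (novel mode).
#' @param seed RNG seed.
#' @return Object of class `sim_query`: `sources` (window x 4 matrix of
#'   source haplotype ids, `NA` where novel), `novel` logical matrix,
#'   `breakpoints` (list of window boundaries per query haplotype) and the
#'   materialized `sequences` of the four query haplotypes.
#' @export
simulate_query <- function(sim, mode = c("member", "recombinant", "novel"),
                           n_breakpoints = 2, novel_fraction = 0.1, seed = 1) {
  mode <- match.arg(mode)
  W <- nrow(sim$windows)
  with_seed(seed, {
    sources <- matrix(NA_character_, W, 4)
    breakpoints <- vector("list", 4)
    if (mode == "member") {
      pick <- sample(sim$haplotypes, 4)
      for (j in 1:4) sources[, j] <- pick[j]
    } else {
      for (j in 1:4) {
        bp <- if (n_breakpoints > 0 && W > 1)
          sort(sample(2:W, min(n_breakpoints, W - 1))) else integer(0)
        breakpoints[[j]] <- bp
        cur <- sample(sim$haplotypes, 1)
        for (w in seq_len(W)) {
          if (w %in% bp)
            cur <- sample(setdiff(sim$haplotypes, cur), 1)
          sources[w, j] <- cur
        }
      }
    }
    novel <- matrix(FALSE, W, 4)
    novel_seqs <- list()
    if (mode == "novel") {
      novel <- matrix(runif(W * 4) < novel_fraction, W, 4)
      r_nov <- 2 * sim$config$mutation_rate
      for (w in seq_len(W)) for (j in 1:4) {
        if (!novel[w, j]) next
        seg <- strsplit(substr(sim$reference[[1]], sim$windows$start[w] + 1L,
                               sim$windows$end[w]), "")[[1]]
        mut <- which(runif(length(seg)) < r_nov)
        seg[mut] <- transition_of(seg[mut])
        novel_seqs[[paste(w, j)]] <- paste(seg, collapse = "")
      }
    }
    sources[novel] <- NA_character_
    seqs <- vapply(1:4, function(j) {
      paste(vapply(seq_len(W), function(w) {
        if (novel[w, j]) return(novel_seqs[[paste(w, j)]])
        h <- match(sources[w, j], sim$haplotypes)
        substr(sim$founders[[sim$truth[w, h]]], sim$windows$start[w] + 1L,
               sim$windows$end[w])
      }, character(1)), collapse = "")
    }, character(1))
    names(seqs) <- paste0("query_hap", 1:4)
    obj <- list(mode = mode, sources = sources, novel = novel,
                breakpoints = breakpoints, sequences = seqs)
    class(obj) <- "sim_query"
    obj
  })
}

#' Truth node-copy instances of a simulated query
#'
#' Maps each non-novel query window back to the graph node containing its
#' source haplotype.
#'
#' @param graph a [build_haplotype_graph()] over the simulated haplotypes.
#' @param query a [simulate_query()] result.
#' @return `data.frame` with columns `node`, `copies`.
#' @export
query_truth_nodes <- function(graph, query) {
  W <- nrow(query$sources)
  hg_assert(W == nrow(graph$windows), "graph and query window count differ")
  nodes <- character(0)
  for (w in seq_len(W)) {
    src <- query$sources[w, ]
    src <- src[!is.na(src)]
    nodes <- c(nodes, unname(graph$membership[[w]][src]))
  }
  truth_copy_table(nodes)
}

#' Simulate marker k-mer counts for a query genome
#'
#' Each marker present in c of the query haplotypes (canonical k-mer match
#' against the query sequences) receives a negative-binomial count with mean
#' `c * lambda` (variance `mu + overdispersion * mu^2`; Poisson when
#' `overdispersion = 0`); the generator is deliberately heavier-tailed than
#' the Gaussian inference model. A seeded `error_fraction` of the absent
#' markers receives low-mean noise counts (1 + Poisson(1)).
#'
#' @param markers named list node -> marker k-mers.
#' @param query_seqs character vector of the query haplotype sequences.
#' @param lambda haploid marker depth.
#' @param error_fraction fraction of absent markers receiving noise counts.
#' @param overdispersion negative-binomial overdispersion.
#' @param seed RNG seed.
#' @return A [kmer_count_table()] of the markers with non-zero counts.
#' @export
simulate_kmer_counts <- function(markers, query_seqs, lambda = 30,
                                 error_fraction = 0.01, overdispersion = 0.05,
                                 seed = 1) {
  hg_assert(lambda > 0, "lambda must be positive")
  all_mk <- unlist(markers, use.names = FALSE)
  if (length(all_mk) == 0)
    return(kmer_count_table(character(0), integer(0)))
  k <- nchar(all_mk[1])
  copies <- cpp_marker_presence(all_mk, as.list(unname(query_seqs)),
                                as.integer(k))
  with_seed(seed, {
    cnt <- integer(length(all_mk))
    pres <- copies > 0
    if (any(pres)) {
      mu <- copies[pres] * lambda
      cnt[pres] <- if (overdispersion > 0)
        rnbinom(sum(pres), mu = mu, size = 1 / overdispersion)
      else rpois(sum(pres), mu)
    }
    err <- !pres & runif(length(all_mk)) < error_fraction
    cnt[err] <- 1L + rpois(sum(err), 1)
    keep <- cnt > 0
    kmer_count_table(all_mk[keep], cnt[keep])
  })
}

#' Simulate node-level marker counts with known copy numbers
#'
#' A count-level generator for exercising the copy-number EM directly:
#' each node draws a true copy number, then `markers_per_node` counts from
#' a Poisson (or negative binomial) with mean `copy * lambda`; a
#' `noise_fraction` of all counts can be replaced by low-mean draws
#' (1 + Poisson(1)) emulating sequencing-error k-mers.
#'
#' @param n_nodes number of nodes.
#' @param markers_per_node markers per node.
#' @param lambda haploid depth.
#' @param copy_weights probabilities of copies 0..4.
#' @param overdispersion negative-binomial overdispersion (0 = Poisson).
#' @param noise_fraction fraction of counts replaced by noise.
#' @param seed RNG seed.
#' @return List with `counts` (a `node_counts` list) and `copy` (true copy
#'   vector).
#' @export
simulate_node_counts <- function(n_nodes = 2000, markers_per_node = 20,
                                 lambda = 30,
                                 copy_weights = c(0.4, 0.3, 0.15, 0.1, 0.05),
                                 overdispersion = 0, noise_fraction = 0,
                                 seed = 1) {
  with_seed(seed, {
    copy <- sample(0:4, n_nodes, replace = TRUE, prob = copy_weights)
    counts <- lapply(copy, function(c) {
      if (c == 0) return(numeric(markers_per_node))
      mu <- c * lambda
      if (overdispersion > 0)
        as.numeric(rnbinom(markers_per_node, mu = mu, size = 1 / overdispersion))
      else as.numeric(rpois(markers_per_node, mu))
    })
    if (noise_fraction > 0) {
      tot <- n_nodes * markers_per_node
      hit <- which(runif(tot) < noise_fraction)
      flat <- unlist(counts)
      flat[hit] <- 1 + rpois(length(hit), 1)
      counts <- split(flat, rep(seq_len(n_nodes), each = markers_per_node))
    }
    names(counts) <- sprintf("node%05d", seq_len(n_nodes))
    out <- counts
    attr(out, "uninformative") <- character(0)
    class(out) <- "node_counts"
    list(counts = out, copy = setNames(copy, names(counts)))
  })
}

#' Write simulated pan-genome inputs to disk
#'
#' Writes the reference FASTA, the haplotype FASTA, the truth table TSV and
#' (optionally) the variant table in the long TSV dialect.
#'
#' @param sim a [simulate_pangenome()] result.
#' @param dir output directory (created if needed).
#' @param variants also write the variant TSV (can be large).
#' @return Invisibly, the directory.
#' @export
write_pangenome <- function(sim, dir, variants = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(sim$reference, file.path(dir, "reference.fa"))
  write_fasta(pangenome_sequences(sim), file.path(dir, "haplotypes.fa"))
  truth <- data.frame(chrom = sim$windows$chrom, window = sim$windows$index,
                      start = sim$windows$start, end = sim$windows$end,
                      sim$truth, check.names = FALSE)
  write.table(truth, file.path(dir, "truth.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (variants) write_variants_tsv(sim$variants, file.path(dir, "variants.tsv"))
  invisible(dir)
}
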