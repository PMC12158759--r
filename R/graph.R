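node_id_of <- function(chrom, index, j) {
  sprintf("%s_w%05d_n%02d", chrom, index, j)
}

#' Build the haplotype graph
#'
#' The reference is tiled into non-overlapping windows (100 kb by default),
#' haplotypes are clustered per window by SNP-profile distance
#' ([cluster_window()]; windows without variants collapse via
#' [cluster_empty_window()]), each cluster becomes a node, and nodes in
#' adjacent windows are connected when linked by a contributing haplotype
#' ([build_edges()]). A node's representative is its lexicographically
#' smallest member haplotype.
#'
#' @param vt a [variant_table()] over the contributing haplotypes.
#' @param ref a [reference_index()].
#' @param width window width in bp.
#' @param threshold clustering threshold (fraction of compared SNPs).
#' @param denominator see [cluster_window()].
#' @return Object of class `haplotype_graph` with elements `windows`,
#'   `nodes` (with a `members` list column), `edges` (with a `support` list
#'   column) and `membership` (per window, named haplotype -> node vector).
#' @export
build_haplotype_graph <- function(vt, ref, width = 100000L, threshold = 0.10,
                                  denominator = c("pairwise", "window")) {
  denominator <- match.arg(denominator)
  windows <- make_windows(ref, width)
  haps <- sort(colnames(vt$alleles))
  nodes <- list()
  membership <- vector("list", nrow(windows))
  names(membership) <- paste(windows$chrom, windows$index)
  for (i in seq_len(nrow(windows))) {
    rows <- variant_rows_in_window(vt, windows$chrom[i], windows$start[i], windows$end[i])
    part <- if (length(rows) == 0) {
      cluster_empty_window(haps)
    } else {
      cluster_window(vt$alleles[rows, haps, drop = FALSE],
                     threshold = threshold, denominator = denominator)
    }
    ids <- vapply(seq_along(part$clusters), function(j)
      node_id_of(windows$chrom[i], windows$index[i], j), character(1))
    nodes[[i]] <- data.frame(
      node = ids,
      chrom = windows$chrom[i], window_index = windows$index[i],
      start = windows$start[i], end = windows$end[i],
      representative = vapply(part$clusters, `[`, character(1), 1),
      n_members = vapply(part$clusters, length, integer(1)),
      indistinguishable = part$flagged,
      stringsAsFactors = FALSE
    )
    nodes[[i]]$members <- part$clusters
    membership[[i]] <- setNames(ids[part$membership[haps]], haps)
  }
  nodes <- do.call(rbind, nodes)
  rownames(nodes) <- NULL
  edges <- build_edges(membership, windows)
  obj <- list(windows = windows, nodes = nodes, edges = edges,
              membership = membership, threshold = threshold, width = width)
  class(obj) <- "haplotype_graph"
  obj
}

#' Connect nodes of adjacent windows along contributing haplotypes
#'
#' For every haplotype and every pair of adjacent windows on the same
#' chromosome, the edge between the haplotype's two nodes gains that
#' haplotype in its support; edges with empty support do not exist.
#'
#' @param membership list (one element per window, named `"chrom index"`) of
#'   named vectors mapping haplotype id to node id.
#' @param windows window table from [make_windows()].
#' @return `data.frame` with columns `from`, `to`, `n_support` and a
#'   `support` list column.
#' @export
build_edges <- function(membership, windows) {
  haps <- sort(names(membership[[1]]))
  for (m in membership) {
    miss <- setdiff(haps, names(m))
    extra <- setdiff(names(m), haps)
    if (length(miss) > 0 || length(extra) > 0)
      stop("haplotype(s) missing from a window's partition: ",
           paste(c(miss, extra), collapse = ", "))
  }
  from <- character(0); to <- character(0); sup <- list()
  acc <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(windows) - 1)) {
    if (windows$chrom[i] != windows$chrom[i + 1]) next
    a <- membership[[i]]; b <- membership[[i + 1]]
    for (h in haps) {
      key <- paste0(a[[h]], "\t", b[[h]])
      acc[[key]] <- c(acc[[key]], h)
    }
  }
  keys <- sort(ls(acc))
  parts <- strsplit(keys, "\t", fixed = TRUE)
  edges <- data.frame(
    from = vapply(parts, `[`, character(1), 1),
    to = vapply(parts, `[`, character(1), 2),
    n_support = vapply(keys, function(k) length(acc[[k]]), integer(1)),
    stringsAsFactors = FALSE
  )
  edges$support <- lapply(keys, function(k) sort(acc[[k]]))
  rownames(edges) <- NULL
  edges
}

#' @export
print.haplotype_graph <- function(x, ...) {
  cat("haplotype_graph\n")
  cat("  windows:", nrow(x$windows), "of", x$width, "bp on",
      length(unique(x$windows$chrom)), "chromosome(s)\n")
  cat("  nodes:  ", nrow(x$nodes),
      sprintf("(mean %.2f per window)", nrow(x$nodes) / nrow(x$windows)), "\n")
  cat("  edges:  ", nrow(x$edges), "\n")
  cat("  haplotypes:", length(x$membership[[1]]), "\n")
  invisible(x)
}

#' @export
summary.haplotype_graph <- function(object, ...) {
  npw <- table(object$nodes$window_index)
  res <- list(
    n_windows = nrow(object$windows),
    n_nodes = nrow(object$nodes),
    n_edges = nrow(object$edges),
    n_haplotypes = length(object$membership[[1]]),
    nodes_per_window_mean = nrow(object$nodes) / nrow(object$windows),
    nodes_per_window_range = range(as.integer(npw)),
    n_indistinguishable_windows = sum(
      object$nodes$indistinguishable[!duplicated(object$nodes$window_index)])
  )
  class(res) <- "summary.haplotype_graph"
  res
}

#' @export
print.summary.haplotype_graph <- function(x, ...) {
  cat("haplotype graph summary\n")
  cat(sprintf("  %d windows, %d nodes, %d edges, %d haplotypes\n",
              x$n_windows, x$n_nodes, x$n_edges, x$n_haplotypes))
  cat(sprintf("  nodes per window: mean %.2f, range %d-%d\n",
              x$nodes_per_window_mean, x$nodes_per_window_range[1],
              x$nodes_per_window_range[2]))
  cat(sprintf("  windows without variant information: %d\n",
              x$n_indistinguishable_windows))
  invisible(x)
}

# node rows of one window
nodes_in_window <- function(graph, chrom, index) {
  graph$nodes[graph$nodes$chrom == chrom & graph$nodes$window_index == index, ,
              drop = FALSE]
}
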