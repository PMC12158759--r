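# fetch the sequence of haplotype `hap` on chromosome `chrom`.
# `sequences` is either a named character vector (haplotype -> sequence, valid
# when the graph has a single chromosome) or a named list of named character
# vectors (haplotype -> chromosome -> sequence).
get_hap_seq <- function(sequences, hap, chrom) {
  s <- sequences[[hap]]
  if (is.null(s)) stop("no sequence for haplotype ", hap)
  if (length(s) > 1 || !is.null(names(s))) {
    if (!is.null(names(s)) && chrom %in% names(s)) return(s[[chrom]])
    if (length(s) == 1) return(s[[1]])
    stop("no sequence for haplotype ", hap, " on ", chrom)
  }
  s
}

#' Extract node-specific marker k-mers
#'
#' A canonical k-mer is a marker of a node if it occurs in the windowed
#' sequence of every member haplotype, lies inside the synteny mask (when one
#' is given), and occurs in no other node's windowed sequences anywhere in the
#' graph, so marker sets are disjoint across nodes and a marker detects its
#' node unambiguously. k-mers containing non-ACGT letters are skipped.
#'
#' @param graph a [build_haplotype_graph()] result.
#' @param sequences per-haplotype chromosome sequences (named character
#'   vector for a single chromosome, or haplotype -> chromosome -> sequence
#'   list).
#' @param k k-mer length (default 51).
#' @param mask optional [region_mask()] of regions eligible for markers
#'   (e.g. regions syntenic to the reference); when `NULL`, all positions are
#'   eligible.
#' @param max_per_node cap on markers kept per node (`Inf` keeps all;
#'   capping keeps the lexicographically smallest markers, deterministic).
#' @return Named list: node id -> character vector of canonical marker
#'   k-mers.
#' @export
extract_markers <- function(graph, sequences, k = 51L, mask = NULL,
                            max_per_node = Inf) {
  nodes <- graph$nodes
  too_short <- nodes$end - nodes$start < k
  if (any(too_short)) {
    warning(sum(too_short), " window-node(s) narrower than k; empty marker sets")
  }
  node_full <- vector("list", nrow(nodes))
  node_frag <- vector("list", nrow(nodes))
  for (i in seq_len(nrow(nodes))) {
    members <- nodes$members[[i]]
    seqs <- vapply(members, function(h)
      substr(get_hap_seq(sequences, h, nodes$chrom[i]),
             nodes$start[i] + 1L, nodes$end[i]), character(1))
    hg_assert(all(nchar(seqs) == nodes$end[i] - nodes$start[i]),
              paste0("sequence of a member of ", nodes$node[i],
                     " does not cover its window"))
    useqs <- unique(unname(seqs))
    node_full[[i]] <- useqs
    if (is.null(mask)) {
      node_frag[[i]] <- lapply(useqs, function(s) s)
    } else {
      iv <- mask_intersect(mask, nodes$chrom[i], nodes$start[i], nodes$end[i])
      node_frag[[i]] <- lapply(useqs, function(s) {
        if (nrow(iv) == 0) return(character(0))
        substring(s, iv$start - nodes$start[i] + 1L, iv$end - nodes$start[i])
      })
    }
  }
  cap <- if (is.finite(max_per_node)) as.integer(max_per_node) else 0L
  precap <- if (cap > 0L) max(1000L, 10L * cap) else 0L
  res <- cpp_extract_markers(node_frag, node_full, as.integer(k), cap, precap)
  names(res) <- nodes$node
  res
}

#' Write / read a marker TSV (node, kmer)
#'
#' @param markers named list node -> marker k-mers.
#' @param path file path.
#' @return `write_markers_tsv` returns `path` invisibly; `read_markers_tsv`
#'   the named list.
#' @export
write_markers_tsv <- function(markers, path) {
  df <- data.frame(
    node = rep(names(markers), lengths(markers)),
    kmer = unlist(markers, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_markers_tsv
#' @export
read_markers_tsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  split(df$kmer, factor(df$node, levels = unique(df$node)))
}
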