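#' Serialize a haplotype graph as GFA 1.0 with a membership sidecar
#'
#' Writes one S-line per node (carrying the representative haplotype's
#' windowed sequence) and one L-line per edge (0M overlap). Node membership
#' and window coordinates, which GFA cannot carry, go into a TSV sidecar at
#' `<path>.membership.tsv` (columns `node`, `chrom`, `window_index`, `start`,
#' `end`, `representative`, `members` comma-separated, `indistinguishable`,
#' `n_markers`).
#'
#' @param graph a [build_haplotype_graph()] result.
#' @param sequences per-haplotype sequences (see [extract_markers()]).
#' @param path output GFA path.
#' @param markers optional named marker list; only marker counts are stored.
#' @return Invisibly, the sidecar path.
#' @export
write_graph_gfa <- function(graph, sequences, path, markers = NULL) {
  nodes <- graph$nodes
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  writeLines("H\tVN:Z:1.0", con)
  if (nrow(nodes) > 0) {
    seqs <- vapply(seq_len(nrow(nodes)), function(i) {
      s <- get_hap_seq(sequences, nodes$representative[i], nodes$chrom[i])
      out <- substr(s, nodes$start[i] + 1L, nodes$end[i])
      if (!nzchar(out))
        stop("node ", nodes$node[i], " has no representative sequence")
      out
    }, character(1))
    writeLines(paste0("S\t", nodes$node, "\t", seqs), con)
  }
  if (nrow(graph$edges) > 0) {
    writeLines(paste0("L\t", graph$edges$from, "\t+\t", graph$edges$to,
                      "\t+\t0M"), con)
  }
  side <- paste0(path, ".membership.tsv")
  df <- data.frame(
    node = nodes$node, chrom = nodes$chrom, window_index = nodes$window_index,
    start = nodes$start, end = nodes$end,
    representative = nodes$representative,
    members = vapply(nodes$members, paste, character(1), collapse = ","),
    indistinguishable = nodes$indistinguishable,
    n_markers = if (is.null(markers)) integer(nrow(nodes)) else
      as.integer(lengths(markers)[nodes$node]),
    stringsAsFactors = FALSE
  )
  write.table(df, side, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(side)
}

#' Read a graph membership sidecar
#'
#' @param path sidecar TSV path written by [write_graph_gfa()].
#' @return `data.frame` with a `members` list column.
#' @export
read_node_memberships <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  df$members <- lapply(strsplit(df$members, ",", fixed = TRUE), sort)
  df
}
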