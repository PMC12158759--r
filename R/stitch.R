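#' Stitch copy-supported nodes into pseudo-contigs
#'
#' Greedy left-to-right lane extension: within each window, a node with copy
#' number c occupies c lanes. A lane extends from window i to i+1 only when
#' an edge connects its current node to exactly one supported successor with
#' remaining lane capacity; ambiguity (two or more such candidates) or the
#' absence of a supported successor terminates the pseudo-contig. Remaining
#' capacity in a window seeds new pseudo-contigs, so every supported
#' lane-window instance belongs to exactly one pseudo-contig. Lanes are
#' interchangeable; the lane index is arbitrary but stable (creation order).
#'
#' @param graph a [build_haplotype_graph()] result.
#' @param fit a [em_copy_numbers()] fit, its assignment table, or a named
#'   integer vector node -> copy number.
#' @return Object of class `pseudo_assembly`: `data.frame` `contigs`
#'   (columns `contig`, `chrom`, `start`, `end`, `lane`, `n_windows`,
#'   `length` and a `path` list column).
#' @export
stitch <- function(graph, fit) {
  copies <- stitch_copies(fit)
  adj <- split(graph$edges$to, graph$edges$from)
  span <- setNames(graph$nodes$end - graph$nodes$start, graph$nodes$node)
  contigs <- list()
  ctr <- 0L
  for (chrom in unique(graph$windows$chrom)) {
    win <- graph$windows[graph$windows$chrom == chrom, , drop = FALSE]
    active <- list() # each: list(id, node, path, start, lane)
    for (i in seq_len(nrow(win))) {
      nd <- nodes_in_window(graph, chrom, win$index[i])
      rem <- setNames(as.integer(copies[nd$node]), nd$node)
      rem[is.na(rem)] <- 0L
      survivors <- list()
      for (lane in active) {
        cand <- intersect(adj[[lane$node]], names(rem)[rem > 0])
        if (length(cand) == 1) {
          rem[cand] <- rem[cand] - 1L
          lane$node <- cand
          lane$path <- c(lane$path, cand)
          survivors[[length(survivors) + 1L]] <- lane
        } else {
          contigs[[length(contigs) + 1L]] <- close_lane(lane, chrom, win, i - 1L, span)
        }
      }
      # unconsumed capacity starts new pseudo-contigs
      lane_no <- 0L
      for (nn in names(rem)) {
        while (rem[nn] > 0) {
          rem[nn] <- rem[nn] - 1L
          ctr <- ctr + 1L
          lane_no <- lane_no + 1L
          survivors[[length(survivors) + 1L]] <-
            list(id = sprintf("pc%05d", ctr), node = nn, path = nn,
                 start = win$start[i], lane = length(survivors) + 1L)
        }
      }
      active <- survivors
    }
    for (lane in active)
      contigs[[length(contigs) + 1L]] <- close_lane(lane, chrom, win, nrow(win), span)
  }
  df <- do.call(rbind, lapply(contigs, function(x) x$row))
  if (is.null(df)) {
    df <- data.frame(contig = character(0), chrom = character(0),
                     start = integer(0), end = integer(0), lane = integer(0),
                     n_windows = integer(0), length = integer(0))
  }
  df$path <- lapply(contigs, function(x) x$path)
  rownames(df) <- NULL
  obj <- list(contigs = df)
  class(obj) <- "pseudo_assembly"
  obj
}

stitch_copies <- function(fit) {
  if (inherits(fit, "copy_number_fit")) fit <- fit$assignments
  if (is.data.frame(fit)) return(setNames(fit$copy, fit$node))
  hg_assert(!is.null(names(fit)), "copy vector must be named by node id")
  fit
}

close_lane <- function(lane, chrom, win, last_i, span) {
  nwin <- length(lane$path)
  list(row = data.frame(
    contig = lane$id, chrom = chrom, start = lane$start,
    end = win$end[last_i], lane = lane$lane, n_windows = nwin,
    length = sum(span[lane$path]), stringsAsFactors = FALSE
  ), path = lane$path)
}

#' @export
print.pseudo_assembly <- function(x, ...) {
  cat("pseudo_assembly:", nrow(x$contigs), "pseudo-contig(s),",
      sum(x$contigs$length), "bp total\n")
  if (nrow(x$contigs) > 0)
    cat(sprintf("  N50 = %d bp, longest = %d bp\n",
                n50(x$contigs$length), max(x$contigs$length)))
  invisible(x)
}

#' Assembly N50
#'
#' The length L such that sequences of length >= L contain at least half the
#' total assembled length.
#'
#' @param lengths sequence lengths in bp.
#' @return Integer N50.
#' @export
#' @examples
#' n50(c(5, 4, 3, 2, 1)) # 4
n50 <- function(lengths) {
  hg_assert(length(lengths) > 0, "no lengths supplied")
  s <- sort(lengths, decreasing = TRUE)
  as.integer(s[which(cumsum(s) >= sum(s) / 2)[1]])
}

#' Score a pseudo-assembly against a truth set
#'
#' Recall and precision are computed over node-copy instances (a node
#' expected/predicted c times contributes c instances; overlap per node is
#' `min(predicted, truth)`). Coverage divides total pseudo-contig length by
#' four times the reference length (tetraploid). With a mask, all four
#' metrics are recomputed after dropping windows overlapping the mask
#' (pseudo-contig paths are split at masked windows).
#'
#' @param pseudo a [stitch()] result.
#' @param truth truth node-copy instances: `data.frame` with columns `node`
#'   and `copies`, or a character vector of node ids with multiplicity.
#' @param graph the underlying [build_haplotype_graph()].
#' @param mask optional [region_mask()] (e.g. pericentromeric regions).
#' @return Object of class `assembly_metrics` with `recall`, `precision`,
#'   `n50`, `coverage` and, when a mask is given, a `masked` sub-list.
#' @export
score_assembly <- function(pseudo, truth, graph, mask = NULL) {
  truth <- truth_copy_table(truth)
  hg_assert(nrow(truth) > 0 && sum(truth$copies) > 0, "empty truth set")
  res <- score_once(pseudo, truth, graph, masked_keys = character(0))
  if (!is.null(mask)) {
    win <- graph$windows
    over <- mask_overlaps(mask, win$chrom, win$start, win$end)
    res$masked <- score_once(pseudo, truth, graph,
                             masked_keys = paste(win$chrom, win$index)[over])
  }
  class(res) <- "assembly_metrics"
  res
}

truth_copy_table <- function(truth) {
  if (is.character(truth)) {
    tab <- table(truth)
    truth <- data.frame(node = names(tab), copies = as.integer(tab),
                        stringsAsFactors = FALSE)
  }
  truth
}

score_once <- function(pseudo, truth, graph, masked_keys) {
  nd <- graph$nodes
  node_key <- setNames(paste(nd$chrom, nd$window_index), nd$node)
  node_span <- setNames(nd$end - nd$start, nd$node)
  keep_node <- function(n) !(node_key[n] %in% masked_keys)

  pred_nodes <- unlist(pseudo$contigs$path, use.names = FALSE)
  pred_nodes <- pred_nodes[keep_node(pred_nodes)]
  pred <- table(pred_nodes)
  tr <- truth[keep_node(truth$node), , drop = FALSE]
  truth_n <- setNames(tr$copies, tr$node)
  inter <- sum(pmin(pred[intersect(names(pred), names(truth_n))],
                    truth_n[intersect(names(pred), names(truth_n))]))
  recall <- if (sum(truth_n) > 0) inter / sum(truth_n) else NA_real_
  precision <- if (sum(pred) > 0) inter / sum(pred) else NA_real_

  # contig lengths after dropping masked windows (paths split at the drop)
  lens <- unlist(lapply(pseudo$contigs$path, function(p) {
    keep <- keep_node(p)
    if (!any(keep)) return(numeric(0))
    runs <- rle(keep)
    ix <- split(seq_along(p), rep(seq_along(runs$lengths), runs$lengths))
    unlist(lapply(ix[runs$values], function(j) sum(node_span[p[j]])))
  }), use.names = FALSE)
  win <- graph$windows
  wkeep <- !(paste(win$chrom, win$index) %in% masked_keys)
  ref_len <- sum(win$end[wkeep] - win$start[wkeep])
  list(
    recall = recall, precision = precision,
    n50 = if (length(lens) > 0) n50(lens) else 0L,
    coverage = if (ref_len > 0) sum(lens) / (4 * ref_len) else NA_real_,
    n_contigs = length(lens), total_length = sum(lens)
  )
}

#' @export
print.assembly_metrics <- function(x, ...) {
  cat(sprintf(
    "assembly_metrics: recall %.3f, precision %.3f, N50 %d bp, coverage %.3f\n",
    x$recall, x$precision, x$n50, x$coverage))
  if (!is.null(x$masked))
    cat(sprintf(
      "  mask-excluded: recall %.3f, precision %.3f, N50 %d bp, coverage %.3f\n",
      x$masked$recall, x$masked$precision, x$masked$n50, x$masked$coverage))
  invisible(x)
}

#' Export pseudo-contig sequences as FASTA
#'
#' Each pseudo-contig record is the concatenation of the representative
#' haplotype's windowed sequences along the node path; the header encodes
#' chromosome, lane and reference span.
#'
#' @param pseudo a [stitch()] result.
#' @param graph the underlying [build_haplotype_graph()].
#' @param sequences per-haplotype sequences (see [extract_markers()]).
#' @param path optional output FASTA path.
#' @return Named character vector of pseudo-contig sequences (invisibly when
#'   `path` is given).
#' @export
export_pseudo_fasta <- function(pseudo, graph, sequences, path = NULL) {
  nd <- graph$nodes
  rownames(nd) <- nd$node
  recs <- vapply(seq_len(nrow(pseudo$contigs)), function(i) {
    p <- pseudo$contigs$path[[i]]
    paste(vapply(p, function(n) {
      s <- get_hap_seq(sequences, nd[n, "representative"], nd[n, "chrom"])
      out <- substr(s, nd[n, "start"] + 1L, nd[n, "end"])
      if (nchar(out) != nd[n, "end"] - nd[n, "start"])
        stop("missing window sequence for node ", n)
      out
    }, character(1)), collapse = "")
  }, character(1))
  names(recs) <- sprintf("%s %s:%d-%d lane=%d", pseudo$contigs$contig,
                         pseudo$contigs$chrom, pseudo$contigs$start,
                         pseudo$contigs$end, pseudo$contigs$lane)
  if (!is.null(path)) {
    write_fasta(recs, path)
    return(invisible(recs))
  }
  recs
}
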