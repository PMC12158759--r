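triage_levels <- c("haplotig", "diplotig", "triplotig", "tetraplotig", "replotig")

#' Classify contigs into ploidy classes by sequencing depth
#'
#' Relative to the per-haplotype depth d, contigs fall into continuous
#' half-open bands: `[0, 1.5 d]` haplotig, `(1.5 d, 2.5 d]` diplotig,
#' `(2.5 d, 3.5 d]` triplotig, `(3.5 d, 4.5 d]` tetraplotig, `(4.5 d, Inf)`
#' replotig. Classification is monotone in depth.
#'
#' @param depth mean contig depth(s), reads per base (>= 0).
#' @param d per-haplotype sequencing depth (> 0).
#' @return Factor with levels haplotig/diplotig/triplotig/tetraplotig/
#'   replotig.
#' @export
#' @examples
#' classify_contig(c(40, 70, 140), d = 30)
classify_contig <- function(depth, d) {
  hg_assert(d > 0, "per-haplotype depth d must be > 0")
  hg_assert(all(depth >= 0), "depth must be >= 0")
  ix <- 1L + (depth > 1.5 * d) + (depth > 2.5 * d) + (depth > 3.5 * d) +
    (depth > 4.5 * d)
  factor(triage_levels[ix], levels = triage_levels)
}

#' Per-class triage summary
#'
#' @param records `data.frame` with columns `contig`, `length`, `depth`
#'   (mean depth per contig); at least one row.
#' @param d per-haplotype depth.
#' @return Object of class `triage_report` with the classified records and a
#'   per-class summary (contig counts, total lengths).
#' @export
triage_report <- function(records, d) {
  hg_assert(is.data.frame(records) && nrow(records) >= 1,
            "need at least one contig record")
  hg_assert(all(c("contig", "length", "depth") %in% colnames(records)),
            "records need columns contig, length, depth")
  records$class <- classify_contig(records$depth, d)
  summary <- data.frame(
    class = triage_levels,
    n_contigs = as.integer(table(records$class)),
    total_length = as.numeric(tapply(records$length, records$class, sum,
                                     default = 0)),
    stringsAsFactors = FALSE
  )
  obj <- list(records = records, summary = summary, d = d)
  class(obj) <- "triage_report"
  obj
}

#' @export
print.triage_report <- function(x, ...) {
  cat("triage_report (per-haplotype depth d =", x$d, ")\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Median-depth estimator for the per-haplotype depth
#'
#' A crude helper when d is unknown: assumes the depth mode corresponds to
#' haplotigs and returns the length-weighted median contig depth.
#'
#' @param records contig records as in [triage_report()].
#' @return Estimated per-haplotype depth.
#' @export
estimate_haploid_depth <- function(records) {
  ord <- order(records$depth)
  w <- cumsum(records$length[ord]) / sum(records$length)
  records$depth[ord][which(w >= 0.5)[1]]
}
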