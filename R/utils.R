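#' Package logging
#'
#' Messages are emitted through [message()] and can be silenced globally with
#' `options(haplograph.quiet = TRUE)`.
#'
#' @param ... parts of the message, pasted together.
#' @return Invisibly, the message string.
#' @keywords internal
hg_log <- function(...) {
  msg <- paste0(...)
  if (!isTRUE(getOption("haplograph.quiet", FALSE))) message("[haplograph] ", msg)
  invisible(msg)
}

#' Canonicalize k-mer strings
#'
#' Returns, for each k-mer, the lexicographic minimum of the k-mer and its
#' reverse complement. All k-mers must consist of A/C/G/T only.
#'
#' @param kmers character vector of k-mer strings.
#' @return Character vector of the same length in canonical form.
#' @export
#' @examples
#' canonicalize_kmers(c("TTT", "AAA", "ACG"))
canonicalize_kmers <- function(kmers) {
  if (length(kmers) == 0) return(character(0))
  cpp_canonicalize(toupper(as.character(kmers)))
}

# run `expr` under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards so library calls do not perturb user RNG
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  force(expr)
}

# stopifnot with a readable message
hg_assert <- function(ok, msg) {
  if (!isTRUE(ok)) stop(msg, call. = FALSE)
  invisible(TRUE)
}
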