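#' Construct a variant table
#'
#' A variant table stores biallelic SNP genotypes of a set of haplotypes
#' against a common reference. Positions are 1-based (as in VCF); all other
#' coordinates in the package are 0-based half-open. Missing genotypes are a
#' first-class state (`NA`), never imputed.
#'
#' @param chrom chromosome of each site.
#' @param pos 1-based position of each site.
#' @param alleles integer matrix, sites x haplotypes, with entries 0 (ref),
#'   1 (alt) or `NA` (missing); column names are haplotype ids.
#' @return Object of class `variant_table`.
#' @export
variant_table <- function(chrom, pos, alleles) {
  alleles <- as.matrix(alleles)
  hg_assert(!is.null(colnames(alleles)), "allele matrix needs haplotype column names")
  hg_assert(length(chrom) == nrow(alleles) && length(pos) == nrow(alleles),
            "chrom/pos length must match allele matrix rows")
  hg_assert(!anyDuplicated(colnames(alleles)), "duplicate haplotype ids")
  key <- paste(chrom, pos)
  hg_assert(!anyDuplicated(key), "duplicate (chrom, pos) sites")
  ord <- order(chrom, pos)
  storage.mode(alleles) <- "integer"
  hg_assert(all(alleles %in% c(0L, 1L, NA)), "alleles must be 0, 1 or NA")
  obj <- list(
    sites = data.frame(chrom = as.character(chrom)[ord], pos = as.integer(pos)[ord],
                       stringsAsFactors = FALSE),
    alleles = alleles[ord, , drop = FALSE]
  )
  class(obj) <- "variant_table"
  obj
}

#' @export
print.variant_table <- function(x, ...) {
  cat("variant_table:", nrow(x$sites), "biallelic SNP sites x",
      ncol(x$alleles), "haplotypes\n")
  cat("  chromosomes:", paste(unique(x$sites$chrom), collapse = ", "), "\n")
  miss <- mean(is.na(x$alleles))
  cat(sprintf("  missing genotype fraction: %.4f\n", miss))
  invisible(x)
}

#' Number of haplotypes / sites in a variant table
#' @param vt a `variant_table`.
#' @return Integer count.
#' @export
n_haplotypes <- function(vt) ncol(vt$alleles)

#' @rdname n_haplotypes
#' @export
n_sites <- function(vt) nrow(vt$sites)

# sites falling in the 0-based half-open window [start, end) on chrom
variant_rows_in_window <- function(vt, chrom, start, end) {
  which(vt$sites$chrom == chrom & vt$sites$pos - 1L >= start & vt$sites$pos - 1L < end)
}

#' Read variants from VCF or a long TSV dialect
#'
#' Keeps biallelic SNPs only; multiallelic records and indels are dropped with
#' a logged count. For VCF input, per-sample genotype strings are split into
#' haplotype alleles using `haplotype_of_sample`, a named list mapping each
#' sample id to its haplotype ids (e.g. `list(cv1 = c("cv1_hap1", ...,
#' "cv1_hap4"))`); by default every sample `s` of ploidy `p` yields haplotypes
#' `s_hap1 .. s_happ`. The TSV dialect has a header line and four columns:
#' `chrom`, `pos`, `haplotype`, `allele` with allele in
#' `ref`/`alt`/`missing`.
#'
#' @param path input file.
#' @param haplotype_of_sample named list mapping VCF sample ids to haplotype
#'   ids (ignored for TSV input).
#' @param format `"auto"` (by extension), `"vcf"` or `"tsv"`.
#' @return A [variant_table()].
#' @export
read_variants <- function(path, haplotype_of_sample = NULL,
                          format = c("auto", "vcf", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "tsv"
  }
  if (format == "vcf") read_variants_vcf(path, haplotype_of_sample) else read_variants_tsv(path)
}

read_variants_vcf <- function(path, haplotype_of_sample = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf@fix
  n_rec <- nrow(fix)
  if (is.null(n_rec) || n_rec == 0) {
    warning("VCF has no variant records: ", path)
    samples <- colnames(vcf@gt)[-1]
    haps <- vcf_haplotype_ids(samples, haplotype_of_sample, ploidy = 4L)
    return(variant_table(character(0), integer(0),
                         matrix(integer(0), 0, length(haps),
                                dimnames = list(NULL, haps))))
  }
  alt <- fix[, "ALT"]
  ref <- fix[, "REF"]
  snp <- !is.na(alt) & !grepl(",", alt) & nchar(ref) == 1 & nchar(alt) == 1
  n_drop <- sum(!snp)
  if (n_drop > 0) hg_log("dropped ", n_drop, " multiallelic/indel record(s)")
  gt <- vcf@gt[snp, , drop = FALSE]
  fix <- fix[snp, , drop = FALSE]
  samples <- colnames(gt)[-1]
  gtm <- gt[, -1, drop = FALSE]
  gt_field <- matrix(sub(":.*$", "", gtm), nrow = nrow(gtm), ncol = ncol(gtm))
  split_gt <- lapply(seq_along(samples), function(j) {
    strsplit(gt_field[, j], "[/|]")
  })
  hap_of <- vcf_haplotype_ids(samples, haplotype_of_sample, 4L, split_gt)
  if (nrow(fix) == 0) {
    warning("no biallelic SNP records in VCF: ", path)
    haps <- unlist(hap_of, use.names = FALSE)
    return(variant_table(character(0), integer(0),
                         matrix(integer(0), 0, length(haps),
                                dimnames = list(NULL, haps))))
  }
  cols <- list()
  for (j in seq_along(samples)) {
    mat <- do.call(rbind, split_gt[[j]])
    hg_assert(ncol(mat) == length(hap_of[[samples[j]]]),
              paste0("sample ", samples[j], ": ploidy does not match haplotype map"))
    for (a in seq_len(ncol(mat))) {
      v <- mat[, a]
      x <- ifelse(v == "0", 0L, ifelse(v == "1", 1L, NA_integer_))
      cols[[hap_of[[samples[j]]][a]]] <- x
    }
  }
  alleles <- do.call(cbind, cols)
  colnames(alleles) <- names(cols)
  variant_table(fix[, "CHROM"], as.integer(fix[, "POS"]), alleles)
}

vcf_haplotype_ids <- function(samples, haplotype_of_sample, ploidy, split_gt = NULL) {
  if (is.null(haplotype_of_sample)) {
    return(setNames(lapply(seq_along(samples), function(j) {
      p <- if (!is.null(split_gt) && length(split_gt[[j]]) > 0)
        length(split_gt[[j]][[1]]) else ploidy
      paste0(samples[j], "_hap", seq_len(p))
    }), samples))
  }
  unknown <- setdiff(names(haplotype_of_sample), samples)
  if (length(unknown) > 0)
    stop("unknown sample id(s) in haplotype map: ", paste(unknown, collapse = ", "))
  missing <- setdiff(samples, names(haplotype_of_sample))
  if (length(missing) > 0)
    stop("sample(s) absent from haplotype map: ", paste(missing, collapse = ", "))
  haplotype_of_sample
}

read_variants_tsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   colClasses = c("character", "integer", "character", "character"))
  hg_assert(all(c("chrom", "pos", "haplotype", "allele") %in% colnames(df)),
            "TSV dialect needs columns chrom, pos, haplotype, allele")
  if (nrow(df) == 0) {
    warning("variant TSV has no records: ", path)
    return(variant_table(character(0), integer(0),
                         matrix(integer(0), 0, 0, dimnames = list(NULL, character(0)))))
  }
  hg_assert(all(df$allele %in% c("ref", "alt", "missing")),
            "allele column must be ref/alt/missing")
  haps <- unique(df$haplotype)
  key <- paste(df$chrom, df$pos)
  ukey <- unique(key)
  site_ix <- match(key, ukey)
  hap_ix <- match(df$haplotype, haps)
  alleles <- matrix(NA_integer_, length(ukey), length(haps),
                    dimnames = list(NULL, haps))
  val <- ifelse(df$allele == "ref", 0L, ifelse(df$allele == "alt", 1L, NA_integer_))
  alleles[cbind(site_ix, hap_ix)] <- val
  first <- !duplicated(key)
  variant_table(df$chrom[first], df$pos[first], alleles)
}

#' Write a variant table in the long TSV dialect
#'
#' @param vt a [variant_table()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_variants_tsv <- function(vt, path) {
  haps <- colnames(vt$alleles)
  n <- nrow(vt$sites)
  df <- data.frame(
    chrom = rep(vt$sites$chrom, times = length(haps)),
    pos = rep(vt$sites$pos, times = length(haps)),
    haplotype = rep(haps, each = n),
    allele = c(ifelse(is.na(vt$alleles), "missing",
                      ifelse(vt$alleles == 0L, "ref", "alt"))),
    stringsAsFactors = FALSE
  )
  df <- df[order(df$chrom, df$pos, match(df$haplotype, haps)), ]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Report the frequency of missing genotype calls
#'
#' @param vt a [variant_table()].
#' @return Named numeric vector: fraction of missing calls per haplotype.
#' @export
missing_frequency <- function(vt) {
  colMeans(is.na(vt$alleles))
}
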