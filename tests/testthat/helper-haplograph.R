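options(haplograph.quiet = TRUE)

# --- independent brute-force oracles (kept free of package k-mer code) ------

rand_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

oracle_canonical <- function(kmers) {
  vapply(kmers, function(s) min(s, oracle_revcomp(s)), character(1),
         USE.NAMES = FALSE)
}

# all distinct canonical k-mers of a sequence, by direct substring enumeration
oracle_kmer_set <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  km <- substring(seq, 1:(n - k + 1), k:n)
  km <- km[!grepl("[^ACGT]", km)]
  unique(oracle_canonical(km))
}

# brute-force per-bp pi: average pairwise difference over all haplotype pairs,
# pairwise-complete, with the unbiasedness handled by direct pair averaging
oracle_pi <- function(alleles, L) {
  n <- ncol(alleles)
  tot <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    a <- alleles[, i]; b <- alleles[, j]
    ok <- !is.na(a) & !is.na(b)
    tot <- tot + sum(a[ok] != b[ok])
  }
  tot / choose(n, 2) / L
}

oracle_n50 <- function(lengths) {
  s <- sort(lengths, decreasing = TRUE)
  half <- sum(s) / 2
  run <- 0
  for (x in s) {
    run <- run + x
    if (run >= half) return(x)
  }
}

# small deterministic pan-genome used across tests
small_sim <- function(seed = 7) {
  simulate_pangenome(seed = seed, n_founders = 6, genome_length = 3e5,
                     window_width = 5e4, target_pi = 0.018,
                     founders_per_window = 3, n_haplotypes = 12)
}

small_graph <- function(sim) {
  build_haplotype_graph(sim$variants,
                        reference_index(sim$chrom, sim$config$genome_length),
                        width = sim$config$window_width)
}

# minimal VCF fixture: 3 biallelic SNPs + 1 indel + 1 multiallelic record,
# two tetraploid samples
write_vcf_fixture <- function(path) {
  lines <- c(
    "##fileformat=VCFv4.2",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2",
    "chr01\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0|1|0|0\t1|1|0|1",
    "chr01\t200\t.\tAT\tA\t.\tPASS\t.\tGT\t0|0|0|0\t0|1|0|0",
    "chr01\t300\t.\tC\tT\t.\tPASS\t.\tGT\t.|1|0|0\t0|0|0|0",
    "chr01\t400\t.\tG\tA,T\t.\tPASS\t.\tGT\t0|1|0|2\t0|0|0|0",
    "chr01\t500\t.\tT\tC\t.\tPASS\t.\tGT\t1|1|1|1\t0|0|1|0"
  )
  writeLines(lines, path)
  path
}
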