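# Shared fixtures and independent oracles, built in code at test time.

# Random genotype matrix: n diploids x m sites on one chromosome.
rand_gm <- function(n = 5, m = 20, chrom = "chr1", missing_rate = 0.1,
                    span = 1e5) {
  pos0 <- sort(sample.int(span, m)) - 1L
  d <- matrix(sample(0:2, n * m, replace = TRUE), nrow = n)
  if (missing_rate > 0) d[runif(n * m) < missing_rate] <- NA_integer_
  ref <- sample(c("A", "C", "G", "T"), m, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                character(1))
  genotype_matrix(sprintf("s%02d", seq_len(n)),
                  data.frame(chrom = chrom, pos0 = pos0, ref = ref,
                             alt = unname(alt)),
                  d)
}

# Pi oracle: per site, explode called diploids into allele tokens and take
# the mean difference over all ORDERED haplotype pairs drawn with
# replacement; sum over sites, divide by window span. Independent of the
# frequency-based implementation.
pi_oracle <- function(dosages, span) {
  tot <- 0
  for (s in seq_len(ncol(dosages))) {
    d <- dosages[, s]
    d <- d[!is.na(d)]
    if (!length(d)) next
    tokens <- unlist(lapply(d, function(x) c(rep(1L, x), rep(0L, 2L - x))))
    pairs <- outer(tokens, tokens, `!=`)
    tot <- tot + mean(pairs)
  }
  tot / span
}

# Random additive (tree-derived) distance matrix on n taxa, plus the tree.
rand_additive <- function(n) {
  tr <- ape::rtree(n, rooted = FALSE, br = function(k) runif(k, 0.1, 2))
  tr$tip.label <- sprintf("t%02d", seq_len(n))
  list(tree = tr, d = cophenetic(tr))
}

# Path-length (patristic) metric of a tree, ordered by the given labels.
path_metric <- function(tree, labels) {
  cophenetic(tree)[labels, labels]
}

# Hypergeometric survival-function oracle.
phyper_oracle <- function(k, n, K, N) {
  if (k == 0) return(1)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

# Minimal VCF text writer for parser tests.
write_vcf_text <- function(records, samples, path) {
  header <- c("##fileformat=VCFv4.2",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(header, records), path)
  path
}
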