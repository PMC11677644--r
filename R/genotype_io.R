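#' Construct a genotype matrix
#'
#' The central data container of the package: diploid biallelic-SNP genotypes
#' coded as alt-allele dosages 0/1/2 with `NA` for missing calls, together with
#' the site table. VCF positions are 1-based; they are converted to 0-based
#' coordinates exactly once, here, and every downstream window operation uses
#' 0-based half-open intervals.
#'
#' @param sample_ids character vector of unique sample names.
#' @param sites data.frame with columns `chrom` (character), `pos0`
#'   (0-based site coordinate, integer), `ref`, `alt` (single bases).
#' @param dosages integer matrix, samples in rows, sites in columns, values in
#'   0/1/2 or `NA`.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(sample_ids, sites, dosages) {
  sample_ids <- as.character(sample_ids)
  stopifnot(!anyDuplicated(sample_ids))
  sites <- as.data.frame(sites)
  req <- c("chrom", "pos0", "ref", "alt")
  if (!all(req %in% names(sites))) {
    stop("sites must have columns: ", paste(req, collapse = ", "))
  }
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "integer"
  if (nrow(dosages) != length(sample_ids) || ncol(dosages) != nrow(sites)) {
    stop("dosage matrix must be samples x sites")
  }
  bad <- dosages[!is.na(dosages)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L)) {
    stop("dosages must be 0, 1, 2 or NA")
  }
  if (nrow(sites)) {
    if (any(sites$pos0 < 0L)) stop("positions must be >= 0 (0-based)")
    if (any(sites$ref == sites$alt)) stop("ref and alt alleles must differ")
    o <- order(sites$chrom, sites$pos0, method = "radix")
    sites <- sites[o, , drop = FALSE]
    dosages <- dosages[, o, drop = FALSE]
    if (anyDuplicated(sites[, c("chrom", "pos0")])) {
      stop("duplicate positions within a chromosome")
    }
  }
  rownames(sites) <- NULL
  rownames(dosages) <- sample_ids
  structure(list(sample_ids = sample_ids, sites = sites, dosages = dosages),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d sites on %d chromosome(s)\n",
              length(x$sample_ids), nrow(x$sites),
              length(unique(x$sites$chrom))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Read diploid genotypes from a VCF file
#'
#' Keeps biallelic SNP records only; multi-allelic records and indels are
#' skipped (their count is reported as a message and attached as the
#' `n_skipped` attribute). Genotypes are converted to alt-allele dosage;
#' half-calls and missing genotypes become `NA`. Phased separators are
#' accepted and treated as unphased — every statistic downstream is
#' phase-free. Gzipped files are handled transparently.
#'
#' @param path VCF file (v4.2, `GT` must be present in FORMAT).
#' @param sample_subset optional character vector restricting (and ordering)
#'   the samples kept; unknown names are an error.
#' @return A [genotype_matrix()].
#' @export
read_vcf <- function(path, sample_subset = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  if (is.null(v@gt) || !"FORMAT" %in% colnames(v@gt)) {
    stop("VCF has no GT field in FORMAT")
  }
  fx <- v@fix
  if (nrow(fx) == 0L) {
    gm <- genotype_matrix(setdiff(colnames(v@gt), "FORMAT"),
                          data.frame(chrom = character(), pos0 = integer(),
                                     ref = character(), alt = character()),
                          matrix(integer(), ncol = 0,
                                 nrow = ncol(v@gt) - 1L))
    attr(gm, "n_skipped") <- 0L
    return(gm)
  }
  if (!any(grepl("(^|:)GT(:|$)", v@gt[, "FORMAT"]))) {
    stop("VCF has no GT field in FORMAT")
  }
  ref <- fx[, "REF"]; alt <- fx[, "ALT"]
  keep <- !is.na(alt) & !grepl(",", alt, fixed = TRUE) &
    nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  n_skipped <- sum(!keep)
  if (n_skipped > 0L) {
    message(sprintf("read_vcf: skipped %d non-biallelic-SNP record(s)",
                    n_skipped))
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt)) stop("VCF has no GT field in FORMAT")
  gt <- gt[keep, , drop = FALSE]
  fx <- fx[keep, , drop = FALSE]
  samples <- colnames(gt)
  if (!is.null(sample_subset)) {
    unknown <- setdiff(sample_subset, samples)
    if (length(unknown)) {
      stop("unknown sample(s) in subset: ", paste(unknown, collapse = ", "))
    }
    gt <- gt[, sample_subset, drop = FALSE]
    samples <- sample_subset
  }
  dos <- gt_to_dosage(gt)           # sites x samples
  gm <- genotype_matrix(
    samples,
    data.frame(chrom = as.character(fx[, "CHROM"]),
               pos0 = as.integer(fx[, "POS"]) - 1L,
               ref = as.character(fx[, "REF"]),
               alt = as.character(fx[, "ALT"]),
               stringsAsFactors = FALSE),
    t(dos))
  attr(gm, "n_skipped") <- n_skipped
  gm
}

# GT strings -> dosage; half-calls ("./1") and full missing -> NA
gt_to_dosage <- function(gt) {
  a1 <- substr(gt, 1L, 1L)
  a2 <- substr(gt, 3L, 3L)
  d <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt))
  ok <- a1 %in% c("0", "1") & a2 %in% c("0", "1")
  d[ok] <- (a1 == "1")[ok] + (a2 == "1")[ok]
  dimnames(d) <- dimnames(gt)
  d
}

#' Write a genotype matrix as minimal VCF v4.2
#'
#' Emits unphased `GT`-only records in coordinate order; internal 0-based
#' coordinates are converted back to the 1-based VCF convention.
#'
#' @param gm a [genotype_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (nrow(gm$sites) && anyDuplicated(gm$sites[, c("chrom", "pos0")])) {
    stop("duplicate positions within a chromosome")
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=silkscan",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", gm$sample_ids), collapse = "\t")), con)
  n <- nrow(gm$sites)
  if (n == 0L) return(invisible(path))
  code <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow = n, ncol = length(gm$sample_ids))
  d <- t(gm$dosages)
  gt[!is.na(d)] <- code[d[!is.na(d)] + 1L]
  lines <- paste(gm$sites$chrom, gm$sites$pos0 + 1L, ".", gm$sites$ref,
                 gm$sites$alt, ".", "PASS", ".", "GT",
                 apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' Define sample-to-population assignment
#'
#' @param assignment named character vector or 2-column data.frame
#'   (`sample_id`, `group`) mapping every sample to exactly one group.
#' @param groups optional ordered group labels; defaults to order of first
#'   appearance.
#' @return An object of class `population_set`.
#' @export
population_set <- function(assignment, groups = NULL) {
  if (is.data.frame(assignment)) {
    a <- as.character(assignment[[2L]])
    names(a) <- as.character(assignment[[1L]])
    assignment <- a
  }
  if (is.null(names(assignment)) || anyDuplicated(names(assignment))) {
    stop("assignment must map each sample to exactly one group")
  }
  if (is.null(groups)) groups <- unique(unname(assignment))
  if (!all(assignment %in% groups)) stop("assignment uses unknown group label")
  if (!all(groups %in% assignment)) stop("every group needs >= 1 sample")
  structure(list(assignment = assignment, groups = groups),
            class = "population_set")
}

#' Read a population assignment table
#'
#' Two-column TSV, `sample_id<TAB>group`, no header required (a header line
#' starting with `sample` is tolerated). Gzip transparent.
#' @param path TSV path.
#' @return A [population_set()].
#' @export
read_populations <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("sample_id", "group"))
  if (nrow(df) && tolower(df$sample_id[1L]) %in% c("sample", "sample_id")) {
    df <- df[-1L, , drop = FALSE]
  }
  population_set(df)
}

#' Per-group alt-allele frequencies at every site
#'
#' The frequency in a group is (sum of non-missing dosages) / (2 x number of
#' called samples); a group with no called sample at a site gets `NA` with
#' call count 0 (an explicit "undefined" flag — `NaN` never propagates).
#'
#' @param gm a [genotype_matrix()].
#' @param pops a [population_set()]; all its samples must be in `gm`.
#' @return list with `freq` and `calls`: group x site matrices (alt-allele
#'   frequency; number of called alleles).
#' @export
group_frequencies <- function(gm, pops) {
  stopifnot(inherits(gm, "genotype_matrix"), inherits(pops, "population_set"))
  missing_samples <- setdiff(names(pops$assignment), gm$sample_ids)
  if (length(missing_samples)) {
    stop("samples not in genotype matrix: ",
         paste(missing_samples, collapse = ", "))
  }
  nsite <- nrow(gm$sites)
  freq <- calls <- matrix(NA_real_, nrow = length(pops$groups), ncol = nsite,
                          dimnames = list(pops$groups, NULL))
  for (g in pops$groups) {
    ids <- names(pops$assignment)[pops$assignment == g]
    d <- gm$dosages[ids, , drop = FALSE]
    ncall <- colSums(!is.na(d))
    s <- colSums(d, na.rm = TRUE)
    f <- ifelse(ncall > 0L, s / (2 * ncall), NA_real_)
    freq[g, ] <- f
    calls[g, ] <- 2 * ncall
  }
  list(freq = freq, calls = calls)
}

#' Allele frequencies at a single site
#'
#' @param gm a [genotype_matrix()].
#' @param pops a [population_set()].
#' @param site_index 1-based index into the site table.
#' @param weighted if `TRUE` the pooled frequency is call-count weighted;
#'   default is the unweighted mean of the defined group frequencies, which
#'   gives the symmetric 0/1 endpoint behaviour of the Fst scan.
#' @return list with per-group `freq`, allele-call `count`, `pooled`
#'   frequency and `undefined` logical flags.
#' @export
site_frequencies <- function(gm, pops, site_index, weighted = FALSE) {
  if (site_index < 1L || site_index > nrow(gm$sites)) {
    stop("site_index out of range")
  }
  gf <- group_frequencies(gm, pops)
  f <- gf$freq[, site_index]
  n <- gf$calls[, site_index]
  def <- !is.na(f)
  pooled <- if (!any(def)) {
    NA_real_
  } else if (weighted) {
    sum(f[def] * n[def]) / sum(n[def])
  } else {
    mean(f[def])
  }
  list(freq = f, count = n, pooled = pooled, undefined = !def)
}
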