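#' Sliding-window specification
#'
#' Defaults are the standard resequencing-scan grid: 100 kb windows advanced
#' in 50 kb steps.
#'
#' @param window_size window width in bp.
#' @param step_size step between window starts in bp; must satisfy
#'   `0 < step_size <= window_size`.
#' @param min_snps minimum SNP count for a window's statistics to be defined.
#' @return An object of class `window_spec`.
#' @export
window_spec <- function(window_size = 100000L, step_size = 50000L,
                        min_snps = 1L) {
  window_size <- as.integer(window_size)
  step_size <- as.integer(step_size)
  min_snps <- as.integer(min_snps)
  stopifnot(step_size > 0L, step_size <= window_size, min_snps >= 1L)
  structure(list(window_size = window_size, step_size = step_size,
                 min_snps = min_snps), class = "window_spec")
}

#' Enumerate sliding windows over chromosomes
#'
#' Windows start at 0, `step_size`, 2*`step_size`, ...; each window is
#' `[start, min(start + window_size, length))` in 0-based half-open
#' coordinates, so the trailing window is truncated at the chromosome end. A
#' new window is only started while it advances coverage by a full step
#' (start <= length - step_size), hence a chromosome shorter than the window
#' yields the single window `[0, length)`.
#'
#' @param chromosome_lengths named numeric vector, chromosome -> length (bp).
#' @param spec a [window_spec()].
#' @return data.frame with columns `chrom`, `start`, `end`.
#' @export
make_windows <- function(chromosome_lengths, spec = window_spec()) {
  stopifnot(length(chromosome_lengths) > 0L, all(chromosome_lengths > 0),
            !is.null(names(chromosome_lengths)))
  out <- lapply(names(chromosome_lengths), function(chr) {
    len <- chromosome_lengths[[chr]]
    starts <- seq(0, max(len - spec$step_size, 0), by = spec$step_size)
    data.frame(chrom = chr, start = starts,
               end = pmin(starts + spec$window_size, len))
  })
  do.call(rbind, out)
}

# Per-site expected heterozygosity 2p(1-p), optionally with the 2N/(2N-1)
# small-sample correction (allele-count aware, vectorised over sites).
site_het <- function(freq, calls, unbiased = FALSE) {
  h <- 2 * freq * (1 - freq)
  if (unbiased) {
    corr <- ifelse(!is.na(calls) & calls > 1, calls / (calls - 1), NA_real_)
    h <- h * corr
  }
  h
}

#' Windowed nucleotide diversity for one group
#'
#' Pi per bp for a single window: the sum over polymorphic sites of the
#' plug-in heterozygosity 2p(1-p), divided by the full window span. This is
#' algebraically the mean per-site difference between two haplotypes drawn
#' with replacement from the group. Sites where the group has no called
#' allele are skipped. `unbiased = TRUE` applies the 2N/(2N-1)
#' sampled-without-replacement correction.
#'
#' @param gm a [genotype_matrix()].
#' @param pops a [population_set()].
#' @param group group label (must exist in `pops`).
#' @param window list or one-row data.frame with `chrom`, `start`, `end`
#'   (0-based half-open bp).
#' @param unbiased apply the small-sample correction.
#' @return Pi per bp (>= 0); 0 for a window without variant sites.
#' @export
window_pi <- function(gm, pops, group, window, unbiased = FALSE) {
  if (!group %in% pops$groups) stop("unknown group: ", group)
  gf <- group_frequencies(gm, pops)
  idx <- which(gm$sites$chrom == window$chrom &
                 gm$sites$pos0 >= window$start & gm$sites$pos0 < window$end)
  h <- site_het(gf$freq[group, idx], gf$calls[group, idx], unbiased)
  sum(h, na.rm = TRUE) / (window$end - window$start)
}

#' Pi ratio between two groups
#'
#' @param pi_num,pi_den windowed Pi of the numerator and denominator group.
#' @return elementwise ratio; `NA` (excluded from outlier distributions)
#'   where the denominator is 0 or either value is undefined.
#' @export
pi_ratio <- function(pi_num, pi_den) {
  out <- ifelse(!is.na(pi_num) & !is.na(pi_den) & pi_den > 0,
                pi_num / pi_den, NA_real_)
  unname(out)
}

# Per-site ingredients of the two windowed Fst estimators, given two rows of
# group frequencies/calls. Returns NA at sites where either group is
# undefined.
fst_site_terms <- function(f1, f2, n1, n2) {
  def <- !is.na(f1) & !is.na(f2)
  pbar <- (f1 + f2) / 2
  hs <- (2 * f1 * (1 - f1) + 2 * f2 * (1 - f2)) / 2
  ht <- 2 * pbar * (1 - pbar)
  # Hudson: numerator removes within-population sampling noise
  hud_num <- (f1 - f2)^2 -
    ifelse(n1 > 1, f1 * (1 - f1) / (n1 - 1), NA_real_) -
    ifelse(n2 > 1, f2 * (1 - f2) / (n2 - 1), NA_real_)
  hud_den <- f1 * (1 - f2) + f2 * (1 - f1)
  hs[!def] <- ht[!def] <- hud_num[!def] <- hud_den[!def] <- NA_real_
  list(hs = hs, ht = ht, hud_num = hud_num, hud_den = hud_den, def = def)
}

#' Windowed Fst between two groups
#'
#' Default estimator (`"nei"`): the ratio-of-sums heterozygosity form
#' `Fst = 1 - sum(H_S) / sum(H_T)` where, per site, `H_S` is the mean of the
#' two groups' 2p(1-p) and `H_T = 2*pbar*(1-pbar)` with `pbar` the unweighted
#' mean frequency. It is exactly 0 when the groups share all frequencies and
#' exactly 1 when they are fixed for opposite alleles. The `"hudson"`
#' estimator (ratio of sums of `(p1-p2)^2` minus within-group sampling terms
#' over between-group heterozygosity) is unbiased for the Balding-Nichols
#' differentiation parameter and is the choice for parameter recovery.
#'
#' @param gm a [genotype_matrix()].
#' @param pops a [population_set()].
#' @param group_pair character vector of exactly two group labels.
#' @param window list with `chrom`, `start`, `end` (0-based half-open).
#' @param estimator `"nei"` (default) or `"hudson"`.
#' @return Fst in [0,1] for `"nei"` (`"hudson"` may be slightly negative by
#'   sampling noise); `NA` when no informative site is in the window.
#' @export
window_fst <- function(gm, pops, group_pair, window, estimator = c("nei", "hudson")) {
  estimator <- match.arg(estimator)
  if (length(group_pair) != 2L) stop("group_pair must contain exactly 2 groups")
  if (!all(group_pair %in% pops$groups)) stop("unknown group in group_pair")
  gf <- group_frequencies(gm, pops)
  idx <- which(gm$sites$chrom == window$chrom &
                 gm$sites$pos0 >= window$start & gm$sites$pos0 < window$end)
  tt <- fst_site_terms(gf$freq[group_pair[1L], idx], gf$freq[group_pair[2L], idx],
                       gf$calls[group_pair[1L], idx], gf$calls[group_pair[2L], idx])
  fst_from_terms(tt, estimator)
}

fst_from_terms <- function(tt, estimator) {
  if (estimator == "nei") {
    use <- !is.na(tt$ht) & tt$ht > 0
    if (!any(use)) return(NA_real_)
    1 - sum(tt$hs[use]) / sum(tt$ht[use])
  } else {
    use <- !is.na(tt$hud_den) & !is.na(tt$hud_num) & tt$hud_den > 0
    if (!any(use)) return(NA_real_)
    sum(tt$hud_num[use]) / sum(tt$hud_den[use])
  }
}

#' Full sliding-window scan of Pi, Pi ratio and Fst
#'
#' Runs the whole windowed computation for a pair of populations in one
#' vectorised pass: per-window SNP count, per-group Pi, the Pi ratio
#' (numerator group first in `group_pair`) and Fst. Windows with fewer than
#' `spec$min_snps` SNPs get `NA` statistics.
#'
#' @param gm a [genotype_matrix()].
#' @param pops a [population_set()].
#' @param group_pair two group labels, numerator group of the Pi ratio first.
#' @param spec a [window_spec()].
#' @param chromosome_lengths named vector; defaults to the last site + 1 per
#'   chromosome observed in `gm` (so trailing windows cover all data).
#' @param estimator Fst estimator, see [window_fst()].
#' @param unbiased apply the 2N/(2N-1) correction to Pi.
#' @return data.frame (one row per window): `chrom`, `start`, `end`,
#'   `n_snps`, `pi_<A>`, `pi_<B>`, `pi_ratio`, `fst`.
#' @export
scan_windows <- function(gm, pops, group_pair, spec = window_spec(),
                         chromosome_lengths = NULL,
                         estimator = c("nei", "hudson"), unbiased = FALSE) {
  estimator <- match.arg(estimator)
  if (length(group_pair) != 2L) stop("group_pair must contain exactly 2 groups")
  if (is.null(chromosome_lengths)) {
    chromosome_lengths <- tapply(gm$sites$pos0, gm$sites$chrom, max) + 1
    chromosome_lengths <- chromosome_lengths[order(names(chromosome_lengths))]
  }
  win <- make_windows(chromosome_lengths, spec)
  gf <- group_frequencies(gm, pops)
  gA <- group_pair[1L]; gB <- group_pair[2L]
  hA <- site_het(gf$freq[gA, ], gf$calls[gA, ], unbiased)
  hB <- site_het(gf$freq[gB, ], gf$calls[gB, ], unbiased)
  tt <- fst_site_terms(gf$freq[gA, ], gf$freq[gB, ],
                       gf$calls[gA, ], gf$calls[gB, ])

  n <- nrow(win)
  n_snps <- integer(n)
  piA <- piB <- fst <- rep(NA_real_, n)
  for (chr in unique(win$chrom)) {
    sidx <- which(gm$sites$chrom == chr)
    pos <- gm$sites$pos0[sidx]
    widx <- which(win$chrom == chr)
    for (w in widx) {
      inw <- sidx[pos >= win$start[w] & pos < win$end[w]]
      n_snps[w] <- length(inw)
      if (length(inw) < spec$min_snps) next
      span <- win$end[w] - win$start[w]
      piA[w] <- sum(hA[inw], na.rm = TRUE) / span
      piB[w] <- sum(hB[inw], na.rm = TRUE) / span
      fst[w] <- fst_from_terms(lapply(tt, `[`, inw), estimator)
    }
  }
  out <- data.frame(chrom = win$chrom, start = win$start, end = win$end,
                    n_snps = n_snps, pi_A = piA, pi_B = piB,
                    pi_ratio = pi_ratio(piA, piB), fst = fst)
  names(out)[names(out) == "pi_A"] <- paste0("pi_", gA)
  names(out)[names(out) == "pi_B"] <- paste0("pi_", gB)
  out
}

#' Outlier thresholds for scan statistics
#'
#' @param fst_quantile upper quantile for the one-sided Fst scan.
#' @param pi_ratio_quantiles lower/upper quantiles for the two-sided Pi-ratio
#'   scan.
#' @return An object of class `outlier_config`.
#' @export
outlier_config <- function(fst_quantile = 0.95,
                           pi_ratio_quantiles = c(0.025, 0.975)) {
  stopifnot(fst_quantile > 0, fst_quantile < 1,
            length(pi_ratio_quantiles) == 2L,
            all(pi_ratio_quantiles > 0), all(pi_ratio_quantiles < 1),
            pi_ratio_quantiles[1L] < pi_ratio_quantiles[2L])
  structure(list(fst_quantile = fst_quantile,
                 pi_ratio_quantiles = pi_ratio_quantiles),
            class = "outlier_config")
}

#' Flag outlier windows against empirical quantile thresholds
#'
#' Thresholds are empirical quantiles of the defined values (sorted-order
#' linear interpolation, the type-7 convention). Flagging is strict: a window
#' exactly at the threshold is not an outlier; undefined values are never
#' flagged. With two-sided scanning the labels carry the direction
#' (`high`/`low`); one-sided scans label flagged windows `high`.
#'
#' @param values numeric per-window statistic, `NA` allowed.
#' @param probs quantile(s): one value for a one-sided upper scan, two values
#'   `(lower, upper)` for a two-sided scan.
#' @param min_defined minimum number of defined values required; below it a
#'   warning is issued and nothing is flagged.
#' @return list with `thresholds` (named numeric) and `direction` (character
#'   vector along `values`: `"high"`, `"low"` or `NA`).
#' @export
call_outliers <- function(values, probs = 0.95, min_defined = 20L) {
  stopifnot(length(probs) %in% 1:2, all(probs > 0), all(probs < 1))
  direction <- rep(NA_character_, length(values))
  ok <- !is.na(values)
  if (sum(ok) < min_defined) {
    warning(sprintf("only %d defined values (< %d); no outliers called",
                    sum(ok), min_defined))
    return(list(thresholds = stats::setNames(rep(NA_real_, length(probs)),
                                             paste0("q", probs)),
                direction = direction))
  }
  thr <- stats::quantile(values[ok], probs = sort(probs), type = 7,
                         names = FALSE)
  if (length(probs) == 1L) {
    thresholds <- c(upper = thr)
    direction[ok & values > thr] <- "high"
  } else {
    thresholds <- c(lower = thr[1L], upper = thr[2L])
    direction[ok & values < thr[1L]] <- "low"
    direction[ok & values > thr[2L]] <- "high"
  }
  list(thresholds = thresholds, direction = direction)
}

#' Write window statistics as BED-like TSV
#'
#' @param windows data.frame from [scan_windows()], optionally with a
#'   `flags` column.
#' @param path output TSV path.
#' @param thresholds optional named list written to `<path>.thresholds.json`.
#' @return `path`, invisibly.
#' @export
write_window_stats <- function(windows, path, thresholds = NULL) {
  utils::write.table(windows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(thresholds)) {
    jsonlite::write_json(thresholds, paste0(path, ".thresholds.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}
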