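#' Mean, SEM and sample size of a trait vector
#'
#' SEM is the sample standard deviation (n-1 denominator) over the square
#' root of n; with a single observation the SEM is undefined and an error is
#' raised rather than reporting 0.
#'
#' @param values numeric vector, `NA` dropped.
#' @return list with `mean`, `sem`, `n`.
#' @export
summarize_trait <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 1L) stop("no values")
  if (n == 1L) stop("SEM undefined for a single value")
  list(mean = mean(values), sem = stats::sd(values) / sqrt(n), n = n)
}

#' Significance stars for a p-value
#'
#' The conventional coding: `***` p < 0.001, `**` p < 0.01, `*` p < 0.05,
#' otherwise `n.s.`. Inequalities are strict, so a p exactly at a boundary
#' takes the less significant label.
#'
#' @param p p-value in [0, 1].
#' @return one of `"***"`, `"**"`, `"*"`, `"n.s."`.
#' @export
p_stars <- function(p) {
  stopifnot(p >= 0, p <= 1)
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else "n.s."
}

#' Two-group trait comparison (Student's t)
#'
#' Pooled-variance two-tailed Student's t-test with `n_A + n_B - 2` degrees
#' of freedom, group summaries as mean +/- SEM, and significance stars.
#' `welch = TRUE` switches to the unequal-variance Welch test. Degenerate
#' zero-pooled-variance input follows the convention p = 1 for equal means
#' and p = 0 (with a message) for unequal means.
#'
#' @param values_a,values_b numeric vectors, each with >= 2 values.
#' @param trait_name optional label carried into the result.
#' @param welch use the Welch-Satterthwaite test instead of pooled variance.
#' @return data.frame row: trait, per-group mean/sem/n, `t`, `df`,
#'   `p_value`, `stars`.
#' @export
compare_groups <- function(values_a, values_b, trait_name = "trait",
                           welch = FALSE) {
  sa <- summarize_trait(values_a)
  sb <- summarize_trait(values_b)
  na <- sa$n; nb <- sb$n
  va <- stats::var(values_a[!is.na(values_a)])
  vb <- stats::var(values_b[!is.na(values_b)])
  if (welch) {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  } else {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  }
  if (is.na(se) || se == 0) {
    if (sa$mean == sb$mean) {
      t <- 0; p <- 1
    } else {
      message("compare_groups: zero variance with unequal means; p set to 0")
      t <- ifelse(sa$mean < sb$mean, -Inf, Inf); p <- 0
    }
    df <- na + nb - 2
  } else {
    t <- (sa$mean - sb$mean) / se
    p <- 2 * stats::pt(-abs(t), df)
  }
  data.frame(trait = trait_name,
             mean_A = sa$mean, sem_A = sa$sem, n_A = na,
             mean_B = sb$mean, sem_B = sb$sem, n_B = nb,
             t = t, df = df, p_value = p, stars = p_stars(p),
             stringsAsFactors = FALSE)
}

#' Uniformity class of a synchronised-behaviour percentage
#'
#' Production-trait convention for hatching / molting synchrony: more than
#' 90% of individuals showing the same behaviour is "uniform", 80 to 90%
#' (inclusive) "relatively uniform", below 80% "non-uniform".
#'
#' @param percent value in [0, 100].
#' @return one of `"uniform"`, `"relatively uniform"`, `"non-uniform"`.
#' @export
classify_uniformity <- function(percent) {
  stopifnot(length(percent) == 1L)
  if (is.na(percent) || percent < 0 || percent > 100) {
    stop("percent must be in [0, 100]")
  }
  if (percent > 90) "uniform"
  else if (percent >= 80) "relatively uniform"
  else "non-uniform"
}

#' Read a long-format trait table
#'
#' TSV with header `strain_id  group  trait  value`.
#' @param path TSV path.
#' @return data.frame with those columns, `value` numeric where possible.
#' @export
read_traits <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  names(df) <- c("strain_id", "group", "trait", "value")[seq_len(ncol(df))]
  df
}

#' Compare every numeric trait between two groups
#'
#' @param traits long-format data.frame from [read_traits()].
#' @param group_pair two group labels; group A is the first.
#' @param welch see [compare_groups()].
#' @return data.frame with one [compare_groups()] row per trait.
#' @export
compare_traits <- function(traits, group_pair, welch = FALSE) {
  stopifnot(length(group_pair) == 2L,
            all(group_pair %in% traits$group))
  out <- lapply(sort(unique(traits$trait)), function(tr) {
    a <- traits$value[traits$trait == tr & traits$group == group_pair[1L]]
    b <- traits$value[traits$trait == tr & traits$group == group_pair[2L]]
    compare_groups(as.numeric(a), as.numeric(b), trait_name = tr,
                   welch = welch)
  })
  res <- do.call(rbind, out)
  names(res) <- sub("_A$", paste0("_", group_pair[1L]), names(res))
  names(res) <- sub("_B$", paste0("_", group_pair[2L]), names(res))
  res
}
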