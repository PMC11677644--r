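#' One-sided hypergeometric over-representation p-value
#'
#' Probability of drawing at least `k` genes carrying a term when `n` genes
#' are sampled without replacement from a universe of `N` genes of which `K`
#' carry the term: `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`. Computed by
#' exact summation of the probability mass in log space, which is stable for
#' the small counts typical of enrichment tables.
#'
#' @param k foreground genes carrying the term (0 <= k <= min(n, K)).
#' @param n foreground size.
#' @param K background genes carrying the term.
#' @param N background size.
#' @return p-value in [0, 1].
#' @export
hypergeom_pvalue <- function(k, n, K, N) {
  stopifnot(length(k) == 1L, length(n) == 1L, length(K) == 1L, length(N) == 1L)
  if (k < 0 || n < 0 || K < 0 || N < 0 || k > min(n, K) || K > N || n > N) {
    stop("hypergeometric bounds violated: need 0 <= k <= min(n, K), K <= N, n <= N")
  }
  if (k == 0) return(1)
  # support of X is max(0, n + K - N) .. min(n, K)
  xs <- k:min(n, K)
  logp <- lchoose(K, xs) + lchoose(N - K, n - xs) - lchoose(N, n)
  m <- max(logp)
  p <- exp(m + log(sum(exp(logp - m))))
  min(p, 1)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Standard step-up procedure with monotonicity enforcement; the returned
#' q-values are aligned with the input order.
#'
#' @param p numeric p-values in [0, 1].
#' @return q-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}

#' Read a gene-to-GO annotation map
#'
#' TSV with columns `gene_id`, `go_id` and optionally `description`; one row
#' per (gene, term) pair. Gzip transparent.
#'
#' @param path TSV path.
#' @return data.frame with `gene_id`, `go_id`, `description`.
#' @export
read_go_map <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE, quote = "",
                          stringsAsFactors = FALSE, fill = TRUE)
  if (ncol(df) < 2L) stop("gene->GO map needs at least 2 tab-separated columns")
  if (ncol(df) == 2L) df$V3 <- ""
  df <- df[, 1:3]
  names(df) <- c("gene_id", "go_id", "description")
  if (nrow(df) && tolower(df$gene_id[1L]) %in% c("gene", "gene_id")) {
    df <- df[-1L, , drop = FALSE]
  }
  rownames(df) <- NULL
  df
}

#' GO-term enrichment of a differentiation-gene list
#'
#' One-sided hypergeometric over-representation of every GO term annotated to
#' at least one foreground gene, against the universe of all GO-annotated
#' genes in the map (genes without any term are dropped from both sets before
#' counting, so the foreground size `n` counts annotated genes only).
#' Q-values are Benjamini-Hochberg. Terms are tested exactly as annotated —
#' no ontology ancestor propagation.
#'
#' @param foreground character vector of gene ids (must be a subset of the
#'   background after annotation filtering).
#' @param go_map data.frame from [read_go_map()].
#' @param background optional character vector of universe gene ids; defaults
#'   to all genes in `go_map`.
#' @return data.frame sorted by p: `go_id`, `description`, `k`, `n`, `K`,
#'   `N`, `gene_ratio` (rendered `"k/n"`), `p_value`, `q_value`.
#' @export
enrich <- function(foreground, go_map, background = NULL) {
  if (is.null(background)) background <- unique(go_map$gene_id)
  go_map <- go_map[go_map$gene_id %in% background, , drop = FALSE]
  annotated <- unique(go_map$gene_id)
  fg <- sort(unique(intersect(foreground, annotated)))
  extra <- setdiff(foreground, background)
  if (length(extra)) {
    stop("foreground gene(s) not in background: ",
         paste(utils::head(extra, 5L), collapse = ", "))
  }
  if (length(fg) == 0L) stop("no GO-annotated foreground gene")
  n <- length(fg)
  N <- length(annotated)
  fmap <- go_map[go_map$gene_id %in% fg, , drop = FALSE]
  terms <- sort(unique(fmap$go_id))
  k <- vapply(terms, function(t) length(unique(fmap$gene_id[fmap$go_id == t])), 0L)
  K <- vapply(terms, function(t)
    length(unique(go_map$gene_id[go_map$go_id == t])), 0L)
  desc <- go_map$description[match(terms, go_map$go_id)]
  p <- mapply(hypergeom_pvalue, k = k, n = n, K = K, N = N)
  out <- data.frame(go_id = terms, description = desc, k = k, n = n,
                    K = K, N = N,
                    gene_ratio = paste0(k, "/", n),
                    p_value = p, q_value = bh_adjust(p),
                    row.names = NULL)
  out[order(out$p_value, out$go_id), , drop = FALSE]
}

#' Write an enrichment table mirroring the classic GO cluster layout
#'
#' Columns: GO ID, Description, Gene Ratio, p Value, Q Value.
#' @param rows data.frame from [enrich()].
#' @param path output TSV path.
#' @param top keep the first `top` rows (a view of the ranked table, not a
#'   significance filter); `Inf` writes all.
#' @return `path`, invisibly.
#' @export
write_enrichment <- function(rows, path, top = Inf) {
  rows <- utils::head(rows, top)
  out <- data.frame(`GO ID` = rows$go_id, Description = rows$description,
                    `Gene Ratio` = rows$gene_ratio, `p Value` = rows$p_value,
                    `Q Value` = rows$q_value, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
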