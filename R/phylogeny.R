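#' Dosage distance between two samples
#'
#' Mean over co-called sites of `|dosage_i - dosage_j| / 2`: 0 for identical
#' genotypes, 1 for opposite homozygotes everywhere. Sites where either
#' sample is missing are excluded; having no co-called site at all is an
#' error.
#'
#' @param gm a [genotype_matrix()].
#' @param pair two sample ids (or row indices).
#' @return distance in [0, 1].
#' @export
dosage_distance <- function(gm, pair) {
  stopifnot(length(pair) == 2L)
  a <- gm$dosages[pair[1L], ]
  b <- gm$dosages[pair[2L], ]
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) stop("no co-called site for pair")
  mean(abs(a[ok] - b[ok])) / 2
}

#' All-pairs dosage distance matrix
#'
#' @param gm a [genotype_matrix()].
#' @param by optional named character vector (sample -> strain/group label);
#'   when given, per-label mean dosages are computed first and distances are
#'   between labels (the strain-mean genotype distance used for trees of
#'   strains rather than individuals).
#' @return symmetric numeric matrix with zero diagonal, labelled.
#' @export
dosage_dist <- function(gm, by = NULL) {
  if (is.null(by)) {
    m <- gm$dosages
  } else {
    stopifnot(!is.null(names(by)), all(names(by) %in% gm$sample_ids))
    labs <- unique(unname(by))
    m <- t(vapply(labs, function(l) {
      colMeans(gm$dosages[names(by)[by == l], , drop = FALSE], na.rm = TRUE)
    }, numeric(ncol(gm$dosages))))
    rownames(m) <- labs
  }
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      a <- m[i, ]; b <- m[j, ]
      ok <- !is.na(a) & !is.na(b)
      if (!any(ok)) stop("no co-called site for pair ",
                         rownames(m)[i], ", ", rownames(m)[j])
      d[i, j] <- d[j, i] <- mean(abs(a[ok] - b[ok])) / 2
    }
  }
  d
}

# Quote a label for Newick if it contains whitespace or reserved characters.
newick_label <- function(x) {
  needs <- grepl("[][ \t(),:;']", x)
  x[needs] <- paste0("'", gsub("'", "''", x[needs]), "'")
  x
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classic Saitou-Nei agglomeration on the Q criterion. Ties in Q are broken
#' deterministically by the lexicographically smallest pair of cluster
#' labels (a cluster is labelled by its smallest member leaf). Negative
#' branch lengths arising from non-additive input are clamped to zero with
#' the deficit moved to the sibling branch, preserving the pair's summed
#' length. The result is unrooted, stored with the conventional trifurcating
#' root.
#'
#' @param d symmetric distance matrix with labelled rows/columns, >= 3 taxa.
#' @return an [ape::ape-package] `phylo` tree.
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 3L) stop("neighbor-joining needs >= 3 taxa")
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("t", seq_len(n))
  stopifnot(isSymmetric(unname(d)), all(diag(d) == 0))
  labs <- rownames(d)
  frag <- newick_label(labs)   # newick fragment per active cluster
  rep_lab <- labs              # deterministic tie-break key
  active <- seq_len(n)

  clamp_pair <- function(la, lb) {
    if (la < 0) { lb <- lb + la; la <- 0 }
    if (lb < 0) { la <- la + lb; lb <- 0 }
    c(max(la, 0), max(lb, 0))
  }

  while (length(active) > 3L) {
    m <- length(active)
    dm <- d[active, active, drop = FALSE]
    r <- rowSums(dm)
    q <- (m - 2) * dm - outer(r, r, `+`)
    diag(q) <- Inf
    best <- which(q == min(q), arr.ind = TRUE)
    best <- best[best[, 1] < best[, 2], , drop = FALSE]
    if (nrow(best) > 1L) {
      key <- apply(best, 1L, function(ij) {
        pr <- sort(c(rep_lab[active[ij[1]]], rep_lab[active[ij[2]]]))
        paste(pr, collapse = "\r")
      })
      best <- best[order(key)[1L], , drop = FALSE]
    }
    i <- best[1, 1]; j <- best[1, 2]
    a <- active[i]; b <- active[j]
    la <- d[a, b] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lb <- d[a, b] - la
    ll <- clamp_pair(la, lb)
    # distances from the new node to every other active cluster
    others <- active[-c(i, j)]
    dnew <- (d[a, others] + d[b, others] - d[a, b]) / 2
    d <- rbind(cbind(d, 0), 0)
    u <- nrow(d)
    d[u, others] <- d[others, u] <- pmax(dnew, 0)
    frag <- c(frag, sprintf("(%s:%.10g,%s:%.10g)", frag[a], ll[1], frag[b], ll[2]))
    rep_lab <- c(rep_lab, min(rep_lab[a], rep_lab[b]))
    active <- c(others, u)
  }

  a <- active[1]; b <- active[2]; c3 <- active[3]
  la <- (d[a, b] + d[a, c3] - d[b, c3]) / 2
  lb <- (d[a, b] + d[b, c3] - d[a, c3]) / 2
  lc <- (d[a, c3] + d[b, c3] - d[a, b]) / 2
  len <- pmax(c(la, lb, lc), 0)
  o <- order(rep_lab[active])
  parts <- sprintf("%s:%.10g", frag[active][o], len[o])
  txt <- paste0("(", paste(parts, collapse = ","), ");")
  ape::read.tree(text = txt)
}

# Serialise one phylo node recursively.
phylo_newick_node <- function(tree, node, digits) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(newick_label(tree$tip.label[node]))
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  parts <- vapply(kids, function(k) {
    e <- which(tree$edge[, 2] == k)
    len <- if (!is.null(tree$edge.length)) tree$edge.length[e] else NA_real_
    sub <- phylo_newick_node(tree, k, digits)
    if (is.na(len)) sub else paste0(sub, ":", format(len, digits = digits))
  }, character(1))
  paste0("(", paste(parts, collapse = ","), ")")
}

#' Write a tree in Newick format
#'
#' Emits branch lengths and terminates with `;`. Labels containing spaces or
#' Newick-reserved characters are single-quoted, so round-tripping through a
#' standard parser restores them.
#'
#' @param tree a `phylo` object (e.g. from [nj_tree()]).
#' @param path output file; `NULL` returns the string instead.
#' @param digits significant digits for branch lengths.
#' @return the Newick string, invisibly when written to a file.
#' @export
write_newick <- function(tree, path = NULL, digits = 10) {
  stopifnot(inherits(tree, "phylo"))
  root <- length(tree$tip.label) + 1L
  txt <- paste0(phylo_newick_node(tree, root, digits), ";")
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Does a set of tips form a split of an unrooted tree?
#'
#' True iff some edge of the tree separates exactly `tips` from the
#' remaining leaves — the topological statement behind "group X is placed
#' between / outside" claims.
#'
#' @param tree a `phylo` object.
#' @param tips character vector of tip labels.
#' @return logical.
#' @export
is_split <- function(tree, tips) {
  labs <- tree$tip.label
  stopifnot(all(tips %in% labs))
  target <- sort(match(tips, labs))
  ntip <- length(labs)
  below <- function(node) {
    if (node <= ntip) return(node)
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    sort(unlist(lapply(kids, below)))
  }
  for (node in tree$edge[, 2]) {
    s <- below(node)
    if (identical(s, target) ||
        identical(sort(setdiff(seq_len(ntip), s)), target)) {
      return(TRUE)
    }
  }
  FALSE
}
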