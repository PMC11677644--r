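#' Merge flagged windows into selection regions
#'
#' Overlapping or bookended (end == next start) windows on the same
#' chromosome are merged into maximal regions; with 50%-overlap sliding
#' windows, adjacency is biologically continuous. All windows passed in must
#' carry the same direction label — mixing directions in one call is an
#' error, merge each tail separately.
#'
#' @param windows data.frame with `chrom`, `start`, `end` (0-based half-open)
#'   and optionally `direction` (single unique value).
#' @param direction direction label for the output regions; defaults to the
#'   windows' `direction` column.
#' @return data.frame of regions: `chrom`, `start`, `end`, `direction`,
#'   `n_windows`.
#' @export
merge_windows <- function(windows, direction = NULL) {
  if (is.null(direction)) {
    if (!"direction" %in% names(windows)) {
      stop("no direction column and no direction argument")
    }
    direction <- unique(windows$direction)
  }
  if (length(unique(direction)) != 1L) {
    stop("merge_windows takes windows of a single direction; ",
         "merge each direction separately")
  }
  direction <- as.character(direction[1L])
  if (nrow(windows) == 0L) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), direction = character(),
                      n_windows = integer()))
  }
  gr <- GenomicRanges::GRanges(
    windows$chrom,
    IRanges::IRanges(start = windows$start + 1, end = windows$end))
  red <- GenomicRanges::reduce(gr, min.gapwidth = 1L)  # merges bookended
  hits <- GenomicRanges::countOverlaps(red, gr)
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(red)),
                    start = GenomicRanges::start(red) - 1,
                    end = as.numeric(GenomicRanges::end(red)),
                    direction = direction, n_windows = hits)
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Read gene models from GFF3
#'
#' Keeps `gene` features only and converts the 1-based inclusive GFF
#' convention to the package's 0-based half-open intervals. The gene
#' identifier is taken from the `ID=` attribute (falling back to `gene_id=`
#' or `Name=`).
#'
#' @param path GFF3 file.
#' @return data.frame of gene models: `gene_id`, `chrom`, `start`, `end`.
#' @export
read_gff <- function(path) {
  gff <- ape::read.gff(path, na.strings = c(".", "?"), GFF3 = TRUE)
  gff <- gff[gff$type == "gene", , drop = FALSE]
  if (nrow(gff) == 0L) {
    return(data.frame(gene_id = character(), chrom = character(),
                      start = numeric(), end = numeric()))
  }
  extract_attr <- function(attr, key) {
    pat <- paste0("(^|;\\s*)", key, "=([^;]+)")
    has <- grepl(pat, attr)
    out <- rep(NA_character_, length(attr))
    out[has] <- sub(paste0(".*", pat, ".*"), "\\2", attr[has])
    out
  }
  ids <- extract_attr(gff$attributes, "ID")
  for (key in c("gene_id", "Name")) {
    miss <- is.na(ids)
    if (!any(miss)) break
    ids[miss] <- extract_attr(gff$attributes[miss], key)
  }
  ids[is.na(ids)] <- paste0("gene", which(is.na(ids)))
  out <- data.frame(gene_id = ids, chrom = as.character(gff$seqid),
                    start = gff$start - 1, end = as.numeric(gff$end))
  if (any(out$start >= out$end)) stop("malformed gene interval in GFF")
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Attach genes to selection regions
#'
#' A gene belongs to a region iff their intervals overlap by at least 1 bp on
#' the same chromosome (partial overlap counts, bedtools-style). Also returns
#' the deduplicated, sorted flat list of all genes hit by any region — the
#' differentiation-gene list fed to enrichment.
#'
#' @param regions data.frame from [merge_windows()].
#' @param genes data.frame from [read_gff()].
#' @return list with `regions` (input plus a `genes` list-column of gene ids)
#'   and `gene_list` (sorted unique character vector).
#' @export
genes_in_regions <- function(regions, genes) {
  if (nrow(regions) == 0L || nrow(genes) == 0L) {
    regions$genes <- rep(list(character()), nrow(regions))
    return(list(regions = regions, gene_list = character()))
  }
  rg <- GenomicRanges::GRanges(regions$chrom,
                               IRanges::IRanges(regions$start + 1, regions$end))
  gg <- GenomicRanges::GRanges(genes$chrom,
                               IRanges::IRanges(genes$start + 1, genes$end))
  hits <- GenomicRanges::findOverlaps(rg, gg, minoverlap = 1L)
  byregion <- split(genes$gene_id[S4Vectors::subjectHits(hits)],
                    factor(S4Vectors::queryHits(hits), levels = seq_len(nrow(regions))))
  regions$genes <- lapply(byregion, function(g) sort(unique(g)))
  list(regions = regions,
       gene_list = sort(unique(genes$gene_id[S4Vectors::subjectHits(hits)])))
}

#' Write selection regions as BED
#'
#' BED columns: chrom, start, end, name (direction), score (member window
#' count).
#' @param regions data.frame from [merge_windows()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  bed <- data.frame(regions$chrom, format(regions$start, scientific = FALSE, trim = TRUE),
                    format(regions$end, scientific = FALSE, trim = TRUE),
                    regions$direction, regions$n_windows)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
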