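#' Default pipeline configuration
#'
#' @param vcf,populations input paths (required at run time).
#' @param gff,go_map,traits optional annotation and trait inputs; stages
#'   needing a missing input are skipped with a warning.
#' @param outdir output directory.
#' @param group_pair two group labels (Pi-ratio numerator first); defaults
#'   to the first two groups of the population file.
#' @param window a [window_spec()].
#' @param outliers an [outlier_config()].
#' @param estimator Fst estimator, see [window_fst()].
#' @param unbiased small-sample Pi correction, see [window_pi()].
#' @param seed integer recorded in the manifest (the scan itself is
#'   deterministic; the seed matters when the config is fed to the
#'   simulator first).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(vcf, populations, gff = NULL, go_map = NULL,
                            traits = NULL, outdir = "silkscan_out",
                            group_pair = NULL, window = window_spec(),
                            outliers = outlier_config(),
                            estimator = "nei", unbiased = FALSE,
                            seed = 1L) {
  structure(list(vcf = vcf, populations = populations, gff = gff,
                 go_map = go_map, traits = traits, outdir = outdir,
                 group_pair = group_pair, window = window,
                 outliers = outliers, estimator = estimator,
                 unbiased = unbiased, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Top-level keys mirror the [pipeline_config()] arguments; `window` and
#' `outliers` are nested mappings (`window_size`/`step_size`/`min_snps`,
#' `fst_quantile`/`pi_ratio_quantiles`).
#'
#' @param path YAML file.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  w <- do.call(window_spec, as.list(y$window %||% list()))
  o <- if (!is.null(y$outliers)) {
    outlier_config(fst_quantile = y$outliers$fst_quantile %||% 0.95,
                   pi_ratio_quantiles =
                     unlist(y$outliers$pi_ratio_quantiles %||% c(0.025, 0.975)))
  } else outlier_config()
  pipeline_config(vcf = y$vcf, populations = y$populations, gff = y$gff,
                  go_map = y$go_map, traits = y$traits,
                  outdir = y$outdir %||% "silkscan_out",
                  group_pair = unlist(y$group_pair),
                  window = w, outliers = o,
                  estimator = y$estimator %||% "nei",
                  unbiased = isTRUE(y$unbiased), seed = y$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stage_msg <- function(stage, ...) {
  message(sprintf("[silkscan:%s] %s", stage, sprintf(...)))
}

stage_try <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full selection-scan pipeline
#'
#' Stages, in order: genotype input, windowed Pi/Pi-ratio/Fst scan, outlier
#' calling, region merging, gene annotation, GO enrichment, neighbor-joining
#' tree, trait comparison. Every output is written under `cfg$outdir`
#' together with a manifest (config hash, seed, package version); a rerun
#' with the same inputs and config is byte-identical apart from the manifest
#' timestamp. Differentiation genes (the enrichment foreground) are the
#' genes in high-Fst regions.
#'
#' @param cfg a [pipeline_config()] or path to its YAML form.
#' @return invisible list: `windows`, `thresholds`, `regions`, `gene_list`,
#'   `enrichment`, `tree`, `trait_comparisons`, `paths`.
#' @export
run_scan <- function(cfg) {
  if (is.character(cfg)) cfg <- read_pipeline_config(cfg)
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)

  gm <- stage_try("genotype_io", read_vcf(cfg$vcf))
  pops <- stage_try("genotype_io", read_populations(cfg$populations))
  pair <- cfg$group_pair %||% pops$groups[1:2]
  stage_msg("genotype_io", "%d samples, %d sites; groups %s vs %s",
            length(gm$sample_ids), nrow(gm$sites), pair[1], pair[2])

  win <- stage_try("windowed_stats",
                   scan_windows(gm, pops, pair, spec = cfg$window,
                                estimator = cfg$estimator,
                                unbiased = cfg$unbiased))
  fst_out <- stage_try("windowed_stats",
                       call_outliers(win$fst, cfg$outliers$fst_quantile))
  ratio_out <- stage_try("windowed_stats",
                         call_outliers(win$pi_ratio,
                                       cfg$outliers$pi_ratio_quantiles))
  win$fst_flag <- fst_out$direction
  win$pi_ratio_flag <- ratio_out$direction
  thresholds <- list(fst = as.list(fst_out$thresholds),
                     pi_ratio = as.list(ratio_out$thresholds))
  paths <- list(windows = file.path(cfg$outdir, "window_stats.tsv"))
  write_window_stats(win, paths$windows, thresholds)
  stage_msg("windowed_stats", "%d windows; %d fst outliers, %d ratio outliers",
            nrow(win), sum(!is.na(win$fst_flag)),
            sum(!is.na(win$pi_ratio_flag)))

  regions <- stage_try("region_annotation", {
    parts <- list(
      merge_windows(win[!is.na(win$fst_flag) & win$fst_flag == "high", ],
                    direction = "high_fst"),
      merge_windows(win[!is.na(win$pi_ratio_flag) & win$pi_ratio_flag == "high", ],
                    direction = "high_pi_ratio"),
      merge_windows(win[!is.na(win$pi_ratio_flag) & win$pi_ratio_flag == "low", ],
                    direction = "low_pi_ratio"))
    do.call(rbind, parts)
  })
  paths$regions <- file.path(cfg$outdir, "regions.bed")
  write_regions_bed(regions, paths$regions)

  gene_list <- character()
  enr <- NULL
  if (!is.null(cfg$gff)) {
    genes <- stage_try("region_annotation", read_gff(cfg$gff))
    fst_regions <- regions[regions$direction == "high_fst", , drop = FALSE]
    gir <- stage_try("region_annotation", genes_in_regions(fst_regions, genes))
    gene_list <- gir$gene_list
    paths$gene_list <- file.path(cfg$outdir, "differentiation_genes.tsv")
    writeLines(gene_list, paths$gene_list)
    stage_msg("region_annotation", "%d regions, %d differentiation genes",
              nrow(regions), length(gene_list))
    if (!is.null(cfg$go_map) && length(gene_list)) {
      go_map <- stage_try("go_enrichment", read_go_map(cfg$go_map))
      enr <- stage_try("go_enrichment", enrich(gene_list, go_map))
      paths$enrichment <- file.path(cfg$outdir, "go_enrichment.tsv")
      write_enrichment(enr, paths$enrichment)
      stage_msg("go_enrichment", "%d terms tested; top: %s (p=%.3g)",
                nrow(enr), enr$go_id[1], enr$p_value[1])
    } else if (is.null(cfg$go_map)) {
      warning("no GO map supplied; enrichment skipped")
    }
  } else {
    warning("no GFF supplied; region annotation and enrichment skipped")
  }

  tree <- stage_try("phylogeny", nj_tree(dosage_dist(gm)))
  paths$tree <- file.path(cfg$outdir, "nj_tree.nwk")
  write_newick(tree, paths$tree)

  cmp <- NULL
  if (!is.null(cfg$traits)) {
    tt <- stage_try("trait_stats", read_traits(cfg$traits))
    tpair <- if (all(pair %in% tt$group)) pair else unique(tt$group)[1:2]
    cmp <- stage_try("trait_stats", compare_traits(tt, tpair))
    paths$trait_comparisons <- file.path(cfg$outdir, "trait_comparisons.tsv")
    utils::write.table(cmp, paths$trait_comparisons, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  } else {
    warning("no trait table supplied; trait comparison skipped")
  }

  cfg_json <- file.path(cfg$outdir, "config.json")
  cfg_plain <- cfg
  cfg_plain$window <- unclass(cfg$window)
  cfg_plain$outliers <- unclass(cfg$outliers)
  jsonlite::write_json(unclass(cfg_plain), cfg_json, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  manifest <- list(config_md5 = unname(tools::md5sum(cfg_json)),
                   seed = cfg$seed,
                   package = "silkscan",
                   version = as.character(utils::packageVersion("silkscan")),
                   r_version = R.version.string,
                   timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(windows = win, thresholds = thresholds, regions = regions,
                 gene_list = gene_list, enrichment = enr, tree = tree,
                 trait_comparisons = cmp, paths = paths))
}

#' Manhattan-style plot of a windowed statistic
#'
#' @param windows data.frame from [scan_windows()].
#' @param stat column to plot (`"fst"` or `"pi_ratio"`).
#' @param threshold optional horizontal threshold line(s).
#' @param path optional PNG path; plots to the active device when `NULL`.
#' @return invisible `NULL`.
#' @export
plot_scan <- function(windows, stat = "fst", threshold = NULL, path = NULL) {
  stopifnot(stat %in% names(windows))
  if (!is.null(path)) {
    grDevices::png(path, width = 1200, height = 400)
    on.exit(grDevices::dev.off())
  }
  chroms <- unique(windows$chrom)
  offsets <- stats::setNames(c(0, cumsum(tapply(windows$end, windows$chrom,
                                                max))[-length(chroms)]), chroms)
  x <- (windows$start + windows$end) / 2 + offsets[windows$chrom]
  col <- (match(windows$chrom, chroms) %% 2L) + 1L
  graphics::plot(x, windows[[stat]], pch = 20, cex = 0.5,
                 col = c("grey30", "steelblue")[col],
                 xlab = "genome position (bp, concatenated)", ylab = stat)
  if (!is.null(threshold)) {
    graphics::abline(h = threshold, col = "red", lty = 2)
  }
  invisible(NULL)
}
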