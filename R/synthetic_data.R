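#' Simulation configuration
#'
#' Ground-truth generator settings for a two- (optionally three-) population
#' diploid SNP panel under the Balding-Nichols model: per-site ancestral
#' frequencies are uniform on `ancestral_freq_range`, and each population's
#' frequency is Beta-distributed around the ancestral value with variance
#' `F * p * (1 - p)`, so `F` is the expected differentiation. Windows listed
#' in `selected_windows` use their own elevated `F_high` — the planted
#' "selective sweep" signal the scan is expected to recover.
#'
#' @param seed integer seed (mandatory); every downstream draw derives from
#'   it, so identical configs give bit-identical outputs.
#' @param n_pops number of populations (2 or 3).
#' @param diploids_per_pop diploid individuals per population.
#' @param chromosome_lengths named vector of chromosome lengths (bp).
#' @param n_snps total SNP count, split across chromosomes by length.
#' @param F_background genome-wide differentiation parameter in (0, 1).
#' @param selected_windows optional data.frame `chrom`, `start`, `end`,
#'   `F_high` (0-based half-open) of elevated-differentiation windows.
#' @param ancestral_freq_range ancestral allele-frequency bounds.
#' @param missing_rate per-call missingness probability in [0, 1).
#' @param mixture optional list `(pop, parents, weight)`: population `pop`'s
#'   frequencies are `weight * p_parents[1] + (1 - weight) * p_parents[2]`
#'   instead of an independent Balding-Nichols draw — an admixed/intermediate
#'   population for phylogeny placement checks.
#' @param pop_labels population labels; default `pop1`, `pop2`, ...
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed, n_pops = 2L, diploids_per_pop = 30L,
                       chromosome_lengths = c(chr1 = 10e6),
                       n_snps = 20000L, F_background = 0.10,
                       selected_windows = NULL,
                       ancestral_freq_range = c(0.05, 0.95),
                       missing_rate = 0.02, mixture = NULL,
                       pop_labels = NULL) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(F_background > 0, F_background < 1,
            n_pops >= 2L, diploids_per_pop >= 1L, n_snps >= 1L,
            all(chromosome_lengths > 0), !is.null(names(chromosome_lengths)),
            length(ancestral_freq_range) == 2L,
            ancestral_freq_range[1] > 0, ancestral_freq_range[2] < 1,
            ancestral_freq_range[1] < ancestral_freq_range[2],
            missing_rate >= 0, missing_rate < 1)
  if (!is.null(selected_windows)) {
    stopifnot(all(c("chrom", "start", "end", "F_high") %in%
                    names(selected_windows)),
              all(selected_windows$F_high > 0),
              all(selected_windows$F_high < 1),
              all(selected_windows$chrom %in% names(chromosome_lengths)),
              all(selected_windows$start >= 0),
              all(selected_windows$end <=
                    chromosome_lengths[selected_windows$chrom]))
  }
  if (!is.null(mixture)) {
    stopifnot(is.list(mixture), all(c("pop", "parents", "weight") %in%
                                      names(mixture)),
              length(mixture$parents) == 2L,
              mixture$pop %in% seq_len(n_pops),
              all(mixture$parents %in% seq_len(n_pops)),
              !(mixture$pop %in% mixture$parents),
              mixture$weight > 0, mixture$weight < 1)
  }
  if (is.null(pop_labels)) pop_labels <- paste0("pop", seq_len(n_pops))
  stopifnot(length(pop_labels) == n_pops)
  structure(list(seed = as.integer(seed), n_pops = as.integer(n_pops),
                 diploids_per_pop = as.integer(diploids_per_pop),
                 chromosome_lengths = chromosome_lengths,
                 n_snps = as.integer(n_snps), F_background = F_background,
                 selected_windows = selected_windows,
                 ancestral_freq_range = ancestral_freq_range,
                 missing_rate = missing_rate, mixture = mixture,
                 pop_labels = pop_labels),
            class = "sim_config")
}

# Deterministic sub-stream seeds so each stage is independently reproducible.
sub_seed <- function(cfg, offset) (cfg$seed + offset) %% 2147483587L

#' Simulate per-site ancestral and per-population allele frequencies
#'
#' Site positions are uniform without replacement within each chromosome
#' (counts proportional to length), sorted. Population frequencies are
#' Balding-Nichols Beta draws with the background `F`, or the window's
#' `F_high` inside selected windows; an `F <= 1e-6` degenerates to the
#' ancestral frequency exactly. A mixture population gets the weighted mean
#' of its parents' realised frequencies.
#'
#' @param cfg a [sim_config()].
#' @return list: `sites` (data.frame `chrom`, `pos0`), `p_anc` (ancestral
#'   frequencies), `p_pop` (populations x sites matrix), `site_F` (per-site
#'   differentiation used).
#' @export
simulate_frequencies <- function(cfg) {
  set.seed(sub_seed(cfg, 0L))
  lens <- cfg$chromosome_lengths
  n_per <- round(cfg$n_snps * lens / sum(lens))
  # rounding drift goes to the largest chromosome
  n_per[which.max(lens)] <- n_per[which.max(lens)] + cfg$n_snps - sum(n_per)
  sites <- do.call(rbind, lapply(names(lens), function(chr) {
    data.frame(chrom = chr,
               pos0 = sort(sample.int(lens[[chr]], n_per[[chr]])) - 1L)
  }))
  n <- nrow(sites)
  p <- stats::runif(n, cfg$ancestral_freq_range[1], cfg$ancestral_freq_range[2])
  site_F <- rep(cfg$F_background, n)
  if (!is.null(cfg$selected_windows)) {
    for (k in seq_len(nrow(cfg$selected_windows))) {
      w <- cfg$selected_windows[k, ]
      inw <- sites$chrom == w$chrom & sites$pos0 >= w$start & sites$pos0 < w$end
      site_F[inw] <- w$F_high
    }
  }
  bn_draw <- function(p, f) {
    out <- p
    live <- f > 1e-6
    out[live] <- stats::rbeta(sum(live),
                              p[live] * (1 - f[live]) / f[live],
                              (1 - p[live]) * (1 - f[live]) / f[live])
    out
  }
  p_pop <- matrix(NA_real_, nrow = cfg$n_pops, ncol = n,
                  dimnames = list(cfg$pop_labels, NULL))
  for (k in seq_len(cfg$n_pops)) p_pop[k, ] <- bn_draw(p, site_F)
  if (!is.null(cfg$mixture)) {
    mw <- cfg$mixture
    p_pop[mw$pop, ] <- mw$weight * p_pop[mw$parents[1], ] +
      (1 - mw$weight) * p_pop[mw$parents[2], ]
  }
  list(sites = sites, p_anc = p, p_pop = p_pop, site_F = site_F)
}

#' Simulate diploid genotypes from population frequencies
#'
#' Each individual's dosage is Binomial(2, p) with its population's site
#' frequency; calls are masked to missing independently at `missing_rate`.
#'
#' @param freqs output of [simulate_frequencies()].
#' @param cfg the same [sim_config()].
#' @return list: `gm` (a [genotype_matrix()]) and `pops`
#'   (a [population_set()]).
#' @export
simulate_genotypes <- function(freqs, cfg) {
  set.seed(sub_seed(cfg, 1L))
  n_sites <- nrow(freqs$sites)
  n_ind <- cfg$n_pops * cfg$diploids_per_pop
  ids <- unlist(lapply(seq_len(cfg$n_pops), function(k)
    sprintf("%s_s%02d", cfg$pop_labels[k], seq_len(cfg$diploids_per_pop))))
  assignment <- stats::setNames(rep(cfg$pop_labels,
                                    each = cfg$diploids_per_pop), ids)
  d <- matrix(NA_integer_, nrow = n_ind, ncol = n_sites)
  for (k in seq_len(cfg$n_pops)) {
    rows <- which(assignment == cfg$pop_labels[k])
    draws <- stats::rbinom(length(rows) * n_sites, 2L,
                           rep(freqs$p_pop[k, ], each = length(rows)))
    d[rows, ] <- matrix(draws, nrow = length(rows))
  }
  if (cfg$missing_rate > 0) {
    d[stats::runif(length(d)) < cfg$missing_rate] <- NA_integer_
  }
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_sites, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1))
  gm <- genotype_matrix(ids,
                        data.frame(chrom = freqs$sites$chrom,
                                   pos0 = freqs$sites$pos0,
                                   ref = ref, alt = unname(alt)),
                        d)
  list(gm = gm, pops = population_set(assignment, cfg$pop_labels))
}

# 1-based inclusive GFF3 emitter for gene models.
write_gff3 <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(genes)) {
    writeLines(paste(genes$chrom, "silkscan", "gene",
                     format(genes$start + 1, scientific = FALSE, trim = TRUE),
                     format(genes$end, scientific = FALSE, trim = TRUE),
                     ".", "+", ".", paste0("ID=", genes$gene_id),
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Simulate gene models and a gene-to-GO annotation with a planted signal
#'
#' Genes are non-overlapping intervals tiled uniformly across the
#' chromosomes (each gene occupies the middle 60% of its tile). Every gene
#' receives one to three background GO terms at random; genes overlapping a
#' selected window additionally receive the designated "selected-linked"
#' term with probability `p_linked_inside`, all other genes with
#' `p_linked_outside` — so the planted term is detectably enriched among
#' genes in outlier regions by construction.
#'
#' @param cfg a [sim_config()].
#' @param n_genes total genes (0 allowed).
#' @param n_terms number of background GO terms.
#' @param p_linked_inside,p_linked_outside planted-term probabilities.
#' @return list: `genes` (data.frame as [read_gff()]), `go_map` (data.frame
#'   as [read_go_map()]), `linked_term` (the planted GO id).
#' @export
simulate_annotation <- function(cfg, n_genes = 200L, n_terms = 20L,
                                p_linked_inside = 0.9,
                                p_linked_outside = 0.05) {
  set.seed(sub_seed(cfg, 2L))
  linked_term <- "GO:0000001"
  if (n_genes == 0L) {
    return(list(genes = data.frame(gene_id = character(), chrom = character(),
                                   start = numeric(), end = numeric()),
                go_map = data.frame(gene_id = character(), go_id = character(),
                                    description = character()),
                linked_term = linked_term))
  }
  lens <- cfg$chromosome_lengths
  n_per <- pmax(round(n_genes * lens / sum(lens)), 1L)
  n_per[which.max(lens)] <- n_per[which.max(lens)] + n_genes - sum(n_per)
  genes <- do.call(rbind, lapply(names(lens), function(chr) {
    ng <- n_per[[chr]]
    tile <- lens[[chr]] / ng
    start <- floor((seq_len(ng) - 1) * tile + 0.2 * tile)
    end <- floor((seq_len(ng) - 1) * tile + 0.8 * tile)
    data.frame(chrom = chr, start = start, end = end)
  }))
  genes$gene_id <- sprintf("g%04d", seq_len(nrow(genes)))
  genes <- genes[, c("gene_id", "chrom", "start", "end")]

  in_selected <- rep(FALSE, nrow(genes))
  if (!is.null(cfg$selected_windows)) {
    for (k in seq_len(nrow(cfg$selected_windows))) {
      w <- cfg$selected_windows[k, ]
      in_selected <- in_selected |
        (genes$chrom == w$chrom & genes$start < w$end & genes$end > w$start)
    }
  }
  bg_terms <- sprintf("GO:%07d", 1L + seq_len(n_terms))
  rows <- lapply(seq_len(nrow(genes)), function(i) {
    terms <- sample(bg_terms, sample(1:3, 1L))
    p_link <- if (in_selected[i]) p_linked_inside else p_linked_outside
    if (stats::runif(1) < p_link) terms <- c(linked_term, terms)
    data.frame(gene_id = genes$gene_id[i], go_id = terms)
  })
  go_map <- do.call(rbind, rows)
  go_map$description <- ifelse(go_map$go_id == linked_term,
                               "selected-linked process",
                               paste0("background process ",
                                      sub("GO:0*", "", go_map$go_id)))
  go_map <- go_map[order(go_map$gene_id, go_map$go_id), ]
  rownames(go_map) <- NULL
  list(genes = genes, go_map = go_map, linked_term = linked_term)
}

#' Simulate a long-format trait table with controlled group differences
#'
#' Normal draws per group around the specified means. The default trait
#' specifications mirror the headline germplasm contrasts between the two
#' study countries (egg number per moth 505 vs 631, normal-egg rate 98 vs
#' 96%, larval stage 21.4 vs 28 d, pupal stage 13.1 vs 16.7 d, incubation
#' 10.4 vs 10.2 d) with field-plausible standard deviations.
#'
#' @param cfg a [sim_config()]; the first two `pop_labels` name the groups.
#' @param trait_specs data.frame `name`, `mean_A`, `mean_B`, `sd`, `n`.
#' @return long-format data.frame `strain_id`, `group`, `trait`, `value`.
#' @export
simulate_traits <- function(cfg, trait_specs = default_trait_specs()) {
  set.seed(sub_seed(cfg, 3L))
  stopifnot(all(c("name", "mean_A", "mean_B", "sd", "n") %in%
                  names(trait_specs)),
            all(trait_specs$sd >= 0), all(trait_specs$n >= 2))
  groups <- cfg$pop_labels[1:2]
  out <- lapply(seq_len(nrow(trait_specs)), function(i) {
    sp <- trait_specs[i, ]
    rbind(
      data.frame(strain_id = sprintf("%s_t%02d", groups[1], seq_len(sp$n)),
                 group = groups[1], trait = sp$name,
                 value = stats::rnorm(sp$n, sp$mean_A, sp$sd)),
      data.frame(strain_id = sprintf("%s_t%02d", groups[2], seq_len(sp$n)),
                 group = groups[2], trait = sp$name,
                 value = stats::rnorm(sp$n, sp$mean_B, sp$sd)))
  })
  do.call(rbind, out)
}

#' Default trait specifications for the demo study
#' @return data.frame consumed by [simulate_traits()].
#' @export
default_trait_specs <- function() {
  data.frame(
    name = c("egg_number", "normal_egg_rate", "larval_stage_d",
             "pupal_stage_d", "incubation_d"),
    mean_A = c(505, 98, 21.4, 13.1, 10.4),
    mean_B = c(631, 96, 28.0, 16.7, 10.2),
    sd = c(60, 2, 1.5, 1.0, 0.5),
    n = c(15L, 15L, 15L, 15L, 15L))
}

#' Generate a complete synthetic study on disk
#'
#' Writes every input the pipeline consumes — VCF, population TSV, GFF3,
#' gene-to-GO TSV and trait TSV — into `dir`, deterministically from the
#' config seed.
#'
#' @param cfg a [sim_config()].
#' @param dir output directory (created if absent).
#' @param n_genes,n_terms see [simulate_annotation()].
#' @return named list of file paths plus the in-memory ground truth
#'   (`gm`, `pops`, `freqs`, `annotation`, `traits`).
#' @export
simulate_study <- function(cfg, dir, n_genes = 200L, n_terms = 20L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  freqs <- simulate_frequencies(cfg)
  geno <- simulate_genotypes(freqs, cfg)
  ann <- simulate_annotation(cfg, n_genes = n_genes, n_terms = n_terms)
  traits <- simulate_traits(cfg)
  paths <- list(vcf = file.path(dir, "genotypes.vcf"),
                populations = file.path(dir, "populations.tsv"),
                gff = file.path(dir, "genes.gff3"),
                go_map = file.path(dir, "gene2go.tsv"),
                traits = file.path(dir, "traits.tsv"))
  write_vcf(geno$gm, paths$vcf)
  utils::write.table(data.frame(sample_id = names(geno$pops$assignment),
                                group = unname(geno$pops$assignment)),
                     paths$populations, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  write_gff3(ann$genes, paths$gff)
  utils::write.table(ann$go_map, paths$go_map, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(traits, paths$traits, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  c(paths, list(gm = geno$gm, pops = geno$pops, freqs = freqs,
                annotation = ann, traits = traits))
}
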