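# Synthetic CRISPR-KO screens with planted ground truth: essential genes,
# contiguous biased regions, negative-binomial counts around a shared
# plasmid. Every pipeline stage can be tested against the planted truth.

#' Configuration for a synthetic screen
#'
#' Defaults emulate a genome-wide screen at desk scale: 2000 genes tiled
#' over 10 chromosomes with 5 sgRNAs per gene, 3 treatment replicates,
#' log-normal plasmid abundances around ~1000 reads per guide, 10% planted
#' essential genes at a logFC shift of -3, and three contiguous 30-gene
#' biased regions at shift -2 emulating cutting toxicity in high
#' copy-number segments (their genes are flagged amplified and
#' non-expressed in the ground truth).
#'
#' @param n_genes Total number of genes (default 2000).
#' @param guides_per_gene sgRNAs per gene (default 5).
#' @param n_chromosomes Chromosomes the genes are tiled over (default 10).
#' @param replicates Treatment replicates (default 3).
#' @param plasmid_meanlog,plasmid_sdlog Log-normal parameters of plasmid
#'   abundances (defaults `log(1000)`, 0.6).
#' @param essential_fraction Fraction of (non-bias-region) genes planted as
#'   essential (default 0.1).
#' @param essential_shift Mean logFC of essential-gene guides (default -3).
#' @param bias_regions `data.frame` with columns `chrom` (integer index),
#'   `gene_start`, `gene_end` (gene offsets within the chromosome,
#'   inclusive) and `shift`; `NULL` gives the default three 30-gene regions
#'   at shift -2. Regions must not overlap.
#' @param noise_sd Per-guide Gaussian logFC noise (default 0.25).
#' @param nb_dispersion Negative-binomial dispersion of counts around their
#'   expectation (default 0.05; 0 gives Poisson).
#' @param depth_factor Sequencing-depth multiplier of treatment libraries
#'   relative to the plasmid (default 1).
#' @param seed Integer seed; a fixed seed makes the screen deterministic.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 2000, guides_per_gene = 5,
                              n_chromosomes = 10, replicates = 3,
                              plasmid_meanlog = log(1000),
                              plasmid_sdlog = 0.6,
                              essential_fraction = 0.1,
                              essential_shift = -3,
                              bias_regions = NULL,
                              noise_sd = 0.25, nb_dispersion = 0.05,
                              depth_factor = 1, seed = 1) {
  stopifnot(n_genes >= n_chromosomes, guides_per_gene >= 1, replicates >= 1,
            essential_fraction >= 0, essential_fraction <= 1, noise_sd >= 0,
            nb_dispersion >= 0, depth_factor > 0)
  genes_per_chrom <- floor(n_genes / n_chromosomes)
  if (is.null(bias_regions)) {
    span <- 30
    picks <- unique(pmin(c(2, 5, 8), n_chromosomes))
    offset <- max(1, floor((genes_per_chrom - span) / 2))
    bias_regions <- data.frame(
      chrom = picks, gene_start = offset,
      gene_end = pmin(offset + span - 1, genes_per_chrom), shift = -2)
  }
  stopifnot(all(bias_regions$gene_start >= 1),
            all(bias_regions$gene_end <= genes_per_chrom),
            all(bias_regions$gene_start <= bias_regions$gene_end))
  for (ch in unique(bias_regions$chrom)) {
    rr <- bias_regions[bias_regions$chrom == ch, , drop = FALSE]
    if (nrow(rr) > 1L) {
      rr <- rr[order(rr$gene_start), ]
      if (any(rr$gene_start[-1] <= rr$gene_end[-nrow(rr)]))
        stop("overlapping bias regions on chromosome ", ch, call. = FALSE)
    }
  }
  structure(list(n_genes = n_genes, guides_per_gene = guides_per_gene,
                 n_chromosomes = n_chromosomes, replicates = replicates,
                 plasmid_meanlog = plasmid_meanlog,
                 plasmid_sdlog = plasmid_sdlog,
                 essential_fraction = essential_fraction,
                 essential_shift = essential_shift,
                 bias_regions = bias_regions, noise_sd = noise_sd,
                 nb_dispersion = nb_dispersion, depth_factor = depth_factor,
                 seed = as.integer(seed),
                 genes_per_chrom = genes_per_chrom),
            class = "simulation_config")
}

#' Simulate a pooled CRISPR-KO screen
#'
#' Lays genes out in order along chromosomes (one gene every 10 kb, guides
#' 100 bp apart within a gene), draws plasmid counts once from a log-normal,
#' assigns each guide a true logFC (essential shift + bias-region shift +
#' Gaussian noise) and draws treatment counts from a negative binomial
#' around `plasmid * 2^logFC * depth_factor` independently per replicate.
#'
#' @param config A [simulation_config()].
#' @return A list with `library` (guide annotation `data.frame`), `counts`
#'   (raw `count_table`) and `truth`, itself a list with per-gene table
#'   (`gene`, `chrom`, `essential`, `in_bias`, `cn`, `fpkm`), per-guide
#'   true logFCs, and the planted per-region guide index ranges
#'   (`regions`: `chrom`, `first_guide`, `last_guide` as indices within the
#'   chromosome's genome order).
#' @export
simulate_screen <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(config$seed)
  gpc <- config$genes_per_chrom
  n_genes <- gpc * config$n_chromosomes
  gene_chrom <- rep(seq_len(config$n_chromosomes), each = gpc)
  gene_offset <- rep(seq_len(gpc), times = config$n_chromosomes)
  gene_id <- sprintf("gene_%04d", seq_len(n_genes))

  in_bias <- rep(FALSE, n_genes)
  bias_shift <- rep(0, n_genes)
  for (r in seq_len(nrow(config$bias_regions))) {
    reg <- config$bias_regions[r, ]
    sel <- gene_chrom == reg$chrom & gene_offset >= reg$gene_start &
      gene_offset <= reg$gene_end
    in_bias[sel] <- TRUE
    bias_shift[sel] <- reg$shift
  }
  n_ess <- round(config$essential_fraction * n_genes)
  essential <- rep(FALSE, n_genes)
  eligible <- which(!in_bias)
  essential[sample(eligible, min(n_ess, length(eligible)))] <- TRUE

  gpg <- config$guides_per_gene
  n_guides <- n_genes * gpg
  g_gene <- rep(seq_len(n_genes), each = gpg)
  lib <- data.frame(
    guide_id = sprintf("sg_%05d", seq_len(n_guides)),
    gene = gene_id[g_gene],
    chrom = as.character(gene_chrom[g_gene]),
    start = (gene_offset[g_gene] - 1) * 10000 + 1000 +
      (rep(seq_len(gpg), times = n_genes) - 1) * 100,
    stringsAsFactors = FALSE
  )
  lib$end <- lib$start + 19

  true_lfc <- config$essential_shift * essential[g_gene] +
    bias_shift[g_gene] + rnorm(n_guides, 0, config$noise_sd)
  plasmid <- pmax(1, round(rlnorm(n_guides, config$plasmid_meanlog,
                                  config$plasmid_sdlog)))
  mu <- plasmid * 2^true_lfc * config$depth_factor
  draw <- function() {
    if (config$nb_dispersion > 0)
      rnbinom(n_guides, mu = mu, size = 1 / config$nb_dispersion)
    else rpois(n_guides, mu)
  }
  treatments <- vapply(seq_len(config$replicates), function(i) draw(),
                       numeric(n_guides))
  colnames(treatments) <- paste0("rep", seq_len(config$replicates))
  counts <- count_table(lib$guide_id, lib$gene, plasmid, treatments,
                        normalised = FALSE)

  # planted region boundaries as guide indices within each chromosome's order
  regions <- config$bias_regions
  regions$first_guide <- (regions$gene_start - 1) * gpg + 1
  regions$last_guide <- regions$gene_end * gpg

  genes_tab <- data.frame(
    gene = gene_id, chrom = as.character(gene_chrom),
    essential = essential, in_bias = in_bias,
    cn = ifelse(in_bias, 8L, 2L),
    fpkm = ifelse(in_bias, 0.01, 10),
    stringsAsFactors = FALSE
  )
  list(library = lib, counts = counts,
       truth = list(genes = genes_tab,
                    guide_logfc = setNames(true_lfc, lib$guide_id),
                    regions = regions))
}

#' A hand-checkable miniature screen
#'
#' Deterministic 20-gene, 60-guide screen on one chromosome with three
#' essential genes (gene_01..gene_03, true logFC -3), a 12-gene biased
#' region (gene_06..gene_17, shift -1) and no noise. The plasmid count is
#' 160 for every guide and both treatment replicates equal
#' `160 * 2^logFC`, so normalisation, segmentation, centering and count
#' inversion all have integer-friendly closed-form expectations.
#'
#' @return As [simulate_screen()]: `library`, `counts`, `truth`, plus
#'   `expected` holding the analytic per-guide logFCs and the identifiers of
#'   the guides inside the planted biased region (ordered guide positions
#'   16..51).
#' @export
worked_fixture <- function() {
  n_genes <- 20; gpg <- 3
  gene_id <- sprintf("gene_%02d", seq_len(n_genes))
  essential <- seq_len(n_genes) %in% 1:3
  in_bias <- seq_len(n_genes) %in% 6:17
  lfc_gene <- ifelse(essential, -3, 0) + ifelse(in_bias, -1, 0)
  g_gene <- rep(seq_len(n_genes), each = gpg)
  lib <- data.frame(
    guide_id = sprintf("sg_%03d", seq_len(n_genes * gpg)),
    gene = gene_id[g_gene],
    chrom = "1",
    start = (g_gene - 1) * 10000 + 1000 +
      (rep(seq_len(gpg), times = n_genes) - 1) * 100,
    stringsAsFactors = FALSE
  )
  lib$end <- lib$start + 19
  plasmid <- rep(160, nrow(lib))
  t1 <- 160 * 2^lfc_gene[g_gene]
  treatments <- cbind(rep1 = t1, rep2 = t1)
  counts <- count_table(lib$guide_id, lib$gene, plasmid, treatments,
                        normalised = FALSE)
  genes_tab <- data.frame(gene = gene_id, chrom = "1",
                          essential = essential, in_bias = in_bias,
                          cn = ifelse(in_bias, 8L, 2L),
                          fpkm = ifelse(in_bias, 0.01, 10),
                          stringsAsFactors = FALSE)
  list(library = lib, counts = counts,
       truth = list(genes = genes_tab,
                    guide_logfc = setNames(lfc_gene[g_gene], lib$guide_id),
                    regions = data.frame(chrom = "1", gene_start = 6,
                                         gene_end = 17, shift = -1,
                                         first_guide = 16, last_guide = 51)),
       expected = list(true_logfc = setNames(lfc_gene[g_gene], lib$guide_id),
                       bias_guides = lib$guide_id[in_bias[g_gene]]))
}
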