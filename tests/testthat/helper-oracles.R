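# Brute-force oracles and small fixture builders shared across the suite.
# The oracles deliberately re-derive each quantity by direct enumeration,
# independently of the package's own code paths.

# Exhaustive search of the maximal |t| arc over all admissible (i, j).
# Returns the cut positions (interior change-points) and the max |t|.
brute_max_arc <- function(x, min_width = 2) {
  m <- length(x)
  best <- -Inf; bi <- bj <- NA
  for (i in 0:(m - 1)) for (j in (i + 1):m) {
    k <- j - i
    if (i == 0 && j == m) next
    if (k < min_width || k > m - min_width) next
    if (i > 0 && i < min_width) next
    if (j < m && (m - j) < min_width) next
    tt <- abs(cbs_statistic(x, i, j))
    if (tt > best) { best <- tt; bi <- i; bj <- j }
  }
  list(cuts = as.integer(sort(setdiff(c(bi, bj), c(0L, m)))), t = best,
       i = bi, j = bj)
}

# Prefix-scan oracle for the precision-based FDR threshold.
# labels: logical, TRUE = essential, in ranked (ascending score) control
# order; scores: the control scores in the same order.
brute_fdr_scan <- function(ctrl_scores, ctrl_is_essential, fdr) {
  k_star <- 0L; f_star <- -Inf
  for (k in seq_along(ctrl_scores)) {
    ppv <- sum(ctrl_is_essential[1:k]) / k
    if (1 - ppv <= fdr) { k_star <- k; f_star <- ctrl_scores[k] }
  }
  list(k_star = k_star, f_star = f_star)
}

# A genome-ordered profile directly from a vector of logFCs: one chromosome,
# `genes_per_segment` guides per gene.
toy_profile <- function(logfc, guides_per_gene = 2, chrom = "1") {
  n <- length(logfc)
  gene_idx <- ceiling(seq_len(n) / guides_per_gene)
  data.frame(
    guide_id = sprintf("g%03d", seq_len(n)),
    gene = sprintf("gene%03d", gene_idx),
    chrom = chrom,
    start = seq_len(n) * 100,
    end = seq_len(n) * 100 + 19,
    logfc = logfc,
    stringsAsFactors = FALSE
  )
}

# A one-segment-per-row segment table covering a toy profile.
manual_segments <- function(profile, bounds) {
  # bounds: list of c(start_row, end_row)
  do.call(rbind, lapply(bounds, function(b) {
    rows <- b[1]:b[2]
    data.frame(chrom = profile$chrom[b[1]], start_index = b[1],
               end_index = b[2], global_start = b[1], global_end = b[2],
               start_bp = profile$start[b[1]], end_bp = profile$end[b[2]],
               seg_mean = mean(profile$logfc[rows]),
               n_guides = length(rows),
               n_genes = length(unique(profile$gene[rows])))
  }))
}

# independent least-squares slope for the critical-point oracle
ls_slope_oracle <- function(x, y) {
  unname(coef(lm(y ~ x))[2])
}

write_tmp <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}
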