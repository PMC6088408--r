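# Median-ratio normalisation, plasmid-count filtering and log fold-changes.

#' Remove guides poorly represented in the plasmid
#'
#' Guides with fewer than `min_reads` plasmid reads carry unreliable
#' fold-change estimates and are removed before normalisation. The cutoff is
#' strict: a guide with exactly `min_reads` reads is retained.
#'
#' @param counts A raw [count_table()].
#' @param min_reads Minimal plasmid read count (default 30).
#' @return A list with `counts` (the filtered table) and `removed` (the
#'   guide identifiers filtered out).
#' @export
filter_low_plasmid <- function(counts, min_reads = 30) {
  stopifnot(inherits(counts, "count_table"))
  if (counts$normalised)
    stop("plasmid filtering must be applied to raw counts", call. = FALSE)
  keep <- counts$plasmid >= min_reads
  if (!any(keep))
    stop("all guides fall below the plasmid read cutoff; empty screen",
         call. = FALSE)
  removed <- counts$guides[!keep]
  filtered <- count_table(counts$guides[keep], counts$genes[keep],
                          counts$plasmid[keep],
                          counts$treatments[keep, , drop = FALSE],
                          normalised = FALSE)
  list(counts = filtered, removed = removed)
}

#' Median-ratio normalisation of a count table
#'
#' Computes one size factor per sample column (plasmid and every treatment
#' replicate, treated as one batch) as the median across guides of the ratio
#' between the guide's count in that sample and the guide's geometric mean
#' across all samples; guides with a zero in any sample are excluded from the
#' median (their geometric mean is zero) but are still scaled. Normalised
#' counts are the raw counts divided by the sample's size factor.
#'
#' @param counts A filtered [count_table()] (see [filter_low_plasmid()]).
#' @return An object of class `normalisation_result`: a list with `table`
#'   (the normalised, real-valued `count_table`), `size_factors` (named
#'   vector, plasmid first) and `n_reference_guides` (guides entering the
#'   median).
#' @export
median_ratio_normalise <- function(counts) {
  stopifnot(inherits(counts, "count_table"))
  mat <- cbind(plasmid = counts$plasmid, counts$treatments)
  positive <- rowSums(mat > 0) == ncol(mat)
  if (!any(positive))
    stop("no guide has positive counts in every sample; size factors undefined",
         call. = FALSE)
  geo <- exp(rowMeans(log(mat[positive, , drop = FALSE])))
  sf <- apply(mat[positive, , drop = FALSE], 2, function(col) median(col / geo))
  if (any(sf <= 0))
    stop("non-positive size factor; degenerate count table", call. = FALSE)
  norm <- sweep(mat, 2, sf, "/")
  table <- count_table(counts$guides, counts$genes, norm[, 1],
                       norm[, -1, drop = FALSE], normalised = TRUE)
  structure(list(table = table, size_factors = sf,
                 n_reference_guides = sum(positive)),
            class = "normalisation_result")
}

#' @export
print.normalisation_result <- function(x, ...) {
  cat("median-ratio normalisation\n  size factors: ",
      paste(sprintf("%s=%.4g", names(x$size_factors), x$size_factors),
            collapse = ", "),
      "\n  reference guides: ", x$n_reference_guides, "\n", sep = "")
  invisible(x)
}

#' Per-guide replicate-averaged log2 fold-changes
#'
#' For each treatment replicate the depletion/enrichment of a guide is the
#' log2 ratio of its normalised treatment count to its normalised plasmid
#' count; the guide's fold-change is the mean over replicates. A pseudocount
#' guards against zeros that survive the plasmid filter (treatment dropouts).
#'
#' @param norm A `normalisation_result` (or a normalised `count_table`).
#' @param pseudocount Value added to both numerator and denominator
#'   (default 0.5; set 0 to disable).
#' @return A `data.frame` with columns `guide_id`, `gene`, `logfc`, plus a
#'   `per_replicate` matrix attribute with the unaveraged values.
#' @export
compute_logfc <- function(norm, pseudocount = 0.5) {
  ct <- if (inherits(norm, "normalisation_result")) norm$table else norm
  stopifnot(inherits(ct, "count_table"))
  eps <- pseudocount
  per_rep <- log2(sweep(ct$treatments + eps, 1, ct$plasmid + eps, "/"))
  lfc <- rowMeans(per_rep)
  out <- data.frame(guide_id = ct$guides, gene = ct$genes, logfc = lfc,
                    stringsAsFactors = FALSE)
  attr(out, "per_replicate") <- per_rep
  out
}
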