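# Identification and centering of biased segments.

#' Parameters for segment correction
#'
#' A segment is considered a candidate gene-independent artefact — and is
#' centered — only when its guides collectively target at least `min_genes`
#' distinct genes: a sustained fitness effect shared by several adjacent
#' genes is far more likely to reflect cutting toxicity than coincident
#' essentiality.
#'
#' @param min_genes Minimal number of distinct target genes a segment must
#'   contain to be corrected (default 3).
#' @param center Centering statistic: `"mean"` (default) or `"median"`, the
#'   latter more robust to outlying guides.
#' @param exclude_genes Optional gene symbols removed from the profile
#'   before segmentation (default empty: the method is fully unsupervised).
#' @return An object of class `correction_params`.
#' @export
correction_params <- function(min_genes = 3, center = c("mean", "median"),
                              exclude_genes = character()) {
  center <- match.arg(center)
  stopifnot(min_genes >= 1)
  structure(list(min_genes = as.integer(min_genes), center = center,
                 exclude_genes = as.character(exclude_genes)),
            class = "correction_params")
}

#' Center biased segments of a fold-change profile
#'
#' For every segment whose guides target at least `min_genes` distinct
#' genes, the segment's center statistic (mean or median of its logFCs) is
#' subtracted from every member guide, flattening segment-level bias while
#' preserving within-segment relative effects. All other guides are
#' untouched.
#'
#' @param profile Genome-ordered profile (see [sort_by_genome()]).
#' @param segments Segment table from [segment_genome()]; must partition the
#'   profile.
#' @param params A [correction_params()] object.
#' @return An object of class `correction_result`: a list with
#'   `corrected_profile` (same rows/order as `profile`, corrected `logfc`),
#'   `segments` (input segments plus `corrected` flag and `offset`), and
#'   `offsets` (per-guide subtracted value, 0 outside corrected segments).
#' @export
correct_profile <- function(profile, segments, params = correction_params()) {
  stopifnot(is.data.frame(segments),
            all(c("global_start", "global_end", "n_genes") %in% names(segments)))
  covered <- unlist(mapply(seq, segments$global_start, segments$global_end,
                           SIMPLIFY = FALSE))
  if (length(covered) != nrow(profile) || anyDuplicated(covered) ||
      !setequal(covered, seq_len(nrow(profile))))
    stop("segments do not partition the profile", call. = FALSE)
  offsets <- numeric(nrow(profile))
  corrected <- segments$n_genes >= params$min_genes
  seg_offset <- numeric(nrow(segments))
  for (s in which(corrected)) {
    rows <- segments$global_start[s]:segments$global_end[s]
    ctr <- if (params$center == "mean") mean(profile$logfc[rows])
           else median(profile$logfc[rows])
    offsets[rows] <- ctr
    seg_offset[s] <- ctr
  }
  out <- profile
  out$logfc <- profile$logfc - offsets
  segments$corrected <- corrected
  segments$offset <- seg_offset
  structure(list(corrected_profile = out, segments = segments,
                 offsets = offsets, params = params),
            class = "correction_result")
}

#' @export
print.correction_result <- function(x, ...) {
  cat(sprintf("correction_result: %d/%d segment(s) centered (%s, min %d genes)\n",
              sum(x$segments$corrected), nrow(x$segments), x$params$center,
              x$params$min_genes))
  invisible(x)
}

#' Run segmentation and correction in one step
#'
#' Convenience wrapper: optionally removes `exclude_genes`, segments the
#' profile and centers biased segments.
#'
#' @param profile Genome-ordered profile.
#' @param cbs A [cbs_params()] object.
#' @param correction A [correction_params()] object.
#' @return A `correction_result` (see [correct_profile()]); when genes were
#'   excluded, the corrected profile covers the remaining guides only.
#' @export
segment_and_correct <- function(profile, cbs = cbs_params(),
                                correction = correction_params()) {
  if (length(correction$exclude_genes) > 0L) {
    profile <- profile[!(profile$gene %in% correction$exclude_genes), ,
                       drop = FALSE]
    rownames(profile) <- NULL
  }
  segs <- segment_genome(profile, cbs)
  correct_profile(profile, segs, correction)
}

#' Adaptive choice of the minimal-genes threshold
#'
#' Runs segmentation + correction for every candidate threshold, both with
#' and without removing a filter set of a priori essential genes, and scores
#' each trial by the reduction in area under the recall curve (AURC) it
#' achieves for bias-indicator gene sets (amplified, amplified
#' non-expressed) versus an essential test set whose recall should be
#' preserved. The chosen threshold maximises bias recall reduction minus
#' essential recall reduction, averaged over the filter-set conditions;
#' ties go to the smallest candidate.
#'
#' @param profile Genome-ordered profile.
#' @param candidate_ns Candidate thresholds (default `c(2, 3, 5, 10)`).
#' @param control_sets A list with character vectors `essential_test`,
#'   `amplified`, `amplified_non_expressed`, and optionally `filter_set`
#'   (genes removed in the "filtered" condition).
#' @param cbs A [cbs_params()] object.
#' @param center Centering statistic passed through to the correction.
#' @return A list with `chosen_n` and `trials`, a `data.frame` with one row
#'   per (candidate, filter condition) giving the three AURC recall
#'   reductions (percent).
#' @export
choose_min_genes <- function(profile, candidate_ns = c(2, 3, 5, 10),
                             control_sets, cbs = cbs_params(),
                             center = "mean") {
  needed <- c("essential_test", "amplified", "amplified_non_expressed")
  stopifnot(all(needed %in% names(control_sets)))
  filter_set <- control_sets$filter_set
  conditions <- if (length(filter_set) > 0L) c(FALSE, TRUE) else FALSE
  trials <- list()
  for (n in candidate_ns) for (filt in conditions) {
    excl <- if (filt) filter_set else character()
    res <- segment_and_correct(profile, cbs,
                               correction_params(min_genes = n, center = center,
                                                 exclude_genes = excl))
    post <- gene_level_means(res$corrected_profile)
    pre <- gene_level_means(profile[profile$guide_id %in%
                                      res$corrected_profile$guide_id, ,
                                    drop = FALSE])
    red <- vapply(needed, function(set_name) {
      pos <- intersect(control_sets[[set_name]], names(pre))
      if (length(pos) == 0L) return(NA_real_)
      recall_reduction(pre, post, pos)
    }, numeric(1))
    trials[[length(trials) + 1L]] <- data.frame(
      min_genes = n, filter_set_removed = filt,
      reduction_essential_test = red[["essential_test"]],
      reduction_amplified = red[["amplified"]],
      reduction_amplified_non_expressed = red[["amplified_non_expressed"]])
  }
  trials <- do.call(rbind, trials)
  score <- with(trials,
                (reduction_amplified + reduction_amplified_non_expressed) / 2 -
                  reduction_essential_test)
  by_n <- tapply(score, trials$min_genes, mean, na.rm = TRUE)
  if (all(is.na(by_n)) || all(abs(trials$reduction_amplified) < 1e-9,
                              na.rm = TRUE)) {
    chosen <- min(candidate_ns)
    no_op <- TRUE
  } else {
    best <- max(by_n, na.rm = TRUE)
    chosen <- min(as.numeric(names(by_n)[which(by_n >= best - 1e-9)]))
    no_op <- FALSE
  }
  list(chosen_n = chosen, trials = trials, no_op = no_op)
}

# per-gene mean logFC, named by gene
gene_level_means <- function(profile) {
  gs <- tapply(profile$logfc, profile$gene, mean)
  setNames(as.numeric(gs), names(gs))
}
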