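# Depletion calling at fixed FDR, recall/PR machinery, and copy-number bias
# diagnostics.

#' Precision-based depletion threshold at a fixed FDR
#'
#' Items (guides or genes) are ranked by increasing logFC (most depleted
#' first). Walking down the ranked members of the positive (essential) and
#' negative (non-essential) control sets only, the precision
#' `PPV(k) = |P(k) n E| / |P(k)|` is computed at every control rank `k`;
#' `k*` is the largest `k` with `1 - PPV(k) <= fdr`, and `F*` is the logFC
#' of the control item at rank `k*`. Every library item with logFC strictly
#' below `F*` is called depleted at this FDR, whether or not it is a
#' control.
#'
#' @param scores Named numeric vector of logFCs (names are item
#'   identifiers).
#' @param essential,non_essential Character vectors naming the control
#'   items; they must be disjoint and each must intersect `names(scores)`.
#' @param fdr Target false discovery rate (default 0.05).
#' @return An object of class `depletion_call`: a list with `k_star`,
#'   `f_star` (`-Inf` when no rank satisfies the bound), `called` (item
#'   names), `fdr`, `n_controls`, and the control-level `ppv` curve.
#' @export
fdr_threshold <- function(scores, essential, non_essential, fdr = 0.05) {
  stopifnot(is.numeric(scores), !is.null(names(scores)))
  if (length(intersect(essential, non_essential)) > 0L)
    stop("essential and non-essential control sets overlap", call. = FALSE)
  is_ctrl <- names(scores) %in% c(essential, non_essential)
  if (!any(names(scores) %in% essential) ||
      !any(names(scores) %in% non_essential))
    stop("both control sets must be represented among the scored items",
         call. = FALSE)
  ord <- order(scores, names(scores))       # ascending logFC, stable
  ranked <- scores[ord]
  ctrl <- ranked[is_ctrl[ord]]
  is_E <- names(ctrl) %in% essential
  ppv <- cumsum(is_E) / seq_along(ctrl)
  ok <- which(1 - ppv <= fdr)
  if (length(ok) == 0L) {
    call_obj <- list(k_star = 0L, f_star = -Inf, called = character(0),
                     fdr = fdr, n_controls = length(ctrl), ppv = ppv)
  } else {
    k_star <- max(ok)
    f_star <- unname(ctrl[k_star])
    called <- names(scores)[scores < f_star]
    call_obj <- list(k_star = k_star, f_star = f_star, called = called,
                     fdr = fdr, n_controls = length(ctrl), ppv = ppv)
  }
  structure(call_obj, class = "depletion_call")
}

#' @export
print.depletion_call <- function(x, ...) {
  cat(sprintf("depletion_call: k* = %d of %d controls, F* = %.4g, %d called (FDR %.3g)\n",
              x$k_star, x$n_controls, x$f_star, length(x$called), x$fdr))
  invisible(x)
}

#' Gene-level depletion calls
#'
#' Averages the logFCs of the guides targeting each gene and applies
#' [fdr_threshold()] at the gene level.
#'
#' @param profile Profile `data.frame` with columns `gene` and `logfc`.
#' @param essential,non_essential Gene-level control sets.
#' @param fdr Target FDR (default 0.05).
#' @return A `depletion_call` with an extra element `gene_scores` (named
#'   per-gene mean logFCs).
#' @export
call_genes <- function(profile, essential, non_essential, fdr = 0.05) {
  gs <- tapply(profile$logfc, profile$gene, mean)
  gs <- setNames(as.numeric(gs), names(gs))
  out <- fdr_threshold(gs, essential, non_essential, fdr = fdr)
  out$gene_scores <- gs
  out
}

#' Recall curve and its area
#'
#' Recall of a positive set as a function of rank over the full ascending
#' ranking of scores; the area (AURC) is computed by the trapezoid rule over
#' the normalised rank axis. Uninformative scores give an AURC near 0.5;
#' positives concentrated at the top push it towards 1.
#'
#' @param scores Named numeric vector (ascending = most depleted first).
#' @param positive_set Character vector of positive item names (non-empty
#'   intersection with `names(scores)` required).
#' @return A list with `rank_fraction`, `recall` and `aurc`.
#' @export
recall_curve <- function(scores, positive_set) {
  stopifnot(!is.null(names(scores)))
  pos <- names(scores) %in% positive_set
  if (!any(pos)) stop("positive set not represented among scored items",
                      call. = FALSE)
  ord <- order(scores, names(scores))
  hits <- cumsum(pos[ord])
  recall <- hits / sum(pos)
  x <- seq_along(scores) / length(scores)
  aurc <- trapezoid_area(c(0, x), c(0, recall))
  list(rank_fraction = x, recall = recall, aurc = aurc)
}

trapezoid_area <- function(x, y) {
  sum(diff(x) * (head(y, -1) + y[-1]) / 2)
}

#' Percent reduction in area under the recall curve
#'
#' `100 * (AURC_pre - AURC_post) / AURC_pre`: positive when the positive
#' set's recall worsens after correction (the desired direction for
#' bias-indicator sets, the undesired one for true essentials).
#'
#' @param pre_scores,post_scores Named score vectors before/after
#'   correction.
#' @param positive_set Positive item names.
#' @return Percent reduction (numeric scalar).
#' @export
recall_reduction <- function(pre_scores, post_scores, positive_set) {
  a_pre <- recall_curve(pre_scores, positive_set)$aurc
  a_post <- recall_curve(post_scores, positive_set)$aurc
  100 * (a_pre - a_post) / a_pre
}

#' Recall of a gene set at a fixed FDR
#'
#' Fraction of the positive set called depleted at the [fdr_threshold()]
#' cutoff.
#'
#' @inheritParams fdr_threshold
#' @param positive_set Items whose recall is measured.
#' @return Recall in `[0, 1]`.
#' @export
recall_at_fdr <- function(scores, essential, non_essential, positive_set,
                          fdr = 0.05) {
  dc <- fdr_threshold(scores, essential, non_essential, fdr = fdr)
  pos <- intersect(positive_set, names(scores))
  if (length(pos) == 0L) return(NA_real_)
  mean(pos %in% dc$called)
}

#' Preservation of the depletion signal through correction
#'
#' For each `k`, the `k` most-depleted guides of the pre-correction profile
#' are treated as positives and the post-correction ranking as the
#' classifier; the area under the precision/recall curve (average
#' precision) measures how well correction preserves the original signal.
#'
#' @param pre,post Named numeric vectors over the same guide universe.
#' @param top_k Integer vector of positive-set sizes.
#' @return A `data.frame` with columns `k` and `auprc`.
#' @export
profile_preservation <- function(pre, post, top_k) {
  stopifnot(setequal(names(pre), names(post)))
  if (any(top_k > length(pre)))
    stop("top_k exceeds the number of scored guides", call. = FALSE)
  post <- post[names(pre)]
  res <- vapply(top_k, function(k) {
    pos_names <- names(sort(pre))[seq_len(k)]
    average_precision(post, pos_names)
  }, numeric(1))
  data.frame(k = top_k, auprc = res)
}

# area under the precision/recall curve as average precision over hits,
# scores ranked ascending (most depleted first)
average_precision <- function(scores, positive_set) {
  ord <- order(scores, names(scores))
  pos <- names(scores)[ord] %in% positive_set
  prec <- cumsum(pos) / seq_along(pos)
  mean(prec[pos])
}

#' Copy-number bias starting point
#'
#' The smallest copy number `n > 2` at which the mean logFCs of segments
#' with that CN differ significantly (Welch's t-test) from those of CN = 2
#' segments. Groups with fewer than two segments are skipped with a
#' warning.
#'
#' @param segment_means_by_cn Named list mapping copy-number values to
#'   numeric vectors of segment mean logFCs; must contain a `"2"` entry with
#'   at least two segments.
#' @param alpha Significance level of the Welch test (default 0.05).
#' @return The starting-point CN, or `NA` if no CN qualifies; attribute
#'   `p_values` carries the per-CN test results.
#' @export
bias_starting_point <- function(segment_means_by_cn, alpha = 0.05) {
  cns <- as.numeric(names(segment_means_by_cn))
  stopifnot(!anyNA(cns))
  ref <- segment_means_by_cn[["2"]]
  if (is.null(ref) || length(ref) < 2L)
    stop("CN = 2 group must contain at least two segments", call. = FALSE)
  candidates <- sort(cns[cns > 2])
  pvals <- setNames(rep(NA_real_, length(candidates)), candidates)
  start <- NA_real_
  for (n in candidates) {
    grp <- segment_means_by_cn[[as.character(n)]]
    if (length(grp) < 2L) {
      warning("CN ", n, " group has fewer than two segments; skipped",
              call. = FALSE)
      next
    }
    p <- t.test(grp, ref, var.equal = FALSE)$p.value
    pvals[as.character(n)] <- p
    if (is.na(start) && p < alpha) start <- n
  }
  structure(start, p_values = pvals)
}

#' Copy-number bias critical point
#'
#' Segment mean logFCs are first averaged per copy-number value. For every
#' candidate knee `n` in `3..m-1` (`m` = maximal observed CN) two
#' least-squares lines are fitted — `P(n)` on CN values `2..n` and `L(n)` on
#' `n+1..m` — and the critical point is the `n` maximising the absolute
#' difference of their slopes. Candidates leaving fewer than two distinct CN
#' values on either side are skipped.
#'
#' @param segment_cn Numeric vector of per-segment copy numbers.
#' @param segment_means Numeric vector of per-segment mean logFCs, parallel
#'   to `segment_cn`.
#' @param weak_tolerance Slope differences below this value flag the result
#'   as weak (default 0.05).
#' @return A list with `critical_point`, `slope_difference`, `weak`
#'   (logical) and the per-candidate `slope_diffs`.
#' @export
bias_critical_point <- function(segment_cn, segment_means,
                                weak_tolerance = 0.05) {
  stopifnot(length(segment_cn) == length(segment_means))
  avg <- tapply(segment_means, segment_cn, mean)
  cn_vals <- as.numeric(names(avg))
  keep <- cn_vals >= 2
  cn_vals <- cn_vals[keep]; avg <- as.numeric(avg[keep])
  m <- max(cn_vals)
  if (m < 4) stop("need a maximal copy number of at least 4", call. = FALSE)
  cand <- 3:(m - 1)
  diffs <- setNames(rep(NA_real_, length(cand)), cand)
  for (n in cand) {
    low <- cn_vals >= 2 & cn_vals <= n
    high <- cn_vals >= n + 1 & cn_vals <= m
    if (sum(low) < 2L || sum(high) < 2L) next
    s1 <- ls_slope(cn_vals[low], avg[low])
    s2 <- ls_slope(cn_vals[high], avg[high])
    diffs[as.character(n)] <- abs(s1 - s2)
  }
  if (all(is.na(diffs))) {
    # with m = 4 there is a single candidate but only one CN value on its
    # right side; report it, flagged as weak, rather than failing
    if (length(cand) == 1L)
      return(list(critical_point = cand, slope_difference = NA_real_,
                  weak = TRUE, slope_diffs = diffs))
    stop("no admissible candidate knee (too few distinct CN values)",
         call. = FALSE)
  }
  best <- cand[which.max(diffs)]
  list(critical_point = best,
       slope_difference = max(diffs, na.rm = TRUE),
       weak = max(diffs, na.rm = TRUE) < weak_tolerance,
       slope_diffs = diffs)
}

ls_slope <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

#' Impact of correction on fitness-gene calls
#'
#' Compares per-gene significance calls before and after correction.
#' *Attenuated* genes are significant (either direction) before but not
#' after correction; *distorted* genes stay significant but flip direction.
#' Percentages are reported against all screened genes and against the
#' pre-correction significant set. Attenuated loss-of-fitness genes are
#' further partitioned sequentially into disjoint explanation classes:
#' non-expressed (FPKM below `fpkm_cutoff`), copy-number amplified, prior
#' known non-essential, and mild phenotype (pre-correction mean logFC above
#' the upper quartile of all pre-correction loss-of-fitness genes).
#'
#' @param pre_calls,post_calls `data.frame`s with columns `gene`,
#'   `significant` (logical) and `direction` (`"loss"` or `"gain"`, the
#'   sign of the fitness effect).
#' @param annotations Optional list with named numeric vector `fpkm`,
#'   logical/character vector `amplified` (gene names or named logicals),
#'   and character vector `non_essential`. Classes whose annotation is
#'   missing are reported as `NA` (not computable).
#' @param pre_gene_logfc Named numeric vector of pre-correction per-gene
#'   mean logFCs (needed for the mild-phenotype class).
#' @param fpkm_cutoff Expression cutoff for the non-expressed class
#'   (default 0.05 FPKM).
#' @return A list with counts and percentages of attenuated/distorted genes
#'   and the partition of attenuated loss-of-fitness genes.
#' @export
fitness_gene_impact <- function(pre_calls, post_calls, annotations = list(),
                                pre_gene_logfc = NULL, fpkm_cutoff = 0.05) {
  stopifnot(all(c("gene", "significant", "direction") %in% names(pre_calls)),
            all(c("gene", "significant", "direction") %in% names(post_calls)))
  idx <- match(pre_calls$gene, post_calls$gene)
  if (anyNA(idx)) stop("gene universes of pre/post calls differ", call. = FALSE)
  post <- post_calls[idx, ]
  n_all <- nrow(pre_calls)
  sig_pre <- pre_calls$significant
  attenuated <- sig_pre & !post$significant
  distorted <- sig_pre & post$significant &
    pre_calls$direction != post$direction
  att_loss_genes <- pre_calls$gene[attenuated & pre_calls$direction == "loss"]
  # sequential disjoint partition of attenuated loss-of-fitness genes
  partition <- list()
  remaining <- att_loss_genes
  take <- function(members) {
    hit <- intersect(remaining, members)
    remaining <<- setdiff(remaining, hit)
    hit
  }
  partition$non_expressed <- if (!is.null(annotations$fpkm))
    take(names(annotations$fpkm)[annotations$fpkm < fpkm_cutoff]) else NA
  partition$amplified <- if (!is.null(annotations$amplified)) {
    amp <- annotations$amplified
    amp_genes <- if (is.character(amp)) amp else names(amp)[as.logical(amp)]
    take(amp_genes)
  } else NA
  partition$non_essential <- if (!is.null(annotations$non_essential))
    take(annotations$non_essential) else NA
  partition$mild_phenotype <- if (!is.null(pre_gene_logfc)) {
    loss_genes <- pre_calls$gene[sig_pre & pre_calls$direction == "loss"]
    q <- quantile(pre_gene_logfc[intersect(loss_genes,
                                           names(pre_gene_logfc))], 0.75,
                  names = FALSE)
    take(names(pre_gene_logfc)[pre_gene_logfc > q])
  } else NA
  partition$unexplained <- remaining
  list(
    n_screened = n_all,
    n_significant_pre = sum(sig_pre),
    attenuated = pre_calls$gene[attenuated],
    distorted = pre_calls$gene[distorted],
    pct_attenuated_vs_screened = 100 * sum(attenuated) / n_all,
    pct_attenuated_vs_significant =
      if (sum(sig_pre) > 0) 100 * sum(attenuated) / sum(sig_pre) else 0,
    pct_distorted_vs_screened = 100 * sum(distorted) / n_all,
    pct_distorted_vs_significant =
      if (sum(sig_pre) > 0) 100 * sum(distorted) / sum(sig_pre) else 0,
    attenuated_loss_partition = partition
  )
}
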