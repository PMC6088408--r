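# Back-transformation of corrected logFCs to replicate-level counts, so
# that downstream mean-variance callers (e.g. MAGeCK run with normalisation
# disabled) can consume corrected data.

#' Derive corrected treatment counts from corrected logFCs
#'
#' For a guide with plasmid count `c`, corrected logFC `N` and uncorrected
#' replicate counts `t*_1..t*_n` summing to `T*`, the corrected
#' replicate counts are
#' \deqn{t_i = n \, c \, 2^N \, t^*_i / T^*}
#' so that the across-replicate mean equals `c * 2^N` while the replicate
#' proportions of the uncorrected data are preserved. When `T* = 0` the
#' corrected mean is split equally (`t_i = c * 2^N`).
#'
#' @param corrected_logfc A `data.frame` with columns `guide_id` and `logfc`
#'   (the corrected values), e.g. `corrected_profile` from
#'   [correct_profile()].
#' @param counts The (normalised) `count_table` whose treatments are the
#'   uncorrected `t*` and whose plasmid column supplies `c`. Guide sets must
#'   match exactly.
#' @param round_counts If `TRUE`, round the emitted counts to integers
#'   (half-even); default `FALSE` keeps reals.
#' @return An object of class `corrected_counts`: a list with `table` (a
#'   `count_table` with corrected treatments and untouched plasmid) and
#'   `logfc` (the corrected `N` per guide, aligned).
#' @export
invert_to_counts <- function(corrected_logfc, counts, round_counts = FALSE) {
  stopifnot(inherits(counts, "count_table"),
            all(c("guide_id", "logfc") %in% names(corrected_logfc)))
  idx <- match(counts$guides, corrected_logfc$guide_id)
  if (anyNA(idx) || length(corrected_logfc$guide_id) != length(counts$guides))
    stop("guide sets of corrected logFCs and count table do not match",
         call. = FALSE)
  N <- corrected_logfc$logfc[idx]
  cc <- counts$plasmid
  tstar <- counts$treatments
  n <- ncol(tstar)
  Tstar <- rowSums(tstar)
  mean_t <- cc * 2^N
  t_corr <- matrix(0, nrow = nrow(tstar), ncol = n,
                   dimnames = dimnames(tstar))
  pos <- Tstar > 0
  if (any(pos))
    t_corr[pos, ] <- n * mean_t[pos] * tstar[pos, , drop = FALSE] / Tstar[pos]
  if (any(!pos))
    t_corr[!pos, ] <- mean_t[!pos]   # equal split when all replicates are 0
  if (round_counts) t_corr <- round(t_corr)
  table <- count_table(counts$guides, counts$genes, cc, t_corr,
                       normalised = counts$normalised)
  structure(list(table = table, logfc = setNames(N, counts$guides)),
            class = "corrected_counts")
}

#' @export
print.corrected_counts <- function(x, ...) {
  cat("corrected_counts for", length(x$table$guides), "guides,",
      ncol(x$table$treatments), "replicate(s)\n")
  invisible(x)
}

#' Quantify the round-trip discrepancy of corrected counts
#'
#' Recomputes the replicate-averaged logFC `mean_i log2(t_i / c)` from the
#' corrected counts and returns the maximum absolute deviation from the
#' target `N` across guides. Because the back-transformation fixes the
#' arithmetic mean of the counts while `N` is a mean of logs, the deviation
#' is zero only when the replicate counts are equal (in particular for a
#' single replicate); for unequal replicates the deviation equals
#' `log2(arithmetic mean / geometric mean)` of the preserved replicate
#' proportions and is reported, not hidden.
#'
#' @param corrected A `corrected_counts` object (all `t_i > 0` required for
#'   an exact check unless a pseudocount is supplied).
#' @param pseudocount Added to counts before taking logs (default 0).
#' @return Maximum absolute deviation (numeric scalar).
#' @export
roundtrip_check <- function(corrected, pseudocount = 0) {
  stopifnot(inherits(corrected, "corrected_counts"))
  ct <- corrected$table
  eps <- pseudocount
  recomputed <- rowMeans(log2(sweep(ct$treatments + eps, 1,
                                    ct$plasmid + eps, "/")))
  max(abs(recomputed - corrected$logfc))
}
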