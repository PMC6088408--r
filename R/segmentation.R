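# Circular binary segmentation of genome-ordered logFC profiles.
#
# Each chromosome is segmented independently. The change-point statistic is
# the pooled-variance two-sample t comparing a circular arc of the ordered
# values against its complement; the arc maximising |t| is accepted as a
# change-point pair when its permutation p-value falls below alpha, and the
# resulting pieces are segmented recursively. Arc boundaries are reported as
# linear change-points: an interior arc yields two change-points (three
# pieces), an arc touching either end yields one.

#' Parameters for circular binary segmentation
#'
#' @param alpha Significance threshold to accept a change-point (default
#'   0.01).
#' @param nperm Number of permutations for p-value computation (default
#'   10000). A sequential early-stopping rule equivalent to the full run is
#'   applied unless `early_stop = FALSE`: permutation stops once the outcome
#'   at `alpha` is decided (see the package vignette).
#' @param min_width Minimal number of markers (guides) per segment
#'   (default 2).
#' @param seed Optional integer seeding the permutation stream; recorded so
#'   runs are reproducible.
#' @param early_stop Logical; disable to always run all `nperm` permutations.
#' @param min_perm Minimal permutations before an early significance call
#'   (default 500).
#' @return An object of class `cbs_params`.
#' @export
cbs_params <- function(alpha = 0.01, nperm = 10000, min_width = 2,
                       seed = NULL, early_stop = TRUE, min_perm = 500) {
  stopifnot(alpha > 0, alpha < 1, nperm >= 1, min_width >= 2,
            min_perm >= 1)
  structure(list(alpha = alpha, nperm = as.integer(nperm),
                 min_width = as.integer(min_width),
                 seed = if (is.null(seed)) NULL else as.integer(seed),
                 early_stop = isTRUE(early_stop),
                 min_perm = as.integer(min_perm)),
            class = "cbs_params")
}

#' Circular binary segmentation arc statistic
#'
#' Pooled-variance two-sample t statistic comparing the mean of the circular
#' arc `(i, j]` of `values` (1-based positions `i + 1 .. j`) against the mean
#' of its complement. `i = 0` and `j = length(values)` give ordinary
#' (non-wrapping) prefixes/suffixes.
#'
#' @param values Numeric vector.
#' @param i,j Arc bounds with `0 <= i < j <= length(values)`, not the full
#'   circle.
#' @return The signed t statistic (positive when the arc mean exceeds the
#'   complement mean); `Inf`/`-Inf` when the within-group variance is zero.
#' @export
cbs_statistic <- function(values, i, j) {
  m <- length(values)
  stopifnot(i >= 0, j > i, j <= m)
  if (i == 0 && j == m)
    stop("degenerate arc: complement is empty", call. = FALSE)
  arc <- values[(i + 1):j]
  comp <- values[-((i + 1):j)]
  n1 <- length(arc); n2 <- length(comp)
  d <- mean(arc) - mean(comp)
  if (n1 + n2 < 3) return(sign(d) * Inf)
  sp2 <- (sum((arc - mean(arc))^2) + sum((comp - mean(comp))^2)) / (n1 + n2 - 2)
  if (sp2 <= 0) return(if (d == 0) 0 else sign(d) * Inf)
  d / sqrt(sp2 * (1 / n1 + 1 / n2))
}

#' Locate the maximal change-point arc
#'
#' Finds the arc `(i, j]` maximising `|cbs_statistic(values, i, j)|` over all
#' arcs for which every resulting linear piece would have at least
#' `min_width` markers.
#'
#' @param values Numeric vector (length >= `2 * min_width`).
#' @param min_width Minimal markers per piece.
#' @return A list with `i`, `j`, the signed statistic `t`, and the
#'   between-group sum of squares `B` used internally for permutation
#'   comparisons; `i = j = -1` when no admissible arc exists.
#' @export
cbs_max_split <- function(values, min_width = 2) {
  res <- .cbs_max_stat_cpp(as.numeric(values), as.integer(min_width))
  res
}

#' Permutation p-value for the maximal arc statistic
#'
#' @param values Numeric vector.
#' @param params A [cbs_params()] object.
#' @param exact If `TRUE` (only for `length(values) <= 9`), enumerate all
#'   orderings instead of sampling permutations.
#' @return A list with the p-value `p`, `significant` (p below alpha),
#'   `nperm_done` and the split location (`i`, `j`, `t`).
#' @export
cbs_split_pvalue <- function(values, params = cbs_params(), exact = FALSE) {
  values <- as.numeric(values)
  best <- cbs_max_split(values, params$min_width)
  if (best$i < 0)
    return(list(p = 1, significant = FALSE, nperm_done = 0L,
                i = -1L, j = -1L, t = NA_real_))
  if (exact) {
    p <- .cbs_exact_pvalue_cpp(values, params$min_width, best$B)
    return(list(p = p, significant = p < params$alpha,
                nperm_done = NA_integer_, i = best$i, j = best$j, t = best$t))
  }
  pv <- .cbs_perm_pvalue_cpp(values, params$min_width, best$B, params$nperm,
                             params$alpha, params$early_stop, params$min_perm,
                             0.9999)
  list(p = pv$p, significant = pv$significant, nperm_done = pv$nperm_done,
       i = best$i, j = best$j, t = best$t)
}

#' Segment one chromosome's ordered values
#'
#' Recursive circular binary segmentation: the maximal-|t| arc is tested by
#' permutation; if accepted, the vector is split at the arc boundaries and
#' each piece is segmented recursively. The returned segments partition the
#' vector.
#'
#' @param values Numeric vector of genome-ordered logFCs for one chromosome.
#' @param params A [cbs_params()] object. `params$seed`, when set, seeds the
#'   permutation stream (call-local; the caller's RNG state is restored).
#' @return A `data.frame` with columns `start_index`, `end_index` (1-based,
#'   inclusive), `seg_mean` and `n_guides`.
#' @export
segment_chromosome <- function(values, params = cbs_params()) {
  values <- as.numeric(values)
  m <- length(values)
  stopifnot(m >= 1)
  if (!is.null(params$seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(params$seed)
  }
  bounds <- segment_recurse(values, 1L, m, params)
  segs <- data.frame(start_index = vapply(bounds, `[[`, integer(1), 1L),
                     end_index   = vapply(bounds, `[[`, integer(1), 2L))
  segs <- segs[order(segs$start_index), , drop = FALSE]
  rownames(segs) <- NULL
  segs$seg_mean <- mapply(function(a, b) mean(values[a:b]),
                          segs$start_index, segs$end_index)
  segs$n_guides <- segs$end_index - segs$start_index + 1L
  stopifnot(segs$start_index[1] == 1L,
            segs$end_index[nrow(segs)] == m,
            all(segs$start_index[-1] == segs$end_index[-nrow(segs)] + 1L))
  segs
}

segment_recurse <- function(values, lo, hi, params) {
  m <- hi - lo + 1L
  if (m < 2L * params$min_width) return(list(c(lo, hi)))
  sp <- cbs_split_pvalue(values[lo:hi], params)
  if (sp$i < 0 || !sp$significant) return(list(c(lo, hi)))
  cuts <- integer(0)
  if (sp$i > 0) cuts <- c(cuts, lo + sp$i - 1L)   # last index of left piece
  if (sp$j < m) cuts <- c(cuts, lo + sp$j - 1L)   # last index of arc
  starts <- c(lo, cuts + 1L)
  ends <- c(cuts, hi)
  out <- list()
  for (p in seq_along(starts))
    out <- c(out, segment_recurse(values, starts[p], ends[p], params))
  out
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
}

#' Segment a genome-ordered fold-change profile
#'
#' Applies [segment_chromosome()] to each chromosome of the profile in turn.
#' Segments never span chromosomes. The distinct-gene count per segment — the
#' quantity gating correction — is taken from the profile's gene labels.
#'
#' @param profile Genome-ordered profile from [sort_by_genome()] (columns
#'   `guide_id`, `gene`, `chrom`, `start`, `logfc`; `end` optional).
#' @param params A [cbs_params()] object. The seed (when set) is applied
#'   once for the whole genome so the run is reproducible end to end.
#' @return A `data.frame` with one row per segment: `chrom`, `start_index` /
#'   `end_index` (within the chromosome), `global_start` / `global_end`
#'   (row indices into `profile`), `start_bp` / `end_bp` (genomic positions
#'   of the first and last member guide), `seg_mean`, `n_guides`, `n_genes`.
#' @export
segment_genome <- function(profile, params = cbs_params()) {
  stopifnot(all(c("guide_id", "gene", "chrom", "start", "logfc") %in%
                  names(profile)))
  if (!is.null(params$seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(params$seed)
  }
  inner <- params
  inner$seed <- NULL  # one stream for the whole genome
  chroms <- unique(profile$chrom)
  res <- list()
  for (ch in chroms) {
    rows <- which(profile$chrom == ch)
    if (length(rows) == 0L) {
      warning("chromosome ", ch, " has no guides; skipped", call. = FALSE)
      next
    }
    segs <- segment_chromosome(profile$logfc[rows], inner)
    segs$chrom <- ch
    segs$global_start <- rows[segs$start_index]
    segs$global_end <- rows[segs$end_index]
    segs$start_bp <- profile$start[segs$global_start]
    end_col <- if ("end" %in% names(profile)) profile$end else profile$start
    segs$end_bp <- end_col[segs$global_end]
    segs$n_genes <- mapply(function(a, b)
      length(unique(profile$gene[a:b])), segs$global_start, segs$global_end)
    res[[ch]] <- segs
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out[, c("chrom", "start_index", "end_index", "global_start", "global_end",
          "start_bp", "end_bp", "seg_mean", "n_guides", "n_genes")]
}
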