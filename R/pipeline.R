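# Pipeline orchestration: normalise -> logFC -> genome sort -> segment ->
# correct -> corrected counts (-> evaluate), with a run manifest capturing
# everything needed to reproduce a run.

#' Run the full correction pipeline
#'
#' Executes the stages in order, writing all artefacts and a JSON run
#' manifest to `output_dir`. Any stage failure aborts with an error message
#' prefixed by the stage name.
#'
#' @param library_path,counts_path Input files (see [read_guide_library()]
#'   and [read_count_table()]).
#' @param plasmid_column,treatment_columns Count-table column names.
#' @param output_dir Directory for outputs (created if needed).
#' @param min_reads Plasmid filter cutoff (default 30).
#' @param pseudocount logFC pseudocount (default 0.5).
#' @param cbs A [cbs_params()] object.
#' @param correction A [correction_params()] object.
#' @param library_dialect Optional named list of column-name overrides
#'   passed to [read_guide_library()] (e.g. `list(id_col = "CODE")`).
#' @param evaluation_sets Optional list with gene-set character vectors
#'   `essential` and `non_essential`; when given, gene-level depletion calls
#'   pre/post correction are written too.
#' @return Invisibly, a list with the stage results and the manifest.
#' @export
run_pipeline <- function(library_path, counts_path, plasmid_column,
                         treatment_columns, output_dir,
                         min_reads = 30, pseudocount = 0.5,
                         cbs = cbs_params(), correction = correction_params(),
                         library_dialect = list(),
                         evaluation_sets = NULL) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("%s: %s", name, conditionMessage(e)), call. = FALSE))
  }
  log_msg <- function(...) message(sprintf(...))

  lib <- stage("read_library",
               do.call(read_guide_library,
                       c(list(path = library_path), library_dialect)))
  counts <- stage("normalize",
                  read_count_table(counts_path, plasmid_column,
                                   treatment_columns))
  log_msg("read %d guides, %d replicates", length(counts$guides),
          ncol(counts$treatments))

  flt <- stage("normalize", filter_low_plasmid(counts, min_reads))
  norm <- stage("normalize", median_ratio_normalise(flt$counts))
  log_msg("normalize: %d guides in, %d filtered (plasmid < %d reads)",
          length(counts$guides), length(flt$removed), min_reads)
  lfc <- stage("normalize", compute_logfc(norm, pseudocount))

  profile <- stage("sort", sort_by_genome(lfc, lib))
  log_msg("sort: %d guides ordered, %d dropped (no annotation)",
          nrow(profile), attr(profile, "n_dropped"))

  segs <- stage("segment", segment_genome(profile, cbs))
  log_msg("segment: %d segments over %d chromosomes", nrow(segs),
          length(unique(segs$chrom)))

  corr <- stage("correct", correct_profile(profile, segs, correction))
  log_msg("correct: %d of %d segments centered",
          sum(corr$segments$corrected), nrow(corr$segments))

  cc <- stage("counts", {
    norm_kept <- subset_count_table(norm$table,
                                    corr$corrected_profile$guide_id)
    invert_to_counts(corr$corrected_profile, norm_kept)
  })

  out <- function(f) file.path(output_dir, f)
  write_count_table(norm$table, out("normalised_counts.tsv"))
  write_tsv_precise(data.frame(sample = names(norm$size_factors),
                               size_factor = unname(norm$size_factors)),
                    out("size_factors.tsv"))
  write_tsv_precise(profile, out("logfc_uncorrected.tsv"))
  write_tsv_precise(corr$corrected_profile, out("logfc_corrected.tsv"))
  write_segment_report(corr$segments, out("segments.tsv"))
  write_tsv_precise(data.frame(guide_id = corr$corrected_profile$guide_id,
                               offset = corr$offsets),
                    out("offsets.tsv"))
  write_count_table(cc$table, out("corrected_counts.tsv"))

  eval_res <- NULL
  if (!is.null(evaluation_sets)) {
    eval_res <- stage("evaluate", {
      pre <- call_genes(profile, evaluation_sets$essential,
                        evaluation_sets$non_essential)
      post <- call_genes(corr$corrected_profile, evaluation_sets$essential,
                         evaluation_sets$non_essential)
      list(pre = pre, post = post)
    })
    write_tsv_precise(
      data.frame(stage = c("pre", "post"),
                 k_star = c(eval_res$pre$k_star, eval_res$post$k_star),
                 f_star = c(eval_res$pre$f_star, eval_res$post$f_star),
                 n_called = c(length(eval_res$pre$called),
                              length(eval_res$post$called))),
      out("depletion_calls.tsv"))
  }

  manifest <- list(
    tool = "screenseg", version = as.character(packageVersion("screenseg")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    parameters = list(min_reads = min_reads, pseudocount = pseudocount,
                      alpha = cbs$alpha, nperm = cbs$nperm,
                      min_width = cbs$min_width, seed = cbs$seed,
                      min_genes = correction$min_genes,
                      center = correction$center),
    inputs = list(library = unname(tools::md5sum(library_path)),
                  counts = unname(tools::md5sum(counts_path))),
    guides = list(input = length(counts$guides),
                  plasmid_filtered = length(flt$removed),
                  unannotated_dropped = attr(profile, "n_dropped"),
                  analysed = nrow(profile)))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(list(profile = profile, segments = segs, correction = corr,
                 corrected_counts = cc, normalisation = norm,
                 evaluation = eval_res, manifest = manifest))
}

subset_count_table <- function(ct, guide_ids) {
  keep <- match(guide_ids, ct$guides)
  if (anyNA(keep)) stop("guides missing from count table", call. = FALSE)
  count_table(ct$guides[keep], ct$genes[keep], ct$plasmid[keep],
              ct$treatments[keep, , drop = FALSE], normalised = ct$normalised)
}

#' Write the files of a simulated screen
#'
#' Emits library, counts and ground-truth TSVs for a [simulate_screen()]
#' result, in the dialects the readers of this package expect.
#'
#' @param sim Result of [simulate_screen()] or [worked_fixture()].
#' @param output_dir Target directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_simulated_screen <- function(sim, output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  lib_path <- file.path(output_dir, "library.tsv")
  counts_path <- file.path(output_dir, "counts.tsv")
  truth_path <- file.path(output_dir, "truth_genes.tsv")
  lib <- sim$library
  names(lib) <- c("sgRNA", "gene", "chr", "start", "end")
  write_tsv_precise(lib, lib_path)
  write_count_table(sim$counts, counts_path)
  write_tsv_precise(sim$truth$genes, truth_path)
  invisible(c(library = lib_path, counts = counts_path, truth = truth_path))
}
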