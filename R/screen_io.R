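# I/O for guide libraries, count tables and segment reports, plus the
# canonical genome ordering used by segmentation.

#' Read an sgRNA library annotation table
#'
#' Parses a delimited text file mapping each sgRNA to its target gene and
#' genomic location. Column names are configurable so that library exports
#' with different headers can be read without editing the file.
#'
#' @param path Path to a TSV/CSV file with a header row.
#' @param id_col,gene_col,chrom_col,start_col,end_col Names of the columns
#'   holding the guide identifier, gene symbol, chromosome, and 1-based
#'   inclusive start/end coordinates. If `end_col` is absent from the file
#'   the end defaults to the start coordinate.
#' @param sep Field separator; `NULL` (default) auto-detects tab vs comma
#'   from the header line.
#' @return A `data.frame` with columns `guide_id`, `gene`, `chrom`, `start`,
#'   `end`, in file order.
#' @export
read_guide_library <- function(path, id_col = "sgRNA", gene_col = "gene",
                               chrom_col = "chr", start_col = "start",
                               end_col = "end", sep = NULL) {
  stopifnot(file.exists(path))
  if (is.null(sep)) sep <- detect_sep(path)
  tab <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE, quote = "", comment.char = "")
  needed <- c(id_col, gene_col, chrom_col, start_col)
  missing_cols <- setdiff(needed, names(tab))
  if (length(missing_cols) > 0L)
    stop("library file is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  lib <- data.frame(
    guide_id = as.character(tab[[id_col]]),
    gene     = as.character(tab[[gene_col]]),
    chrom    = as.character(tab[[chrom_col]]),
    start    = as.numeric(tab[[start_col]]),
    stringsAsFactors = FALSE
  )
  lib$end <- if (end_col %in% names(tab)) as.numeric(tab[[end_col]]) else lib$start
  validate_library(lib)
  lib
}

validate_library <- function(lib) {
  dup <- unique(lib$guide_id[duplicated(lib$guide_id)])
  if (length(dup) > 0L)
    stop("duplicated guide_id(s) in library: ", paste(dup, collapse = ", "),
         call. = FALSE)
  if (any(!nzchar(lib$chrom) | is.na(lib$chrom)))
    stop("empty chromosome name in library", call. = FALSE)
  bad <- which(lib$end < lib$start)
  if (length(bad) > 0L)
    stop("library rows with end < start: ", paste(head(bad, 5), collapse = ", "),
         call. = FALSE)
  invisible(lib)
}

detect_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else ","
}

#' Construct a count table
#'
#' A count table holds one plasmid (library control) column and `n >= 1`
#' treatment replicate columns of per-guide read counts.
#'
#' @param guides Character vector of guide identifiers.
#' @param genes Character vector of gene symbols, parallel to `guides`.
#' @param plasmid Numeric vector of plasmid counts.
#' @param treatments Numeric matrix (guides x replicates) of treatment counts.
#' @param normalised Logical; whether counts have been normalised.
#' @return An object of class `count_table`.
#' @export
count_table <- function(guides, genes, plasmid, treatments,
                        normalised = FALSE) {
  treatments <- as.matrix(treatments)
  stopifnot(length(guides) == length(plasmid),
            length(guides) == length(genes),
            nrow(treatments) == length(guides))
  if (ncol(treatments) < 1L)
    stop("at least one treatment replicate column is required", call. = FALSE)
  if (any(plasmid < 0) || any(treatments < 0))
    stop("counts must be non-negative", call. = FALSE)
  if (anyDuplicated(guides))
    stop("duplicated guide_id(s) in count table", call. = FALSE)
  if (is.null(colnames(treatments)))
    colnames(treatments) <- paste0("rep", seq_len(ncol(treatments)))
  structure(list(guides = as.character(guides), genes = as.character(genes),
                 plasmid = as.numeric(plasmid), treatments = treatments,
                 normalised = isTRUE(normalised)),
            class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d guides, %d gene(s), %d replicate(s), %s\n",
              length(x$guides), length(unique(x$genes)),
              ncol(x$treatments),
              if (x$normalised) "normalised" else "raw"))
  invisible(x)
}

#' @export
as.data.frame.count_table <- function(x, ...) {
  out <- data.frame(sgRNA = x$guides, gene = x$genes, plasmid = x$plasmid,
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(x$treatments))
}

#' Read a read-count table
#'
#' Reads a delimited file with header `sgRNA gene <sample names...>` into a
#' [count_table()]. Any negative or non-numeric count aborts with the
#' offending row index.
#'
#' @param path Path to the counts file.
#' @param plasmid_column Name of the plasmid count column.
#' @param treatment_columns Character vector of treatment column names
#'   (length >= 1).
#' @param id_col,gene_col Names of the guide-identifier and gene columns.
#' @param sep Field separator; auto-detected when `NULL`.
#' @return A `count_table` with `normalised = FALSE`, in file order.
#' @export
read_count_table <- function(path, plasmid_column, treatment_columns,
                             id_col = "sgRNA", gene_col = "gene", sep = NULL) {
  stopifnot(file.exists(path))
  if (length(treatment_columns) < 1L)
    stop("at least one treatment column must be named", call. = FALSE)
  if (is.null(sep)) sep <- detect_sep(path)
  tab <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE, quote = "", comment.char = "")
  needed <- c(id_col, gene_col, plasmid_column, treatment_columns)
  missing_cols <- setdiff(needed, names(tab))
  if (length(missing_cols) > 0L)
    stop("counts file is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  for (cn in c(plasmid_column, treatment_columns)) {
    v <- suppressWarnings(as.numeric(tab[[cn]]))
    bad <- which(is.na(v) | v < 0)
    if (length(bad) > 0L)
      stop(sprintf("invalid count in column '%s' at row %d", cn, bad[1]),
           call. = FALSE)
    tab[[cn]] <- v
  }
  count_table(guides = tab[[id_col]], genes = tab[[gene_col]],
              plasmid = tab[[plasmid_column]],
              treatments = as.matrix(tab[, treatment_columns, drop = FALSE]),
              normalised = FALSE)
}

#' Write a count table
#'
#' Emits the `sgRNA gene <samples...>` tab-delimited dialect read by
#' [read_count_table()]. Reals are written with 15 significant digits so a
#' write/read round trip preserves integers exactly and reals to at least 12
#' significant digits.
#'
#' @param ct A `count_table`.
#' @param path Output path.
#' @param plasmid_name Column name to use for the plasmid counts.
#' @export
write_count_table <- function(ct, path, plasmid_name = "plasmid") {
  stopifnot(inherits(ct, "count_table"))
  df <- as.data.frame(ct)
  names(df)[names(df) == "plasmid"] <- plasmid_name
  write_tsv_precise(df, path)
  invisible(path)
}

write_tsv_precise <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  for (cn in names(df)[num]) {
    v <- df[[cn]]
    df[[cn]] <- ifelse(is.finite(v) & v == round(v) & abs(v) < 2^53,
                       sprintf("%.0f", v), sprintf("%.15g", v))
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Order a fold-change profile along the genome
#'
#' Joins per-guide values with the library annotation and sorts them by
#' chromosome (in `chrom_order`) and start coordinate, the ordering on which
#' segmentation operates. Guides absent from the library are dropped and
#' counted. Ties in (chromosome, start) are broken by guide identifier so the
#' ordering is deterministic; the operation is idempotent.
#'
#' @param profile A `data.frame` with columns `guide_id` and `logfc` (other
#'   columns are preserved).
#' @param library Library annotation as returned by [read_guide_library()].
#' @param chrom_order Character vector giving the chromosome order; defaults
#'   to natural order (1..22, X, Y, then unknown names alphabetically).
#' @return A `data.frame` with columns `guide_id`, `gene`, `chrom`, `start`,
#'   `end`, `logfc`, genome-ordered, with attribute `n_dropped` giving the
#'   number of guides discarded for lacking library annotation.
#' @export
sort_by_genome <- function(profile, library, chrom_order = NULL) {
  stopifnot(is.data.frame(profile), all(c("guide_id", "logfc") %in% names(profile)))
  idx <- match(profile$guide_id, library$guide_id)
  dropped <- profile$guide_id[is.na(idx)]
  if (length(dropped) > 0L)
    warning(length(dropped), " guide(s) absent from the library were dropped",
            call. = FALSE)
  keep <- !is.na(idx)
  out <- data.frame(
    guide_id = profile$guide_id[keep],
    gene     = library$gene[idx[keep]],
    chrom    = library$chrom[idx[keep]],
    start    = library$start[idx[keep]],
    end      = library$end[idx[keep]],
    logfc    = profile$logfc[keep],
    stringsAsFactors = FALSE
  )
  if (is.null(chrom_order)) chrom_order <- default_chrom_order(out$chrom)
  chr_rank <- match(out$chrom, chrom_order)
  unknown <- is.na(chr_rank)
  if (any(unknown)) {
    extra <- sort(unique(out$chrom[unknown]))
    chr_rank[unknown] <- length(chrom_order) + match(out$chrom[unknown], extra)
  }
  ord <- order(chr_rank, out$start, out$guide_id)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- length(dropped)
  attr(out, "dropped") <- dropped
  out
}

#' Natural chromosome order
#'
#' Orders chromosome names numerically (1..22) followed by X and Y;
#' any other names sort last, alphabetically. `chr` prefixes are honoured.
#'
#' @param chroms Character vector of chromosome names (may repeat).
#' @return Character vector of unique chromosome names in natural order.
#' @export
default_chrom_order <- function(chroms) {
  u <- unique(as.character(chroms))
  core <- sub("^chr", "", u)
  num <- suppressWarnings(as.numeric(core))
  rank <- ifelse(!is.na(num), num,
                 ifelse(core == "X", 23, ifelse(core == "Y", 24, NA)))
  known <- u[!is.na(rank)]
  known <- known[order(rank[!is.na(rank)])]
  unknown <- sort(u[is.na(rank)])
  c(known, unknown)
}

#' Write a segment report
#'
#' BED-like tab-delimited report: chromosome, start position of the first
#' guide, end position of the last guide, segment mean logFC, number of
#' guides, number of distinct genes, and whether the segment was corrected.
#'
#' @param segments Segment `data.frame` as produced by [segment_genome()]
#'   (optionally carrying a `corrected` column from [correct_profile()]).
#' @param path Output path.
#' @export
write_segment_report <- function(segments, path) {
  cols <- c("chrom", "start_bp", "end_bp", "seg_mean", "n_guides", "n_genes")
  stopifnot(all(cols %in% names(segments)))
  out <- segments[, cols, drop = FALSE]
  out$corrected <- if ("corrected" %in% names(segments))
    as.integer(segments$corrected) else 0L
  write_tsv_precise(out, path)
  invisible(path)
}

#' Read a segment report written by [write_segment_report()]
#' @param path Path to the report.
#' @return A `data.frame` with the report columns.
#' @export
read_segment_report <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  tab$corrected <- as.logical(tab$corrected)
  tab
}
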