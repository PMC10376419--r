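#' Read a genus-level count table
#'
#' Reads a TSV/CSV count table into the canonical orientation (samples as
#' rows, genera as columns). Orientation can be forced with `dialect` or
#' auto-detected: if every row name matches a column of the metadata-style id
#' pattern the table is kept as-is; with `dialect = "auto"` the table is
#' transposed when it has more rows than a typical cohort and fewer columns
#' (heuristic: taxa-as-rows files are taller than wide).
#'
#' @param path file path; first column holds ids, first row is a header.
#' @param dialect `"samples-as-rows"`, `"taxa-as-rows"`, or `"auto"`.
#' @param sep field separator; default tab.
#' @param min_depth samples with total count below this are dropped with a
#'   message (default 1, i.e. only all-zero samples are dropped).
#' @return integer matrix (samples x taxa) with unique dimnames; taxa whose
#'   total count is zero are retained and listed in
#'   `attr(, "zero_taxa")`.
#' @export
read_count_table <- function(path, dialect = c("samples-as-rows",
                                               "taxa-as-rows", "auto"),
                             sep = "\t", min_depth = 1) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) format_error(paste0("file not found: ", path))
  df <- utils::read.delim(path, sep = sep, header = TRUE, row.names = 1,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m)) format_error("count table body must be numeric")
  if (dialect == "taxa-as-rows" ||
      (dialect == "auto" && nrow(m) > 3 * ncol(m))) m <- t(m)
  validate_counts(m, min_depth = min_depth)
}

validate_counts <- function(m, min_depth = 1) {
  bad <- which(m < 0 | m != round(m), arr.ind = TRUE)
  if (nrow(bad) > 0)
    format_error(sprintf(
      "negative or non-integer count at sample '%s', taxon '%s'",
      rownames(m)[bad[1, 1]] %||% bad[1, 1],
      colnames(m)[bad[1, 2]] %||% bad[1, 2]))
  if (anyDuplicated(rownames(m))) format_error("duplicate sample ids")
  if (anyDuplicated(colnames(m))) format_error("duplicate taxon ids")
  depth <- rowSums(m)
  drop <- depth < max(min_depth, 1)
  if (any(drop)) {
    message("dropping ", sum(drop), " sample(s) below min depth: ",
            paste(rownames(m)[drop], collapse = ", "))
    m <- m[!drop, , drop = FALSE]
  }
  storage.mode(m) <- "integer"
  zero_taxa <- colnames(m)[colSums(m) == 0]
  attr(m, "zero_taxa") <- zero_taxa
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a count table as TSV
#'
#' Samples as rows, sample id in the first column, genus names as the header.
#' @param counts samples x taxa matrix.
#' @param path output path.
#' @export
write_count_table <- function(counts, path) {
  df <- data.frame(sample_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample metadata table
#'
#' CSV/TSV with columns `sample_id`, `sex` (male/female), `group`
#' (case/control; `MCI` is accepted as a synonym for case), and optional
#' `age`, `bmi`.
#'
#' @param path file path.
#' @param sep field separator, guessed from the extension by default.
#' @return a validated data.frame.
#' @export
read_sample_metadata <- function(path,
                                 sep = if (grepl("\\.tsv$", path)) "\t" else ",") {
  if (!file.exists(path)) format_error(paste0("file not found: ", path))
  df <- utils::read.delim(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE)
  validate_metadata(df)
}

validate_metadata <- function(df) {
  need <- c("sample_id", "sex", "group")
  miss <- setdiff(need, names(df))
  if (length(miss))
    format_error(paste0("metadata lacks column(s): ",
                        paste(miss, collapse = ", ")))
  if (anyDuplicated(df$sample_id)) format_error("duplicate sample ids in metadata")
  df$sex <- tolower(df$sex)
  df$group <- tolower(df$group)
  df$group[df$group == "mci"] <- "case"
  if (!all(df$sex %in% c("male", "female")))
    format_error("sex must be 'male' or 'female'")
  if (!all(df$group %in% c("case", "control")))
    format_error("group must be 'case'/'MCI' or 'control'")
  df
}

#' Align a count table with its metadata
#'
#' Restricts both inputs to the intersection of their sample ids, in the
#' count table's order, and reports any samples dropped. Idempotent.
#'
#' @param counts samples x taxa matrix.
#' @param metadata data.frame with a `sample_id` column.
#' @return list with elements `counts` and `metadata`, identically ordered.
#' @export
align_samples <- function(counts, metadata) {
  ids <- intersect(rownames(counts), metadata$sample_id)
  dropped <- c(setdiff(rownames(counts), ids),
               setdiff(metadata$sample_id, ids))
  if (length(dropped))
    message("align_samples: dropping ", length(dropped),
            " unmatched sample(s)")
  counts <- counts[ids, , drop = FALSE]
  metadata <- metadata[match(ids, metadata$sample_id), , drop = FALSE]
  rownames(metadata) <- NULL
  tab <- table(metadata$group)
  if (length(ids) == 0 || length(tab) < 2 || any(tab < 2))
    data_error("need at least 2 samples per group after alignment")
  list(counts = counts, metadata = metadata)
}

#' Write an effect-size table as TSV
#' @param effects a `taxon_effects` data.frame from [aldex_effects()].
#' @param path output path.
#' @export
write_effects <- function(effects, path) {
  utils::write.table(effects, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an effect-size table written by [write_effects()]
#' @param path TSV path.
#' @return a `taxon_effects` data.frame.
#' @export
read_effects <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  class(df) <- c("taxon_effects", "data.frame")
  df
}

#' Write nested results (SEM fits, ROC curves, reports) as JSON
#' @param x a list-like result object.
#' @param path output path.
#' @export
write_results_json <- function(x, path) {
  jsonlite::write_json(strip_for_json(x), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a JSON result bundle
#' @param path JSON path.
#' @export
read_results_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

strip_for_json <- function(x) {
  if (is.function(x) || is.environment(x)) return(NULL)
  if (is.list(x)) {
    x <- lapply(unclass(x), strip_for_json)
    x[!vapply(x, is.null, logical(1))]
  } else if (is.matrix(x)) {
    apply(x, 1, identity, simplify = FALSE)
  } else x
}
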