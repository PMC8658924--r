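#' Read a GEO series-matrix file
#'
#' Parses the tab-separated expression table embedded between the
#' `!series_matrix_table_begin` and `!series_matrix_table_end` marker lines of
#' a GEO series-matrix file (plain text or gzip-compressed). Metadata lines
#' (prefix `!`) are ignored; condition and time metadata come from a sidecar
#' annotation table instead, because GEO sample titles encode them in
#' accession-specific ways.
#'
#' Columns are restricted to the annotated samples, in file order. Rows whose
#' values are all missing are dropped with a message; a missing value inside an
#' otherwise present row is an error, because the downstream decomposition has
#' no missing-data handling. Values are used exactly as stored: no log
#' transform and no renormalization is applied before the pipeline's own
#' standardization.
#'
#' @param path series-matrix file, `.txt` or `.txt.gz`.
#' @param annotation data.frame as returned by [read_annotation()]: columns
#'   `sample_id`, `condition`, `time_h`. Every annotated sample must be present
#'   in the file.
#' @return An [expression_matrix()].
#' @export
read_series_matrix <- function(path, annotation) {
  annotation <- validate_annotation(annotation)
  lines <- readLines(gzfile(path))
  begin <- grep("^!series_matrix_table_begin", lines)
  end <- grep("^!series_matrix_table_end", lines)
  if (length(begin) != 1L || length(end) != 1L || end <= begin + 1L) {
    offending <- if (!length(begin)) "(missing !series_matrix_table_begin)"
                 else lines[begin[1L]]
    stop("malformed series-matrix table block near: ", offending, call. = FALSE)
  }
  block <- lines[(begin + 1L):(end - 1L)]
  fields <- strsplit(block, "\t", fixed = TRUE)
  unquote <- function(x) gsub('^"|"$', "", x)
  header <- unquote(fields[[1L]])
  if (header[1L] != "ID_REF")
    stop("malformed series-matrix table block: first header cell is '",
         header[1L], "', expected 'ID_REF' (line ", begin + 1L, ")",
         call. = FALSE)
  file_samples <- header[-1L]

  missing_ids <- setdiff(annotation$sample_id, file_samples)
  if (length(missing_ids))
    stop("annotated samples absent from file: ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  keep <- which(file_samples %in% annotation$sample_id)

  ncells <- length(header)
  rows <- vapply(fields[-1L], function(f) {
    length(f) <- ncells
    f
  }, character(ncells))                      # cells x probe-lines
  ids <- unquote(rows[1L, ])
  kept_samples <- file_samples[keep]
  cells <- rows[1L + keep, , drop = FALSE]   # retained samples x probes
  is_missing <- is.na(cells) | cells %in% c("", "null", "NULL", "NA")
  vals <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
  bad <- which(is.na(vals) & !is_missing, arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf(
      "non-numeric value '%s' in data block at probe row %d ('%s'), sample column %d ('%s')",
      cells[bad[1L, 1L], bad[1L, 2L]], bad[1L, 2L], ids[bad[1L, 2L]],
      bad[1L, 1L], kept_samples[bad[1L, 1L]]), call. = FALSE)
  }
  vals <- t(vals)                            # probes x retained samples
  all_missing <- rowSums(!is.na(vals)) == 0L
  if (any(all_missing)) {
    message("dropping ", sum(all_missing), " probe row(s) with all values missing: ",
            paste(utils::head(ids[all_missing], 5L), collapse = ", "),
            if (sum(all_missing) > 5L) ", ..." else "")
    vals <- vals[!all_missing, , drop = FALSE]
    ids <- ids[!all_missing]
  }
  if (anyNA(vals)) {
    at <- which(is.na(vals), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing value at probe '%s', sample '%s' (partial missingness is not supported)",
                 ids[at[1L]], kept_samples[at[2L]]), call. = FALSE)
  }
  rownames(vals) <- ids
  colnames(vals) <- kept_samples
  idx <- match(colnames(vals), annotation$sample_id)
  expression_matrix(vals,
                    condition = annotation$condition[idx],
                    time_h = annotation$time_h[idx])
}

#' Write an expression matrix in the series-matrix dialect
#'
#' Emits a minimal file that [read_series_matrix()] parses back losslessly:
#' a few `!` header lines, the `!series_matrix_table_begin` / `_end` delimited
#' tab-separated table with a quoted `"ID_REF"` header and quoted probe ids.
#' Used by the synthetic-data command so the reader is exercised end to end.
#'
#' @param m an [expression_matrix()].
#' @param path output path; a `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_series_matrix <- function(m, path) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(c(
    "!Series_title\t\"synthetic time-course expression\"",
    sprintf("!Sample_geo_accession\t%s",
            paste(sprintf('"%s"', sample_ids(m)), collapse = "\t")),
    "!series_matrix_table_begin"), con)
  header <- paste(c('"ID_REF"', sprintf('"%s"', sample_ids(m))), collapse = "\t")
  body <- paste(sprintf('"%s"', probe_ids(m)),
                apply(m$values, 1L, function(r)
                  paste(sprintf("%.17g", r), collapse = "\t")),
                sep = "\t")
  writeLines(c(header, body, "!series_matrix_table_end"), con)
  invisible(path)
}

#' Read and validate a sample-annotation sidecar table
#'
#' Tab-separated with header `sample_id`, `condition`, `time_h`; one row per
#' sample, condition in `{treated, control}`, time in hours.
#'
#' @param path annotation TSV.
#' @return Validated data.frame.
#' @export
read_annotation <- function(path) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_annotation(ann)
}

validate_annotation <- function(ann) {
  need <- c("sample_id", "condition", "time_h")
  if (!all(need %in% names(ann)))
    stop("annotation must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  ann$sample_id <- as.character(ann$sample_id)
  ann$condition <- as.character(ann$condition)
  ann$time_h <- as.numeric(ann$time_h)
  if (anyDuplicated(ann$sample_id))
    stop("duplicate sample_id in annotation", call. = FALSE)
  bad <- setdiff(unique(ann$condition), c("treated", "control"))
  if (length(bad))
    stop("annotation condition must be 'treated' or 'control'; found: ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (any(!is.finite(ann$time_h)) || any(ann$time_h < 0))
    stop("annotation time_h must be finite nonnegative hours", call. = FALSE)
  ann
}

#' Write a probe score report
#'
#' Tab-separated, one row per probe in input order, columns `probe_id`,
#' `statistic`, `p_value`, `adjusted_p`, `selected`. Numeric columns are
#' written with 15 significant digits so a round trip preserves p-values well
#' beyond 12 significant digits. Optional `#`-prefixed header comments record
#' the run configuration; the reader skips them.
#'
#' @param scores data.frame with at least the five report columns (the probe
#'   score table of [run_pca_fe()] or the result table of [run_linreg_fe()]).
#' @param path output TSV path.
#' @param header_comments character vector written as `# `-prefixed lines
#'   before the header.
#' @return `path`, invisibly.
#' @export
write_probe_report <- function(scores, path, header_comments = character()) {
  cols <- c("probe_id", "statistic", "p_value", "adjusted_p", "selected")
  if (!is.data.frame(scores) || nrow(scores) == 0L)
    stop("scores table is empty; nothing to report", call. = FALSE)
  if (!all(cols %in% names(scores)))
    stop("scores table lacks columns: ",
         paste(setdiff(cols, names(scores)), collapse = ", "), call. = FALSE)
  out <- scores[, cols]
  for (nm in c("statistic", "p_value", "adjusted_p"))
    out[[nm]] <- sprintf("%.15g", out[[nm]])
  out$selected <- ifelse(scores$selected, "TRUE", "FALSE")
  con <- file(path, "wt")
  on.exit(close(con))
  if (length(header_comments))
    writeLines(paste0("# ", header_comments), con)
  writeLines(paste(cols, collapse = "\t"), con)
  writeLines(do.call(paste, c(unname(out), sep = "\t")), con)
  invisible(path)
}

#' Read back a probe report written by [write_probe_report()]
#' @param path report TSV path.
#' @return data.frame with the five report columns.
#' @export
read_probe_report <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  df$selected <- as.logical(df$selected)
  df
}

#' Export the selected probes as a gene list
#'
#' One symbol per line, suitable for pasting into enrichment web services.
#' Only probes flagged `selected` are exported. With a probe-to-symbol mapping
#' (two-column data.frame `probe_id`, `symbol`, e.g. a GPL annotation export),
#' duplicate symbols are collapsed to their first occurrence and unmapped
#' probes are skipped with a message; without a mapping, probe ids are emitted.
#'
#' @param scores probe score table with `probe_id` and `selected` columns.
#' @param path output text file.
#' @param mapping optional data.frame with columns `probe_id`, `symbol`.
#' @return Character vector of exported lines, invisibly.
#' @export
export_gene_list <- function(scores, path, mapping = NULL) {
  sel <- scores$probe_id[scores$selected]
  if (!length(sel)) {
    warning("no probes selected; writing empty gene list", call. = FALSE)
    writeLines(character(), path)
    return(invisible(character()))
  }
  if (is.null(mapping)) {
    out <- sel
  } else {
    if (!all(c("probe_id", "symbol") %in% names(mapping)))
      stop("mapping must have columns probe_id, symbol", call. = FALSE)
    idx <- match(sel, mapping$probe_id)
    unmapped <- sel[is.na(idx)]
    if (length(unmapped))
      message("skipping ", length(unmapped), " unmapped probe(s): ",
              paste(utils::head(unmapped, 5L), collapse = ", "),
              if (length(unmapped) > 5L) ", ..." else "")
    out <- unique(mapping$symbol[idx[!is.na(idx)]])
  }
  writeLines(out, path)
  invisible(out)
}

#' Read a two-column probe-to-symbol mapping TSV
#' @param path TSV with header `probe_id`, `symbol`.
#' @return data.frame.
#' @export
read_probe_mapping <- function(path) {
  mp <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("probe_id", "symbol") %in% names(mp)))
    stop("mapping file must have columns probe_id, symbol", call. = FALSE)
  mp
}
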